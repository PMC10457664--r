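# Deterministic generator of synthetic compound-target bioactivity
# landscapes carrying the structure the dynamic-calibration framework
# exploits: clustered binary fingerprints (Tanimoto reflects cluster
# membership), protein-family sequences (alignment similarity reflects
# family membership) and affinities from a latent bilinear surface plus
# Gaussian assay noise.

#' Configuration of the synthetic bioactivity landscape
#'
#' Defaults describe a modest but realistic desk-scale landscape: 256-bit
#' fingerprints (shorter than the 2048-bit production default, purely for
#' speed -- the similarity layer is parameter-generic), 24 cluster-core
#' bits, 8% background bit rate, 60-residue kinase-domain-like sequences
#' with 15% within-family substitution, a rank-4 bilinear affinity
#' surface centred at pKd 6 and assay noise of 0.6 log units, the order
#' of inter-assay variability seen in public binding databases.
#'
#' @param n_compounds,n_targets Entity counts.
#' @param n_compound_clusters,n_target_families Group counts.
#' @param fp_bits Fingerprint length.
#' @param core_bits_per_cluster Bits in each cluster's always-set core
#'   block (blocks are disjoint across clusters).
#' @param bit_flip_rate Background probability of a non-core bit.
#' @param seq_length Sequence length (no indels are introduced).
#' @param mutation_rate Per-site substitution rate within a family.
#' @param latent_dim Rank of the bilinear affinity surface.
#' @param noise_sd Assay noise standard deviation (pKd units).
#' @param density Fraction of the compound x target grid measured.
#' @param affinity_offset Surface centre (pKd-like scale).
#' @param seed Master seed; all sub-steps derive child seeds from it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds, n_targets,
                             n_compound_clusters = 5L,
                             n_target_families = 4L,
                             fp_bits = 256L, core_bits_per_cluster = 24L,
                             bit_flip_rate = 0.08, seq_length = 60L,
                             mutation_rate = 0.15, latent_dim = 4L,
                             noise_sd = 0.6, density = 1,
                             affinity_offset = 6, seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_targets = as.integer(n_targets),
              n_compound_clusters = as.integer(n_compound_clusters),
              n_target_families = as.integer(n_target_families),
              fp_bits = as.integer(fp_bits),
              core_bits_per_cluster = as.integer(core_bits_per_cluster),
              bit_flip_rate = bit_flip_rate,
              seq_length = as.integer(seq_length),
              mutation_rate = mutation_rate,
              latent_dim = as.integer(latent_dim),
              noise_sd = noise_sd, density = density,
              affinity_offset = affinity_offset, seed = as.integer(seed))
  stopifnot(cfg$n_compounds >= 1L, cfg$n_targets >= 1L,
            cfg$n_compound_clusters <= cfg$n_compounds,
            cfg$n_target_families <= cfg$n_targets,
            cfg$bit_flip_rate >= 0, cfg$bit_flip_rate < 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate < 1,
            cfg$noise_sd >= 0, cfg$density > 0, cfg$density <= 1)
  if (cfg$core_bits_per_cluster * cfg$n_compound_clusters > cfg$fp_bits) {
    stop("core bit blocks exceed the fingerprint length", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic bioactivity landscape
#'
#' Compounds: each cluster owns a disjoint core bit-block always set for
#' its members; remaining bits are set independently at `bit_flip_rate`,
#' so within-cluster Tanimoto similarity stochastically exceeds
#' between-cluster similarity.  Targets: one random ancestor sequence per
#' family; members substitute each site independently at
#' `mutation_rate`.  Affinities: `y = offset + u_c . v_t + noise` with
#' family/cluster-level latent vectors and small member-level jitter; a
#' uniformly random `density` fraction of the grid is measured.  Fully
#' reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_data` list: `compounds` ([compound_set()]),
#'   `targets` ([target_set()]), `interactions` ([interaction_table()]),
#'   `truth` (data frame of the full noise-free surface),
#'   `compound_clusters` and `target_families` (named integer vectors),
#'   and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  comp_ids <- sprintf("C%04d", seq_len(cfg$n_compounds))
  targ_ids <- sprintf("T%03d", seq_len(cfg$n_targets))
  cluster <- stats::setNames(
    rep_len(seq_len(cfg$n_compound_clusters), cfg$n_compounds), comp_ids)
  family <- stats::setNames(
    rep_len(seq_len(cfg$n_target_families), cfg$n_targets), targ_ids)

  # fingerprints: disjoint core block per cluster + background bits
  fp <- with_seed(derive_seed(cfg$seed, 101L), {
    m <- matrix(stats::rbinom(cfg$n_compounds * cfg$fp_bits, 1L,
                              cfg$bit_flip_rate),
                cfg$n_compounds, cfg$fp_bits)
    for (g in seq_len(cfg$n_compound_clusters)) {
      block <- seq.int((g - 1L) * cfg$core_bits_per_cluster + 1L,
                       g * cfg$core_bits_per_cluster)
      m[cluster == g, block] <- 1L
    }
    m
  })
  compounds <- compound_set(comp_ids, fingerprints = fp)

  # sequences: per-family ancestor, iid per-site substitution (no indels)
  aa20 <- setdiff(aa_alphabet(), "X")
  seqs <- with_seed(derive_seed(cfg$seed, 102L), {
    ancestors <- replicate(cfg$n_target_families,
                           sample(aa20, cfg$seq_length, replace = TRUE),
                           simplify = FALSE)
    vapply(seq_len(cfg$n_targets), function(i) {
      anc <- ancestors[[family[i]]]
      mut <- stats::runif(cfg$seq_length) < cfg$mutation_rate
      if (any(mut)) {
        anc[mut] <- vapply(anc[mut], function(a) {
          sample(setdiff(aa20, a), 1L)
        }, character(1L))
      }
      paste(anc, collapse = "")
    }, character(1L))
  })
  targets <- target_set(stats::setNames(seqs, targ_ids))

  # latent bilinear surface: group-level latents, member-level jitter
  d <- cfg$latent_dim
  surface <- with_seed(derive_seed(cfg$seed, 103L), {
    u_g <- matrix(stats::rnorm(cfg$n_compound_clusters * d),
                  cfg$n_compound_clusters, d)
    v_g <- matrix(stats::rnorm(cfg$n_target_families * d),
                  cfg$n_target_families, d)
    u <- u_g[cluster, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_compounds * d, sd = 0.1),
             cfg$n_compounds, d)
    v <- v_g[family, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_targets * d, sd = 0.1),
             cfg$n_targets, d)
    cfg$affinity_offset + tcrossprod(u, v) / sqrt(d)
  })
  dimnames(surface) <- list(comp_ids, targ_ids)

  grid <- expand.grid(compound_id = comp_ids, target_id = targ_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$y_true <- surface[cbind(grid$compound_id, grid$target_id)]
  n_meas <- round(cfg$density * nrow(grid))
  measured <- with_seed(derive_seed(cfg$seed, 104L),
                        sort(sample.int(nrow(grid), n_meas)))
  noise <- with_seed(derive_seed(cfg$seed, 105L),
                     stats::rnorm(n_meas, sd = cfg$noise_sd))
  interactions <- interaction_table(grid$compound_id[measured],
                                    grid$target_id[measured],
                                    grid$y_true[measured] + noise)
  structure(list(compounds = compounds, targets = targets,
                 interactions = interactions, truth = grid,
                 compound_clusters = cluster, target_families = family,
                 config = cfg),
            class = "synthetic_data")
}

#' Hold out whole clusters/families to create shifted test scenarios
#'
#' Removes `n_holdout_clusters` whole compound clusters and
#' `n_holdout_families` whole target families from training, so the
#' S2/S3/S4 scenarios exhibit genuine covariate shift rather than random
#' entity removal; S1 is a random pair holdout among seen entities.
#' Invariant checking is delegated to [validate_scenario_split()].
#'
#' @param generated A `synthetic_data` object from [synth_generate()].
#' @param n_holdout_clusters,n_holdout_families Whole groups to hold out
#'   (must be smaller than the totals).
#' @param s1_fraction Fraction of remaining pairs held out as S1.
#' @param seed Integer seed (defaults to the generator seed).
#' @return A `scenario_split`.
#' @export
shift_holdout <- function(generated, n_holdout_clusters = 1L,
                          n_holdout_families = 1L, s1_fraction = 0.1,
                          seed = generated$config$seed) {
  stopifnot(inherits(generated, "synthetic_data"))
  cfg <- generated$config
  if (n_holdout_clusters >= cfg$n_compound_clusters ||
      n_holdout_families >= cfg$n_target_families) {
    stop("cannot hold out all clusters or families", call. = FALSE)
  }
  cl <- generated$compound_clusters
  fam <- generated$target_families
  held_cl <- if (n_holdout_clusters > 0L) {
    with_seed(derive_seed(seed, 201L),
              sample(seq_len(cfg$n_compound_clusters), n_holdout_clusters))
  } else integer(0)
  held_fam <- if (n_holdout_families > 0L) {
    with_seed(derive_seed(seed, 202L),
              sample(seq_len(cfg$n_target_families), n_holdout_families))
  } else integer(0)
  build_scenarios(generated$interactions,
                  held_c = names(cl)[cl %in% held_cl],
                  held_t = names(fam)[fam %in% held_fam],
                  s1_fraction = s1_fraction,
                  s1_seed = derive_seed(seed, 203L))
}

#' Write a synthetic landscape to a fixture directory
#'
#' Emits `compounds.tsv` (id + fingerprint bitstring), `targets.fasta`,
#' `interactions.tsv` and `truth.tsv` as plain text.
#'
#' @param generated A `synthetic_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(generated, dir) {
  stopifnot(inherits(generated, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- generated$compounds$fingerprints
  utils::write.table(
    data.frame(id = generated$compounds$ids,
               fingerprint = apply(fp, 1L, paste, collapse = "")),
    file.path(dir, "compounds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(paste0(">", names(generated$targets), "\n",
                    unclass(generated$targets)),
             file.path(dir, "targets.fasta"))
  utils::write.table(
    data.frame(compound_id = generated$interactions$compound_id,
               target_id = generated$interactions$target_id,
               affinity = fmt6(generated$interactions$affinity)),
    file.path(dir, "interactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(compound_id = generated$truth$compound_id,
               target_id = generated$truth$target_id,
               y_true = fmt6(generated$truth$y_true)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
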