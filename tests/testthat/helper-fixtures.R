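# Fixture builders shared across test files.  Everything is generated in
# code at test time; the larger validity study is computed once per test
# run and memoized.

fast_knn_spec <- function(k = 15L) {
  regressor_spec("knn_baseline", list(k = k))
}

# Small landscape + similarity sources + shifted split, for structural
# and behavioural tests.
tiny_landscape <- function(seed = 3L, n_compounds = 40L, n_targets = 12L,
                           density = 0.9, noise_sd = 0.6,
                           holdout = c(1L, 1L), s1_fraction = 0.2) {
  cfg <- synthetic_config(n_compounds = n_compounds, n_targets = n_targets,
                          n_compound_clusters = 4L, n_target_families = 3L,
                          density = density, noise_sd = noise_sd,
                          seed = seed)
  g <- synth_generate(cfg)
  list(g = g,
       cs = build_similarity_matrix(g$compounds, "compound"),
       ts = build_similarity_matrix(g$targets, "target"),
       split = shift_holdout(g, holdout[1], holdout[2],
                             s1_fraction = s1_fraction))
}

# Hand-built similarity matrix from a named square matrix-like spec.
manual_sim <- function(values, ids) similarity_matrix(values, ids)

# The exchangeable S1 validity study: 125 compounds x 48 targets, 5/6 of
# the grid measured (5000 pairs), 2000 random S1 test pairs, 3000
# training pairs, assay noise 0.6; a kNN point model; the
# absolute-residual conformal regressor with a 500-pair calibration
# split; and both dynamic-calibration variants with k = 25 compound /
# q = 10 target neighbours.  Ten replicate landscapes.
validity_study_env <- new.env(parent = emptyenv())

validity_study <- function(n_seeds = 10L) {
  key <- paste0("study_", n_seeds)
  if (!is.null(validity_study_env[[key]])) return(validity_study_env[[key]])
  levels <- confidence_grid()
  spec <- fast_knn_spec()
  per_seed <- lapply(seq_len(n_seeds), function(s) {
    cfg <- synthetic_config(n_compounds = 125L, n_targets = 48L,
                            n_compound_clusters = 5L,
                            n_target_families = 4L, density = 5 / 6,
                            noise_sd = 0.6, seed = s)
    g <- synth_generate(cfg)
    cs <- build_similarity_matrix(g$compounds, "compound")
    ts <- build_similarity_matrix(g$targets, "target")
    sp <- shift_holdout(g, 0L, 0L, s1_fraction = 0.4)
    truths <- region_truths(sp$tests$S1)

    shafer <- icp_fit(sp$train, "shafer", g$compounds, cs, ts,
                      spec = spec, calibration = 500L,
                      seed = 1000L + s)
    r_shafer <- predict(shafer, sp$tests$S1, confidence = levels)

    dad <- dad_fit(sp$train, g$compounds, cs, ts, spec = spec,
                   seed = 2000L + s)
    nbhd <- neighborhood(k = 25L, q = 10L)
    regions <- list(
      shafer = r_shafer,
      dad_cv = predict(dad, sp$tests$S1, confidence = levels,
                       variant = "cv", nbhd = nbhd),
      dad_nn = predict(dad, sp$tests$S1, confidence = levels,
                       variant = "nn", nbhd = nbhd))
    metrics <- do.call(rbind, lapply(names(regions), function(m) {
      do.call(rbind, lapply(levels, function(lv) {
        sub <- regions[[m]][regions[[m]]$confidence == lv, , drop = FALSE]
        data.frame(seed = s, method = m, level = lv,
                   n_errors = round(error_rate(sub, truths) *
                                      sum(!sub$abstained)),
                   n_covered = sum(!sub$abstained), n_test = nrow(sub))
      }))
    }))
    # per-pair monotonicity of the region half-width in the confidence
    mono_violations <- vapply(c("dad_cv", "dad_nn"), function(m) {
      r <- regions[[m]]
      lo <- r[r$confidence == min(levels), ]
      hi <- r[r$confidence == max(levels), ]
      both <- !lo$abstained & !hi$abstained
      sum(hi$alpha[both] < lo$alpha[both])
    }, numeric(1L))
    list(metrics = metrics, mono_violations = mono_violations,
         n_both_covered = vapply(c("dad_cv", "dad_nn"), function(m) {
           r <- regions[[m]]
           sum(!r[r$confidence == min(levels), ]$abstained &
                 !r[r$confidence == max(levels), ]$abstained)
         }, numeric(1L)))
  })
  study <- list(
    metrics = do.call(rbind, lapply(per_seed, `[[`, "metrics")),
    mono_violations = Reduce(`+`, lapply(per_seed, `[[`,
                                         "mono_violations")),
    n_both_covered = Reduce(`+`, lapply(per_seed, `[[`, "n_both_covered")),
    n_test_per_seed = 2000L, levels = levels, n_seeds = n_seeds)
  validity_study_env[[key]] <- study
  study
}

# Pooled error rate per (method, level) across study seeds.
study_error <- function(study, method) {
  m <- study$metrics[study$metrics$method == method, , drop = FALSE]
  agg_err <- tapply(m$n_errors, m$level, sum)
  agg_cov <- tapply(m$n_covered, m$level, sum)
  data.frame(level = as.numeric(names(agg_err)),
             error = as.numeric(agg_err) / as.numeric(agg_cov),
             n_covered = as.numeric(agg_cov))
}
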