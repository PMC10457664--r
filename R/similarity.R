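# Compound fingerprints and Tanimoto similarity; protein local-alignment
# similarity (Smith-Waterman, affine gaps, BLOSUM62); similarity-matrix
# assembly with a plain-text cache.

#' Fingerprint parameters
#'
#' Circular (Morgan) fingerprint settings: radius 2 and 2048 bits are the
#' customary ECFP4-style defaults for chemical similarity.
#'
#' @param radius Non-negative integer neighbourhood radius.
#' @param n_bits Fingerprint length; a power of two >= 64 (the usual
#'   folding convention).
#' @return A `fingerprint_params` list.
#' @export
fingerprint_params <- function(radius = 2L, n_bits = 2048L) {
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  stopifnot(radius >= 0L, n_bits >= 64L)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("n_bits must be a power of two", call. = FALSE)
  }
  structure(list(radius = radius, n_bits = n_bits),
            class = "fingerprint_params")
}

#' Load the packaged BLOSUM62 substitution matrix
#'
#' NCBI integer values over the 20 amino acids plus B, Z and X.
#'
#' @return A named integer matrix.
#' @export
blosum62 <- function() {
  path <- system.file("extdata", "BLOSUM62.txt", package = "dadcp")
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' Local-alignment parameters
#'
#' Affine-gap Smith-Waterman settings.  A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`; the defaults (BLOSUM62, 10/4) are
#' the customary protein local-alignment settings for kinase-domain
#' comparison.
#'
#' @param substitution_matrix Named symmetric integer matrix.
#' @param gap_open,gap_extend Positive integer penalties with
#'   `gap_open >= gap_extend >= 1`.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(substitution_matrix = blosum62(),
                             gap_open = 10L, gap_extend = 4L) {
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  stopifnot(gap_open >= gap_extend, gap_extend >= 1L)
  m <- as.matrix(substitution_matrix)
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("substitution matrix must have matching row/column names",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_params")
}

#' Morgan fingerprint of a SMILES string
#'
#' Computed with RDKit's Morgan generator through a bundled Python helper
#' (RDKit is the de-facto standard implementation of circular
#' fingerprints).  Deterministic for a given SMILES and parameter set.
#'
#' @param smiles Character vector of SMILES strings.
#' @param params A [fingerprint_params()].
#' @param python Python interpreter to invoke.
#' @return A binary integer matrix, one row per input SMILES.
#' @export
morgan_fingerprint <- function(smiles, params = fingerprint_params(),
                               python = "python") {
  stopifnot(inherits(params, "fingerprint_params"), is.character(smiles),
            length(smiles) >= 1L)
  script <- system.file("python", "morgan_fp.py", package = "dadcp")
  infile <- tempfile("smiles"); on.exit(unlink(infile), add = TRUE)
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(
    python, c(script, params$radius, params$n_bits),
    stdin = infile, stdout = TRUE, stderr = FALSE))
  if (length(out) != length(smiles)) {
    stop("fingerprint helper failed (is RDKit available to '", python,
         "'?)", call. = FALSE)
  }
  bad <- startsWith(out, "ERROR\t")
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(sub("^ERROR\t", "", out[bad]), collapse = ", "),
         call. = FALSE)
  }
  fp <- do.call(rbind, lapply(strsplit(out, ""), as.integer))
  stopifnot(ncol(fp) == params$n_bits)
  fp
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`.  Two all-zero fingerprints are defined to have
#' similarity 1 (degenerate featureless molecules), with a warning.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) {
    warning("both fingerprints all-zero; defining similarity as 1")
    return(1)
  }
  sum(a & b) / union
}

# All-pairs Tanimoto over a binary fingerprint matrix (rows = compounds),
# via bit-count linear algebra: |a AND b| = a . b and
# |a OR b| = |a| + |b| - |a AND b|.
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  card <- rowSums(fp)
  uni <- outer(card, card, "+") - inter
  s <- ifelse(uni > 0, inter / uni, 1)
  diag(s) <- 1
  s
}

encode_seq <- function(seq, alphabet) {
  idx <- match(strsplit(seq, "")[[1]], alphabet) - 1L
  if (anyNA(idx)) {
    stop("sequence contains residues absent from the substitution matrix",
         call. = FALSE)
  }
  idx
}

#' Smith-Waterman local alignment score
#'
#' Maximum local-alignment score under affine gap penalties (see
#' [alignment_params()]).  The score is a non-negative integer, symmetric
#' in its arguments; an empty sequence scores 0.
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings).
#' @param params An [alignment_params()].
#' @return Non-negative integer score.
#' @export
smith_waterman_score <- function(seq_a, seq_b, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  if (!nzchar(seq_a) || !nzchar(seq_b)) return(0L)
  alphabet <- rownames(params$substitution_matrix)
  .sw_score_cpp(encode_seq(seq_a, alphabet), encode_seq(seq_b, alphabet),
                params$substitution_matrix, params$gap_open,
                params$gap_extend)
}

#' Normalized local-alignment similarity
#'
#' Self-normalized Smith-Waterman similarity,
#' `score(a, b) / sqrt(score(a, a) * score(b, b))`, clamped to \[0, 1\] —
#' the geometric-mean normalization customary for protein similarity
#' profiling.  Requires positive self-scores.
#'
#' @param seq_a,seq_b Amino-acid sequences.
#' @param params An [alignment_params()].
#' @return Similarity in \[0, 1\].
#' @export
normalized_target_similarity <- function(seq_a, seq_b,
                                         params = alignment_params()) {
  saa <- smith_waterman_score(seq_a, seq_a, params)
  sbb <- smith_waterman_score(seq_b, seq_b, params)
  if (saa <= 0 || sbb <= 0) {
    stop("self-alignment score must be positive for normalization",
         call. = FALSE)
  }
  s <- smith_waterman_score(seq_a, seq_b, params) / sqrt(saa * sbb)
  min(max(s, 0), 1)
}

#' Build a pairwise similarity matrix over compounds or targets
#'
#' Compounds: Tanimoto similarity over their binary fingerprints.
#' Targets: normalized Smith-Waterman similarity over their sequences
#' (or raw scores self-normalized; see `normalize`).  When `cache_dir`
#' is given, the matrix is stored as delimited text keyed by a content
#' hash of the ids, inputs and parameters, and recomputation loads the
#' cached file.
#'
#' @param entities A [compound_set()] (with fingerprints) for
#'   `kind = "compound"`, or a [target_set()] for `kind = "target"`.
#' @param kind `"compound"` or `"target"`.
#' @param params [alignment_params()] for targets; ignored for compounds.
#' @param cache_dir Optional directory for the plain-text cache.
#' @return A [similarity_matrix()].
#' @export
build_similarity_matrix <- function(entities,
                                    kind = c("compound", "target"),
                                    params = NULL, cache_dir = NULL) {
  kind <- match.arg(kind)
  if (kind == "compound") {
    stopifnot(inherits(entities, "compound_set"))
    if (is.null(entities$fingerprints)) {
      stop("compound set has no fingerprints; featurize first",
           call. = FALSE)
    }
    ids <- entities$ids
    payload <- list(kind, ids, entities$fingerprints)
  } else {
    stopifnot(inherits(entities, "target_set"))
    if (is.null(params)) params <- alignment_params()
    ids <- names(entities)
    payload <- list(kind, ids, unclass(entities), params)
  }
  if (length(ids) < 1L) stop("need at least one entity", call. = FALSE)

  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir,
                            paste0("sim_", content_hash(payload), ".tsv"))
    if (file.exists(cache_file)) {
      return(read_similarity_matrix(cache_file))
    }
  }

  if (kind == "compound") {
    zero <- rowSums(entities$fingerprints) == 0L
    if (any(zero)) {
      warning("all-zero fingerprint(s): ",
              paste(ids[zero], collapse = ", "),
              "; self-similarity defined as 1")
    }
    vals <- tanimoto_matrix(entities$fingerprints)
  } else {
    n <- length(ids)
    self <- vapply(seq_len(n), function(i) {
      smith_waterman_score(entities[[i]], entities[[i]], params)
    }, integer(1L))
    if (any(self <= 0)) {
      stop("non-positive self-alignment score for target(s): ",
           paste(ids[self <= 0], collapse = ", "), call. = FALSE)
    }
    vals <- diag(nrow = n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          s <- smith_waterman_score(entities[[i]], entities[[j]], params) /
            sqrt(self[i] * self[j])
          vals[i, j] <- vals[j, i] <- min(max(s, 0), 1)
        }
      }
    }
  }
  out <- similarity_matrix(vals, ids)
  if (!is.null(cache_file)) write_similarity_matrix(out, cache_file)
  out
}

# Content hash for the similarity-matrix cache: md5 of the serialized
# inputs, via tools::md5sum on a temp file (no extra dependencies).
content_hash <- function(payload) {
  f <- tempfile("hash")
  on.exit(unlink(f), add = TRUE)
  saveRDS(payload, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}
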