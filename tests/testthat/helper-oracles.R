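# Independent reference implementations used as oracles.  These are
# deliberately naive (full-matrix dynamic programming, exhaustive scans,
# set arithmetic) and share no code with the package internals they check.

# Smith-Waterman local alignment by explicit three-matrix dynamic
# programming over full (n+1) x (m+1) matrices.  Affine gaps: a gap of
# length L costs open + (L - 1) * ext.
sw_oracle <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) return(0L)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + s)
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  as.integer(best)
}

# Tanimoto by explicit set arithmetic over bit-index sets.
tanimoto_oracle <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  u <- union(ia, ib)
  if (length(u) == 0) return(1)
  length(intersect(ia, ib)) / length(u)
}

# Minimal dominating calibration score by exhaustive scan over the
# sorted calibration scores, counting dominated putative scores one
# candidate at a time.
alpha_delta_min_oracle <- function(s_cal, s_x, delta) {
  n <- length(s_cal)
  if (n == 0) return(NA_real_)
  for (cand in sort(s_cal)) {
    if (sum(s_x <= cand) >= (1 - delta) * n) return(cand)
  }
  NA_real_
}

# ICP calibration quantile by brute-force scan: smallest score a with
# #{scores >= a} / (n + 1) <= delta; +Inf when no score qualifies.
icp_alpha_oracle <- function(scores, delta) {
  n <- length(scores)
  for (a in sort(unique(scores))) {
    if (sum(scores >= a) / (n + 1) <= delta) return(a)
  }
  Inf
}

random_peptide <- function(len) {
  paste(sample(setdiff(dadcp:::aa_alphabet(), "X"), len, replace = TRUE),
        collapse = "")
}
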