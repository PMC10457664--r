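# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib dadcp, .registration = TRUE
NULL

# Deterministic child-seed derivation: one master seed expands into
# independent per-purpose seeds without consuming the global RNG stream.
# Kept below 2^31 - 1 so the result is always a valid R integer.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(offset)) %%
               2147483587)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Amino-acid alphabet: 20 standard residues plus the ambiguity code X.
aa_alphabet <- function() c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                            "I", "L", "K", "M", "F", "P", "S", "T", "W",
                            "Y", "V", "X")

check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  x
}

pair_key <- function(compound_id, target_id) {
  paste(compound_id, target_id, sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
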