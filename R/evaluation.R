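# Cold-start scenario construction (S1-S4) and conformal-prediction
# diagnostics: per-confidence error rate over covered pairs, coverage,
# efficiency (median region half-width) and calibration curves.

#' Truth lookup vector for prediction regions
#'
#' @param table An [interaction_table()] of measured test pairs.
#' @return Named numeric vector keyed by (compound, target) pair.
#' @export
region_truths <- function(table) {
  stats::setNames(table$affinity,
                  pair_key(table$compound_id, table$target_id))
}

truths_for <- function(regions, truths) {
  if (inherits(truths, "interaction_table")) truths <- region_truths(truths)
  y <- truths[pair_key(regions$compound_id, regions$target_id)]
  if (anyNA(y)) stop("missing truth for some region pair(s)", call. = FALSE)
  as.numeric(y)
}

single_level <- function(regions) {
  if (length(unique(regions$confidence)) != 1L) {
    stop("expected regions at a single confidence level", call. = FALSE)
  }
  regions
}

#' Empirical error rate over covered pairs
#'
#' Fraction of non-abstained regions whose true affinity falls outside
#' `[lower, upper]`; boundary hits count as inside.  A conformal
#' predictor is valid at a level when this does not exceed `1 - level`.
#' With no covered pair the rate is undefined (`NA`).
#'
#' @param regions `prediction_regions` at a single confidence level.
#' @param truths [interaction_table()] or named truth vector (see
#'   [region_truths()]).
#' @return Error rate in \[0, 1\], or `NA_real_`.
#' @export
error_rate <- function(regions, truths) {
  regions <- single_level(regions)
  y <- truths_for(regions, truths)
  cov <- !regions$abstained
  if (!any(cov)) return(NA_real_)
  outside <- y[cov] < regions$lower[cov] | y[cov] > regions$upper[cov]
  mean(outside)
}

#' Coverage: fraction of pairs receiving a region
#'
#' @param regions `prediction_regions` at a single confidence level.
#' @return `n_covered / n_test`.
#' @export
coverage <- function(regions) {
  regions <- single_level(regions)
  if (!nrow(regions)) stop("no regions", call. = FALSE)
  mean(!regions$abstained)
}

#' Efficiency: median region half-width over covered pairs
#'
#' Smaller is more informative.  `NA` when nothing is covered.
#'
#' @param regions `prediction_regions` at a single confidence level.
#' @return Median alpha, or `NA_real_`.
#' @export
efficiency <- function(regions) {
  regions <- single_level(regions)
  a <- regions$alpha[!regions$abstained]
  if (!length(a)) return(NA_real_)
  stats::median(a)
}

#' Calibration curve: expected vs observed confidence
#'
#' One point per confidence level: `(level, 1 - error_rate)`.  Observed
#' above expected at every level diagnoses underconfidence (conservative
#' regions); below, overconfidence.
#'
#' @param regions `prediction_regions` over the full confidence grid.
#' @param truths Truths as in [error_rate()].
#' @return Data frame with columns `expected`, `observed`, `n_covered`.
#' @export
calibration_curve <- function(regions, truths) {
  levels <- sort(unique(regions$confidence))
  rows <- lapply(levels, function(lv) {
    sub <- regions[regions$confidence == lv, , drop = FALSE]
    data.frame(expected = lv,
               observed = 1 - error_rate(sub, truths),
               n_covered = sum(!sub$abstained))
  })
  do.call(rbind, rows)
}

#' Cold-start scenario split
#'
#' Builds the four test scenarios from a measured interaction table:
#' S2 holds out compounds (all their pairs become S2/S4 tests), S3 holds
#' out targets, S4 is the cross of held-out compounds and held-out
#' targets, and S1 is a random pair-level holdout from the remaining
#' (seen-entity) pairs.  Entity holdout is either uniformly random or
#' cluster-based: whole single-linkage clusters at a Tanimoto (or
#' sequence-similarity) threshold are removed, producing genuine
#' covariate shift.
#'
#' @param table Aggregated [interaction_table()].
#' @param s1_fraction Fraction of remaining pairs held out as S1.
#' @param s2_fraction Fraction of compounds held out.
#' @param s3_fraction Fraction of targets held out.
#' @param strategy `"random"` or `"cluster"`.
#' @param compound_sim,target_sim [similarity_matrix()] objects (required
#'   for `strategy = "cluster"`).
#' @param cluster_threshold Single-linkage similarity threshold used to
#'   define clusters (default 0.7).
#' @param seed Integer seed.
#' @return A `scenario_split`: list with `train`, `tests` (named list
#'   `S1`-`S4` of interaction tables) and `provenance`.
#' @export
scenario_split <- function(table, s1_fraction = 0.1, s2_fraction = 0.1,
                           s3_fraction = 0.1,
                           strategy = c("random", "cluster"),
                           compound_sim = NULL, target_sim = NULL,
                           cluster_threshold = 0.7, seed = 1L) {
  strategy <- match.arg(strategy)
  comp_ids <- sort(unique(table$compound_id))
  targ_ids <- sort(unique(table$target_id))
  n_c_out <- round(s2_fraction * length(comp_ids))
  n_t_out <- round(s3_fraction * length(targ_ids))
  if (n_c_out >= length(comp_ids) || n_t_out >= length(targ_ids)) {
    stop("infeasible holdout fractions", call. = FALSE)
  }
  pick <- function(ids, n_out, sim, off) {
    if (n_out == 0L) return(character(0))
    if (strategy == "random" || is.null(sim)) {
      return(with_seed(derive_seed(seed, off), sample(ids, n_out)))
    }
    d <- stats::as.dist(1 - unclass(sim)[ids, ids])
    cl <- stats::cutree(stats::hclust(d, method = "single"),
                        h = 1 - cluster_threshold)
    cl_order <- with_seed(derive_seed(seed, off),
                          sample(unique(cl)))
    out <- character(0)
    for (g in cl_order) {
      if (length(out) >= n_out) break
      out <- c(out, ids[cl == g])
    }
    out
  }
  held_c <- pick(comp_ids, n_c_out, compound_sim, 21L)
  held_t <- pick(targ_ids, n_t_out, target_sim, 22L)
  build_scenarios(table, held_c, held_t, s1_fraction,
                  derive_seed(seed, 23L))
}

# Shared S1-S4 assembly given the held-out entity sets.
build_scenarios <- function(table, held_c, held_t, s1_fraction, s1_seed) {
  in_c <- table$compound_id %in% held_c
  in_t <- table$target_id %in% held_t
  s4 <- table[in_c & in_t, , drop = FALSE]
  s2 <- table[in_c & !in_t, , drop = FALSE]
  s3 <- table[!in_c & in_t, , drop = FALSE]
  rest <- table[!in_c & !in_t, , drop = FALSE]
  n_s1 <- round(s1_fraction * nrow(rest))
  idx <- if (n_s1 > 0L) with_seed(s1_seed, sample.int(nrow(rest), n_s1))
         else integer(0)
  s1 <- rest[idx, , drop = FALSE]
  train <- if (length(idx)) rest[-idx, , drop = FALSE] else rest
  # S1 entities must all be seen in training; drop the rare S1 pair whose
  # compound or target only occurs in held-out pairs.
  seen <- s1$compound_id %in% train$compound_id &
    s1$target_id %in% train$target_id
  s1 <- s1[seen, , drop = FALSE]
  split <- structure(
    list(train = train,
         tests = list(S1 = s1, S2 = s2, S3 = s3, S4 = s4),
         provenance = list(held_compounds = held_c,
                           held_targets = held_t, seed = s1_seed)),
    class = "scenario_split")
  validate_scenario_split(split)
  split
}

#' Validate the invariants of a scenario split
#'
#' S2/S4 test compounds must not occur in training, S3/S4 targets must
#' not occur in training, S1 entities must all be seen, and every test
#' set must be pair-disjoint from training.
#'
#' @param split A `scenario_split`.
#' @return `split`, invisibly; errors on violation.
#' @export
validate_scenario_split <- function(split) {
  train <- split$train
  tr_c <- unique(train$compound_id)
  tr_t <- unique(train$target_id)
  tr_pairs <- pair_key(train$compound_id, train$target_id)
  with_tests <- function(name, check) {
    tbl <- split$tests[[name]]
    if (nrow(tbl) && !check(tbl)) {
      stop("scenario split invariant violated for ", name, call. = FALSE)
    }
  }
  with_tests("S2", function(t) !any(t$compound_id %in% tr_c))
  with_tests("S4", function(t) !any(t$compound_id %in% tr_c) &&
               !any(t$target_id %in% tr_t))
  with_tests("S3", function(t) !any(t$target_id %in% tr_t))
  with_tests("S1", function(t) all(t$compound_id %in% tr_c) &&
               all(t$target_id %in% tr_t))
  for (name in names(split$tests)) {
    with_tests(name, function(t) {
      !any(pair_key(t$compound_id, t$target_id) %in% tr_pairs)
    })
  }
  invisible(split)
}

#' Union of all test scenarios
#'
#' @param split A `scenario_split`.
#' @return An [interaction_table()] concatenating S1-S4.
#' @export
scenario_s0 <- function(split) {
  out <- do.call(rbind, lapply(split$tests, as.data.frame))
  rownames(out) <- NULL
  interaction_table(out$compound_id, out$target_id, out$affinity)
}

#' Evaluate conformal predictors across scenarios and confidence levels
#'
#' Fits each requested method once on the split's training set and
#' reports, for every (method, scenario, level) cell, the error rate
#' over covered pairs, the coverage, the median region half-width and the
#' observed confidence -- the long-format protocol used throughout the
#' package.  A failure in one cell is recorded (`NA` metrics), not fatal.
#'
#' @param split A `scenario_split`.
#' @param compounds A [compound_set()] with fingerprints.
#' @param compound_sim,target_sim [similarity_matrix()] objects covering
#'   all entities in the split.
#' @param methods Character vector from `dad_cv`, `dad_nn`, `shafer`,
#'   `error_model`, `knn_dist`, `knn_std`.
#' @param confidence Confidence grid.
#' @param spec A [regressor_spec()].
#' @param nbhd A [neighborhood()] for the dAD variants.
#' @param calibration,gamma,k Baseline configuration (see [icp_fit()]).
#' @param min_calibration_size Abstention floor for the dAD variants.
#' @param covered_only When `TRUE`, baseline cells are evaluated only on
#'   the pairs the dAD variants covered at that level (the paired
#'   comparison protocol).
#' @param seed Integer master seed.
#' @return An `evaluation_report` data frame, one row per cell.
#' @export
evaluate_cp <- function(split, compounds, compound_sim, target_sim,
                        methods = c("dad_cv", "dad_nn", "shafer"),
                        confidence = confidence_grid(),
                        spec = regressor_spec(), nbhd = neighborhood(),
                        calibration = 0.2, gamma = 0, k = 25L,
                        min_calibration_size = 10L, covered_only = FALSE,
                        seed = 1L) {
  known <- c("dad_cv", "dad_nn", "shafer", "error_model", "knn_dist",
             "knn_std")
  stopifnot(all(methods %in% known))
  train <- split$train
  dad <- NULL
  if (any(startsWith(methods, "dad")) || covered_only) {
    dad <- dad_fit(train, compounds, compound_sim, target_sim, spec = spec,
                   seed = derive_seed(seed, 31L))
  }
  fits <- list()
  for (m in methods) {
    fits[[m]] <- if (startsWith(m, "dad")) dad else
      icp_fit(train, method = m, compounds = compounds,
              compound_sim = compound_sim, target_sim = target_sim,
              spec = spec, calibration = calibration, gamma = gamma,
              k = k, seed = derive_seed(seed, 32L))
  }
  dad_regions <- list()  # scenario -> variant -> regions (for covered_only)
  if (covered_only) {
    for (sc in names(split$tests)) {
      tbl <- split$tests[[sc]]
      if (!nrow(tbl)) next
      dad_regions[[sc]] <- lapply(c("cv", "nn"), function(v) {
        predict(dad, tbl, confidence = confidence, variant = v,
                nbhd = nbhd, min_calibration_size = min_calibration_size)
      })
    }
  }
  rows <- list()
  for (m in methods) {
    for (sc in names(split$tests)) {
      tbl <- split$tests[[sc]]
      if (!nrow(tbl)) next
      truths <- region_truths(tbl)
      regions <- tryCatch({
        if (startsWith(m, "dad")) {
          predict(fits[[m]], tbl, confidence = confidence,
                  variant = sub("dad_", "", m), nbhd = nbhd,
                  min_calibration_size = min_calibration_size)
        } else {
          predict(fits[[m]], tbl, confidence = confidence)
        }
      }, error = function(e) e)
      for (lv in confidence) {
        if (inherits(regions, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, scenario = sc, confidence = lv,
            error_rate = NA_real_, coverage = NA_real_,
            median_alpha = NA_real_, n_test = nrow(tbl),
            n_covered = NA_integer_, observed_confidence = NA_real_,
            note = conditionMessage(regions), stringsAsFactors = FALSE)
          next
        }
        sub <- regions[regions$confidence == lv, , drop = FALSE]
        if (covered_only && !startsWith(m, "dad")) {
          covered_pairs <- Reduce(intersect, lapply(
            dad_regions[[sc]], function(r) {
              rl <- r[r$confidence == lv & !r$abstained, , drop = FALSE]
              pair_key(rl$compound_id, rl$target_id)
            }))
          sub <- sub[pair_key(sub$compound_id, sub$target_id) %in%
                       covered_pairs, , drop = FALSE]
        }
        if (!nrow(sub)) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, scenario = sc, confidence = lv,
            error_rate = NA_real_, coverage = NA_real_,
            median_alpha = NA_real_, n_test = 0L, n_covered = 0L,
            observed_confidence = NA_real_, note = "no evaluable pairs",
            stringsAsFactors = FALSE)
          next
        }
        err <- error_rate(sub, truths)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, scenario = sc, confidence = lv,
          error_rate = err, coverage = coverage(sub),
          median_alpha = efficiency(sub), n_test = nrow(sub),
          n_covered = sum(!sub$abstained),
          observed_confidence = 1 - err, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_report", "data.frame")
  out
}
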