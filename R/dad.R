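# Dynamic applicability domain conformal prediction: per-test-pair
# calibration sets assembled from the compound/target neighbourhood of
# the tested pair, local non-conformity scores, minimal dominating
# calibration score per confidence level, symmetric prediction regions
# with abstention, and the confidence-filtered screening step.

#' Neighbourhood sizes for dynamic calibration
#'
#' `k` compounds and `q` targets nearest to the tested pair bound the
#' training pairs eligible for its calibration set.  The defaults (250
#' compounds, 25 targets) suit datasets with thousands of entities;
#' smaller spaces call for smaller values, and both are clamped to the
#' available entity counts with a warning.
#'
#' @param k Positive integer: compound neighbours.
#' @param q Positive integer: target neighbours.
#' @return A `neighborhood` list.
#' @export
neighborhood <- function(k = 250L, q = 25L) {
  k <- as.integer(k); q <- as.integer(q)
  stopifnot(k >= 1L, q >= 1L)
  structure(list(k = k, q = q), class = "neighborhood")
}

#' Most similar entities to a query
#'
#' Ranks `candidate_ids` by similarity to the query, descending, with
#' ties broken by ascending id (stable), and returns the top `n`.  The
#' query itself is eligible when it appears among the candidates.
#'
#' @param query Either an entity id present in `sim`, or a named numeric
#'   vector of similarities covering all candidates.
#' @param candidate_ids Character vector of candidate entity ids.
#' @param sim A [similarity_matrix()] (ignored when `query` is a numeric
#'   vector).
#' @param n Number of neighbours to return.
#' @return Character vector of the `n` most similar candidate ids.
#' @export
nearest_entities <- function(query, candidate_ids, sim = NULL, n) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (is.numeric(query)) {
    s <- query[candidate_ids]
  } else {
    stopifnot(inherits(sim, "similarity_matrix"))
    if (!query %in% rownames(sim)) {
      stop("query '", query, "' absent from similarity matrix",
           call. = FALSE)
    }
    s <- unclass(sim)[query, candidate_ids]
  }
  if (anyNA(s)) {
    stop("similarity not computable for some candidates", call. = FALSE)
  }
  n <- min(as.integer(n), length(candidate_ids))
  candidate_ids[order(-s, candidate_ids)][seq_len(n)]
}

#' Minimal dominating calibration score
#'
#' For a test pair with calibration non-conformity scores `s_cal` and
#' putative test scores `s_x` (both of length `N`), finds the smallest
#' element `a` of `s_cal` such that at least a `1 - delta` fraction of
#' `s_x` satisfies `s_x <= a` (inclusive comparison at ties).  When no
#' calibration score dominates enough putative scores the predictor
#' abstains, returning `NA` with the reason in attribute `"reason"`.
#'
#' @param s_cal Non-negative calibration scores.
#' @param s_x Non-negative putative test scores, same length.
#' @param delta Significance level in (0, 1); confidence is `1 - delta`.
#' @return The minimal dominating score, or `NA_real_` (abstain).
#' @export
alpha_delta_min <- function(s_cal, s_x, delta) {
  stopifnot(delta > 0, delta < 1)
  n <- length(s_cal)
  if (n == 0L) {
    return(structure(NA_real_, reason = "empty calibration set"))
  }
  if (length(s_x) != n) {
    stop("s_cal and s_x must have equal length", call. = FALSE)
  }
  cand <- sort(s_cal)
  counts <- findInterval(cand, sort(s_x))
  ok <- counts >= (1 - delta) * n
  if (!any(ok)) {
    return(structure(NA_real_, reason = "no dominating calibration score"))
  }
  cand[which.max(ok)]
}

#' Assemble the dynamic calibration set for one test pair
#'
#' Members are the measured training pairs whose compound is among the
#' `k` nearest compounds and whose target is among the `q` nearest
#' targets of the tested pair.  Three score vectors are attached, all
#' aligned to the members:
#'
#' * `s_nn` — `|y_cal - mean(y_cal of the set)|` (local label spread);
#' * `s_cv` — `|y_cal - mean out-of-fold CV prediction|`, looked up from
#'   the training CV table;
#' * `s_x`  — `|y_cal - y_pred|`, the putative test scores.
#'
#' @param compound_id,target_id The tested pair.
#' @param train Training [interaction_table()].
#' @param compound_sim,target_sim [similarity_matrix()] objects covering
#'   the tested entities and all training entities.
#' @param nbhd A [neighborhood()].
#' @param cv_table A `cv_score_table` over `train` (same row order).
#' @param y_pred Point prediction for the tested pair.
#' @param exclude_self Drop the tested pair itself from the set when it
#'   is a training pair (off by default).
#' @return A `dynamic_calibration_set` list with elements `members`
#'   (data frame), `s_nn`, `s_cv`, `s_x` and `n`.
#' @export
build_dynamic_calibration_set <- function(compound_id, target_id, train,
                                          compound_sim, target_sim, nbhd,
                                          cv_table, y_pred,
                                          exclude_self = FALSE) {
  stopifnot(inherits(nbhd, "neighborhood"))
  comp_ids <- sort(unique(train$compound_id))
  targ_ids <- sort(unique(train$target_id))
  k <- nbhd$k
  q <- nbhd$q
  if (k > length(comp_ids) || q > length(targ_ids)) {
    warning("neighbourhood clamped to available entities (k=",
            min(k, length(comp_ids)), ", q=", min(q, length(targ_ids)), ")")
    k <- min(k, length(comp_ids))
    q <- min(q, length(targ_ids))
  }
  near_c <- nearest_entities(compound_id, comp_ids, compound_sim, k)
  near_t <- nearest_entities(target_id, targ_ids, target_sim, q)
  mask <- train$compound_id %in% near_c & train$target_id %in% near_t
  if (exclude_self) {
    mask <- mask & !(train$compound_id == compound_id &
                       train$target_id == target_id)
  }
  members <- train[mask, , drop = FALSE]
  y_cal <- members$affinity
  out <- list(compound_id = compound_id, target_id = target_id,
              members = as.data.frame(members),
              s_nn = abs(y_cal - mean(y_cal)),
              s_cv = cv_table$alpha_cv[mask],
              s_x = abs(y_cal - y_pred),
              y_pred = y_pred,
              n = sum(mask))
  if (out$n == 0L) out$s_nn <- numeric(0)
  class(out) <- "dynamic_calibration_set"
  out
}

#' Fit the dynamic applicability domain conformal predictor
#'
#' Trains the point model on all training pairs, runs repeated
#' cross-validation to obtain per-pair out-of-fold scores, and stores the
#' similarity sources needed to assemble per-test-pair calibration sets.
#'
#' @param train Training [interaction_table()] (duplicates must already
#'   be aggregated).
#' @param compounds A [compound_set()] with fingerprints for every
#'   compound that will ever be featurized (training and test).
#' @param compound_sim,target_sim [similarity_matrix()] objects covering
#'   training and test entities.
#' @param spec A [regressor_spec()].
#' @param n_folds,n_repeats Cross-validation geometry (default 10 x 10).
#' @param seed Integer master seed.
#' @return A `dad_model`.
#' @export
dad_fit <- function(train, compounds, compound_sim, target_sim,
                    spec = regressor_spec(), n_folds = 10L,
                    n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(train, "interaction_table"))
  if (anyDuplicated(pair_key(train$compound_id, train$target_id))) {
    stop("training table has duplicate pairs; run aggregate_duplicates()",
         call. = FALSE)
  }
  model <- fit_full_model(train, spec, compounds, target_sim,
                          derive_seed(seed, 1L))
  cv_table <- repeated_cv_scores(train, spec, compounds, target_sim,
                                 n_folds = n_folds, n_repeats = n_repeats,
                                 seed = derive_seed(seed, 2L))
  structure(list(train = train, compounds = compounds,
                 compound_sim = compound_sim, target_sim = target_sim,
                 model = model, cv_table = cv_table, seed = seed),
            class = "dad_model")
}

#' Prediction regions from the dynamic applicability domain predictor
#'
#' For every test pair and confidence level, assembles the dynamic
#' calibration set, derives the minimal dominating calibration score and
#' emits the symmetric region `y_pred +/- alpha`.  The predictor abstains
#' when the calibration set is smaller than `min_calibration_size` or no
#' calibration score dominates the required fraction of putative test
#' scores.
#'
#' @param object A `dad_model` from [dad_fit()].
#' @param newdata Data frame of test pairs (`compound_id`, `target_id`).
#' @param confidence Vector of confidence levels in (0, 1).
#' @param variant `"cv"` (out-of-fold residual scores) or `"nn"` (local
#'   label-spread scores).
#' @param nbhd A [neighborhood()].
#' @param min_calibration_size Abstain below this set size (default 10).
#' @param exclude_self See [build_dynamic_calibration_set()].
#' @param ... Unused.
#' @return A `prediction_regions` data frame: one row per (pair, level)
#'   with columns `compound_id`, `target_id`, `y_pred`, `confidence`,
#'   `alpha`, `lower`, `upper`, `abstained`, `n_calibration`.
#' @export
predict.dad_model <- function(object, newdata,
                              confidence = confidence_grid(),
                              variant = c("cv", "nn"),
                              nbhd = neighborhood(),
                              min_calibration_size = 10L,
                              exclude_self = FALSE, ...) {
  variant <- match.arg(variant)
  confidence <- validate_confidence(confidence)
  train <- object$train
  y_pred <- predict(object$model, newdata)
  comp_ids <- sort(unique(train$compound_id))
  targ_ids <- sort(unique(train$target_id))
  k <- min(nbhd$k, length(comp_ids))
  q <- min(nbhd$q, length(targ_ids))
  if (k < nbhd$k || q < nbhd$q) {
    warning("neighbourhood clamped to available entities (k=", k,
            ", q=", q, ")")
  }
  csim <- unclass(object$compound_sim)
  tsim <- unclass(object$target_sim)
  alpha_cv <- object$cv_table$alpha_cv
  tr_c <- train$compound_id
  tr_t <- train$target_id
  tr_y <- train$affinity

  rows <- vector("list", nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    cid <- newdata$compound_id[i]
    tid <- newdata$target_id[i]
    near_c <- comp_ids[order(-csim[cid, comp_ids], comp_ids)][seq_len(k)]
    near_t <- targ_ids[order(-tsim[tid, targ_ids], targ_ids)][seq_len(q)]
    mask <- tr_c %in% near_c & tr_t %in% near_t
    if (exclude_self) mask <- mask & !(tr_c == cid & tr_t == tid)
    y_cal <- tr_y[mask]
    n_cal <- length(y_cal)
    s_cal <- if (variant == "cv") alpha_cv[mask] else abs(y_cal - mean(y_cal))
    s_x <- abs(y_cal - y_pred[i])
    alpha <- vapply(confidence, function(level) {
      if (n_cal < min_calibration_size) return(NA_real_)
      as.numeric(alpha_delta_min(s_cal, s_x, 1 - level))
    }, numeric(1L))
    rows[[i]] <- data.frame(
      compound_id = cid, target_id = tid, y_pred = y_pred[i],
      confidence = confidence, alpha = alpha,
      lower = y_pred[i] - alpha, upper = y_pred[i] + alpha,
      abstained = is.na(alpha), n_calibration = n_cal,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prediction_regions", "data.frame")
  attr(out, "method") <- paste0("dad_", variant)
  out
}

#' Default confidence-level grid
#'
#' @param levels Strictly increasing confidence levels in (0, 1).
#' @return Numeric vector of levels.
#' @export
confidence_grid <- function(levels = c(0.75, 0.80, 0.85, 0.90, 0.95,
                                       0.99)) {
  validate_confidence(levels)
}

validate_confidence <- function(levels) {
  levels <- as.numeric(levels)
  if (!length(levels) || any(levels <= 0) || any(levels >= 1) ||
      is.unsorted(levels, strictly = TRUE)) {
    stop("confidence levels must be strictly increasing and in (0, 1)",
         call. = FALSE)
  }
  levels
}

#' Confidence-filtered screening of prediction regions
#'
#' Retains candidate interactions predicted active with their whole
#' prediction region above the activity threshold: a pair passes iff it
#' is not abstained, `y_pred >= activity_threshold` and
#' `lower >= activity_threshold`.  The default threshold of pKd 5.5
#' separates bioactivities deemed relevant for compound-kinase screening.
#'
#' @param regions `prediction_regions` at a single confidence level.
#' @param activity_threshold Lower activity bound in pKd/pKi units.
#' @param require_covered When `FALSE`, abstained pairs are judged on
#'   `y_pred` alone (no region requirement).
#' @return The retained subset of `regions`.
#' @export
screen <- function(regions, activity_threshold = 5.5,
                   require_covered = TRUE) {
  if (length(unique(regions$confidence)) > 1L) {
    stop("screening requires regions at a single confidence level",
         call. = FALSE)
  }
  keep_pred <- regions$y_pred >= activity_threshold
  keep <- if (require_covered) {
    !regions$abstained & keep_pred & !is.na(regions$lower) &
      regions$lower >= activity_threshold
  } else {
    keep_pred & (regions$abstained |
                   (!is.na(regions$lower) &
                      regions$lower >= activity_threshold))
  }
  regions[keep, , drop = FALSE]
}
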