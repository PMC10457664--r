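# Reference inductive conformal regressors with a fixed calibration
# split: absolute-residual scores (constant-width regions), error-model
# normalization, and two k-nearest-neighbour normalizations (distance and
# label-spread), plus the gamma sensitivity tuning rule.

#' Split training pairs into proper-training and calibration sets
#'
#' @param table An [interaction_table()].
#' @param calibration Either a fraction in (0, 1) or an integer size.
#' @param seed Integer seed; the split is reproducible and pair-level.
#' @return List with elements `proper` and `calibration`, disjoint and
#'   exhaustive.
#' @export
split_proper_calibration <- function(table, calibration = 0.2, seed = 1L) {
  n <- nrow(table)
  size <- if (calibration < 1) round(calibration * n) else
    as.integer(calibration)
  if (size < 1L || size >= n) {
    stop("infeasible calibration size ", size, " for ", n, " pairs",
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n, size))
  list(proper = table[-idx, , drop = FALSE],
       calibration = table[idx, , drop = FALSE])
}

#' Calibration-quantile non-conformity score
#'
#' The region half-width multiplier of an inductive conformal regressor:
#' the `ceiling((1 - delta) * (n + 1))`-th smallest calibration score.
#' When that index exceeds `n` (calibration set too small for the
#' requested confidence) the region is unbounded and `Inf` is returned,
#' flagged via attribute `"infinite"`.
#'
#' @param scores Non-negative calibration non-conformity scores.
#' @param delta Significance level in (0, 1).
#' @return The quantile score (possibly `Inf`).
#' @export
icp_alpha <- function(scores, delta) {
  stopifnot(delta > 0, delta < 1)
  n <- length(scores)
  if (n == 0L) stop("empty calibration set", call. = FALSE)
  idx <- ceiling((1 - delta) * (n + 1))
  if (idx > n) {
    return(structure(Inf, infinite = TRUE))
  }
  sort(scores)[idx]
}

#' Fit the residual error model for normalized conformal regression
#'
#' Trains a second regressor (same family as the point model) on the
#' proper-training features to predict `ln(|residual| + beta)`, with
#' `beta = 0.01` keeping the logarithm finite; the normalizer
#' `exp(mu(x))` is then strictly positive.  When all residuals are zero
#' the model degenerates to the constant `ln(beta)`.
#'
#' @param proper Proper-training [interaction_table()].
#' @param point_model The `fitted_model` trained on `proper`.
#' @param spec A [regressor_spec()] for the error model.
#' @param seed Integer seed.
#' @param beta Positivity offset inside the logarithm.
#' @return An `error_model` with a `predict` method returning `mu(x)`.
#' @export
fit_error_model <- function(proper, point_model, spec, seed,
                            beta = 0.01) {
  res <- abs(proper$affinity - predict(point_model, proper))
  target <- log(res + beta)
  x <- featurize_pairs(proper, point_model$compounds,
                       point_model$target_sim, point_model$profile_ids)
  reg <- if (all(res == 0)) {
    structure(list(constant = log(beta)), class = "constant_regressor")
  } else {
    fit_regressor(spec, x, target, seed)
  }
  structure(list(regressor = reg, point_model = point_model, beta = beta),
            class = "error_model")
}

#' @export
predict.error_model <- function(object, newdata, ...) {
  if (inherits(object$regressor, "constant_regressor")) {
    return(rep(object$regressor$constant, nrow(newdata)))
  }
  x <- featurize_pairs(newdata, object$point_model$compounds,
                       object$point_model$target_sim,
                       object$point_model$profile_ids)
  predict_regressor(object$regressor, x)
}

# Pair distance in the joint compound-target space: similarity of a pair
# is the product of its compound and target similarities, so d = 0 iff
# both entities match.  This is the multiplicative adaptation of
# single-entity QSAR nearest-neighbour normalizers to interaction pairs.
pair_distances <- function(query, reference, compound_sim, target_sim) {
  cs <- unclass(compound_sim)[query$compound_id, reference$compound_id,
                              drop = FALSE]
  ts <- unclass(target_sim)[query$target_id, reference$target_id,
                            drop = FALSE]
  1 - cs * ts
}

#' k-nearest-neighbour normalizers for conformal regression
#'
#' For each query pair, either the mean distance to its `k` nearest
#' proper-training pairs (`mode = "distance"`, the lambda coefficient) or
#' the standard deviation of those neighbours' labels
#' (`mode = "stdev"`, the xi coefficient), divided by the median of the
#' same statistic over all proper-training pairs (self-neighbours
#' excluded for the reference statistic), yielding a unit-median
#' normalizer.
#'
#' @param query Data frame of pairs to normalize.
#' @param proper Proper-training [interaction_table()].
#' @param compound_sim,target_sim [similarity_matrix()] objects.
#' @param k Number of neighbour pairs (default 25).
#' @param mode `"distance"` or `"stdev"`.
#' @return Numeric vector of normalizers, one per query pair.
#' @export
knn_normalizers <- function(query, proper, compound_sim, target_sim,
                            k = 25L, mode = c("distance", "stdev")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k > nrow(proper)) {
    stop("k exceeds proper-training size", call. = FALSE)
  }
  if (mode == "stdev" && k < 2L) {
    stop("stdev mode needs k >= 2", call. = FALSE)
  }
  stat_for <- function(d_row, labels, drop_first) {
    ord <- order(d_row)
    if (drop_first) ord <- ord[-1L]
    nn <- ord[seq_len(k)]
    if (mode == "distance") mean(d_row[nn]) else stats::sd(labels[nn])
  }
  # reference statistic over proper-training pairs (self excluded)
  d_ref <- pair_distances(proper, proper, compound_sim, target_sim)
  ref <- vapply(seq_len(nrow(proper)), function(i) {
    row <- d_ref[i, ]
    row[i] <- -Inf  # guarantee self is the dropped first neighbour
    stat_for(row, proper$affinity, drop_first = TRUE)
  }, numeric(1L))
  med <- stats::median(ref)
  if (!is.finite(med) || med <= 0) {
    stop("degenerate ", mode, " statistic: median normalizing constant ",
         "is zero", call. = FALSE)
  }
  d_q <- pair_distances(query, proper, compound_sim, target_sim)
  raw <- vapply(seq_len(nrow(query)), function(i) {
    stat_for(d_q[i, ], proper$affinity, drop_first = FALSE)
  }, numeric(1L))
  raw / med
}

#' Fit a reference inductive conformal regressor
#'
#' Splits the training pairs into proper-training and calibration sets,
#' fits the point model on the proper part, and computes calibration
#' scores `|y - y_hat| / normalizer` where the normalizer depends on the
#' method:
#'
#' * `shafer` — 1 (constant-width regions);
#' * `error_model` — `exp(mu(x))`, with `mu` a second regressor
#'   estimating log prediction error;
#' * `knn_dist` — `gamma + lambda(x)` (normalized neighbour distance);
#' * `knn_std` — `gamma + xi(x)` (normalized neighbour label spread).
#'
#' @param train Training [interaction_table()].
#' @param method One of `"shafer"`, `"error_model"`, `"knn_dist"`,
#'   `"knn_std"`.
#' @param compounds A [compound_set()] with fingerprints.
#' @param compound_sim,target_sim [similarity_matrix()] objects covering
#'   training and test entities.
#' @param spec A [regressor_spec()].
#' @param calibration Fraction or size of the calibration split.
#' @param gamma Sensitivity parameter added to the kNN normalizers.
#' @param k Neighbour count for the kNN normalizers.
#' @param seed Integer master seed.
#' @return An `icp_model`.
#' @export
icp_fit <- function(train, method = c("shafer", "error_model", "knn_dist",
                                      "knn_std"),
                    compounds, compound_sim, target_sim,
                    spec = regressor_spec(), calibration = 0.2,
                    gamma = 0, k = 25L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(gamma >= 0)
  parts <- split_proper_calibration(train, calibration,
                                    derive_seed(seed, 11L))
  proper <- parts$proper
  calib <- parts$calibration
  model <- fit_full_model(proper, spec, compounds, target_sim,
                          derive_seed(seed, 12L))
  resid <- abs(calib$affinity - predict(model, calib))
  err_model <- NULL
  norm_cal <- rep(1, nrow(calib))
  if (method == "error_model") {
    err_model <- fit_error_model(proper, model, spec,
                                 derive_seed(seed, 13L))
    norm_cal <- exp(predict(err_model, calib))
  } else if (method %in% c("knn_dist", "knn_std")) {
    mode <- if (method == "knn_dist") "distance" else "stdev"
    norm_cal <- gamma + knn_normalizers(calib, proper, compound_sim,
                                        target_sim, k = k, mode = mode)
  }
  if (any(norm_cal <= 0)) {
    stop("non-positive normalizer on the calibration set; increase gamma",
         call. = FALSE)
  }
  structure(list(method = method, model = model, err_model = err_model,
                 proper = proper, calibration = calib,
                 scores = resid / norm_cal, gamma = gamma, k = k,
                 compound_sim = compound_sim, target_sim = target_sim,
                 seed = seed),
            class = "icp_model")
}

#' Prediction regions from a reference conformal regressor
#'
#' Regions are `y_pred +/- icp_alpha(scores, 1 - level) * normalizer(x)`.
#' These predictors never abstain; with a calibration set too small for a
#' level the region is infinite (flagged by an `Inf` half-width).
#'
#' @param object An `icp_model` from [icp_fit()].
#' @param newdata Data frame of test pairs.
#' @param confidence Vector of confidence levels.
#' @param ... Unused.
#' @return A `prediction_regions` data frame (see [predict.dad_model()]).
#' @export
predict.icp_model <- function(object, newdata,
                              confidence = confidence_grid(), ...) {
  confidence <- validate_confidence(confidence)
  y_pred <- predict(object$model, newdata)
  norm_x <- switch(object$method,
    shafer = rep(1, nrow(newdata)),
    error_model = exp(predict(object$err_model, newdata)),
    knn_dist = object$gamma +
      knn_normalizers(newdata, object$proper, object$compound_sim,
                      object$target_sim, k = object$k, mode = "distance"),
    knn_std = object$gamma +
      knn_normalizers(newdata, object$proper, object$compound_sim,
                      object$target_sim, k = object$k, mode = "stdev"))
  if (any(norm_x == 0)) {
    warning("zero normalizer for some test pair(s): degenerate zero-width ",
            "regions; consider gamma > 0")
  }
  rows <- lapply(confidence, function(level) {
    a_base <- as.numeric(icp_alpha(object$scores, 1 - level))
    alpha <- a_base * norm_x
    data.frame(compound_id = newdata$compound_id,
               target_id = newdata$target_id,
               y_pred = y_pred, confidence = level, alpha = alpha,
               lower = y_pred - alpha, upper = y_pred + alpha,
               abstained = FALSE,
               n_calibration = length(object$scores),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(pair_key(out$compound_id, out$target_id),
                     pair_key(newdata$compound_id, newdata$target_id)),
               out$confidence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prediction_regions", "data.frame")
  attr(out, "method") <- object$method
  out
}

#' Tune the gamma sensitivity parameter on a validation split
#'
#' Given validation prediction regions computed for every candidate
#' gamma, picks, among gammas that are valid at every confidence level
#' and whose mean error rate over the grid does not exceed the mean of
#' the maximal permissible error rates (`mean(1 - level)`), the one with
#' the narrowest median region; when no gamma is valid, the one with the
#' smallest mean error rate is returned with a warning.
#'
#' @param regions_by_gamma Named list (names = gamma values) of
#'   `prediction_regions` over the same validation pairs at the full
#'   confidence grid.
#' @param truths Named numeric vector of true affinities keyed by
#'   `compound_id`/`target_id` (see [region_truths()]).
#' @return The selected gamma (numeric scalar).
#' @export
tune_gamma <- function(regions_by_gamma, truths) {
  if (!length(regions_by_gamma)) stop("empty gamma grid", call. = FALSE)
  gammas <- as.numeric(names(regions_by_gamma))
  stats_g <- lapply(regions_by_gamma, function(regions) {
    levels <- sort(unique(regions$confidence))
    errs <- vapply(levels, function(lv) {
      error_rate(regions[regions$confidence == lv, , drop = FALSE], truths)
    }, numeric(1L))
    list(levels = levels, errs = errs,
         med = stats::median(regions$alpha[!regions$abstained]))
  })
  valid <- vapply(stats_g, function(s) {
    all(s$errs <= 1 - s$levels) && mean(s$errs) <= mean(1 - s$levels)
  }, logical(1L))
  if (any(valid)) {
    meds <- vapply(stats_g, `[[`, numeric(1L), "med")
    cand <- which(valid)
    return(gammas[cand[which.min(meds[cand])]])
  }
  warning("no gamma valid at every level; returning smallest mean error")
  means <- vapply(stats_g, function(s) mean(s$errs), numeric(1L))
  gammas[which.min(means)]
}
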