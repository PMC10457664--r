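# Pluggable point-prediction models over compound-target pairs, plus the
# repeated cross-validation machinery that yields per-training-pair
# out-of-fold scores (the ingredient of the CV non-conformity variant).

#' Specify a point-prediction regressor
#'
#' The conformal layer is model-agnostic: any regressor exposing a
#' fit/predict contract can drive it.  Built-ins:
#'
#' * `gradient_boosting` — xgboost with modest fixed hyperparameters
#'   (overridable through `hyperparameters`).
#' * `knn_baseline` — k-nearest-neighbour mean in feature space
#'   (hyperparameter `k`, default 15).
#' * `user_supplied` — provide `hyperparameters$fit(x, y)` returning an
#'   opaque model and `hyperparameters$predict(model, x)` returning a
#'   numeric vector.
#'
#' @param name One of `"gradient_boosting"`, `"knn_baseline"`,
#'   `"user_supplied"`.
#' @param hyperparameters Named list of overrides (validated against the
#'   regressor's schema).
#' @param feature_mode Currently `"fingerprint_profile"`: concatenation of
#'   the compound fingerprint and the target's similarity-profile row.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(name = c("gradient_boosting", "knn_baseline",
                                    "user_supplied"),
                           hyperparameters = list(),
                           feature_mode = "fingerprint_profile") {
  name <- match.arg(name)
  stopifnot(is.list(hyperparameters))
  schema <- switch(name,
    gradient_boosting = c("nrounds", "max_depth", "eta", "subsample",
                          "colsample_bytree", "min_child_weight"),
    knn_baseline = "k",
    user_supplied = c("fit", "predict"))
  unknown <- setdiff(names(hyperparameters), schema)
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (name == "user_supplied" &&
      (!is.function(hyperparameters$fit) ||
       !is.function(hyperparameters$predict))) {
    stop("user_supplied regressor needs fit and predict functions",
         call. = FALSE)
  }
  structure(list(name = name, hyperparameters = hyperparameters,
                 feature_mode = feature_mode),
            class = "regressor_spec")
}

#' Featurize compound-target pairs
#'
#' Default scheme: the compound's binary fingerprint concatenated with
#' the target's similarity-profile row over a fixed panel of (training)
#' targets.  The profile encoding keeps the model usable for targets
#' never seen in training, as long as their similarities to the training
#' panel are computable.
#'
#' @param table An [interaction_table()] (affinity column optional).
#' @param compounds A [compound_set()] with fingerprints.
#' @param target_sim A [similarity_matrix()] over targets covering every
#'   target in `table` and every id in `profile_ids`.
#' @param profile_ids Target panel defining the profile columns.
#' @return Numeric matrix, one row per pair, rownames = pair keys.
#' @export
featurize_pairs <- function(table, compounds, target_sim, profile_ids) {
  stopifnot(inherits(compounds, "compound_set"),
            inherits(target_sim, "similarity_matrix"))
  if (is.null(compounds$fingerprints)) {
    stop("compound set has no fingerprints", call. = FALSE)
  }
  miss_c <- setdiff(unique(table$compound_id), compounds$ids)
  if (length(miss_c)) {
    stop("compound(s) without fingerprint: ",
         paste(utils::head(miss_c, 5L), collapse = ", "), call. = FALSE)
  }
  miss_t <- setdiff(c(unique(table$target_id), profile_ids),
                    rownames(target_sim))
  if (length(miss_t)) {
    stop("target(s) absent from similarity matrix: ",
         paste(utils::head(miss_t, 5L), collapse = ", "), call. = FALSE)
  }
  fp <- compounds$fingerprints[table$compound_id, , drop = FALSE]
  prof <- unclass(target_sim)[table$target_id, profile_ids, drop = FALSE]
  x <- cbind(fp, prof)
  storage.mode(x) <- "double"
  rownames(x) <- pair_key(table$compound_id, table$target_id)
  colnames(x) <- c(paste0("fp", seq_len(ncol(fp))),
                   paste0("tprof_", profile_ids))
  x
}

# Internal fit/predict dispatch over the regressor spec ---------------------

fit_regressor <- function(spec, x, y, seed) {
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    gradient_boosting = {
      params <- list(
        max_depth = hp$max_depth %||% 5L,
        eta = hp$eta %||% 0.1,
        subsample = hp$subsample %||% 0.8,
        colsample_bytree = hp$colsample_bytree %||% 0.8,
        min_child_weight = hp$min_child_weight %||% 3,
        objective = "reg:squarederror",
        nthread = 1L,
        seed = seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      with_seed(seed,
        xgboost::xgb.train(params = params, data = dtrain,
                           nrounds = hp$nrounds %||% 150L, verbose = 0L))
    },
    knn_baseline = list(x = x, y = y, k = hp$k %||% 15L,
                        xsq = rowSums(x^2)),
    user_supplied = hp$fit(x, y))
  structure(list(spec = spec, fit = fit), class = "dadcp_regressor")
}

predict_regressor <- function(object, x) {
  spec <- object$spec
  out <- switch(spec$name,
    gradient_boosting = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1L))),
    knn_baseline = {
      tr <- object$fit
      k <- min(tr$k, nrow(tr$x))
      # squared Euclidean distances via the crossprod expansion
      d2 <- outer(rowSums(x^2), tr$xsq, "+") - 2 * tcrossprod(x, tr$x)
      unname(apply(d2, 1L, function(row) {
        mean(tr$y[order(row)[seq_len(k)]])
      }))
    },
    user_supplied = as.numeric(spec$hyperparameters$predict(object$fit, x)))
  if (any(!is.finite(out))) {
    stop("regressor produced non-finite predictions", call. = FALSE)
  }
  out
}

#' Fit the full-data point-prediction model
#'
#' The dynamic-calibration framework uses a single model trained on all
#' training pairs (no held-out calibration split).
#'
#' @param table Training [interaction_table()].
#' @param spec A [regressor_spec()].
#' @param compounds A [compound_set()] with fingerprints.
#' @param target_sim Target [similarity_matrix()].
#' @param seed Integer seed; refits with the same seed are identical.
#' @param profile_ids Target panel for the similarity-profile features
#'   (defaults to the training targets, sorted).
#' @return A `fitted_model`.
#' @export
fit_full_model <- function(table, spec, compounds, target_sim, seed,
                           profile_ids = sort(unique(table$target_id))) {
  stopifnot(inherits(spec, "regressor_spec"))
  if (nrow(table) < 2L) {
    stop("need at least two training pairs", call. = FALSE)
  }
  x <- featurize_pairs(table, compounds, target_sim, profile_ids)
  reg <- fit_regressor(spec, x, table$affinity, seed)
  structure(list(regressor = reg, spec = spec, compounds = compounds,
                 target_sim = target_sim, profile_ids = profile_ids,
                 seed = seed,
                 data_hash = content_hash(list(x, table$affinity))),
            class = "fitted_model")
}

#' Predict binding affinities for compound-target pairs
#'
#' @param object A `fitted_model` from [fit_full_model()].
#' @param newdata A data frame with `compound_id` and `target_id` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  x <- featurize_pairs(newdata, object$compounds, object$target_sim,
                       object$profile_ids)
  predict_regressor(object$regressor, x)
}

#' Out-of-fold scores from repeated cross-validation
#'
#' Runs `n_repeats` independent `n_folds`-fold cross-validations over the
#' training pairs (folds partition pairs, not entities).  Every pair is
#' predicted exactly once per repeat, always by a model whose training
#' fold excluded it.  The per-pair CV mean and the non-conformity score
#' `alpha_cv = |y - mean(oof predictions)|` feed the CV variant of the
#' dynamic calibration scores.
#'
#' @param table Training [interaction_table()].
#' @param spec A [regressor_spec()].
#' @param compounds,target_sim Featurization context as in
#'   [fit_full_model()].
#' @param n_folds,n_repeats Cross-validation geometry (default 10 x 10).
#' @param seed Integer master seed; fold assignments and model seeds are
#'   derived from it deterministically.
#' @param profile_ids Target panel for featurization.
#' @return A `cv_score_table` data frame with columns `compound_id`,
#'   `target_id`, `y`, `y_cv_mean`, `alpha_cv`; attributes carry the CV
#'   geometry, per-repeat out-of-fold predictions (`oof_predictions`) and
#'   fold assignments (`fold_assignments`).
#' @export
repeated_cv_scores <- function(table, spec, compounds, target_sim,
                               n_folds = 10L, n_repeats = 10L, seed = 1L,
                               profile_ids = sort(unique(table$target_id))) {
  n <- nrow(table)
  n_folds <- as.integer(n_folds)
  n_repeats <- as.integer(n_repeats)
  if (n_folds > n) {
    stop("n_folds (", n_folds, ") exceeds table size (", n, ")",
         call. = FALSE)
  }
  x <- featurize_pairs(table, compounds, target_sim, profile_ids)
  y <- table$affinity
  oof <- matrix(NA_real_, n, n_repeats)
  folds <- matrix(NA_integer_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- with_seed(derive_seed(seed, 1000L + r),
                      sample(rep(seq_len(n_folds), length.out = n)))
    folds[, r] <- fold
    for (f in seq_len(n_folds)) {
      hold <- fold == f
      reg <- fit_regressor(spec, x[!hold, , drop = FALSE], y[!hold],
                           derive_seed(seed, r * 100L + f))
      oof[hold, r] <- predict_regressor(reg, x[hold, , drop = FALSE])
    }
  }
  y_cv <- rowMeans(oof)
  out <- data.frame(compound_id = table$compound_id,
                    target_id = table$target_id,
                    y = y, y_cv_mean = y_cv, alpha_cv = abs(y - y_cv),
                    stringsAsFactors = FALSE)
  attr(out, "n_folds") <- n_folds
  attr(out, "n_repeats") <- n_repeats
  attr(out, "seed") <- as.integer(seed)
  attr(out, "oof_predictions") <- oof
  attr(out, "fold_assignments") <- folds
  class(out) <- c("cv_score_table", "data.frame")
  out
}

#' Write / read a CV score table as delimited text
#'
#' @param cv A `cv_score_table`.
#' @param path File path.
#' @return `path` (write) or a data frame (read).
#' @export
write_cv_scores <- function(cv, path) {
  utils::write.table(
    data.frame(compound_id = cv$compound_id, target_id = cv$target_id,
               y = fmt6(cv$y), y_cv_mean = fmt6(cv$y_cv_mean),
               alpha_cv = fmt6(cv$alpha_cv)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_scores
#' @export
read_cv_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric"))
}
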