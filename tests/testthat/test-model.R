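# Helpers: a deterministic mean-predicting regressor and an oracle
# regressor that looks up the true label for any pair (via rownames).
mean_spec <- function() {
  regressor_spec("user_supplied", list(
    fit = function(x, y) mean(y),
    predict = function(m, x) rep(m, nrow(x))))
}

oracle_spec <- function(truth_map) {
  regressor_spec("user_supplied", list(
    fit = function(x, y) NULL,
    predict = function(m, x) unname(truth_map[rownames(x)])))
}

tiny_featurization_fixture <- function(seed = 5L) {
  set.seed(seed)
  n_c <- 6L; n_t <- 5L
  fp <- matrix(rbinom(n_c * 64, 1, 0.3), n_c)
  cmp <- compound_set(paste0("c", 1:n_c), fingerprints = fp)
  sim <- diag(n_t)
  sim[lower.tri(sim)] <- runif(sum(lower.tri(sim)), 0.1, 0.9)
  sim <- (sim + t(sim)); diag(sim) <- 1
  ts <- similarity_matrix(pmin(sim, 1), paste0("t", 1:n_t))
  list(cmp = cmp, ts = ts)
}

test_that("pair featurization concatenates fingerprint and profile", {
  fx <- tiny_featurization_fixture()
  tbl <- interaction_table(c("c1", "c2"), c("t1", "t3"), c(5, 6))
  profile <- paste0("t", 1:5)
  x <- featurize_pairs(tbl, fx$cmp, fx$ts, profile)
  expect_equal(dim(x), c(2L, 64L + 5L))
  expect_identical(x, featurize_pairs(tbl, fx$cmp, fx$ts, profile))
  expect_equal(unname(x[1, 65:69]), unname(unclass(fx$ts)["t1", profile]))

  novel <- interaction_table("c1", "t9", 5)
  expect_error(featurize_pairs(novel, fx$cmp, fx$ts, profile),
               "absent from similarity matrix")
})

test_that("full-data model fitting is deterministic and learns", {
  fx <- tiny_featurization_fixture()
  tbl <- interaction_table(rep(paste0("c", 1:6), each = 5),
                           rep(paste0("t", 1:5), times = 6),
                           rep(7, 30))
  fit <- fit_full_model(tbl, fast_knn_spec(k = 3), fx$cmp, fx$ts, seed = 9)
  expect_equal(predict(fit, tbl[1:4, ]), rep(7, 4))
  expect_error(fit_full_model(tbl[1, ], fast_knn_spec(), fx$cmp, fx$ts, 9),
               "at least two")

  # noise-free bilinear landscape is learnable by gradient boosting
  cfg <- synthetic_config(n_compounds = 30L, n_targets = 10L,
                          n_compound_clusters = 3L, n_target_families = 2L,
                          noise_sd = 0, density = 1, seed = 11L)
  g <- synth_generate(cfg)
  ts <- build_similarity_matrix(g$targets, "target")
  spec <- regressor_spec("gradient_boosting",
                         list(nrounds = 120L, max_depth = 4L))
  fit2 <- fit_full_model(g$interactions, spec, g$compounds, ts, seed = 5)
  pred <- predict(fit2, g$interactions)
  expect_lt(mean((pred - g$interactions$affinity)^2), 0.05)
  # refit with the same seed reproduces predictions exactly
  fit3 <- fit_full_model(g$interactions, spec, g$compounds, ts, seed = 5)
  expect_identical(pred, predict(fit3, g$interactions))
})

test_that("repeated CV keeps every prediction out-of-fold", {
  fx <- tiny_featurization_fixture()
  set.seed(13)
  tbl <- interaction_table(rep(paste0("c", 1:6), each = 5),
                           rep(paste0("t", 1:5), times = 6),
                           rnorm(30, 6))
  cv <- repeated_cv_scores(tbl, mean_spec(), fx$cmp, fx$ts,
                           n_folds = 5L, n_repeats = 3L, seed = 4L)
  oof <- attr(cv, "oof_predictions")
  folds <- attr(cv, "fold_assignments")
  expect_false(anyNA(oof))
  expect_equal(ncol(oof), 3L)
  # every out-of-fold prediction equals the mean of the labels outside
  # the pair's fold -- i.e. the pair's own fold never leaks in
  for (r in 1:3) {
    for (f in 1:5) {
      held <- folds[, r] == f
      expect_equal(oof[held, r],
                   rep(mean(tbl$affinity[!held]), sum(held)))
    }
  }
  expect_equal(cv$alpha_cv, abs(tbl$affinity - rowMeans(oof)),
               tolerance = 1e-12)
  # bit-identical recomputation from the same seed
  cv2 <- repeated_cv_scores(tbl, mean_spec(), fx$cmp, fx$ts,
                            n_folds = 5L, n_repeats = 3L, seed = 4L)
  expect_identical(cv$y_cv_mean, cv2$y_cv_mean)
  expect_error(repeated_cv_scores(tbl, mean_spec(), fx$cmp, fx$ts,
                                  n_folds = 50L, seed = 1L),
               "exceeds")
})

test_that("two-pair leave-one-out CV gives the other label's error", {
  fx <- tiny_featurization_fixture()
  tbl <- interaction_table(c("c1", "c2"), c("t1", "t1"), c(0, 10))
  cv <- repeated_cv_scores(tbl, mean_spec(), fx$cmp, fx$ts,
                           n_folds = 2L, n_repeats = 2L, seed = 8L)
  expect_equal(cv$alpha_cv, c(10, 10))
})

test_that("median CV score grows with assay noise", {
  meds <- vapply(c(0, 0.5, 1.0), function(sigma) {
    cfg <- synthetic_config(n_compounds = 30L, n_targets = 10L,
                            n_compound_clusters = 3L,
                            n_target_families = 2L, noise_sd = sigma,
                            density = 1, seed = 17L)
    g <- synth_generate(cfg)
    ts <- build_similarity_matrix(g$targets, "target")
    cv <- repeated_cv_scores(g$interactions, fast_knn_spec(k = 5),
                             g$compounds, ts, n_folds = 5L,
                             n_repeats = 2L, seed = 6L)
    median(cv$alpha_cv)
  }, numeric(1L))
  expect_true(all(diff(meds) > 0))
})

test_that("regressor specs validate their hyperparameter schema", {
  expect_error(regressor_spec("knn_baseline", list(bogus = 1)),
               "unknown hyperparameter")
  expect_error(regressor_spec("user_supplied", list(fit = identity)),
               "needs fit and predict")
})
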