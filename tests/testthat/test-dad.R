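test_that("nearest entity ranking is similarity-descending, id-stable", {
  sim <- manual_sim(rbind(c(1, 0.8, 0.8, 0.5),
                          c(0.8, 1, 0.2, 0.1),
                          c(0.8, 0.2, 1, 0.3),
                          c(0.5, 0.1, 0.3, 1)),
                    c("q", "c1", "c2", "c3"))
  cands <- c("c1", "c2", "c3")
  expect_identical(nearest_entities("q", cands, sim, 3),
                   c("c1", "c2", "c3"))
  expect_identical(nearest_entities("q", cands, sim, 1), "c1")  # tie -> id
  sim2 <- manual_sim(rbind(c(1, 1, 0.4), c(1, 1, 0.4), c(0.4, 0.4, 1)),
                     c("q", "c2", "c9"))
  expect_identical(nearest_entities("q", c("c2", "c9"), sim2, 1), "c2")
  expect_error(nearest_entities("q", cands, sim, 0), "positive")
})

test_that("dynamic calibration sets intersect the two neighbourhoods", {
  train <- interaction_table(rep(c("c1", "c2", "c3"), each = 3),
                             rep(c("t1", "t2", "t3"), times = 3),
                             c(5, 6, 7, 6, 7, 8, 7, 8, 9))
  csim <- manual_sim(rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.1),
                           c(0.1, 0.1, 1)), c("c1", "c2", "c3"))
  tsim <- manual_sim(rbind(c(1, 0.2, 0.8), c(0.2, 1, 0.1),
                           c(0.8, 0.1, 1)), c("t1", "t2", "t3"))
  cv <- data.frame(alpha_cv = seq(0.1, 0.9, by = 0.1))

  zc <- build_dynamic_calibration_set("c1", "t1", train, csim, tsim,
                                      neighborhood(1, 1), cv, y_pred = 6)
  expect_equal(zc$n, 1L)
  expect_identical(zc$members$compound_id, "c1")
  expect_identical(zc$members$target_id, "t1")

  zc2 <- build_dynamic_calibration_set("c1", "t1", train, csim, tsim,
                                       neighborhood(2, 2), cv, y_pred = 6)
  expect_true(all(zc2$members$compound_id %in% c("c1", "c2")))
  expect_true(all(zc2$members$target_id %in% c("t1", "t3")))
  # labels for those members: c1:(t1,t3)=5,7 ; c2:(t1,t3)=6,8 -> mean 6.5
  expect_equal(zc2$s_nn, abs(c(5, 7, 6, 8) - 6.5))
  expect_equal(zc2$s_x, abs(c(5, 7, 6, 8) - 6))
  expect_equal(zc2$s_cv, cv$alpha_cv[c(1, 3, 4, 6)])
})

test_that("non-conformity score vectors follow their definitions", {
  train <- interaction_table(c("c1", "c1", "c1"), c("t1", "t2", "t3"),
                             c(5, 6, 7))
  csim <- manual_sim(matrix(1), "c1")
  tsim <- manual_sim(diag(3) * 0 + 0.5 + diag(3) * 0.5,
                     c("t1", "t2", "t3"))
  cv <- data.frame(alpha_cv = c(0.3, 0.1, 0.2))
  zc <- build_dynamic_calibration_set("c1", "t1", train, csim, tsim,
                                      neighborhood(1, 3), cv, y_pred = 6)
  expect_equal(zc$s_nn, c(1, 0, 1))
  expect_equal(zc$s_x, c(1, 0, 1))
  expect_equal(zc$s_cv, c(0.3, 0.1, 0.2))
})

test_that("alpha_delta_min matches its worked examples", {
  expect_equal(alpha_delta_min(c(0.5, 1, 2, 3), c(0.4, 0.9, 1.5, 2.5),
                               0.25), 2)
  s_cal <- c(2, 0.7, 1.1, 5)
  s_x <- c(0.1, 0.2, 0.3, 0.4)
  for (d in c(0.01, 0.1, 0.3)) {
    expect_equal(alpha_delta_min(s_cal, s_x, d), min(s_cal))
  }
  out <- alpha_delta_min(c(0.1, 0.2), c(5, 6), 0.25)
  expect_true(is.na(out))
  empty <- alpha_delta_min(numeric(0), numeric(0), 0.1)
  expect_true(is.na(empty))
  expect_identical(attr(empty, "reason"), "empty calibration set")
})

test_that("alpha_delta_min equals the exhaustive-scan oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    s_cal <- rlnorm(n)
    s_x <- rlnorm(n, sdlog = runif(1, 0.5, 2))
    d <- runif(1, 0.01, 0.5)
    expect_identical(as.numeric(alpha_delta_min(s_cal, s_x, d)),
                     as.numeric(alpha_delta_min_oracle(s_cal, s_x, d)))
  }
})

test_that("prediction regions are symmetric, monotone and abstain safely", {
  lx <- tiny_landscape()
  fit <- dad_fit(lx$split$train, lx$g$compounds, lx$cs, lx$ts,
                 spec = fast_knn_spec(k = 5), n_folds = 5L,
                 n_repeats = 2L, seed = 7L)
  r <- predict(fit, lx$split$tests$S1, confidence = c(0.75, 0.99),
               variant = "cv", nbhd = neighborhood(10, 5),
               min_calibration_size = 5L)
  cov <- r[!r$abstained, ]
  expect_equal(cov$upper - cov$y_pred, cov$y_pred - cov$lower)
  lo <- r[r$confidence == 0.75, ]
  hi <- r[r$confidence == 0.99, ]
  both <- !lo$abstained & !hi$abstained
  expect_true(all(hi$alpha[both] >= lo$alpha[both]))
  # a huge min_calibration_size forces abstention everywhere
  r2 <- predict(fit, lx$split$tests$S1[1:3, ], confidence = 0.9,
                variant = "nn", nbhd = neighborhood(10, 5),
                min_calibration_size = 10000L)
  expect_true(all(r2$abstained))
  expect_true(all(is.na(r2$alpha)))
})

test_that("members always come from the k/q nearest entities", {
  lx <- tiny_landscape()
  train <- lx$split$train
  cv <- dadcp:::repeated_cv_scores(train, fast_knn_spec(k = 5),
                                   lx$g$compounds, lx$ts, n_folds = 5L,
                                   n_repeats = 1L, seed = 2L)
  tst <- lx$split$tests$S2[1:5, ]
  comp_ids <- sort(unique(train$compound_id))
  targ_ids <- sort(unique(train$target_id))
  for (i in seq_len(nrow(tst))) {
    zc <- build_dynamic_calibration_set(
      tst$compound_id[i], tst$target_id[i], train, lx$cs, lx$ts,
      neighborhood(8, 4), cv, y_pred = 6)
    near_c <- nearest_entities(tst$compound_id[i], comp_ids, lx$cs, 8)
    near_t <- nearest_entities(tst$target_id[i], targ_ids, lx$ts, 4)
    expect_true(all(zc$members$compound_id %in% near_c))
    expect_true(all(zc$members$target_id %in% near_t))
    expect_equal(length(zc$s_x), zc$n)
    expect_equal(length(zc$s_nn), zc$n)
  }
})

test_that("screening keeps only confidently active regions", {
  regions <- data.frame(
    compound_id = paste0("c", 1:4), target_id = "t1",
    y_pred = c(6.3, 6.0, 7.0, 5.4), confidence = 0.9,
    alpha = c(0.7, 0.8, NA, 0.1),
    lower = c(5.6, 5.2, NA, 5.3), upper = c(7.0, 6.8, NA, 5.5),
    abstained = c(FALSE, FALSE, TRUE, FALSE), n_calibration = 50L)
  kept <- screen(regions, activity_threshold = 5.5)
  expect_identical(kept$compound_id, "c1")
  mixed <- regions
  mixed$confidence[1] <- 0.75
  expect_error(screen(mixed), "single confidence")
})
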