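dense_grid_table <- function(n_c = 10L, n_t = 10L, seed = 5L) {
  set.seed(seed)
  grid <- expand.grid(compound_id = sprintf("c%02d", 1:n_c),
                      target_id = sprintf("t%02d", 1:n_t),
                      stringsAsFactors = FALSE)
  interaction_table(grid$compound_id, grid$target_id,
                    rnorm(nrow(grid), 6))
}

test_that("scenario splits partition the grid as expected", {
  tbl <- dense_grid_table()
  sp <- scenario_split(tbl, s1_fraction = 0.1, s2_fraction = 0.2,
                       s3_fraction = 0.2, seed = 9L)
  expect_equal(nrow(sp$tests$S4), 4L)         # 2 held compounds x 2 targets
  expect_equal(nrow(sp$tests$S2), 2L * 8L)
  expect_equal(nrow(sp$tests$S3), 8L * 2L)
  expect_equal(nrow(sp$tests$S1) + nrow(sp$train), 64L)
  sp2 <- scenario_split(tbl, s1_fraction = 0.1, s2_fraction = 0.2,
                        s3_fraction = 0.2, seed = 9L)
  expect_identical(sp$tests$S1, sp2$tests$S1)
  expect_identical(sp$provenance$held_compounds,
                   sp2$provenance$held_compounds)

  # the validator rejects a corrupted split (an S2 compound in training)
  bad <- sp
  bad$train <- rbind(as.data.frame(bad$train),
                     as.data.frame(sp$tests$S2[1, ]))
  class(bad$train) <- class(sp$train)
  expect_error(validate_scenario_split(bad), "S2")
  expect_equal(nrow(scenario_s0(sp)),
               sum(vapply(sp$tests, nrow, integer(1L))))
})

test_that("cluster-based holdout removes whole similarity clusters", {
  lx <- tiny_landscape(seed = 33L, holdout = c(0L, 0L), s1_fraction = 0)
  tbl <- lx$g$interactions
  sp <- scenario_split(tbl, s1_fraction = 0.1, s2_fraction = 0.2,
                       s3_fraction = 0, strategy = "cluster",
                       compound_sim = lx$cs, cluster_threshold = 0.25,
                       seed = 4L)
  held <- sp$provenance$held_compounds
  expect_gt(length(held), 0L)
  # no held-out compound may appear in any training pair
  expect_length(intersect(held, unique(sp$train$compound_id)), 0L)
  # cluster membership of the generator is respected: held compounds
  # form whole generator clusters
  cl <- lx$g$compound_clusters
  expect_setequal(held, names(cl)[cl %in% unique(cl[held])])
})

test_that("error rate, coverage and efficiency follow their definitions", {
  mk <- function(lower, upper, abst = FALSE) {
    n <- length(lower)
    data.frame(compound_id = paste0("c", seq_len(n)), target_id = "t",
               y_pred = (lower + upper) / 2, confidence = 0.9,
               alpha = (upper - lower) / 2, lower = lower, upper = upper,
               abstained = rep_len(abst, n), n_calibration = 10L)
  }
  truths <- setNames(c(6, 6, 6, 6),
                     dadcp:::pair_key(paste0("c", 1:4), "t"))
  all_in <- mk(rep(5, 4), rep(7, 4))
  expect_equal(error_rate(all_in, truths), 0)
  one_out <- mk(c(5, 5, 5, 6.5), c(7, 7, 7, 7))
  expect_equal(error_rate(one_out, truths), 0.25)
  # boundary hits count as inside
  boundary <- mk(c(6, 5, 5, 5), c(7, 6, 7, 7))
  expect_equal(error_rate(boundary, truths), 0)

  expect_equal(coverage(all_in), 1)
  all_abst <- mk(rep(NA_real_, 4), rep(NA_real_, 4), abst = TRUE)
  expect_equal(coverage(all_abst), 0)
  expect_true(is.na(error_rate(all_abst, truths)))

  expect_equal(efficiency(mk(c(5, 4, 3), c(7, 8, 9))), 2)
  expect_equal(efficiency(mk(c(5, 3), c(7, 9))), 2)

  multi <- rbind(all_in, transform(all_in, confidence = 0.75))
  curve <- calibration_curve(multi, truths)
  expect_equal(curve$expected, c(0.75, 0.9))
  expect_equal(curve$observed, c(1, 1))
  expect_error(error_rate(multi, truths), "single confidence")
})

test_that("the evaluation report crosses methods, scenarios and levels", {
  lx <- tiny_landscape(seed = 27L)
  report <- evaluate_cp(
    lx$split, lx$g$compounds, lx$cs, lx$ts,
    methods = c("dad_cv", "shafer"), confidence = c(0.8, 0.9),
    spec = fast_knn_spec(k = 5), nbhd = neighborhood(10, 5),
    calibration = 0.25, min_calibration_size = 5L, seed = 3L)
  expect_equal(nrow(report), 2L * 4L * 2L)
  expect_true(all(report$n_covered <= report$n_test))
  covered_err <- report$error_rate[!is.na(report$error_rate)]
  expect_true(all(covered_err >= 0 & covered_err <= 1))
  expect_equal(report$observed_confidence, 1 - report$error_rate)

  report2 <- evaluate_cp(
    lx$split, lx$g$compounds, lx$cs, lx$ts,
    methods = c("dad_cv", "shafer"), confidence = c(0.8, 0.9),
    spec = fast_knn_spec(k = 5), nbhd = neighborhood(10, 5),
    calibration = 0.25, min_calibration_size = 5L, seed = 3L)
  expect_identical(report, report2)
})

test_that("covered-only evaluation restricts baselines to dAD coverage", {
  lx <- tiny_landscape(seed = 29L)
  report <- evaluate_cp(
    lx$split, lx$g$compounds, lx$cs, lx$ts,
    methods = c("dad_cv", "dad_nn", "shafer"), confidence = c(0.9, 0.99),
    spec = fast_knn_spec(k = 5), nbhd = neighborhood(10, 5),
    calibration = 0.25, min_calibration_size = 5L, covered_only = TRUE,
    seed = 3L)
  for (sc in c("S1", "S4")) {
    n_sh <- report$n_test[report$method == "shafer" &
                            report$scenario == sc &
                            report$confidence == 0.99]
    n_cv <- report$n_covered[report$method == "dad_cv" &
                               report$scenario == sc &
                               report$confidence == 0.99]
    if (length(n_sh) && length(n_cv)) expect_lte(n_sh, n_cv)
  }
})
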