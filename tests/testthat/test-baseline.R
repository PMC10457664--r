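test_that("proper/calibration split is disjoint, exhaustive, seeded", {
  tbl <- interaction_table(paste0("c", 1:100), rep("t1", 100),
                           rnorm(100, 6))
  parts <- split_proper_calibration(tbl, 20L, seed = 3L)
  expect_equal(nrow(parts$proper), 80L)
  expect_equal(nrow(parts$calibration), 20L)
  keys <- function(t) dadcp:::pair_key(t$compound_id, t$target_id)
  expect_length(intersect(keys(parts$proper), keys(parts$calibration)), 0L)
  expect_setequal(c(keys(parts$proper), keys(parts$calibration)),
                  keys(tbl))
  parts2 <- split_proper_calibration(tbl, 20L, seed = 3L)
  expect_identical(parts$calibration, parts2$calibration)
  expect_error(split_proper_calibration(tbl[1:50, ], 4000L, 1L),
               "infeasible")
})

test_that("the calibration quantile follows the (n+1) convention", {
  expect_equal(icp_alpha(1:99, 0.05), 95)
  expect_identical(as.numeric(icp_alpha(c(3), 0.05)), Inf)
  expect_true(attr(icp_alpha(c(3), 0.05), "infinite"))
  expect_equal(icp_alpha(rep(2.5, 40), 0.25), 2.5)
  expect_error(icp_alpha(numeric(0), 0.1), "empty")

  set.seed(41)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    scores <- rlnorm(n)
    d <- runif(1, 0.01, 0.3)
    expect_identical(unname(as.numeric(icp_alpha(scores, d))),
                     icp_alpha_oracle(scores, d))
  }
})

test_that("degenerate error model reduces to the constant-width regions", {
  lx <- tiny_landscape(seed = 9L)
  # k = 1 nearest neighbour predicts each training pair by itself, so
  # proper-training residuals are all zero -> constant mu = ln(beta)
  spec <- fast_knn_spec(k = 1)
  em <- icp_fit(lx$split$train, "error_model", lx$g$compounds, lx$cs,
                lx$ts, spec = spec, calibration = 0.25, seed = 5L)
  sh <- icp_fit(lx$split$train, "shafer", lx$g$compounds, lx$cs,
                lx$ts, spec = spec, calibration = 0.25, seed = 5L)
  tst <- lx$split$tests$S1[1:10, ]
  r_em <- predict(em, tst, confidence = c(0.8, 0.9))
  r_sh <- predict(sh, tst, confidence = c(0.8, 0.9))
  expect_equal(r_em$alpha, r_sh$alpha, tolerance = 1e-12)
  # constant-width property of the unnormalized method
  expect_equal(length(unique(r_sh$alpha[r_sh$confidence == 0.9])), 1L)
})

test_that("knn normalizers match a brute-force all-pairs computation", {
  lx <- tiny_landscape(seed = 15L)
  proper <- lx$split$train[1:60, ]
  query <- lx$split$tests$S1[1:8, ]
  k <- 5L
  lam <- knn_normalizers(query, proper, lx$cs, lx$ts, k = k,
                         mode = "distance")

  dist_one <- function(c1, t1, c2, t2) {
    1 - unclass(lx$cs)[c1, c2] * unclass(lx$ts)[t1, t2]
  }
  raw_stat <- function(cid, tid, drop_self_at = NA) {
    d <- mapply(dist_one, cid, tid, proper$compound_id, proper$target_id)
    if (!is.na(drop_self_at)) d[drop_self_at] <- Inf
    mean(sort(d)[seq_len(k)])
  }
  ref <- vapply(seq_len(nrow(proper)), function(i) {
    raw_stat(proper$compound_id[i], proper$target_id[i],
             drop_self_at = i)
  }, numeric(1L))
  expected <- vapply(seq_len(nrow(query)), function(i) {
    raw_stat(query$compound_id[i], query$target_id[i])
  }, numeric(1L)) / median(ref)
  expect_equal(lam, expected)

  # a query identical to a proper-training pair contributes distance 0
  q0 <- proper[3, ]
  lam0 <- knn_normalizers(q0, proper, lx$cs, lx$ts, k = 1L,
                          mode = "distance")
  expect_equal(unname(lam0), 0)

  # identical neighbour labels give zero label spread
  const <- interaction_table(proper$compound_id, proper$target_id,
                             rep(6, nrow(proper)))
  expect_error(knn_normalizers(query, const, lx$cs, lx$ts, k = 3L,
                               mode = "stdev"), "degenerate")
})

test_that("reference regions behave per method family", {
  lx <- tiny_landscape(seed = 21L)
  spec <- fast_knn_spec(k = 5)
  tst <- lx$split$tests$S1[1:12, ]
  sh <- icp_fit(lx$split$train, "shafer", lx$g$compounds, lx$cs, lx$ts,
                spec = spec, calibration = 0.25, seed = 2L)
  r <- predict(sh, tst, confidence = 0.9)
  expect_equal(length(unique(r$alpha)), 1L)
  expect_false(any(r$abstained))

  kd <- icp_fit(lx$split$train, "knn_dist", lx$g$compounds, lx$cs,
                lx$ts, spec = spec, calibration = 0.25, gamma = 0.2,
                k = 5L, seed = 2L)
  rk <- predict(kd, tst, confidence = 0.9)
  expect_gt(length(unique(rk$alpha)), 1L)
  expect_false(any(rk$abstained))

  ks <- icp_fit(lx$split$train, "knn_std", lx$g$compounds, lx$cs,
                lx$ts, spec = spec, calibration = 0.25, gamma = 0.1,
                k = 5L, seed = 2L)
  rs <- predict(ks, tst, confidence = 0.9)
  expect_false(any(rs$abstained))
  expect_equal(rs$upper - rs$y_pred, rs$y_pred - rs$lower)
})

test_that("gamma tuning prefers the narrowest valid setting", {
  mk_regions <- function(width, y) {
    do.call(rbind, lapply(c(0.8, 0.9), function(lv) {
      data.frame(compound_id = paste0("c", seq_along(y)),
                 target_id = "t", y_pred = y, confidence = lv,
                 alpha = width, lower = y - width, upper = y + width,
                 abstained = FALSE, n_calibration = 10L)
    }))
  }
  y <- rep(6, 40)
  truths <- setNames(rep(6, 40), dadcp:::pair_key(paste0("c", 1:40), "t"))
  wide <- mk_regions(1.2, y)
  narrow <- mk_regions(0.9, y)
  pick <- tune_gamma(list(`0` = wide, `0.3` = narrow), truths)
  expect_equal(pick, 0.3)
  expect_equal(tune_gamma(list(`0.7` = wide), truths), 0.7)

  # nothing valid: every region misses the truth
  off <- mk_regions(0.1, y + 5)
  expect_warning(bad <- tune_gamma(list(`0` = off, `1` = off), truths),
                 "no gamma valid")
  expect_true(bad %in% c(0, 1))
})
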