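test_that("confidence_counts tabulates responses by ground truth", {
  s <- generate_session(small_config(seed = 70))
  rec <- s$trials[s$trials$phase == "recognition", ]
  cc <- confidence_counts(rec)
  expect_equal(sum(cc), nrow(rec))
  expect_equal(unname(rowSums(cc)), c(10, 10))  # small fixture: 10 old, 10 new
  expect_error(confidence_counts(s$trials), "recognition trials only")

  all_old <- make_recognition_trials(10, labels = rep(0L, 10))
  all_old$response_value <- 36L
  cc2 <- confidence_counts(all_old)
  expect_equal(sum(cc2 != 0), 1)
  expect_equal(cc2["old", "36"], 10)
})

test_that("roc_points reproduces hand-computed cumulative rates", {
  counts <- matrix(c(2, 3, 5, 10, 10, 20,
                     20, 10, 10, 5, 3, 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("old", "new"), 31:36))
  pts <- roc_points(counts)
  expect_equal(pts$threshold, 36:31)
  expect_equal(pts$hit, c(0.40, 0.60, 0.80, 0.90, 0.96, 1.00))
  expect_equal(pts$fa, c(0.04, 0.10, 0.20, 0.40, 0.60, 1.00))

  sym <- matrix(rep(c(5, 5, 5, 5, 5, 5), 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("old", "new"), 31:36))
  pts_sym <- roc_points(sym)
  expect_equal(pts_sym$hit, pts_sym$fa)
  expect_equal(auc_trapezoid(pts_sym), 0.5)

  perfect <- matrix(c(0, 0, 0, 0, 0, 50,
                      50, 0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
                    dimnames = list(c("old", "new"), 31:36))
  pts_p <- roc_points(perfect)
  expect_equal(pts_p$fa[1], 0)
  expect_equal(pts_p$hit[1], 1)
  expect_equal(auc_trapezoid(pts_p), 1.0)

  zero_row <- matrix(c(rep(1, 6), rep(0, 6)), nrow = 2, byrow = TRUE,
                     dimnames = list(c("old", "new"), 31:36))
  expect_error(roc_points(zero_row), "both old and new")
})

test_that("trapezoid AUC equals the Mann-Whitney oracle on random tables", {
  set.seed(99)
  for (i in 1:100) {
    counts <- random_count_table()
    pts <- roc_points(counts)
    expect_true(all(diff(pts$fa) >= 0) && all(diff(pts$hit) >= 0))
    expect_equal(auc_trapezoid(pts), mann_whitney_auc(counts),
                 tolerance = 1e-12)
  }
  bad <- data.frame(fa = c(0.2, 0.1, 1), hit = c(0.5, 0.6, 1))
  expect_error(auc_trapezoid(bad), "nondecreasing")
})

test_that("zROC slope recovers the strength-variance ratio", {
  p <- behavior_params(d_prime = 1.2)
  labels <- rep(c(0L, 1L), 10000)

  # equal-variance generator: slope near 1
  beh <- simulate_recognition_behavior(labels, p, 4)
  tr <- make_recognition_trials(length(labels), labels = labels)
  tr$response_value <- beh$response_code
  z <- zroc_slope(tr, n_boot = 50, seed = 1)
  expect_true(z$defined)
  expect_lt(abs(z$slope - 1), 0.08)
  expect_false(isTRUE(z$asymmetric))

  # unequal variance (old strength sd 1.25): slope < 1, flagged asymmetric
  set.seed(11)
  strength <- ifelse(labels == 0L, stats::rnorm(length(labels), 1.2, 1.25),
                     stats::rnorm(length(labels), 0, 1))
  tr_uv <- tr
  tr_uv$response_value <- 31L + findInterval(strength, p$criteria)
  z_uv <- zroc_slope(tr_uv, n_boot = 50, seed = 2)
  expect_lt(z_uv$slope, 1)
  expect_lt(abs(z_uv$slope - 1 / 1.25), 0.1)
  expect_true(z_uv$asymmetric)
})

test_that("zROC drops boundary points and flags undefined fits", {
  # saturated responding leaves < 2 interior points
  tr <- make_recognition_trials(40)
  tr$response_value <- ifelse(tr$new_old_label == 0L, 36L, 31L)
  z <- zroc_slope(tr, n_boot = 10, seed = 1)
  expect_false(z$defined)
  expect_true(is.na(z$slope))

  # a point with fa = 0 is excluded, not propagated as -Inf
  counts <- matrix(c(10, 10, 10, 10, 5, 5,
                     10, 15, 10, 10, 5, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("old", "new"), 31:36))
  tr2 <- make_recognition_trials(100,
                                 labels = rep(c(0L, 1L), each = 50))
  tr2$response_value <- c(rep(31:36, counts["old", ]),
                          rep(31:36, counts["new", ]))
  z2 <- zroc_slope(tr2, n_boot = 10, seed = 1)
  expect_true(is.finite(z2$slope))
  pts <- roc_points(confidence_counts(tr2))
  keep <- pts$fa > 0 & pts$fa < 1 & pts$hit > 0 & pts$hit < 1
  oracle <- stats::coef(stats::lm(stats::qnorm(pts$hit[keep]) ~
                                    stats::qnorm(pts$fa[keep])))[[2]]
  expect_equal(z2$slope, oracle)
})

test_that("accuracy is higher on high- than low-confidence trials when memory is strong", {
  p <- behavior_params(d_prime = 2)
  diffs <- vapply(1:50, function(seed) {
    labels <- rep(c(0L, 1L), 50)
    beh <- simulate_recognition_behavior(labels, p, seed)
    tr <- make_recognition_trials(100, labels = labels)
    tr$response_value <- beh$response_code
    a <- confidence_accuracy_split(tr)
    a$acc_high - a$acc_low
  }, numeric(1))
  tt <- stats::t.test(diffs)
  expect_gt(mean(diffs), 0)
  expect_lt(tt$p.value, 0.001)

  # ceiling: all correct in both groups
  tr <- make_recognition_trials(20)
  tr$response_value <- ifelse(tr$new_old_label == 0L, 36L, 31L)
  a <- confidence_accuracy_split(tr)
  expect_equal(a$acc_high, 1.0)
  expect_true(is.na(a$acc_low) || a$acc_low == 1.0)

  # regrouping moves trials between groups but conserves total correct count
  labels <- rep(c(0L, 1L), 50)
  beh <- simulate_recognition_behavior(labels, behavior_params(), 8)
  tr <- make_recognition_trials(100, labels = labels)
  tr$response_value <- beh$response_code
  a1 <- confidence_accuracy_split(tr, high_codes = c(31L, 36L))
  a2 <- confidence_accuracy_split(tr, high_codes = c(31L, 32L, 35L, 36L))
  tot1 <- a1$acc_high * a1$n_high + a1$acc_low * a1$n_low
  tot2 <- a2$acc_high * a2$n_high + a2$acc_low * a2$n_low
  expect_equal(tot1, tot2)
  expect_equal(a1$n_high + a1$n_low, a2$n_high + a2$n_low)
})

test_that("chance-level sessions produce symmetric confidence tables", {
  labels <- rep(c(0L, 1L), 10000)
  beh <- simulate_recognition_behavior(labels, behavior_params(d_prime = 0), 13)
  tr <- make_recognition_trials(length(labels), labels = labels)
  tr$response_value <- beh$response_code
  cc <- confidence_counts(tr)
  chi <- suppressWarnings(stats::chisq.test(cc))
  expect_gt(chi$p.value, 0.001)
})
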