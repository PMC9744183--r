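test_that("A_w hits its analytic anchors", {
  expect_equal(a_w(runif(20), runif(20, 10, 11))$a_w, 1)   # disjoint ranges
  x <- c(1, 2, 3, 4, 5)
  expect_equal(a_w(x, x)$a_w, 0.5)                          # identical samples
  r <- a_w(c(1, 3, 5), c(2, 4))
  expect_equal(r$p_hat, 0.5)                                # 3 of 6 pairs
  expect_equal(r$a_w, 0.5)
})

test_that("A_w equals exhaustive pair counting on random samples", {
  set.seed(50)
  for (i in 1:25) {
    a <- sample(1:8, sample(3:10, 1), replace = TRUE)
    b <- sample(1:8, sample(3:10, 1), replace = TRUE)
    cmp <- outer(a, b, `>`) + 0.5 * outer(a, b, `==`)
    p_hat <- sum(cmp) / (length(a) * length(b))
    r <- a_w(a, b)
    expect_equal(r$p_hat, p_hat, tolerance = 1e-12)
    expect_equal(r$a_w, max(p_hat, 1 - p_hat), tolerance = 1e-12)
  }
})

test_that("MI of a feature with itself hits the log2(bins) cap", {
  set.seed(51)
  x <- rnorm(1000)
  r <- mutual_information(x, x, n_perm = 50, seed = 1)
  expect_equal(r$mi, log2(10), tolerance = 1e-9)
  # invariance under strictly monotone transforms (equal-count binning)
  y <- rnorm(1000)
  m1 <- mutual_information(x, y, n_perm = 10, seed = 2)$mi
  m2 <- mutual_information(exp(x), y^3 + 5 * y, n_perm = 10, seed = 2)$mi
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("MI treats small categorical variables as naturally discrete", {
  x <- rep(c(0, 1), each = 5)
  y <- rep(c(7, 9), each = 5)   # perfectly aligned 2-category variables
  expect_equal(mutual_information(x, y, n_perm = 20, seed = 3)$mi, 1)
  const <- rep(1, 20)
  expect_equal(mutual_information(const, rnorm(20), n_perm = 20, seed = 4)$mi, 0)
})

test_that("MI permutation null is calibrated for independent draws", {
  set.seed(52)
  ps <- replicate(20, {
    mutual_information(rnorm(1000), rnorm(1000), n_perm = 60,
                       seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("CC-group permutation test: calibration and power", {
  set.seed(53)
  ps_null <- replicate(40, {
    compare_cc_groups(rnorm(15), rnorm(15), n_perm = 99,
                      seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(ps_null > 0.05), 0.8)
  ps_shift <- replicate(10, {
    compare_cc_groups(rnorm(20) + 10, rnorm(20), n_perm = 199,
                      seed = sample.int(1e6, 1))$p_value
  })
  expect_true(all(ps_shift <= 0.05))
  # single-permutation universe degenerates gracefully
  expect_lte(compare_cc_groups(1, 1, n_perm = 10, seed = 1)$p_value, 1)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(54)
  ps <- replicate(150, {
    compare_cc_groups(rnorm(10), rnorm(10), n_perm = 200,
                      seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("TreeSHAP satisfies local accuracy (additivity) to 1e-6", {
  set.seed(55)
  n <- 100
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- ifelse(x$a + 0.5 * x$b + rnorm(n, 0, 0.5) > 0, "PV", "PYR")
  m <- ranger::ranger(x = x, y = factor(y, c("PYR", "PV")), num.trees = 25,
                      max.depth = 6, probability = TRUE, keep.inbag = TRUE,
                      seed = 9, num.threads = 1)
  ts <- tree_shap(m, as.matrix(x), as.matrix(x[1:20, ]))
  expect_lt(max(abs(rowSums(ts$phi) + ts$base_value - ts$prediction)), 1e-6)
  # traversal prediction agrees with ranger itself
  pr <- predict(m, x[1:20, ], num.threads = 1)$predictions[, "PV"]
  expect_equal(unname(ts$prediction), unname(pr), tolerance = 1e-9)
  # the planted signal receives the largest attribution
  imp <- colMeans(abs(ts$phi))
  expect_equal(names(which.max(imp)), "a")
})

test_that("importance report folds chunk statistics and flags planted signals", {
  set.seed(56)
  cols <- c("sig", "sig__mean", "sig__sd", "noise", "noise__mean", "noise__sd")
  real <- matrix(abs(rnorm(20 * 6, 0.02, 0.005)), 20, 6,
                 dimnames = list(NULL, cols))
  real[, "sig"] <- 0.5; real[, "sig__mean"] <- 0.3
  null <- matrix(abs(rnorm(50 * 6, 0.02, 0.005)), 50, 6,
                 dimnames = list(NULL, cols))
  rep <- importance_with_null(real, null)
  expect_equal(nrow(rep), 2L)  # folded to base features
  expect_equal(rep$feature[1], "sig")
  expect_gt(rep$importance[1], 0.8)  # 0.5 + 0.3 + folded sd column
  expect_lte(rep$p_value[rep$feature == "sig"], 0.02)
  expect_gt(rep$p_value[rep$feature == "noise"], 0.1)
  bad <- null[, c(2:6, 1)]
  expect_error(importance_with_null(real, bad), "share")
})

test_that("a constant feature receives zero attribution", {
  set.seed(57)
  n <- 80
  x <- data.frame(a = rnorm(n), flat = rep(1, n))
  y <- ifelse(x$a > 0, "PV", "PYR")
  m <- ranger::ranger(x = x, y = factor(y, c("PYR", "PV")), num.trees = 20,
                      probability = TRUE, keep.inbag = TRUE, seed = 3,
                      num.threads = 1)
  ts <- tree_shap(m, as.matrix(x), as.matrix(x[1:10, ]))
  expect_equal(max(abs(ts$phi[, "flat"])), 0)
})

test_that("group tests dispatch correctly and handle degenerate inputs", {
  set.seed(58)
  a <- rnorm(20); b <- rnorm(20)
  r <- group_tests(c(a, b), rep(c("g1", "g2"), each = 20), test = "utest")
  expect_gt(r$p_value, 0.05)
  expect_warning(rt <- group_tests(rep(1, 10), rep(c("g1", "g2"), 5),
                                   test = "utest"), "tied")
  expect_equal(rt$p_value, 1)
  # paired equal vectors degenerate to p = 1
  expect_warning(rw <- group_tests(a, test = "wilcoxon", paired_with = a), "zero")
  expect_equal(rw$p_value, 1)
  # three groups, one shifted by 10 SDs: omnibus significant, only that pair flagged
  vals <- c(rnorm(15), rnorm(15), rnorm(15) + 10)
  grp <- rep(c("g1", "g2", "g3"), each = 15)
  rk <- group_tests(vals, grp, test = "kruskal")
  expect_lte(rk$p_value, 0.05)
  flagged <- rk$pairwise$p_value <= 0.05
  hit <- grepl("g3", rk$pairwise$comparison)
  expect_true(all(flagged == hit))
})
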