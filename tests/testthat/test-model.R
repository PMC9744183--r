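make_table <- function(n_pyr, n_pv, informative = TRUE, seed = 1) {
  set.seed(seed)
  n <- n_pyr + n_pv
  lab <- c(rep("PYR", n_pyr), rep("PV", n_pv))
  shift <- if (informative) ifelse(lab == "PV", 3, 0) else 0
  data.frame(unit_id = sprintf("u%03d", seq_len(n)), chunk = 1L,
             label = lab, region = sample(c("CA1", "nCX"), n, replace = TRUE),
             f1 = rnorm(n) + shift, f2 = rnorm(n), f3 = rnorm(n),
             check.names = FALSE)
}

test_that("stratified partition reproduces the reference 328/80 and 83/21 split", {
  labels <- c(rep("PYR", 411), rep("PV", 101))
  p <- stratified_partition(labels, seed = 1)
  expect_equal(sum(labels[p$train] == "PYR"), 328L)
  expect_equal(sum(labels[p$train] == "PV"), 80L)
  expect_equal(sum(labels[p$test] == "PYR"), 83L)
  expect_equal(sum(labels[p$test] == "PV"), 21L)
  expect_length(intersect(p$train, p$test), 0L)
  # 10 + 10 at 0.8 -> 8/8 train, 2/2 test
  p2 <- stratified_partition(rep(c("PYR", "PV"), each = 10), seed = 2)
  expect_equal(length(p2$train), 16L)
  # different seeds: same counts, different membership
  p3 <- stratified_partition(labels, seed = 3)
  expect_equal(length(p3$train), length(p$train))
  expect_false(identical(p3$train, p$train))
  expect_error(stratified_partition(c("PYR", "PYR", "PV")), "at least 2")
})

test_that("class weights follow the inverse-frequency formula", {
  w <- class_weights(c(rep("PYR", 328), rep("PV", 80)))
  expect_equal(unname(w["PYR"]), 408 / (2 * 328))
  expect_equal(unname(w["PV"]), 2.55)
  wb <- class_weights(rep(c("PYR", "PV"), 10))
  expect_equal(unname(wb), c(1, 1))
  w3 <- class_weights(c(rep("PYR", 30), rep("PV", 10)))
  expect_equal(unname(w3[c("PYR", "PV")]), c(40 / 60, 2))
})

test_that("roc_auc agrees with the rank-statistic oracle and handles ties", {
  set.seed(40)
  for (i in 1:10) {
    lab <- sample(c("PYR", "PV"), 40, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(lab)) < 2) next
    sc <- round(runif(40), 1)  # coarse scores force ties
    r <- rank(sc)
    n_pv <- sum(lab == "PV"); n_pyr <- sum(lab == "PYR")
    oracle <- (sum(r[lab == "PV"]) - n_pv * (n_pv + 1) / 2) / (n_pv * n_pyr)
    expect_equal(roc_auc(lab, sc), oracle, tolerance = 1e-12)
  }
  expect_equal(roc_auc(c("PYR", "PV", "PYR"), c(0.5, 0.5, 0.5)), 0.5)
})

test_that("grid search returns the singleton grid and breaks ties by declaration order", {
  tab <- make_table(30, 30)
  g1 <- compact_param_grid()[3, ]
  expect_equal(grid_search(tab, g1, seed = 1)$params, as.list(g1))
  # duplicated rows tie exactly; the first must win
  g2 <- rbind(g1, g1)
  gs <- grid_search(tab, g2, seed = 1)
  expect_equal(gs$params, as.list(g2[1, ]))
  expect_equal(gs$mean_auc[1], gs$mean_auc[2])
})

test_that("separable features reach AUC 1, constant features stay at exactly 0.5", {
  tab <- make_table(40, 20, informative = TRUE)
  tab$f1 <- ifelse(tab$label == "PV", 10, 0)  # perfectly separable
  ex <- run_experiment(tab, n_partitions = 5, grid = compact_param_grid()[1, ],
                       seed = 2)
  expect_equal(stats::median(ex$auc), 1)
  tabc <- make_table(40, 20)
  tabc$f1 <- 1; tabc$f2 <- 2; tabc$f3 <- 3
  exc <- run_experiment(tabc, n_partitions = 5, grid = compact_param_grid()[1, ],
                        seed = 3)
  expect_true(all(exc$auc == 0.5))
})

test_that("chunked experiments keep chunks unit-disjoint across train/test", {
  pop <- small_population()
  tabs <- list(nochunk = feature_table(pop, probe8, modalities = "spatial"),
               chunked = chunk_feature_table(pop, 25L, probe8,
                                             modalities = "spatial", seed = 4))
  # spy on the partition: rebuild it with the same derived seed
  ul <- tabs$nochunk[!duplicated(tabs$nochunk$unit_id), c("unit_id", "label")]
  sp <- derive_seed(5, 1)
  part <- stratified_partition(ul$label, seed = sp)
  train_ids <- ul$unit_id[part$train]
  test_ids <- ul$unit_id[part$test]
  expect_length(intersect(train_ids, test_ids), 0L)
  ex <- run_experiment(tabs$nochunk, tabs$chunked, n_partitions = 1,
                       grid = compact_param_grid()[1, ], seed = 5)
  expect_identical(sort(names(ex$runs[[1]]$unit_scores)), sort(test_ids))
})

test_that("shuffled-label runs hover at chance on informative features", {
  tab <- make_table(40, 20, informative = TRUE, seed = 6)
  ex <- run_experiment(tab, n_partitions = 15, grid = compact_param_grid()[1, ],
                       seed = 7, shuffle_labels = TRUE)
  expect_gte(stats::median(ex$auc), 0.3)
  expect_lte(stats::median(ex$auc), 0.7)
  # the same table without shuffling separates well
  ex0 <- run_experiment(tab, n_partitions = 5, grid = compact_param_grid()[1, ],
                        seed = 7)
  expect_gt(stats::median(ex0$auc), 0.8)
})

test_that("region generalization reports the stated error formula and a null case", {
  # identical class structure in both regions: error not consistently > 0
  tab <- make_table(60, 30, informative = TRUE, seed = 8)
  rep1 <- region_generalization(tab, train_region = "CA1", n_partitions = 8,
                                grid = compact_param_grid()[1, ], seed = 9)
  expect_equal(rep1$generalization_error,
               (rep1$auc_train_region - rep1$auc_other_region) /
                 rep1$auc_train_region)
  expect_true(all(rep1$generalization_error <= 1))
  expect_gt(mean(rep1$generalization_error <= 0.1), 0.4)
  one_region <- make_table(10, 10)
  one_region$region <- "CA1"
  expect_error(region_generalization(one_region, train_region = "CA1"), "region")
})
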