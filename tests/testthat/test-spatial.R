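test_that("time-based features: constructed offsets give exact SS and SD", {
  ev <- fake_events(c(0, 10, -10))
  tb <- time_based_features(ev, "fmc")
  expect_equal(unname(tb["time_lag_ss"]), 0.1)   # mean(100,100)/1e3
  expect_equal(unname(tb["time_lag_sd"]), 10)    # population SD of {10,-10}
  # simultaneous events
  tb0 <- time_based_features(fake_events(rep(5, 4)), "neg")
  expect_equal(unname(tb0["time_lag_ss"]), 0)
  expect_equal(unname(tb0["time_lag_sd"]), 0)
  # fewer than two usable channels -> missing
  tb_na <- time_based_features(fake_events(c(0, 3), mask = c(TRUE, FALSE)), "fmc")
  expect_true(all(is.na(tb_na)))
})

test_that("time-based features match brute-force recomputation", {
  set.seed(30)
  for (i in 1:20) {
    times <- round(runif(8, 0, 100))
    mask <- c(TRUE, runif(7) > 0.3)  # main always kept
    ev <- fake_events(times, mask = mask, main = 1L)
    tb <- time_based_features(ev, "smc")
    off <- times[-1][mask[-1]] - times[1]
    if (length(off) < 1) {
      expect_true(all(is.na(tb)))
    } else {
      expect_equal(unname(tb["time_lag_ss"]), mean(off^2) / 1e3)
      expect_equal(unname(tb["time_lag_sd"]), sqrt(mean((off - mean(off))^2)))
    }
  }
})

test_that("event graph: single edge weight, simultaneity, edge count", {
  g2 <- linear_probe_geometry(2L)  # 20 um apart
  eg <- build_event_graph(fake_events(c(0, 10)), "fmc", g2)
  expect_equal(nrow(eg$edges), 1L)
  expect_equal(eg$edges$weight, 2000)  # 0.020 mm / 10 us = 2000 mm/s
  gf <- graph_features(eg)
  expect_equal(unname(gf), rep(2000, 3))
  # all simultaneous -> no edges, features missing
  eg0 <- build_event_graph(fake_events(rep(1, 3)), "neg", linear_probe_geometry(3L))
  expect_equal(nrow(eg0$edges), 0L)
  expect_true(all(is.na(graph_features(eg0))))
  # 5 distinct times -> complete DAG with 10 edges, all earlier -> later
  g5 <- linear_probe_geometry(5L)
  eg5 <- build_event_graph(fake_events(c(3, 1, 4, 0, 9)), "smc", g5)
  expect_equal(nrow(eg5$edges), 10L)
  tm <- eg5$nodes$time_us
  expect_true(all(tm[eg5$edges$from] < tm[eg5$edges$to]))
})

test_that("longest/shortest path DP equals exhaustive enumeration (<= 6 nodes)", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(2:6, 1)
    geom <- probe_geometry(seq_len(n), cbind(runif(n, 0, 50), runif(n, 0, 200)))
    times <- sample(0:8, n, replace = TRUE)
    if (length(unique(times)) == 1L) times[1] <- times[1] + 1L
    eg <- build_event_graph(fake_events(times), "fmc", geom)
    for (constrained in c(TRUE, FALSE)) {
      gf <- graph_features(eg, constrained = constrained)
      oracle <- enumerate_paths(eg, constrained = constrained)
      expect_equal(unname(gf["longest_path"]), oracle[1], tolerance = 1e-9)
      expect_equal(unname(gf["shortest_path"]), oracle[2], tolerance = 1e-9)
    }
  }
})

test_that("equal-weight chain: longest path sums all links", {
  # 4 collinear channels, 20 um pitch, times 0 < 1 < 2 < 3 us
  g4 <- linear_probe_geometry(4L)
  eg <- build_event_graph(fake_events(c(0, 1, 2, 3)), "neg", g4)
  # chain of adjacent edges: each 20 um / 1 us = 20000 mm/s
  gf <- graph_features(eg)
  expect_equal(unname(gf["longest_path"]), 3 * 20000)
  # direct earliest -> latest edge: 60 um / 3 us = same speed here
  expect_equal(unname(gf["shortest_path"]), 20000)
})

test_that("SPD features: constructed vectors and the area identity", {
  ev <- fake_events(1:3, amps = c(-1, -0.5, -0.25))
  spd <- spd_features(ev)
  expect_equal(unname(spd["spd_count"]), 2)     # >= 0.5 counted (tie included)
  expect_equal(unname(spd["spd_area"]), 1.75)
  # all equal
  spd1 <- spd_features(fake_events(1:4, amps = rep(-2, 4)))
  expect_equal(unname(spd1["spd_count"]), 4)
  expect_equal(unname(spd1["spd_sd"]), 0)
  expect_equal(unname(spd1["spd_area"]), 4)
  # area == sum of scaled values exactly, and equals the numeric integral
  set.seed(32)
  for (i in 1:20) {
    amps <- -runif(8, 0.05, 1)
    spd <- spd_features(fake_events(1:8, amps = amps))
    v <- abs(amps) / max(abs(amps))
    expect_identical(unname(spd["spd_area"]), sum(v))
    thr <- seq(0, 1, by = 1e-4)
    integral <- sum(vapply(thr, function(th) sum(v >= th), numeric(1))) * 1e-4
    expect_equal(unname(spd["spd_area"]), integral, tolerance = 1e-2)
  }
})

test_that("full spatial extraction returns the 18 named features", {
  u <- small_population()[[1]]
  sp <- extract_spatial_features(mean_and_upsample(u), probe8)
  reg <- feature_registry()
  expect_identical(names(sp), reg$name[reg$modality == "spatial"])
  expect_length(sp, 18L)
})

test_that("FMC dispersion orders PYR < PV and NEG reverses on the reference population", {
  tabs <- reference_spatial_tables()
  tab <- tabs$nochunk
  med <- function(col, lab) stats::median(tab[tab$label == lab, col], na.rm = TRUE)
  expect_lt(med("fmc_time_lag_sd", "PYR"), med("fmc_time_lag_sd", "PV"))
  expect_gt(med("neg_time_lag_sd", "PYR"), med("neg_time_lag_sd", "PV"))
})

test_that("across-chunk SDs of spatial features are larger for PV units", {
  tab <- reference_spatial_tables()$c25
  sd_cols <- grep("__sd$", names(tab), value = TRUE)
  one_per_unit <- tab[!duplicated(tab$unit_id), ]
  # scale features over all units, then compare median per-unit SDs by class
  n_higher <- 0L
  for (cl in sd_cols) {
    base <- sub("__sd$", "", cl)
    scale_f <- stats::sd(tab[[base]], na.rm = TRUE)
    if (!is.finite(scale_f) || scale_f == 0) next
    m_pyr <- stats::median(one_per_unit[one_per_unit$label == "PYR", cl], na.rm = TRUE)
    m_pv <- stats::median(one_per_unit[one_per_unit$label == "PV", cl], na.rm = TRUE)
    if (m_pv > m_pyr) n_higher <- n_higher + 1L
  }
  expect_gt(n_higher, length(sd_cols) / 2)
})
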