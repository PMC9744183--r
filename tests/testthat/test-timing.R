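test_that("ACH counts pairs correctly in edge cases", {
  expect_true(all(compute_ach(numeric(0))$counts == 0))
  expect_true(all(compute_ach(5)$counts == 0))
  a <- compute_ach(c(1, 1.010))  # two spikes 10 ms apart
  expect_equal(sum(a$counts), 1)
  expect_equal(a$counts[20], 1)
  expect_length(a$counts, 2000L)
  expect_length(a$counts_up, 16000L)
  expect_error(compute_ach(c(2, 1)), "sorted")
})

test_that("a long homogeneous Poisson train yields a flat ACH", {
  set.seed(20)
  st <- cumsum(rexp(6000, 5)); st <- st[st < 1200]  # 20 min at 5 Hz
  tf <- extract_timing_features(compute_ach(st), spike_times = st)
  expect_lt(tf["uniform_distance"], 0.02)
  expect_equal(unname(tf["firing_rate"]), 5, tolerance = 0.1)
  # near-uniform short-window CDF crosses 1/e around 50/e ms
  expect_equal(unname(tf["rise_time"]), 50 / exp(1), tolerance = 1)
})

test_that("single-spike ACHs sum to the pairwise ACH", {
  set.seed(21)
  st <- sort(runif(100, 0, 20))
  acc <- matrix(0, 2, 2000)
  for (r in seq_along(st)) acc <- acc + single_spike_ach(st, r)
  expect_equal((acc[1, ] + acc[2, ]) / 2, compute_ach(st)$counts)
  # 2-spike train: each reference sees the one neighbor once per side
  two <- single_spike_ach(c(0, 0.05), 1) + single_spike_ach(c(0, 0.05), 2)
  expect_equal(sum(two), 2)
  expect_equal(two[1, 100], 1)
  expect_equal(two[2, 100], 1)
  # empty neighborhood contributes nothing
  expect_true(all(single_spike_ach(c(0, 10), 1) == 0))
  expect_error(single_spike_ach(c(0, 1), 3), "range")
})

test_that("ACH is invariant to time reversal of the train", {
  set.seed(22)
  st <- sort(runif(200, 0, 30))
  rev_st <- sort(30 - st)
  expect_equal(compute_ach(st)$counts, compute_ach(rev_st)$counts)
})

test_that("per-spike rates follow the mean-inverse-ISI rule", {
  r <- per_spike_rates(c(0, 0.1, 0.6))
  expect_equal(r[2], mean(c(10, 2)))  # ISIs 0.1 s and 0.5 s -> 6 spikes/s
  expect_equal(r[1], 10)              # boundary spike: only one ISI
  expect_equal(r[3], 2)
  u <- small_population()[[1]]
  tf <- extract_timing_features(compute_ach(u$spike_times),
                                rates = per_spike_rates(u$spike_times)[1:5])
  expect_equal(unname(tf["firing_rate"]),
               mean(per_spike_rates(u$spike_times)[1:5], na.rm = TRUE))
})

test_that("timing features match an independent direct-formula oracle", {
  set.seed(23)
  # bursty train
  st <- cumsum(ifelse(runif(3000) < 0.3, runif(3000, 0.003, 0.008),
                      rexp(3000, 2)))
  st <- st[st < 600]
  ach <- compute_ach(st)
  tf <- extract_timing_features(ach, spike_times = st)
  # oracle computed directly from the upsampled histogram
  y <- ach$counts_up
  tt <- (seq_along(y) - 0.5) * 0.0625
  feats <- function(w) {
    p <- pmax(w, 0); p <- p / sum(p)
    n <- length(p)
    c(mean(abs(cumsum(p) - seq_len(n) / n)),
      sum(p[p > 0] * log(p[p > 0] * n)))
  }
  sh <- feats(y[tt < 50]); lo <- feats(y[tt > 50])
  expect_equal(unname(tf["uniform_distance"]), sh[1], tolerance = 1e-12)
  expect_equal(unname(tf["dkl_short"]), sh[2], tolerance = 1e-12)
  expect_equal(unname(tf["jump_index"]), lo[1], tolerance = 1e-12)
  expect_equal(unname(tf["dkl_long"]), lo[2], tolerance = 1e-12)
  p <- pmax(y[tt < 50], 0); p <- p / sum(p)
  expect_equal(unname(tf["rise_time"]),
               tt[which(cumsum(p) > exp(-1))[1]], tolerance = 1e-12)
  P <- Mod(fft(y))^2
  f <- 1:8000; Pk <- P[2:8001]
  expect_equal(unname(tf["psd_center"]), sum(f * Pk) / sum(Pk), tolerance = 1e-9)
  dP <- abs(diff(Pk))
  expect_equal(unname(tf["psd_prime_center"]),
               sum((f[-8000] + 0.5) * dP) / sum(dP), tolerance = 1e-9)
  expect_equal(unname(tf["firing_rate"]), length(st) / diff(range(st)),
               tolerance = 1e-12)
})

test_that("Kullback-Leibler terms are non-negative and vanish only for uniform windows", {
  flat <- compute_ach(numeric(0))
  flat$counts_up <- rep(3, 16000)  # exactly uniform histogram
  tf <- extract_timing_features(flat)
  expect_equal(unname(tf["uniform_distance"]), 0, tolerance = 1e-12)
  expect_equal(unname(tf["dkl_short"]), 0, tolerance = 1e-12)
  expect_equal(unname(tf["dkl_long"]), 0, tolerance = 1e-12)
  set.seed(24)
  for (i in 1:5) {
    st <- sort(runif(100, 0, 10))
    tf <- extract_timing_features(compute_ach(st), spike_times = st)
    expect_gte(tf[["dkl_short"]], 0)
    expect_gte(tf[["dkl_long"]], 0)
    expect_true(tf[["uniform_distance"]] >= 0 && tf[["uniform_distance"]] <= 1)
    expect_true(tf[["jump_index"]] >= 0 && tf[["jump_index"]] <= 1)
  }
})

test_that("degenerate all-zero ACH produces zeroed distribution features with a warning", {
  a <- compute_ach(5)
  expect_warning(tf <- extract_timing_features(a, spike_times = 5), "zero-mass")
  expect_equal(unname(tf["dkl_short"]), 0)
  expect_equal(unname(tf["firing_rate"]), 0)
})
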