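# Autocorrelation histograms and the eight spike-timing features.

ACH_WINDOW_MS <- 1000
ACH_BIN_MS <- 0.5
ACH_NBIN <- 2000L            # single-sided, pre-upsampling
ACH_NBIN_UP <- 16000L        # after eightfold polyphase upsampling
ACH_DT_MS <- 0.0625          # upsampled bin width

# centers of the upsampled bins, ms
ach_bin_times <- function() (seq_len(ACH_NBIN_UP) - 0.5) * ACH_DT_MS

new_ach <- function(counts, n_spikes) {
  up <- if (all(counts == 0)) rep(0, ACH_NBIN_UP) else
    as.numeric(signal::resample(counts, UPSAMPLE_FACTOR, 1L))
  structure(list(counts = counts, counts_up = up,
                 bin_ms = ACH_BIN_MS, n_spikes = n_spikes),
            class = "ach")
}

#' Autocorrelation histogram of a spike train
#'
#' Counts all spike pairs with lags up to 1000 ms into 0.5 ms bins (zero-lag
#' self-pairs excluded). Positive- and negative-lag homolog bins are averaged
#' into a single-sided 0-1000 ms histogram, which is then upsampled eightfold
#' by polyphase filtering (to 0.0625 ms resolution). The result depends only
#' on spike timing. Fewer than two spikes give an all-zero histogram.
#'
#' @param spike_times sorted spike times in seconds.
#' @param window_ms,bin_ms histogram range and bin width (fixed at 1000 and
#'   0.5 in this implementation).
#' @return an object of class `ach` with `counts` (2000 pre-upsampling bins)
#'   and `counts_up` (16000 upsampled bins).
#' @export
compute_ach <- function(spike_times, window_ms = ACH_WINDOW_MS, bin_ms = ACH_BIN_MS) {
  if (window_ms != ACH_WINDOW_MS || bin_ms != ACH_BIN_MS) {
    stop("the ACH range and bin width are fixed at 1000 ms and 0.5 ms")
  }
  t <- as.numeric(spike_times)
  if (is.unsorted(t, strictly = TRUE)) stop("spike times must be sorted")
  counts <- numeric(ACH_NBIN)
  n <- length(t)
  if (n >= 2L) {
    win_s <- window_ms / 1000
    hi <- findInterval(t + win_s, t)
    for (i in seq_len(n - 1L)) {
      if (hi[i] > i) {
        dts <- (t[(i + 1L):hi[i]] - t[i]) * 1000  # ms, all > 0
        b <- ceiling(dts / ACH_BIN_MS - 1e-9)  # tolerate float noise at bin edges
        b[b < 1L] <- 1L
        counts <- counts + tabulate(b, ACH_NBIN)
      }
    }
    # by symmetry the negative side equals the positive side pair-for-pair,
    # so homolog averaging leaves the single-sided pairwise counts unchanged
  }
  new_ach(counts, n)
}

#' Single-spike ACH contribution
#'
#' The two-sided histogram of lags from one reference spike to every other
#' spike within +-1000 ms. Summing the contributions of all spikes of a train
#' and averaging positive/negative homolog bins reproduces the pairwise ACH;
#' summing over a chunk's members gives the chunk ACH.
#'
#' @param spike_times sorted spike times (s) of the whole unit.
#' @param reference index of the reference spike.
#' @return numeric matrix `2 x 2000`: row 1 negative lags (bin k = lags in
#'   `(-(k)*0.5, -(k-1)*0.5]` ms), row 2 positive lags.
#' @export
single_spike_ach <- function(spike_times, reference) {
  t <- as.numeric(spike_times)
  n <- length(t)
  if (reference < 1L || reference > n) stop("reference index out of range")
  win_s <- ACH_WINDOW_MS / 1000
  out <- matrix(0, 2L, ACH_NBIN)
  lo <- findInterval(t[reference] - win_s, t) + 1L
  hi <- findInterval(t[reference] + win_s, t)
  nb <- t[setdiff(lo:hi, reference)]
  if (length(nb)) {
    dts <- (nb - t[reference]) * 1000
    pos <- dts > 0
    if (any(pos)) out[2L, ] <- tabulate(pmax(ceiling(dts[pos] / ACH_BIN_MS - 1e-9), 1L), ACH_NBIN)
    if (any(!pos)) out[1L, ] <- tabulate(pmax(ceiling(-dts[!pos] / ACH_BIN_MS - 1e-9), 1L), ACH_NBIN)
  }
  out
}

#' ACH of a chunk of spikes
#'
#' Accumulates the single-spike ACHs of the chunk members, then symmetrizes
#' (positive/negative homolog average) and upsamples as [compute_ach()] does.
#'
#' @param spike_times sorted spike times (s) of the whole unit.
#' @param members integer indices of the chunk's spikes.
#' @export
chunk_ach <- function(spike_times, members) {
  acc <- matrix(0, 2L, ACH_NBIN)
  for (r in members) acc <- acc + single_spike_ach(spike_times, r)
  new_ach((acc[1L, ] + acc[2L, ]) / 2, length(members))
}

# normalize a window of the upsampled ACH into a PDF; polyphase filtering can
# produce small negative values, which are clamped before normalization
window_pdf <- function(y) {
  y <- pmax(y, 0)
  s <- sum(y)
  if (s <= 0) return(NULL)
  y / s
}

#' Per-spike firing rates for chunk-mode features
#'
#' The single-spike rate is the mean of the inverse interspike intervals
#' before and after the spike; boundary spikes use their only available ISI.
#'
#' @param spike_times sorted spike times (s).
#' @return numeric vector of per-spike rates (spikes/s).
#' @export
per_spike_rates <- function(spike_times) {
  t <- as.numeric(spike_times)
  n <- length(t)
  if (n < 2L) return(rep(NA_real_, n))
  isi <- diff(t)
  pre <- c(NA, isi)
  post <- c(isi, NA)
  rowMeans(cbind(1 / pre, 1 / post), na.rm = TRUE)
}

#' Extract the eight spike-timing features
#'
#' High-frequency features are computed on the mass-normalized 0-50 ms window
#' of the upsampled ACH, low-frequency features on the 50-1000 ms window, and
#' the PSD features on the full 0-1000 ms histogram. Kullback-Leibler
#' divergences are in nats with the `0 log 0 = 0` convention; degenerate
#' (zero-mass) windows yield 0 with a warning. The PSD centroid excludes the
#' DC bin; the PSD-derivative centroid uses the absolute adjacent-difference
#' derivative.
#'
#' @param ach an [compute_ach()] result.
#' @param spike_times spike times (s) of the unit; used for the whole-train
#'   firing rate when `rates` is `NULL`.
#' @param rates optional per-spike rates ([per_spike_rates()] subset); when
#'   given, the firing-rate feature is their mean (chunk mode).
#' @return named numeric vector: `uniform_distance`, `dkl_short`,
#'   `rise_time` (ms), `jump_index`, `dkl_long`, `psd_center` (Hz),
#'   `psd_prime_center` (Hz), `firing_rate` (spikes/s).
#' @export
extract_timing_features <- function(ach, spike_times = NULL, rates = NULL) {
  tt <- ach_bin_times()
  y <- ach$counts_up
  short <- y[tt < 50]
  long <- y[tt > 50]

  degenerate <- FALSE
  cdf_feats <- function(w) {
    p <- window_pdf(w)
    if (is.null(p)) {
      degenerate <<- TRUE
      return(c(dist = 0, dkl = 0))
    }
    n <- length(p)
    u <- 1 / n
    cd <- cumsum(p)
    cu <- seq_len(n) / n
    pl <- p[p > 0]
    c(dist = mean(abs(cd - cu)), dkl = sum(pl * log(pl / u)))
  }
  sh <- cdf_feats(short)
  lo <- cdf_feats(long)
  if (degenerate) warning("zero-mass ACH window; distribution features set to 0")

  # rise time: first time at which the window CDF exceeds 1/e
  p_short <- window_pdf(short)
  rise_time <- if (is.null(p_short)) 0 else {
    k <- which(cumsum(p_short) > exp(-1))[1]
    if (is.na(k)) 50 else (k - 0.5) * ACH_DT_MS
  }

  # PSD of the single-sided upsampled ACH; 16000 samples at 0.0625 ms spacing
  # give a 1 Hz frequency grid up to the 8 kHz Nyquist
  P <- Mod(stats::fft(y))^2
  half <- length(y) %/% 2L
  f <- seq_len(half)          # Hz, DC excluded
  Pk <- P[2:(half + 1L)]
  psd_center <- if (sum(Pk) > 0) sum(f * Pk) / sum(Pk) else 0
  dP <- abs(diff(Pk))
  fd <- f[-length(f)] + 0.5
  psd_prime_center <- if (sum(dP) > 0) sum(fd * dP) / sum(dP) else 0

  firing_rate <- if (!is.null(rates)) {
    mean(rates, na.rm = TRUE)
  } else if (!is.null(spike_times) && length(spike_times) >= 2L) {
    span <- max(spike_times) - min(spike_times)
    if (span > 0) length(spike_times) / span else 0
  } else 0

  c(uniform_distance = unname(sh["dist"]), dkl_short = unname(sh["dkl"]),
    rise_time = rise_time, jump_index = unname(lo["dist"]),
    dkl_long = unname(lo["dkl"]), psd_center = psd_center,
    psd_prime_center = psd_prime_center, firing_rate = firing_rate)
}
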