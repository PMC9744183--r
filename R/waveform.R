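# Mean-waveform construction, main-channel selection and the eight
# single-channel waveform features.

UPSAMPLE_FACTOR <- 8L
N_UP <- 256L  # 32 raw samples x 8

#' Fourier (frequency-domain) interpolation
#'
#' Upsamples a vector by an integer factor by zero-padding its discrete
#' spectrum (Nyquist bin split in half), which reconstructs the band-limited
#' signal on the finer grid. Linear, so it commutes with averaging.
#'
#' @param x numeric vector (even length).
#' @param factor integer upsampling factor.
#' @return numeric vector of length `length(x) * factor`.
#' @export
fourier_upsample <- function(x, factor = UPSAMPLE_FACTOR) {
  n <- length(x)
  if (n %% 2L != 0L) stop("fourier_upsample() expects an even-length input")
  N <- n * factor
  X <- stats::fft(x)
  half <- n %/% 2L
  Y <- complex(N)
  Y[1:half] <- X[1:half]
  Y[half + 1L] <- X[half + 1L] / 2
  Y[N - half + 1L] <- X[half + 1L] / 2
  if (half >= 2L) Y[(N - half + 2L):N] <- X[(half + 2L):n]
  Re(stats::fft(Y, inverse = TRUE)) * factor / N
}

#' Mean multichannel waveform, upsampled eightfold
#'
#' Averages the snippets of a spike subset per channel, then interpolates each
#' channel eightfold in the frequency domain, yielding 256 samples per channel
#' at 6.25 us resolution (for 20 kHz acquisition). Averaging and interpolation
#' are both linear and commute.
#'
#' @param unit a [unit_recording()].
#' @param spike_subset integer indices of the spikes to average (default all).
#' @return an object of class `mean_waveform` with elements `values`
#'   (n_channels x 256), `main_channel` (largest trough-to-peak magnitude),
#'   `polarity_inverted`, `scaled`, `upsample_factor` and `dt_us`.
#' @export
mean_and_upsample <- function(unit, spike_subset = NULL) {
  if (is.null(spike_subset)) spike_subset <- seq_len(n_spikes(unit))
  if (!length(spike_subset)) stop("spike subset must be non-empty")
  nch <- dim(unit$snippets)[2]
  raw <- matrix(0, nch, 32L)
  for (ch in seq_len(nch)) {
    sub <- unit$snippets[spike_subset, ch, , drop = FALSE]
    raw[ch, ] <- colMeans(matrix(sub, nrow = length(spike_subset)))
  }
  up <- t(apply(raw, 1L, fourier_upsample))
  structure(list(values = up,
                 main_channel = select_main_channel_values(up),
                 polarity_inverted = FALSE,
                 scaled = FALSE,
                 upsample_factor = UPSAMPLE_FACTOR,
                 dt_us = 1e6 / unit$sampling_rate / UPSAMPLE_FACTOR),
            class = "mean_waveform")
}

#' Construct a mean_waveform from a values matrix
#'
#' Mostly useful for tests and for transformed waveforms.
#' @param values n_channels x 256 matrix.
#' @param dt_us sample spacing in microseconds.
#' @export
mean_waveform <- function(values, dt_us = 6.25) {
  values <- rbind(values)
  if (ncol(values) != N_UP) stop("mean_waveform values must have 256 samples per channel")
  structure(list(values = values,
                 main_channel = select_main_channel_values(values),
                 polarity_inverted = FALSE, scaled = FALSE,
                 upsample_factor = UPSAMPLE_FACTOR, dt_us = dt_us),
            class = "mean_waveform")
}

select_main_channel_values <- function(values) {
  ttp <- apply(values, 1L, function(v) max(v) - min(v))
  which.max(ttp)  # ties resolve to the lowest channel index
}

#' Main-channel index of a mean waveform
#'
#' The channel with the largest trough-to-peak (max minus min) magnitude;
#' exact ties go to the lowest channel index.
#' @param w a `mean_waveform`.
#' @export
select_main_channel <- function(w) select_main_channel_values(w$values)

#' Scale and polarity-align a mean waveform
#'
#' If the main channel's maximal positivity exceeds its maximal negativity in
#' absolute value, the whole multichannel waveform is inverted (so that
#' inter-channel sign relations are preserved). All channels are then divided
#' by the absolute value of the main channel's minimum, mapping the main
#' channel into `[-1, 1]` with its trough at exactly -1. Idempotent.
#'
#' @param w a `mean_waveform`.
#' @return the scaled `mean_waveform`.
#' @export
scale_align <- function(w) {
  v <- w$values
  main <- w$main_channel
  if (all(v == 0)) stop("cannot scale an all-zero waveform")
  inverted <- FALSE
  if (abs(max(v[main, ])) > abs(min(v[main, ]))) {
    v <- -v
    inverted <- TRUE
  }
  v <- v / abs(min(v[main, ]))
  w$values <- v
  w$polarity_inverted <- xor(w$polarity_inverted, inverted)
  w$scaled <- TRUE
  w
}

# Second-derivative windows (ms relative to the trough). Boundaries are
# snapped to the 6.25 us sample grid toward the trough; windows are closed on
# the side nearer the trough and half-open on the far side.
d2_window <- function(from_ms, to_ms, dt_us) {
  # from_ms nearer the trough than to_ms; both positive magnitudes
  near <- floor(from_ms * 1000 / dt_us + 1e-9)
  far <- floor(to_ms * 1000 / dt_us + 1e-9)
  c(near, far)
}

#' Extract the eight single-channel waveform features
#'
#' Operates on a scaled, polarity-aligned 256-sample main-channel vector
#' (minimum exactly -1). Derivatives are adjacent-sample differences; the
#' second derivative is the twice-applied difference, its i-th value aligned
#' with sample i+1. Feature values are reported on the same unit scales as
#' the descriptor set uses: break measure in 1e-1 AU, smile-cry in 1e-2 AU,
#' acceleration in 1e-6 AU.
#'
#' @param x numeric vector of length 256 (scaled main channel).
#' @param dt_us sample spacing, 6.25 us by default.
#' @param speed_tol tolerance band for the maximum-speed feature: the first
#'   derivative counts as "maintaining the same change rate" while it stays
#'   within `speed_tol` of the post-trough maximum derivative (relative).
#' @return named numeric vector with elements `ttp_duration` (ms),
#'   `ttp_magnitude` (AU), `fwhm` (ms), `rise_coefficient` (ms),
#'   `maximum_speed` (ms), `break_measure`, `smile_cry`, `acceleration`.
#' @export
extract_waveform_features <- function(x, dt_us = 6.25, speed_tol = 0.05) {
  n <- length(x)
  dt_ms <- dt_us / 1000
  t <- which.min(x)
  # peak = ensuing maximal positivity; if nothing after the trough is
  # positive, the post-trough global maximum is used regardless of sign
  if (t >= n) p <- t else p <- t + which.max(x[(t + 1L):n])
  ttp_duration <- (p - t) * dt_ms
  ttp_magnitude <- x[p] - x[t]

  # FWHM: width of the contiguous sub-half-trough interval around the trough
  a <- t; while (a > 1L && x[a - 1L] <= -0.5) a <- a - 1L
  b <- t; while (b < n && x[b + 1L] <= -0.5) b <- b + 1L
  fwhm <- (b - a) * dt_ms

  # Rise coefficient: straight line from the trough to the last sample;
  # time from the trough to the maximal absolute deviation from that line
  idx <- t:n
  line <- x[t] + (x[n] - x[t]) * (idx - t) / max(n - t, 1L)
  rise_coefficient <- (idx[which.max(abs(x[idx] - line))] - t) * dt_ms

  # Maximum speed: longest post-trough stretch on which the first derivative
  # stays within the tolerance band of its post-trough maximum
  d1 <- diff(x)
  post <- d1[t:(n - 1L)]
  dmax <- max(post)
  inband <- abs(post - dmax) <= speed_tol * abs(dmax) + 1e-15
  r <- rle(inband)
  maximum_speed <- max(c(0L, r$lengths[r$values])) * dt_ms

  # Second-derivative window sums; d2[i] is aligned with sample i+1
  d2 <- diff(x, differences = 2L)
  d2_at <- function(lo, hi, closed_near_low) {
    # offsets in samples relative to the trough, window [lo, hi) or (lo, hi]
    ks <- if (closed_near_low) seq.int(lo, hi - 1L) else seq.int(lo + 1L, hi)
    samp <- t + ks          # sample index
    i <- samp - 1L          # d2 index for that sample
    d2[i[i >= 1L & i <= length(d2)]]
  }
  w_break <- d2_window(0.08, 0.3, dt_us)   # before the trough
  w_smile <- d2_window(0.26, 0.76, dt_us)  # late after the trough
  w_accel <- d2_window(0.08, 0.25, dt_us)  # just after the trough
  break_measure <- sum(d2_at(-w_break[2], -w_break[1], FALSE)) / 1e-1
  smile_cry <- sum(d2_at(w_smile[1], w_smile[2], TRUE)) / 1e-2
  acceleration <- sum(d2_at(w_accel[1], w_accel[2], TRUE)^2) / 1e-6

  c(ttp_duration = ttp_duration, ttp_magnitude = ttp_magnitude,
    fwhm = fwhm, rise_coefficient = rise_coefficient,
    maximum_speed = maximum_speed, break_measure = break_measure,
    smile_cry = smile_cry, acceleration = acceleration)
}

#' Waveform features of a unit (or spike subset)
#'
#' Convenience wrapper: mean waveform, scaling/alignment, then
#' [extract_waveform_features()] on the main channel.
#' @inheritParams mean_and_upsample
#' @export
waveform_features_of_unit <- function(unit, spike_subset = NULL) {
  w <- scale_align(mean_and_upsample(unit, spike_subset))
  extract_waveform_features(w$values[w$main_channel, ], dt_us = w$dt_us)
}
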