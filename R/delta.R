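# Event detection and the event-based delta-transformation that strips all
# single-channel waveform information from a multichannel mean waveform.

DELTA_CENTER <- 128L  # 0-based; the "129th sample" in 1-based counting

# polarity rule decided once per unit on the main channel and applied jointly
# to all channels, preserving inter-channel sign relations
ensure_polarity <- function(w) {
  main <- w$main_channel
  if (abs(max(w$values[main, ])) > abs(min(w$values[main, ]))) {
    w$values <- -w$values
    w$polarity_inverted <- !w$polarity_inverted
  }
  w
}

#' Per-channel channel mask by trough-to-peak magnitude
#'
#' Channels whose trough-to-peak magnitude is below a fraction of the maximal
#' trough-to-peak magnitude over all channels are flagged out of the
#' time-based and graph-based spatial features. The comparison is `>=`, so a
#' channel sitting exactly on the threshold is kept; the main channel always
#' passes.
#'
#' @param w a `mean_waveform`.
#' @param threshold fraction of the maximal magnitude; 0.25 by default.
#' @return logical vector, one flag per channel.
#' @export
channel_mask <- function(w, threshold = 0.25) {
  ttp <- apply(w$values, 1L, function(v) max(v) - min(v))
  ttp >= threshold * max(ttp)
}

#' Detect the three per-channel events (FMC, NEG, SMC)
#'
#' After joint polarity alignment, the global median is taken over all
#' channels and all samples of the mean waveform. Per channel, NEG is the time
#' of maximal negativity (first minimum on ties); FMC is the nearest sample
#' before NEG that lies strictly above the global median, and SMC the nearest
#' such sample after NEG. A channel that never recrosses the median within the
#' window has the event set to the window edge and is flagged missing for that
#' event (it is then excluded from time- and graph-based features).
#'
#' @param w a `mean_waveform` (scaled or not; detection is scale-free).
#' @param mask_threshold threshold passed to [channel_mask()].
#' @return an object of class `event_set`: a data.frame with 0-based sample
#'   indices `fmc`, `neg`, `smc`, event times in us, `neg_amplitude`,
#'   missing-event flags and the channel `mask`; attributes `global_median`,
#'   `main_channel`, `dt_us`.
#' @export
detect_events <- function(w, mask_threshold = 0.25) {
  w <- ensure_polarity(w)
  v <- w$values
  nch <- nrow(v)
  med <- stats::median(v)
  fmc <- neg <- smc <- integer(nch)
  fmc_missing <- smc_missing <- logical(nch)
  for (ch in seq_len(nch)) {
    x <- v[ch, ]
    nidx <- which.min(x)
    neg[ch] <- nidx
    before <- if (nidx > 1L) which(x[1:(nidx - 1L)] > med) else integer(0)
    if (length(before)) fmc[ch] <- max(before) else {
      fmc[ch] <- 1L; fmc_missing[ch] <- TRUE
    }
    after <- if (nidx < N_UP) which(x[(nidx + 1L):N_UP] > med) + nidx else integer(0)
    if (length(after)) smc[ch] <- min(after) else {
      smc[ch] <- N_UP; smc_missing[ch] <- TRUE
    }
  }
  ev <- data.frame(channel = seq_len(nch),
                   fmc = fmc - 1L, neg = neg - 1L, smc = smc - 1L,
                   fmc_us = (fmc - 1L) * w$dt_us,
                   neg_us = (neg - 1L) * w$dt_us,
                   smc_us = (smc - 1L) * w$dt_us,
                   neg_amplitude = v[cbind(seq_len(nch), neg)],
                   fmc_missing = fmc_missing,
                   smc_missing = smc_missing,
                   mask = channel_mask(w, mask_threshold))
  structure(ev, class = c("event_set", "data.frame"),
            global_median = med, main_channel = w$main_channel,
            dt_us = w$dt_us, global_min = min(v))
}

#' Event-based delta-transformation of a multichannel waveform
#'
#' Each channel is replaced by a delta-like function: zeros everywhere except
#' at the channel's event time, where it takes the channel's maximal
#' negativity scaled by the absolute global minimum over all channels. All
#' channels are then shifted by one common offset so that the main channel's
#' event lands at the 129th sample (0-based index 128), removing the residual
#' waveform information carried by the event times themselves. Events shifted
#' out of the window are dropped and the channel flagged.
#'
#' @param w the `mean_waveform` the events came from.
#' @param ev an [detect_events()] result.
#' @param event one of `"fmc"`, `"neg"`, `"smc"`.
#' @return object of class `delta_waveform`: `values` (n_channels x 256, one
#'   nonzero sample per surviving channel, values in `[-1, 0)`), `scale`
#'   (absolute global minimum), `centered_event`, `dropped` flags.
#' @export
delta_transform <- function(w, ev, event = c("fmc", "neg", "smc")) {
  event <- match.arg(event)
  w <- ensure_polarity(w)
  main <- attr(ev, "main_channel")
  times <- ev[[event]]
  gmin <- attr(ev, "global_min")
  offset <- DELTA_CENTER - times[main]
  nch <- nrow(ev)
  vals <- matrix(0, nch, N_UP)
  dropped <- logical(nch)
  for (ch in seq_len(nch)) {
    idx <- times[ch] + offset
    if (idx >= 0L && idx < N_UP) {
      vals[ch, idx + 1L] <- ev$neg_amplitude[ch] / abs(gmin)
    } else {
      dropped[ch] <- TRUE
    }
  }
  structure(list(values = vals, scale = abs(gmin),
                 centered_event = event, main_channel = main,
                 dropped = dropped, dt_us = attr(ev, "dt_us")),
            class = "delta_waveform")
}

#' Main-channel vector of a delta-transformed waveform as a mean_waveform
#'
#' Wraps the delta-transformed values so that the waveform-feature pipeline
#' can be run on them unchanged (the information-destruction check).
#' @param dw a `delta_waveform`.
#' @export
delta_as_waveform <- function(dw) {
  mean_waveform(dw$values, dt_us = dw$dt_us)
}
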