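# Ground-truth-labeled synthetic populations of PYR-like and PV-like units.
# The generator emulates three class contrasts: waveform width (trough-to-peak
# duration), firing statistics (rate and burstiness), and per-channel
# event-time dispersion (separate FMC/NEG/SMC jitters plus a slow intraunit
# wander that makes across-chunk variability class dependent).

#' Class parameters for the synthetic generator
#'
#' Defaults for the two presets target the reference medians of the recorded
#' populations: PYR-like units are wide-spiked (0.77 ms trough-to-peak), slow
#' (0.69 spikes/s) and bursty, with tight FMC dispersion (15.9 us) and looser
#' NEG dispersion (13.5 us); PV-like units are narrow-spiked (0.29 ms), fast
#' (8.95 spikes/s), near-renewal, with loose FMC (40.6 us) and tight NEG
#' (9.4 us) dispersion and larger intraunit wander.
#'
#' @param label `"PYR"` or `"PV"`.
#' @param rate_hz mean firing rate (spikes/s).
#' @param burst_fraction probability that a spike extends a burst.
#' @param burst_isi_ms intra-burst interspike-interval range (ms).
#' @param refractory_ms absolute refractory period (ms).
#' @param ttp_ms trough-to-peak duration of the template (ms).
#' @param trough_width_ms full width of the trough at half depth (ms).
#' @param amp_decay_per_um spatial amplitude attenuation constant (1/um);
#'   channel amplitude is `exp(-decay * distance_from_soma)`.
#' @param fmc_jitter_us,neg_jitter_us,smc_jitter_us SDs of the per-channel
#'   systematic event-time offsets (us).
#' @param noise_sd additive per-sample noise SD relative to the soma trough
#'   depth.
#' @param n_spikes_range min/max spikes kept per unit.
#' @param intraunit_drift_us SD of the slow per-spike, per-channel timing
#'   wander (us); larger for PV so across-chunk feature SDs separate classes.
#' @return an object of class `class_params`.
#' @export
class_params <- function(label, rate_hz, burst_fraction = 0,
                         burst_isi_ms = c(3, 8), refractory_ms = 1.5,
                         ttp_ms = 0.5, trough_width_ms = 0.2,
                         amp_decay_per_um = 0.022,
                         fmc_jitter_us = 20, neg_jitter_us = 10,
                         smc_jitter_us = 25, noise_sd = 0.025,
                         n_spikes_range = c(25L, 4000L),
                         intraunit_drift_us = 10) {
  stopifnot(rate_hz > 0, refractory_ms > 0,
            burst_fraction >= 0, burst_fraction <= 1,
            fmc_jitter_us >= 0, neg_jitter_us >= 0, smc_jitter_us >= 0)
  structure(as.list(environment()), class = "class_params")
}

#' Preset class parameters
#'
#' `"reference"` returns the PYR/PV defaults described in [class_params()];
#' `"null"` returns a pair of classes with identical templates, rates and
#' jitters (only the labels differ), for chance-level checks.
#'
#' @param preset `"reference"` or `"null"`.
#' @return list with elements `pyr` and `pv`.
#' @export
synth_preset <- function(preset = c("reference", "null")) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    list(pyr = class_params("PYR", rate_hz = 0.69, burst_fraction = 0.3,
                            ttp_ms = 0.77, trough_width_ms = 0.21,
                            fmc_jitter_us = 15.9, neg_jitter_us = 13.5,
                            smc_jitter_us = 26, intraunit_drift_us = 8),
         pv = class_params("PV", rate_hz = 8.95, burst_fraction = 0.02,
                           ttp_ms = 0.29, trough_width_ms = 0.16,
                           fmc_jitter_us = 40.6, neg_jitter_us = 9.4,
                           smc_jitter_us = 24.1, intraunit_drift_us = 25))
  } else {
    base <- function(lab) class_params(lab, rate_hz = 3, burst_fraction = 0.1,
                                       ttp_ms = 0.5, trough_width_ms = 0.19,
                                       fmc_jitter_us = 25, neg_jitter_us = 12,
                                       smc_jitter_us = 25,
                                       intraunit_drift_us = 12)
    list(pyr = base("PYR"), pv = base("PV"))
  }
}

#' Population specification
#'
#' @param n_pyr,n_pv unit counts per class (the reference populations keep
#'   roughly the 80/20 PYR/PV imbalance of the recorded dataset).
#' @param duration_s recording length per unit (s).
#' @param seed master seed; a fixed seed reproduces the population bit-exactly.
#' @param geometry a [probe_geometry()].
#' @param ca1_fraction fraction of units tagged CA1 (the rest are nCX).
#' @export
population_spec <- function(n_pyr, n_pv, duration_s = 300, seed = 1L,
                            geometry = linear_probe_geometry(),
                            ca1_fraction = 0.877) {
  stopifnot(n_pyr >= 0, n_pv >= 0, duration_s > 0)
  structure(list(n_pyr = n_pyr, n_pv = n_pv, duration_s = duration_s,
                 seed = seed, geometry = geometry,
                 ca1_fraction = ca1_fraction),
            class = "population_spec")
}

#' Generate a spike train
#'
#' Interspike intervals follow a two-state mixture: with probability
#' `burst_fraction` an intra-burst interval drawn uniformly from
#' `burst_isi_ms`, otherwise the refractory period plus an exponential whose
#' mean is solved so the overall mean rate equals `rate_hz`. With
#' `burst_fraction = 0` the train is a refractory-modified Poisson process.
#'
#' @param params a [class_params()].
#' @param duration_s train length (s).
#' @param seed integer seed (optional; the caller's RNG is used when `NULL`).
#' @return strictly increasing spike times in `(0, duration_s)`, all ISIs
#'   above the refractory period.
#' @export
generate_spike_train <- function(params, duration_s, seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(seed)) set.seed(seed)
  bf <- params$burst_fraction
  mb <- mean(params$burst_isi_ms) / 1000
  refr <- params$refractory_ms / 1000
  me <- (1 / params$rate_hz - bf * mb) / (1 - bf) - refr
  if (me <= 0) stop("rate too high for the refractory period / burst mix")
  times <- numeric(0)
  t_cur <- 0
  repeat {
    n_draw <- max(64L, ceiling((duration_s - t_cur) * params$rate_hz * 1.3))
    is_burst <- stats::runif(n_draw) < bf
    isi <- ifelse(is_burst,
                  stats::runif(n_draw, params$burst_isi_ms[1],
                               params$burst_isi_ms[2]) / 1000,
                  refr + stats::rexp(n_draw, 1 / me))
    new <- t_cur + cumsum(isi)
    times <- c(times, new)
    t_cur <- new[n_draw]
    if (t_cur >= duration_s) break
  }
  times[times < duration_s]
}

# Continuous per-channel spike template evaluated on a fine (6.25 us) grid.
# Triphasic, fully smooth (hence well band-limited at 20 kHz sampling):
# a pronounced narrow initial positivity (so that a first median crossing
# exists before the trough and sits on a steep, amplitude-insensitive
# descent), a Gaussian trough whose full width at half depth is
# trough_width_ms, and a Gaussian after-potential trough_to_peak later.
# The three event offsets are realized by a smooth time warp: the trough
# center rides d_neg, while the leading and trailing flanks are warped
# toward d_fmc and d_smc respectively, so the first/second median crossings
# and the argmin are controllable separately.
template_fine <- function(params, d_fmc = 0, d_neg = 0, d_smc = 0) {
  dt <- 6.25
  t <- seq(-500, 2100, by = dt)
  c0 <- 500                                        # trough time, us
  sig_t <- params$trough_width_ms * 1000 / 2.355   # FWHM -> Gaussian SD
  tau <- sig_t / 2
  s_left <- stats::plogis((c0 + d_neg - 1.2 * sig_t - t) / tau)
  s_right <- stats::plogis((t - (c0 + d_neg + 1.2 * sig_t)) / tau)
  warp <- d_neg + (d_fmc - d_neg) * s_left + (d_smc - d_neg) * s_right
  tr <- -exp(-((t - warp) - c0)^2 / (2 * sig_t^2))
  peak_c <- c0 + d_smc + params$ttp_ms * 1000      # after-potential
  sig_p <- 0.15 * params$ttp_ms * 1000
  pk <- 0.35 * exp(-(t - peak_c)^2 / (2 * sig_p^2))
  bump_c <- c0 + d_fmc - 2.355 * sig_t - 100       # initial positivity
  bp <- 0.3 * exp(-(t - bump_c)^2 / (2 * 55^2))
  list(t = t, y = tr + pk + bp)
}

#' Generate multichannel snippets for a spike train
#'
#' Builds one continuous template per channel with per-channel systematic
#' FMC/NEG/SMC offsets drawn from the class jitters, attenuates amplitude
#' with distance from a soma channel, applies a slow per-spike AR(1) timing
#' wander per channel, samples 32 points at the acquisition rate per spike,
#' and adds white noise. With zero noise, zero jitters and zero drift every
#' snippet is identical.
#'
#' @param params a [class_params()].
#' @param spike_times spike times (s).
#' @param geometry a [probe_geometry()].
#' @param seed integer seed (optional).
#' @param soma_channel soma channel index; random when `NULL`.
#' @param label,region,unit_id metadata for the resulting unit.
#' @return a [unit_recording()].
#' @export
generate_snippets <- function(params, spike_times, geometry, seed = NULL,
                              soma_channel = NULL, label = params$label,
                              region = "CA1", unit_id = "synth") {
  if (!is.null(seed)) set.seed(seed)
  nch <- n_channels(geometry)
  if (is.null(soma_channel)) soma_channel <- sample.int(nch, 1L)
  ns <- length(spike_times)
  dists <- channel_distances(geometry)[soma_channel, ]
  amps <- exp(-params$amp_decay_per_um * dists)
  # Per-channel systematic event offsets, truncated at 3 SD so the template
  # knots keep their temporal order even for extreme draws. The jitters are
  # specified as the target of the downstream time-lag-SD statistic -- a
  # population SD over the unmasked non-soma channels -- which shrinks
  # small-sample Gaussian SDs by sqrt((k-1)/k) * c4(k); the draws are scaled
  # by the inverse so the recovered medians center on the configured values.
  k <- max(sum(amps >= 0.25) - 1L, 2L)
  c4 <- sqrt(2 / (k - 1)) * gamma(k / 2) / gamma((k - 1) / 2)
  debias <- 1 / (sqrt((k - 1) / k) * c4)
  rtnorm <- function(n, sd) {
    sd <- sd * debias
    pmax(pmin(stats::rnorm(n, 0, sd), 3 * sd), -3 * sd)
  }
  d_fmc <- rtnorm(nch, params$fmc_jitter_us)
  d_neg <- rtnorm(nch, params$neg_jitter_us)
  d_smc <- rtnorm(nch, params$smc_jitter_us)
  snippets <- array(0, dim = c(ns, nch, 32L))
  if (ns == 0L) {
    return(unit_recording(unit_id, spike_times, snippets, label, region))
  }
  t_k <- (0:31) * 50  # us; acquisition grid at 20 kHz
  rho <- 0.98
  for (ch in seq_len(nch)) {
    tmpl <- template_fine(params, d_fmc[ch], d_neg[ch], d_smc[ch])
    # slow AR(1) wander of the channel's timing across spikes
    drift <- numeric(ns)
    if (params$intraunit_drift_us > 0 && ns > 0L) {
      z <- stats::rnorm(ns)
      drift[1] <- params$intraunit_drift_us * z[1]
      if (ns > 1L) for (s in 2:ns) {
        drift[s] <- rho * drift[s - 1L] +
          params$intraunit_drift_us * sqrt(1 - rho^2) * z[s]
      }
      # center per channel: the wander shapes across-chunk variability but
      # leaves the unit's mean waveform at its systematic offsets
      drift <- drift - mean(drift)
    }
    xq <- rep(t_k, times = ns) - rep(drift, each = 32L)
    vals <- stats::approx(tmpl$t, tmpl$y, xout = xq, yleft = 0, yright = 0)$y
    snippets[, ch, ] <- matrix(vals * amps[ch], ns, 32L, byrow = TRUE)
  }
  if (params$noise_sd > 0) {
    snippets <- snippets + array(stats::rnorm(length(snippets), 0, params$noise_sd),
                                 dim = dim(snippets))
  }
  unit_recording(unit_id, spike_times, snippets, label, region)
}

#' Generate a labeled synthetic population
#'
#' Draws `n_pyr + n_pv` units with the given class parameters, assigns region
#' tags by the CA1 fraction, and caps each unit's spike count at
#' `n_spikes_range[2]` (keeping the earliest spikes, which preserves the
#' rate over the retained span). Bit-exactly reproducible for a fixed seed.
#'
#' @param spec a [population_spec()].
#' @param pyr,pv [class_params()] for the two classes (defaults: the
#'   `"reference"` preset).
#' @return list of [unit_recording()] objects (PYR units first).
#' @export
generate_population <- function(spec, pyr = synth_preset()$pyr,
                                pv = synth_preset()$pv) {
  n_tot <- spec$n_pyr + spec$n_pv
  labels <- c(rep("PYR", spec$n_pyr), rep("PV", spec$n_pv))
  regions <- character(n_tot)
  for (lab in c("PYR", "PV")) {
    idx <- which(labels == lab)
    n_ca1 <- round(spec$ca1_fraction * length(idx))
    regions[idx] <- c(rep("CA1", n_ca1), rep("nCX", length(idx) - n_ca1))
  }
  units <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    par <- if (labels[i] == "PYR") pyr else pv
    st <- generate_spike_train(par, spec$duration_s,
                               seed = derive_seed(spec$seed, i))
    cap <- par$n_spikes_range[2]
    if (length(st) > cap) st <- st[seq_len(cap)]
    units[[i]] <- generate_snippets(par, st, spec$geometry,
                                    seed = derive_seed(spec$seed, i + n_tot),
                                    label = labels[i], region = regions[i],
                                    unit_id = sprintf("u%03d", i))
  }
  units
}
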