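# The base feature registry and per-unit feature extraction.

#' The base feature registry
#'
#' Exactly 34 features, partitioned 8 (waveform) / 8 (timing) / 18 (spatial),
#' with the family each feature belongs to.
#'
#' @return data.frame with columns `name`, `modality`, `family`.
#' @export
feature_registry <- function() {
  wf <- c("ttp_duration", "ttp_magnitude", "fwhm", "rise_coefficient",
          "maximum_speed", "break_measure", "smile_cry", "acceleration")
  wf_fam <- c(rep("waveform", 4L), "first_derivative", rep("second_derivative", 3L))
  tm <- c("uniform_distance", "dkl_short", "rise_time", "jump_index",
          "dkl_long", "psd_center", "psd_prime_center", "firing_rate")
  tm_fam <- c(rep("high_frequency", 3L), rep("low_frequency", 2L),
              rep("wide_band", 3L))
  sp <- as.vector(t(outer(SPATIAL_EVENTS,
                          c("time_lag_ss", "time_lag_sd", "average_weight",
                            "longest_path", "shortest_path"), paste, sep = "_")))
  sp_fam <- rep(c(rep("time_based", 2L), rep("graph_based", 3L)), 3L)
  spd <- c("spd_count", "spd_sd", "spd_area")
  data.frame(
    name = c(wf, tm, sp, spd),
    modality = c(rep("waveform", 8L), rep("timing", 8L), rep("spatial", 18L)),
    family = c(wf_fam, tm_fam, sp_fam, rep("value_based", 3L)))
}

feature_names <- function(modalities = c("waveform", "timing", "spatial")) {
  reg <- feature_registry()
  reg$name[reg$modality %in% modalities]
}

#' Extract features for one unit or spike subset
#'
#' Computes the requested modalities from a single mean waveform / ACH:
#' waveform features from the scaled main channel, timing features from the
#' (chunk or pairwise) ACH, spatial features from the delta-event analysis of
#' the multichannel mean waveform.
#'
#' @param unit a [unit_recording()].
#' @param geometry a [probe_geometry()].
#' @param modalities subset of `c("waveform", "timing", "spatial")`.
#' @param spike_subset indices of the spikes to use (default all).
#' @param chunk_mode logical; in chunk mode the ACH is accumulated from
#'   single-spike ACHs and the firing rate is the mean per-spike inverse-ISI
#'   rate of the subset.
#' @return named numeric vector over the selected modalities' features.
#' @export
extract_features <- function(unit, geometry,
                             modalities = c("waveform", "timing", "spatial"),
                             spike_subset = NULL, chunk_mode = FALSE) {
  check_unit_geometry(unit, geometry)
  if (is.null(spike_subset)) spike_subset <- seq_len(n_spikes(unit))
  out <- numeric(0)
  if (any(c("waveform", "spatial") %in% modalities)) {
    w <- mean_and_upsample(unit, spike_subset)
    if ("waveform" %in% modalities) {
      ws <- scale_align(w)
      out <- c(out, extract_waveform_features(ws$values[ws$main_channel, ],
                                              dt_us = ws$dt_us))
    }
    if ("spatial" %in% modalities) {
      out <- c(out, extract_spatial_features(w, geometry))
    }
  }
  if ("timing" %in% modalities) {
    if (chunk_mode) {
      ach <- chunk_ach(unit$spike_times, spike_subset)
      rates <- per_spike_rates(unit$spike_times)[spike_subset]
      tf <- extract_timing_features(ach, rates = rates)
    } else {
      ach <- compute_ach(unit$spike_times)
      tf <- extract_timing_features(ach, spike_times = unit$spike_times)
    }
    out <- c(out, tf)
  }
  out[feature_names(modalities)]
}

#' Feature table of a population (no chunking)
#'
#' One row per unit with metadata columns and the selected base features,
#' plus the chunk-statistic columns computed from the unit's single
#' "chunk" (itself), so the column layout matches chunked tables.
#'
#' @param units list of [unit_recording()] objects.
#' @param geometry a [probe_geometry()].
#' @param modalities feature modalities to extract.
#' @param chunk_stats append the sixfold chunk-statistic columns.
#' @return data.frame feature table.
#' @export
feature_table <- function(units, geometry,
                          modalities = c("waveform", "timing", "spatial"),
                          chunk_stats = TRUE) {
  chunk_feature_table(units, C = "none", geometry = geometry,
                      modalities = modalities, seed = 0L,
                      chunk_stats = chunk_stats)
}
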