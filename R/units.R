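#' A single unit's recording
#'
#' Container for one sorted unit: spike times, the raw multichannel spike
#' snippets (32 samples per channel at the acquisition rate), a ground-truth
#' label and a brain-region tag.
#'
#' @param unit_id character identifier.
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param snippets numeric array `n_spikes x n_channels x 32` of voltage
#'   samples (arbitrary units).
#' @param label `"PYR"`, `"PV"` or `"unknown"`.
#' @param region `"CA1"` or `"nCX"`.
#' @param sampling_rate acquisition rate in Hz; 20000 by default, so a
#'   32-sample snippet spans 1.6 ms.
#' @return an object of class `unit_recording`.
#' @export
unit_recording <- function(unit_id, spike_times, snippets,
                           label = "unknown", region = "CA1",
                           sampling_rate = 20000) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && any(diff(spike_times) <= 0)) {
    stop("spike_times must be strictly increasing")
  }
  if (!is.array(snippets) || length(dim(snippets)) != 3L) {
    stop("snippets must be an n_spikes x n_channels x n_samples array")
  }
  d <- dim(snippets)
  if (d[3] != 32L) stop("raw snippets must have 32 samples per channel")
  if (d[1] != length(spike_times)) {
    stop("snippet count must equal the number of spike times")
  }
  if (!label %in% c("PYR", "PV", "unknown")) stop("invalid label")
  if (!region %in% c("CA1", "nCX")) stop("invalid region")
  structure(list(unit_id = as.character(unit_id),
                 label = label, region = region,
                 spike_times = spike_times,
                 snippets = snippets,
                 sampling_rate = sampling_rate),
            class = "unit_recording")
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf("<unit_recording %s: %d spikes, %d channels, %s, %s>\n",
              x$unit_id, length(x$spike_times), dim(x$snippets)[2],
              x$label, x$region))
  invisible(x)
}

n_spikes <- function(unit) length(unit$spike_times)

#' Dataset manifest
#'
#' Summarizes a dataset: unit counts per label and region, the chunk size in
#' use, and the seed that reproduces any random stage downstream.
#'
#' @param units list of [unit_recording()] objects.
#' @param chunk_size `"none"` or one of 25, 50, 100, 200, 400, 800, 1600.
#' @param seed integer seed recorded with the dataset.
#' @return an object of class `dataset_manifest` with a label x region count
#'   table, `chunk_size` and `seed`.
#' @export
dataset_manifest <- function(units, chunk_size = "none", seed = 1L) {
  if (!identical(chunk_size, "none") &&
      !as.integer(chunk_size) %in% CHUNK_SIZES) {
    stop("chunk_size must be \"none\" or one of 25, 50, 100, 200, 400, 800, 1600")
  }
  counts <- table(label = vapply(units, `[[`, "", "label"),
                  region = vapply(units, `[[`, "", "region"))
  structure(list(counts = counts, chunk_size = chunk_size,
                 seed = as.integer(seed)),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d units, chunk size %s, seed %d>\n",
              sum(x$counts), as.character(x$chunk_size), x$seed))
  print(x$counts)
  invisible(x)
}

check_unit_geometry <- function(unit, geometry) {
  if (dim(unit$snippets)[2] != n_channels(geometry)) {
    stop(sprintf("unit %s has %d channels but geometry declares %d",
                 unit$unit_id, dim(unit$snippets)[2], n_channels(geometry)))
  }
  invisible(TRUE)
}
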