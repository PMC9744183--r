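# Readers and writers for the native dataset container, Neurosuite files,
# feature tables, and the plain-text pipeline configuration.

#' Write a set of units to the native container
#'
#' The native container is a single plain-text file holding every unit of a
#' dataset: a header (format tag, sampling rate, channel count, unit count)
#' followed by one block per unit. Floats are written with 17 significant
#' digits so spike times and snippets round-trip bit-exactly.
#'
#' @param units list of [unit_recording()] objects.
#' @param path output file path.
#' @export
write_units <- function(units, path) {
  if (!length(units)) stop("no units to write")
  sr <- units[[1]]$sampling_rate
  nch <- dim(units[[1]]$snippets)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("spatspike-units v1",
               paste("sampling_rate", fmt_dbl(sr)),
               paste("n_channels", nch),
               paste("n_units", length(units))), con)
  for (u in units) {
    if (dim(u$snippets)[2] != nch) stop("all units must share the channel count")
    ns <- n_spikes(u)
    writeLines(paste("@unit", u$unit_id, u$label, u$region, ns), con)
    writeLines(paste(fmt_dbl(u$spike_times), collapse = " "), con)
    # one line per spike: channels concatenated, 32 samples each
    if (ns > 0L) {
      flat <- matrix(aperm(u$snippets, c(3L, 2L, 1L)), nrow = ns, byrow = TRUE)
      writeLines(apply(flat, 1L, function(r) paste(fmt_dbl(r), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read units from the native container
#'
#' @param path container file written by [write_units()].
#' @param geometry a [probe_geometry()]; the container's channel count must
#'   match it.
#' @return list of [unit_recording()] objects, in file order.
#' @export
read_units <- function(path, geometry) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "spatspike-units v1") {
    stop("not a spatspike unit container")
  }
  hdr <- strsplit(lines[2:4], " ", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1L)
  if (!identical(keys, c("sampling_rate", "n_channels", "n_units"))) {
    stop("container header is missing sampling rate, channel count or unit count")
  }
  sr <- as.numeric(hdr[[1]][2])
  nch <- as.integer(hdr[[2]][2])
  nu <- as.integer(hdr[[3]][2])
  if (nch != n_channels(geometry)) {
    stop(sprintf("container has %d channels but geometry declares %d",
                 nch, n_channels(geometry)))
  }
  units <- vector("list", nu)
  i <- 5L
  for (k in seq_len(nu)) {
    hd <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (hd[1] != "@unit") stop("malformed container: expected @unit block")
    ns <- as.integer(hd[5])
    st <- scan(text = lines[i + 1L], quiet = TRUE)
    if (length(st) != ns) stop("spike time count mismatch in container")
    vals <- if (ns > 0L) {
      scan(text = lines[(i + 2L):(i + 1L + ns)], quiet = TRUE)
    } else numeric(0)
    snip <- aperm(array(vals, dim = c(32L, nch, ns)), c(3L, 2L, 1L))
    units[[k]] <- unit_recording(hd[2], st, snip, label = hd[3],
                                 region = hd[4], sampling_rate = sr)
    i <- i + 2L + ns
  }
  units
}

#' Read Neurosuite .spk/.res/.clu files
#'
#' Reads the classic sorted-spike file family: `.spk` holds interleaved 16-bit
#' snippet samples (sample-major within channel, channel-major within spike),
#' `.res` spike times as sample indices, and `.clu` cluster ids preceded by the
#' cluster count. Clusters 0 and 1 are reserved for noise/artifact by
#' convention and are skipped. Labels are not stored in these files and must be
#' assigned afterwards.
#'
#' @param spk_path,res_path,clu_path file paths.
#' @param n_channels channels per snippet.
#' @param samples_per_spike samples per channel per snippet (32).
#' @param sampling_rate Hz; spike times are `res / sampling_rate`.
#' @return list of [unit_recording()] objects, one per cluster id > 1, ordered
#'   by cluster id, with labels `"unknown"`.
#' @export
read_neurosuite <- function(spk_path, res_path, clu_path,
                            n_channels = 8L, samples_per_spike = 32L,
                            sampling_rate = 20000) {
  res <- as.numeric(scan(res_path, what = numeric(), quiet = TRUE))
  clu <- as.integer(scan(clu_path, what = integer(), quiet = TRUE))
  if (!length(clu)) stop("empty .clu file")
  clu <- clu[-1L]  # leading entry is the cluster count
  if (length(clu) != length(res)) stop(".res and .clu lengths differ")
  n_total <- length(res)
  per_spike <- n_channels * samples_per_spike
  spk <- readBin(spk_path, what = "integer", size = 2L, signed = TRUE,
                 n = n_total * per_spike + 1L, endian = "little")
  if (length(spk) != n_total * per_spike) {
    stop(".spk sample count does not match the .res spike count")
  }
  ids <- sort(unique(clu[clu > 1L]))
  lapply(ids, function(id) {
    sel <- which(clu == id)
    ord <- order(res[sel])
    sel <- sel[ord]
    # spk layout per spike: channel-major, 32 samples per channel
    snip <- array(0, dim = c(length(sel), n_channels, samples_per_spike))
    for (k in seq_along(sel)) {
      block <- spk[((sel[k] - 1L) * per_spike + 1L):(sel[k] * per_spike)]
      snip[k, , ] <- matrix(block, nrow = n_channels, byrow = TRUE)
    }
    unit_recording(sprintf("clu%d", id), res[sel] / sampling_rate, snip,
                   sampling_rate = sampling_rate)
  })
}

#' Write a feature table as CSV
#'
#' Delimited UTF-8 text with a header row and '.' as decimal mark; numeric
#' cells carry 15 significant digits and round-trip well beyond the 12 digits
#' the contract requires.
#'
#' @param table data.frame with metadata columns (`unit_id`, `label`,
#'   `region`, optionally `chunk`) and numeric feature columns.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table)) > 0L) stop("duplicate column names in feature table")
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  meta <- intersect(c("unit_id", "label", "region", "chunk"), names(tab))
  for (m in meta) tab[[m]] <- as.character(tab[[m]])
  if ("chunk" %in% names(tab)) tab$chunk <- as.integer(tab$chunk)
  tab
}

#' Read a pipeline configuration file
#'
#' YAML with keys `channels`, `coords_um` (list of `[x, y]` pairs),
#' `sampling_rate`, `chunk_size`, `seed`, `n_partitions`, and `grids`.
#'
#' @param path YAML file.
#' @return named list; `geometry` is materialized as a [probe_geometry()]
#'   when `channels`/`coords_um` are present.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$channels) && !is.null(cfg$coords_um)) {
    cfg$geometry <- probe_geometry(cfg$channels,
                                   do.call(rbind, cfg$coords_um))
  }
  cfg
}
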