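# The 18 purely spatial features: time-based and graph-based per event
# (FMC, NEG, SMC) plus the value-based spatial-dispersion (SPD) family.

SPATIAL_EVENTS <- c("fmc", "neg", "smc")

# channels usable for time/graph features of one event: masked-in, event not
# missing, and not shifted out of the window
event_channels <- function(ev, event) {
  ok <- ev$mask
  if (event == "fmc") ok <- ok & !ev$fmc_missing
  if (event == "smc") ok <- ok & !ev$smc_missing
  which(ok)
}

#' Time-based spatial features of one event
#'
#' Offsets are the event times of the unmasked non-main channels minus the
#' main channel's event time, in microseconds. `time_lag_ss` is the mean of
#' the squared offsets, reported in 1e3 us^2; `time_lag_sd` is the population
#' standard deviation of the offsets (us). With fewer than two usable
#' channels both are `NA`.
#'
#' @param ev an [detect_events()] result.
#' @param event `"fmc"`, `"neg"` or `"smc"`.
#' @return named numeric vector `c(time_lag_ss, time_lag_sd)`.
#' @export
time_based_features <- function(ev, event = c("fmc", "neg", "smc")) {
  event <- match.arg(event)
  main <- attr(ev, "main_channel")
  chs <- event_channels(ev, event)
  if (length(chs) < 2L || !(main %in% chs)) {
    return(c(time_lag_ss = NA_real_, time_lag_sd = NA_real_))
  }
  t_us <- ev[[paste0(event, "_us")]]
  off <- t_us[setdiff(chs, main)] - t_us[main]
  c(time_lag_ss = mean(off^2) / 1e3, time_lag_sd = pop_sd(off))
}

#' Build the directed event graph of one event
#'
#' Nodes are the usable channels with their event times and probe positions;
#' a directed edge runs from every strictly earlier event to every strictly
#' later one ("nonoverlapping"), weighted by transmission speed: Euclidean
#' electrode distance (mm) over the time difference (s), in mm/s.
#' Simultaneous events are not connected, so the graph is acyclic.
#'
#' @param ev an [detect_events()] result.
#' @param event `"fmc"`, `"neg"` or `"smc"`.
#' @param geometry a [probe_geometry()].
#' @return list with `nodes` (channel, time_us) and `edges`
#'   (from, to, weight) data.frames.
#' @export
build_event_graph <- function(ev, event = c("fmc", "neg", "smc"), geometry) {
  event <- match.arg(event)
  chs <- event_channels(ev, event)
  if (length(chs) < 2L) stop("event graph needs at least 2 usable channels")
  t_us <- ev[[paste0(event, "_us")]][chs]
  D <- channel_distances(geometry)[chs, chs, drop = FALSE]
  from <- to <- integer(0)
  wt <- numeric(0)
  for (i in seq_along(chs)) for (j in seq_along(chs)) {
    if (t_us[i] < t_us[j]) {
      from <- c(from, i); to <- c(to, j)
      # um -> mm and us -> s: (d/1000) / (dt * 1e-6) = d * 1000 / dt
      wt <- c(wt, D[i, j] * 1000 / (t_us[j] - t_us[i]))
    }
  }
  list(nodes = data.frame(channel = chs, time_us = t_us),
       edges = data.frame(from = from, to = to, weight = wt))
}

# Dynamic program over the DAG: heaviest/lightest total edge weight over
# directed paths from an earliest-event node to a latest-event node. The
# unconstrained variant optimizes over all start/end nodes instead.
dag_path_extrema <- function(g, constrained = TRUE) {
  nn <- nrow(g$nodes)
  e <- g$edges
  if (nrow(e) == 0L) return(c(longest = NA_real_, shortest = NA_real_))
  tm <- g$nodes$time_us
  ord <- order(tm)
  if (constrained) {
    starts <- which(tm == min(tm))
    ends <- which(tm == max(tm))
    best_hi <- rep(-Inf, nn); best_lo <- rep(Inf, nn)
    best_hi[starts] <- 0; best_lo[starts] <- 0
    for (v in ord) {
      for (k in which(e$to == v)) {
        u <- e$from[k]; w <- e$weight[k]
        if (best_hi[u] > -Inf) best_hi[v] <- max(best_hi[v], best_hi[u] + w)
        if (best_lo[u] < Inf) best_lo[v] <- min(best_lo[v], best_lo[u] + w)
      }
    }
    hi <- best_hi[ends]; lo <- best_lo[ends]
  } else {
    # free endpoints, paths with at least one edge; with positive weights the
    # minimum degenerates to the single lightest edge
    hi <- rep(-Inf, nn); lo <- rep(Inf, nn)
    for (v in ord) {
      for (k in which(e$to == v)) {
        u <- e$from[k]; w <- e$weight[k]
        hi[v] <- max(hi[v], w + max(hi[u], 0))
        lo[v] <- min(lo[v], w + min(lo[u], 0))
      }
    }
  }
  c(longest = if (any(is.finite(hi))) max(hi[is.finite(hi)]) else NA_real_,
    shortest = if (any(is.finite(lo))) min(lo[is.finite(lo)]) else NA_real_)
}

#' Graph-based spatial features
#'
#' Average edge weight, and the heaviest and lightest path sums through the
#' event graph. By default paths are constrained to run from an
#' earliest-event node to a latest-event node (an unconstrained lightest
#' "path" would degenerate to the single lightest edge; set
#' `constrained = FALSE` for that variant). An empty edge set (all events
#' simultaneous) yields `NA` for all three.
#'
#' @param g a [build_event_graph()] result.
#' @param constrained restrict path termini to earliest/latest events.
#' @return named vector `c(average_weight, longest_path, shortest_path)`
#'   in mm/s.
#' @export
graph_features <- function(g, constrained = TRUE) {
  if (nrow(g$edges) == 0L) {
    return(c(average_weight = NA_real_, longest_path = NA_real_,
             shortest_path = NA_real_))
  }
  ex <- dag_path_extrema(g, constrained = constrained)
  c(average_weight = mean(g$edges$weight),
    longest_path = unname(ex["longest"]),
    shortest_path = unname(ex["shortest"]))
}

#' Value-based spatial-dispersion (SPD) features
#'
#' Uses all channels (no mask): the per-channel maximal negativities are
#' scaled by the global maximal negativity to a vector `v` in `[0, 1]` with
#' maximum 1 (channels without a negative trough clamp to 0). `spd_count` is
#' the number of values at or above 0.5, `spd_sd` the population SD of `v`,
#' and `spd_area` the area under the channel-count-versus-threshold curve,
#' which equals `sum(v)` exactly.
#'
#' @param ev an [detect_events()] result.
#' @return named vector `c(spd_count, spd_sd, spd_area)`.
#' @export
spd_features <- function(ev) {
  amp <- ev$neg_amplitude
  gmin <- min(amp)
  v <- pmax(-amp, 0) / abs(gmin)
  c(spd_count = sum(v >= 0.5), spd_sd = pop_sd(v), spd_area = sum(v))
}

#' The 18 spatial features of a multichannel mean waveform
#'
#' Detects events, applies the 25 percent trough-to-peak mask, and computes
#' the time-based and graph-based features for each of FMC, NEG and SMC plus
#' the three SPD features. Degenerate events (fewer than two usable channels,
#' or all simultaneous) propagate as `NA`; the model pipeline imputes them
#' with training-set medians.
#'
#' @param w a `mean_waveform`.
#' @param geometry a [probe_geometry()].
#' @param mask_threshold trough-to-peak mask threshold.
#' @param constrained_paths see [graph_features()].
#' @return named numeric vector of length 18.
#' @export
extract_spatial_features <- function(w, geometry, mask_threshold = 0.25,
                                     constrained_paths = TRUE) {
  ev <- detect_events(w, mask_threshold)
  out <- numeric(0)
  for (e in SPATIAL_EVENTS) {
    tb <- time_based_features(ev, e)
    gf <- if (length(event_channels(ev, e)) >= 2L) {
      graph_features(build_event_graph(ev, e, geometry), constrained_paths)
    } else {
      c(average_weight = NA_real_, longest_path = NA_real_,
        shortest_path = NA_real_)
    }
    names(tb) <- paste0(e, "_", names(tb))
    names(gf) <- paste0(e, "_", names(gf))
    out <- c(out, tb, gf)
  }
  c(out, spd_features(ev))
}
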