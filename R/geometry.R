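#' Probe geometry
#'
#' Describes the recording sites of one probe shank: integer channel
#' identifiers and per-channel (x, y) positions in micrometers. Distances
#' between sites feed the graph-based spatial features (converted to mm so
#' that edge weights come out in mm/s).
#'
#' @param channel_ids integer vector of channel identifiers.
#' @param coords numeric matrix with one row per channel and columns x, y (um).
#' @return an object of class `probe_geometry`.
#' @examples
#' g <- linear_probe_geometry()
#' channel_distances(g)[1, 2]  # 20 um vertical pitch
#' @export
probe_geometry <- function(channel_ids, coords) {
  coords <- as.matrix(coords)
  if (length(channel_ids) < 2L) stop("probe geometry needs at least 2 channels")
  if (nrow(coords) != length(channel_ids) || ncol(coords) != 2L) {
    stop("`coords` must be an n_channels x 2 matrix of (x, y) positions in um")
  }
  if (anyDuplicated(coords) > 0L) stop("channel positions must be pairwise distinct")
  if (anyDuplicated(channel_ids) > 0L) stop("channel ids must be unique")
  structure(list(channel_ids = as.integer(channel_ids),
                 coords = unname(coords)),
            class = "probe_geometry")
}

#' Default linear shank geometry
#'
#' A single column of recording sites with fixed vertical pitch; the default
#' (8 channels, 20 um pitch) matches the per-shank site layout assumed
#' throughout the package.
#'
#' @param n_channels number of sites.
#' @param pitch_um vertical spacing between neighboring sites (um).
#' @export
linear_probe_geometry <- function(n_channels = 8L, pitch_um = 20) {
  probe_geometry(seq_len(n_channels),
                 cbind(x = rep(0, n_channels),
                       y = (seq_len(n_channels) - 1L) * pitch_um))
}

#' Pairwise Euclidean distances between channels (um)
#' @param geometry a [probe_geometry()].
#' @export
channel_distances <- function(geometry) {
  as.matrix(stats::dist(geometry$coords))
}

n_channels <- function(geometry) length(geometry$channel_ids)
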