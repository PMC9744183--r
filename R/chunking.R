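# Chunk partitioning, per-chunk feature tables, chunk statistics, and
# unit-level vote pooling.

CHUNK_SIZES <- c(25L, 50L, 100L, 200L, 400L, 800L, 1600L)

#' Randomly partition a unit's spikes into chunks
#'
#' For N spikes and chunk size C, the spikes are randomly split into
#' `floor(N / C)` chunks whose sizes all lie in `[C, 2C - 1]` and differ by at
#' most one spike. A unit with fewer than C spikes contributes a single chunk
#' of all its spikes (so label balance is unaffected by small units).
#'
#' @param N number of spikes.
#' @param C chunk size (spikes), or `"none"` for a single all-spike chunk.
#' @param seed integer seed making the random assignment reproducible.
#' @return list of disjoint integer index vectors covering `1:N`.
#' @export
make_chunks <- function(N, C, seed = 1L) {
  if (N < 1L) stop("N must be at least 1")
  if (identical(C, "none") || is.na(suppressWarnings(as.integer(C)))) {
    return(list(seq_len(N)))
  }
  C <- as.integer(C)
  if (C < 1L) stop("C must be at least 1")
  if (N < C) return(list(seq_len(N)))
  k <- N %/% C
  set.seed(seed)
  perm <- sample.int(N)
  base <- N %/% k
  rem <- N %% k
  sizes <- c(rep(base + 1L, rem), rep(base, k - rem))
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

chunk_stat_suffixes <- c("__mean", "__sd", "__q25", "__q50", "__q75")

# mean, SD and quartiles of each base feature across a unit's chunks;
# identical for all chunks of the unit. A single chunk has SD 0.
chunk_statistics <- function(feat_mat) {
  apply(feat_mat, 2L, function(col) {
    ok <- col[is.finite(col)]
    if (!length(ok)) return(rep(NA_real_, 5L))
    q <- stats::quantile(ok, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean(ok), if (length(ok) > 1L) stats::sd(ok) else 0, q)
  })
}

#' Per-chunk feature table of a population
#'
#' Splits every unit's spikes into chunks, extracts the selected base
#' features per chunk (waveforms averaged within the chunk; chunk ACHs
#' accumulated from single-spike ACHs; per-spike firing rates), and appends
#' the five chunk statistics of each feature, expanding the column count
#' sixfold. Chunk statistics are computed (from the single all-spike chunk)
#' for `C = "none"` too, so chunked and unchunked tables share one layout.
#' Every chunk row carries the label, region and id of its source unit.
#'
#' @param units list of [unit_recording()] objects.
#' @param C chunk size in spikes (one of 25, 50, ..., 1600) or `"none"`.
#' @param geometry a [probe_geometry()].
#' @param modalities feature modalities to extract.
#' @param seed master seed for the random chunk assignments.
#' @param chunk_stats append chunk-statistic columns (default TRUE).
#' @return data.frame with columns `unit_id`, `chunk`, `label`, `region`,
#'   then base features, then chunk-statistic columns.
#' @export
chunk_feature_table <- function(units, C, geometry,
                                modalities = c("waveform", "timing", "spatial"),
                                seed = 1L, chunk_stats = TRUE) {
  fn <- feature_names(modalities)
  chunked <- !identical(C, "none")
  rows <- list()
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    if (n_spikes(u) == 0L) {
      warning(sprintf("unit %s has no spikes; skipped", u$unit_id))
      next
    }
    chunks <- make_chunks(n_spikes(u), C, seed = derive_seed(seed, ui))
    fm <- t(vapply(chunks, function(idx) {
      extract_features(u, geometry, modalities, spike_subset = idx,
                       chunk_mode = chunked)
    }, numeric(length(fn))))
    colnames(fm) <- fn
    df <- data.frame(unit_id = u$unit_id, chunk = seq_along(chunks),
                     label = u$label, region = u$region,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(fm, check.names = FALSE))
    if (chunk_stats) {
      st <- chunk_statistics(fm)  # 5 x n_features
      stat_cols <- as.data.frame(matrix(rep(as.vector(st), each = nrow(fm)),
                                        nrow = nrow(fm)), check.names = FALSE)
      names(stat_cols) <- as.vector(outer(chunk_stat_suffixes, fn,
                                          function(s, f) paste0(f, s)))
      # reorder so each feature's statistics sit together
      ord <- as.vector(t(outer(fn, chunk_stat_suffixes, paste0)))
      df <- cbind(df, stat_cols[, ord, drop = FALSE])
    }
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) {
    cols <- c("unit_id", "chunk", "label", "region", fn,
              if (chunk_stats) as.vector(t(outer(fn, chunk_stat_suffixes, paste0))))
    out <- as.data.frame(matrix(numeric(0), 0L, length(cols)), check.names = FALSE)
    names(out) <- cols
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool per-chunk predictions into a unit-level vote
#'
#' A chunk votes PV when its score reaches 0.5. The unit label is the
#' majority class with ties broken toward the positive (PV) class, and the
#' unit score -- used for unit-level ROC curves -- is the fraction of chunks
#' voting PV.
#'
#' @param scores numeric per-chunk PV scores in `[0, 1]` (or a character
#'   vector of per-chunk labels).
#' @return list with `label` (`"PYR"`/`"PV"`) and `score` (PV-vote fraction).
#' @export
pool_votes <- function(scores) {
  if (!length(scores)) stop("pool_votes() needs at least one chunk prediction")
  votes <- if (is.character(scores) || is.factor(scores)) {
    as.character(scores) == "PV"
  } else {
    as.numeric(scores) >= 0.5
  }
  frac <- mean(votes)
  list(label = if (frac >= 0.5) "PV" else "PYR", score = frac)
}
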