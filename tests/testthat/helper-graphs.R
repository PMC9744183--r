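# Fabricate an event_set directly, and an exhaustive path-enumeration oracle
# for the event-graph dynamic program.

fake_events <- function(times_us, mask = rep(TRUE, length(times_us)),
                        main = 1L, amps = NULL) {
  n <- length(times_us)
  if (is.null(amps)) amps <- rep(-1, n)
  ev <- data.frame(channel = seq_len(n),
                   fmc = 0L, neg = 0L, smc = 0L,
                   fmc_us = times_us, neg_us = times_us, smc_us = times_us,
                   neg_amplitude = amps,
                   fmc_missing = FALSE, smc_missing = FALSE, mask = mask)
  structure(ev, class = c("event_set", "data.frame"),
            global_median = 0, main_channel = main, dt_us = 6.25,
            global_min = min(amps))
}

enumerate_paths <- function(g, constrained = TRUE) {
  tm <- g$nodes$time_us
  n <- length(tm)
  starts <- if (constrained) which(tm == min(tm)) else seq_len(n)
  ends <- if (constrained) which(tm == max(tm)) else seq_len(n)
  adj <- lapply(seq_len(n), function(i) which(g$edges$from == i))
  best <- c(-Inf, Inf)
  walk <- function(v, total, has_edge) {
    if (v %in% ends && has_edge) {
      best[1] <<- max(best[1], total); best[2] <<- min(best[2], total)
    }
    for (k in adj[[v]]) walk(g$edges$to[k], total + g$edges$weight[k], TRUE)
  }
  for (s in starts) walk(s, 0, FALSE)
  if (!is.finite(best[1])) c(NA_real_, NA_real_) else best
}
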