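# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage (spike-train generation, chunk assignment, data
#' partitioning, permutation nulls) draws its own seed deterministically from a
#' single master seed, so whole-pipeline runs are reproducible bit-exactly.
#' Results stay within the 32-bit signed integer range R requires.
#'
#' @param master integer master seed.
#' @param salt integer salt distinguishing the consumer.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, salt) {
  m <- as.numeric(master) %% 1000003
  s <- as.numeric(salt) %% 1000003
  as.integer(((m * 2099 + s * 7919 + 1) %% 2147483629) + 1)
}

# Population (divide-by-n) standard deviation. Used for the time-lag and SPD
# dispersion features, where the channels at hand are the whole population of
# interest rather than a sample.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Unit-level ROC AUC for PV-versus-PYR scores
#'
#' Thin wrapper around [pROC::roc()] with fixed level order and direction so
#' that `scores` are always interpreted as evidence for the PV class. Constant
#' scores yield exactly 0.5.
#'
#' @param labels factor or character vector with values `"PYR"` / `"PV"`.
#' @param scores numeric scores, larger meaning more PV-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("roc_auc() needs both classes present in `labels`")
  }
  if (length(unique(scores)) == 1L) return(0.5)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c("PYR", "PV"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Format a double so that it round-trips bit-exactly through text.
fmt_dbl <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
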