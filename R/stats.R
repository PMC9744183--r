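# Effect sizes, mutual information with permutation nulls, rank-correlation
# group comparisons, nonparametric group tests, and the SHAP importance
# report with its shuffled-label null.

#' Nonparametric common-language effect size A_w
#'
#' Estimates the probability that a random draw from one sample exceeds a
#' random draw from the other, counting ties as one half. The direction is
#' disregarded by folding to the `[0.5, 1]` range: 0.5 for fully intermixed
#' distributions, 1 for non-overlapping ones. The p-value is a two-sided
#' Mann-Whitney U test.
#'
#' @param a,b numeric samples.
#' @return list with `a_w`, `direction` (`"a"` or `"b"`, the stochastically
#'   larger sample), `p_hat` (the unfolded probability that a > b), and
#'   `p_value`.
#' @export
a_w <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # #(a>b) + 0.5 #(a=b)
  p_hat <- u / (na * nb)
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  list(a_w = max(p_hat, 1 - p_hat),
       direction = if (p_hat >= 0.5) "a" else "b",
       p_hat = p_hat, p_value = p)
}

# equal-count (quantile) binning via ranks; naturally discrete variables
# (< `bins` unique values) keep their own categories
discretize <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) < bins) return(match(x, ux))
  ceiling(bins * rank(x, ties.method = "first") / length(x))
}

#' Plug-in mutual information with a permutation null
#'
#' Bins each variable into `bins` equal-count bins (variables with fewer than
#' `bins` unique values are treated as naturally discrete) and computes the
#' plug-in mutual information of the contingency table in bits; 10 bins cap
#' the MI at log2(10) = 3.3 bits. The one-tailed p-value is the fraction of
#' `n_perm` pair-shuffled replicates whose MI reaches the observed value.
#' Equal-count binning makes the estimate invariant under strictly monotone
#' transforms of either variable.
#'
#' @param x,y numeric vectors of equal length (at least 10).
#' @param bins number of bins (10).
#' @param n_perm permutation count for the null (5000 in the reference
#'   analysis).
#' @param seed integer seed for the permutations.
#' @return list with `mi` (bits) and `p_value`.
#' @export
mutual_information <- function(x, y, bins = 10L, n_perm = 5000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10L) stop("need at least 10 paired observations")
  bx <- discretize(x, bins)
  by <- discretize(y, bins)
  mi_of <- function(bx, by) {
    tab <- table(bx, by) / length(bx)
    px <- rowSums(tab); py <- colSums(tab)
    pos <- tab > 0
    sum(tab[pos] * log2(tab[pos] / outer(px, py)[pos]))
  }
  mi <- mi_of(bx, by)
  set.seed(seed)
  null <- replicate(n_perm, mi_of(bx, sample(by)))
  list(mi = mi, p_value = (1 + sum(null >= mi)) / (n_perm + 1))
}

#' Permutation comparison of two groups of correlation coefficients
#'
#' Tests whether the median of one group of (rank) correlation coefficients
#' exceeds that of the other: the statistic is the difference of group
#' medians, and the one-tailed p-value compares it with a null built by
#' shuffling coefficients between the groups.
#'
#' @param cc_a,cc_b numeric vectors of correlation coefficients.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with `statistic` (median difference) and `p_value`.
#' @export
compare_cc_groups <- function(cc_a, cc_b, n_perm = 1000L, seed = 1L) {
  if (!length(cc_a) || !length(cc_b)) stop("both groups must be non-empty")
  pool <- c(cc_a, cc_b)
  na <- length(cc_a)
  stat <- stats::median(cc_a) - stats::median(cc_b)
  set.seed(seed)
  null <- replicate(n_perm, {
    idx <- sample.int(length(pool), na)
    stats::median(pool[idx]) - stats::median(pool[-idx])
  })
  list(statistic = stat, p_value = (1 + sum(null >= stat)) / (n_perm + 1))
}

#' Fold chunk-statistic attributions into their base features
#'
#' Sums the absolute attributions of a feature's chunk-statistic columns
#' (`__mean`, `__sd`, `__q25`, `__q50`, `__q75`) into the base feature,
#' yielding one importance value per base feature.
#'
#' @param attr named numeric vector (or matrix with named columns) of
#'   attributions over a chunked table's columns.
#' @return vector (or matrix) over base feature names.
#' @export
fold_attributions <- function(attr) {
  if (is.matrix(attr)) {
    base <- sub("__(mean|sd|q25|q50|q75)$", "", colnames(attr))
    groups <- split(seq_along(base), base)
    out <- vapply(groups, function(j) rowSums(attr[, j, drop = FALSE]),
                  numeric(nrow(attr)))
    out <- rbind(out)
    out[, unique(base), drop = FALSE]
  } else {
    base <- sub("__(mean|sd|q25|q50|q75)$", "", names(attr))
    out <- vapply(split(attr, base), sum, numeric(1))
    out[unique(base)]
  }
}

#' Feature-importance report with a shuffled-label permutation null
#'
#' Takes per-partition mean absolute attributions from real runs and from
#' shuffled-training-label runs (chance-level classifiers), folds
#' chunk-statistic columns into their base features, and reports per feature
#' the median attribution over the real partitions and a one-tailed
#' permutation p-value: the fraction of null partitions whose attribution
#' reaches the observed median.
#'
#' @param real matrix `n_partitions x n_columns` of mean absolute
#'   attributions from real runs (e.g. `mean_abs_shap` collected from
#'   [run_experiment()] with `shap_features = TRUE`).
#' @param null matrix `n_null x n_columns` from shuffled-label runs.
#' @return data.frame with `feature`, `importance`, `p_value`, sorted by
#'   decreasing importance.
#' @export
importance_with_null <- function(real, null) {
  real <- rbind(real); null <- rbind(null)
  if (!identical(colnames(real), colnames(null))) {
    stop("real and null attribution matrices must share their feature columns")
  }
  real_f <- fold_attributions(real)
  null_f <- fold_attributions(null)
  med <- apply(real_f, 2L, stats::median)
  p <- vapply(seq_along(med), function(j) {
    (1 + sum(null_f[, j] >= med[j])) / (nrow(null_f) + 1)
  }, numeric(1))
  out <- data.frame(feature = colnames(real_f), importance = unname(med),
                    p_value = p)
  out[order(-out$importance), ]
}

#' Nonparametric group tests
#'
#' Dispatches the named rank test: two-sided Mann-Whitney U for two unpaired
#' groups, Wilcoxon signed-rank for paired samples (or one group against a
#' constant), and Kruskal-Wallis for three or more groups followed by
#' Tukey-corrected pairwise comparisons of rank means. All-tied inputs yield
#' p = 1 with a warning.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor of the same length (for `"utest"` /
#'   `"kruskal"`); for `"wilcoxon"` supply `values` and `paired_with`.
#' @param test `"utest"`, `"wilcoxon"`, or `"kruskal"`.
#' @param paired_with second sample for the signed-rank test (or a single
#'   number to test the group median against).
#' @param alternative passed to the underlying test where meaningful.
#' @return list with `statistic`, `p_value`, and for Kruskal-Wallis a
#'   `pairwise` data.frame of Tukey-corrected comparisons.
#' @export
group_tests <- function(values, groups = NULL,
                        test = c("utest", "wilcoxon", "kruskal"),
                        paired_with = NULL, alternative = "two.sided") {
  test <- match.arg(test)
  degenerate <- function(x) length(unique(x)) == 1L
  if (test == "utest") {
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("the U test compares exactly two groups")
    a <- values[g == levels(g)[1]]; b <- values[g == levels(g)[2]]
    if (degenerate(c(a, b))) {
      warning("all observations tied; p set to 1")
      return(list(statistic = NA_real_, p_value = 1))
    }
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              alternative = alternative))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (test == "wilcoxon") {
    if (is.null(paired_with)) stop("signed-rank test needs `paired_with`")
    d <- if (length(paired_with) == 1L) values - paired_with else values - paired_with
    if (all(d == 0)) {
      warning("all paired differences are zero; p set to 1")
      return(list(statistic = NA_real_, p_value = 1))
    }
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              alternative = alternative))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  g <- factor(groups)
  if (degenerate(values)) {
    warning("all observations tied; p set to 1")
    return(list(statistic = NA_real_, p_value = 1, pairwise = NULL))
  }
  kw <- stats::kruskal.test(values, g)
  # Tukey HSD on the rank-transformed values for the pairwise comparisons
  r <- rank(values)
  tk <- stats::TukeyHSD(stats::aov(r ~ g))$g
  pw <- data.frame(comparison = rownames(tk), p_value = tk[, "p adj"],
                   row.names = NULL)
  list(statistic = unname(kw$statistic), p_value = kw$p.value, pairwise = pw)
}
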