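# Cross-validated random-forest training: stratified unit-level partitions,
# inverse-frequency class weights, grid search, shuffled-label baselines,
# vote pooling for chunked tables, and cross-region generalization.

#' Stratified unit-level train/test partition
#'
#' Per class, `floor(fraction * n)` units go to the training set and the rest
#' to the test set; membership is random, counts are deterministic. With 411
#' PYR and 101 PV units and the default fraction this yields 328/80 train and
#' 83/21 test.
#'
#' @param labels character vector of unit labels (`"PYR"`/`"PV"`).
#' @param fraction training fraction (0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_partition <- function(labels, fraction = 0.8, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("both classes must be present")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 units")
  set.seed(seed)
  train <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    train <- c(train, sample(idx, floor(fraction * length(idx))))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Inverse-frequency class weights
#'
#' `total samples / (number of classes x class count)`, so a balanced set
#' gets weight 1 per class.
#'
#' @param labels training labels.
#' @return named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(as.character(labels))
  if (any(tab == 0L)) stop("empty class")
  w <- as.numeric(sum(tab)) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' Default hyperparameter grid
#'
#' Four forest dimensions: number of trees, tree depth (0 = unbounded),
#' minimal samples to split a node, minimal samples per leaf. The full grid
#' is the package default; [compact_param_grid()] is a reduced grid for
#' desk-scale runs.
#'
#' @return data.frame, one row per grid member, in declaration order.
#' @export
default_param_grid <- function() {
  expand.grid(num_trees = c(10L, 50L, 100L, 500L),
              max_depth = c(0L, 5L, 10L, 20L),
              min_split = c(2L, 5L, 10L),
              min_leaf = c(1L, 2L, 5L))
}

#' @rdname default_param_grid
#' @export
compact_param_grid <- function() {
  expand.grid(num_trees = c(50L, 150L),
              max_depth = c(0L, 10L),
              min_split = 2L,
              min_leaf = c(1L, 5L))
}

meta_cols <- function(tab) intersect(c("unit_id", "chunk", "label", "region"),
                                     names(tab))

table_features <- function(tab) {
  as.matrix(tab[, setdiff(names(tab), meta_cols(tab)), drop = FALSE])
}

# impute NA feature cells with training-set column medians (0 if a column is
# all-NA in training)
impute_by_train <- function(x_train, x_test) {
  med <- apply(x_train, 2L, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  fill <- function(x) {
    for (j in seq_len(ncol(x))) {
      bad <- !is.finite(x[, j])
      if (any(bad)) x[bad, j] <- med[j]
    }
    x
  }
  list(train = fill(x_train), test = fill(x_test))
}

fit_forest <- function(x, y, params, weights, seed) {
  y <- factor(y, levels = c("PYR", "PV"))
  ranger::ranger(x = as.data.frame(x), y = y,
                 num.trees = params$num_trees,
                 max.depth = params$max_depth,
                 min.node.size = params$min_split,
                 min.bucket = params$min_leaf,
                 class.weights = unname(weights[levels(y)]),
                 probability = TRUE, seed = seed, num.threads = 1L,
                 keep.inbag = TRUE)
}

predict_pv <- function(model, x) {
  p <- stats::predict(model, data = as.data.frame(x), num.threads = 1L)$predictions
  p[, "PV"]
}

#' Five-fold grid search maximizing ROC AUC
#'
#' Splits the training rows into stratified folds, fits every grid member on
#' each fold complement, and returns the member with the highest mean
#' held-out AUC (ties go to the first member in declaration order). When
#' `max_rows` is exceeded (cross-region mode) a random subset is used.
#'
#' @param tab training feature table (rows = samples).
#' @param grid data.frame of hyperparameters ([default_param_grid()] layout).
#' @param k number of folds.
#' @param seed integer seed.
#' @param max_rows cap on the rows used for the search.
#' @return list: `params` (best row as a list), `mean_auc` per grid member.
#' @export
grid_search <- function(tab, grid, k = 5L, seed = 1L, max_rows = Inf) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  set.seed(seed)
  if (nrow(tab) > max_rows) tab <- tab[sample.int(nrow(tab), max_rows), ]
  y <- as.character(tab$label)
  x <- table_features(tab)
  x <- impute_by_train(x, x)$train
  folds <- integer(nrow(tab))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  w <- class_weights(y)
  mean_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) next
      # same per-fold seed for every grid member, so exact ties stay ties
      m <- fit_forest(x[tr, , drop = FALSE], y[tr], as.list(grid[gi, ]),
                      class_weights(y[tr]), seed = derive_seed(seed, 1000L + f))
      aucs <- c(aucs, roc_auc(y[!tr], predict_pv(m, x[!tr, , drop = FALSE])))
    }
    mean_auc[gi] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  list(params = as.list(grid[which.max(mean_auc), ]), mean_auc = mean_auc)
}

unit_labels_of <- function(tab) {
  first <- !duplicated(tab$unit_id)
  data.frame(unit_id = tab$unit_id[first], label = as.character(tab$label[first]),
             region = as.character(tab$region[first]))
}

# train a model on one partition and score test units (vote-pooled when the
# evaluation table is chunked)
run_partition <- function(tab_fit, tab_test, params, seed,
                          shuffled_labels = NULL) {
  y_fit <- as.character(tab_fit$label)
  if (!is.null(shuffled_labels)) {
    y_fit <- shuffled_labels[tab_fit$unit_id]
  }
  imp <- impute_by_train(table_features(tab_fit), table_features(tab_test))
  model <- fit_forest(imp$train, y_fit, params, class_weights(y_fit), seed)
  score <- predict_pv(model, imp$test)
  pooled <- vapply(split(score, tab_test$unit_id), function(s) pool_votes(s)$score,
                   numeric(1))
  ul <- unit_labels_of(tab_test)
  list(model = model, x_fit = imp$train, x_test = imp$test,
       unit_scores = pooled[ul$unit_id], unit_labels = ul$label,
       auc = roc_auc(ul$label, pooled[ul$unit_id]))
}

#' Repeated cross-validated classification experiment
#'
#' For each of `n_partitions` stratified unit-level 80:20 partitions: run the
#' grid search on the no-chunking training table, fit a forest with
#' inverse-frequency class weights on the (chunked, if supplied) training
#' rows, score the test chunks, pool votes per unit, and record the
#' unit-level test AUC. With `shuffle_labels = TRUE` the training-set labels
#' are permuted at the unit level (test labels untouched), giving the
#' empirical chance baseline. Chunked runs reuse the hyperparameters found by
#' the no-chunking search on the same partition.
#'
#' @param tab no-chunking feature table (one row per unit).
#' @param tab_chunked optional chunked feature table with matching columns.
#' @param n_partitions number of repetitions (50 in the reference setup).
#' @param grid hyperparameter grid; singleton grids skip the search.
#' @param fraction training fraction.
#' @param seed master seed; per-partition seeds are derived from it.
#' @param shuffle_labels permute training-set labels (chance baseline).
#' @param shap_features compute per-feature mean absolute TreeSHAP
#'   attributions on the test rows of every partition.
#' @param shap_max_samples cap on test rows used for attributions.
#' @return object of class `experiment_result`: per-partition `runs` (chosen
#'   hyperparameters, unit scores, AUC, optional attributions) and the vector
#'   `auc` of unit-level AUCs.
#' @export
run_experiment <- function(tab, tab_chunked = NULL, n_partitions = 50L,
                           grid = compact_param_grid(), fraction = 0.8,
                           seed = 1L, shuffle_labels = FALSE,
                           shap_features = FALSE, shap_max_samples = 1000L) {
  ul <- unit_labels_of(tab)
  runs <- vector("list", n_partitions)
  for (p in seq_len(n_partitions)) {
    sp <- derive_seed(seed, p)
    part <- stratified_partition(ul$label, fraction, seed = sp)
    train_ids <- ul$unit_id[part$train]
    test_ids <- ul$unit_id[part$test]
    tr_tab <- tab[tab$unit_id %in% train_ids, , drop = FALSE]
    shuf <- NULL
    if (shuffle_labels) {
      set.seed(derive_seed(sp, 7L))
      shuf <- stats::setNames(sample(ul$label[part$train]), train_ids)
      tr_tab$label <- shuf[tr_tab$unit_id]
    }
    best <- if (nrow(grid) == 1L) list(params = as.list(grid[1L, ])) else
      grid_search(tr_tab, grid, seed = derive_seed(sp, 3L))
    fit_tab <- if (is.null(tab_chunked)) tr_tab else
      tab_chunked[tab_chunked$unit_id %in% train_ids, , drop = FALSE]
    test_tab <- if (is.null(tab_chunked)) {
      tab[tab$unit_id %in% test_ids, , drop = FALSE]
    } else {
      tab_chunked[tab_chunked$unit_id %in% test_ids, , drop = FALSE]
    }
    res <- run_partition(fit_tab, test_tab, best$params,
                         seed = derive_seed(sp, 11L), shuffled_labels = shuf)
    run <- list(partition = p, params = best$params, auc = res$auc,
                unit_scores = res$unit_scores, unit_labels = res$unit_labels,
                shuffled = shuffle_labels)
    if (shap_features) {
      xt <- res$x_test
      if (nrow(xt) > shap_max_samples) {
        set.seed(derive_seed(sp, 13L))
        xt <- xt[sample.int(nrow(xt), shap_max_samples), , drop = FALSE]
      }
      phi <- tree_shap(res$model, res$x_fit, xt)
      run$mean_abs_shap <- colMeans(abs(phi$phi))
    }
    runs[[p]] <- run
  }
  structure(list(runs = runs,
                 auc = vapply(runs, `[[`, numeric(1), "auc")),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  q <- stats::quantile(x$auc, c(0.25, 0.5, 0.75))
  cat(sprintf("<experiment_result: %d partitions, unit AUC median [IQR] %.3f [%.3f-%.3f]>\n",
              length(x$auc), q[2], q[1], q[3]))
  invisible(x)
}

#' Cross-region generalization analysis
#'
#' Trains on ~80 percent of the training-region units (chunked rows when a
#' chunked table is supplied), picks hyperparameters on a development/
#' evaluation split of the training chunks (development capped at 5000
#' chunks), and evaluates the unit-level AUC on the held-out same-region test
#' set and on all units of the other region. The generalization error is
#' `(AUC_train_region - AUC_other_region) / AUC_train_region`.
#'
#' @param tab no-chunking feature table.
#' @param tab_chunked optional chunked table (modality-specific chunk size).
#' @param train_region `"CA1"` or `"nCX"`.
#' @param n_partitions repetitions.
#' @param grid hyperparameter grid.
#' @param seed master seed.
#' @return object of class `generalization_report` with per-partition AUCs on
#'   both test sets and generalization errors.
#' @export
region_generalization <- function(tab, tab_chunked = NULL, train_region,
                                  n_partitions = 50L,
                                  grid = compact_param_grid(), seed = 1L) {
  ul <- unit_labels_of(tab)
  if (!all(c("CA1", "nCX") %in% ul$region)) stop("both regions must be present")
  in_region <- ul$region == train_region
  other_ids <- ul$unit_id[!in_region]
  reg_ids <- ul$unit_id[in_region]
  reg_labels <- ul$label[in_region]
  pick <- function(t, ids) t[t$unit_id %in% ids, , drop = FALSE]
  src <- if (is.null(tab_chunked)) tab else tab_chunked
  auc_same <- auc_other <- numeric(n_partitions)
  for (p in seq_len(n_partitions)) {
    sp <- derive_seed(seed + 17L, p)
    part <- stratified_partition(reg_labels, 0.8, seed = sp)
    train_ids <- reg_ids[part$train]
    test_ids <- reg_ids[part$test]
    fit_tab <- pick(src, train_ids)
    best <- if (nrow(grid) == 1L) list(params = as.list(grid[1L, ])) else {
      # development/evaluation split of the training units, chunk-level fit
      dev <- stratified_partition(ul$label[match(train_ids, ul$unit_id)],
                                  0.8, seed = derive_seed(sp, 5L))
      dev_tab <- pick(src, train_ids[dev$train])
      eva_tab <- pick(src, train_ids[dev$test])
      if (nrow(dev_tab) > 5000L) {
        set.seed(derive_seed(sp, 6L))
        dev_tab <- dev_tab[sample.int(nrow(dev_tab), 5000L), ]
      }
      aucs <- vapply(seq_len(nrow(grid)), function(gi) {
        r <- run_partition(dev_tab, eva_tab, as.list(grid[gi, ]),
                           seed = derive_seed(sp, 50L + gi))
        r$auc
      }, numeric(1))
      list(params = as.list(grid[which.max(aucs), ]))
    }
    same <- run_partition(fit_tab, pick(src, test_ids), best$params,
                          seed = derive_seed(sp, 11L))
    other <- run_partition(fit_tab, pick(src, other_ids), best$params,
                           seed = derive_seed(sp, 11L))
    auc_same[p] <- same$auc
    auc_other[p] <- other$auc
  }
  structure(list(train_region = train_region,
                 auc_train_region = auc_same,
                 auc_other_region = auc_other,
                 generalization_error = (auc_same - auc_other) / auc_same),
            class = "generalization_report")
}

#' @export
print.generalization_report <- function(x, ...) {
  cat(sprintf("<generalization_report %s: same-region AUC %.3f, other %.3f, error %.3f (medians)>\n",
              x$train_region, stats::median(x$auc_train_region),
              stats::median(x$auc_other_region),
              stats::median(x$generalization_error)))
  invisible(x)
}
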