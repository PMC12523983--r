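# Multiclass classification with gradient-boosted trees, per-class TPR
# confusion summaries, label regrouping, hierarchical clustering and PCA.

scale_matrix <- function(mat, center, scale) {
  sweep(sweep(mat, 2, center, "-"), 2, scale, "/")
}

profile_matrix <- function(profiles, features) {
  miss <- setdiff(features, names(profiles))
  if (length(miss) > 0) {
    stop("schema error: profiles lack feature column(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  m <- as.matrix(profiles[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Train a gradient-boosted multiclass cell classifier
#'
#' Features are z-scored with the training statistics (recorded in the model
#' metadata); the booster is fitted single-threaded with a fixed seed so the
#' fit is reproducible.
#'
#' @param train labelled profile table (`class` column set).
#' @param features feature names to use (e.g. a `separation_result`'s
#'   `selected`).
#' @param n_trees,max_depth,eta booster hyperparameters (defaults 200 / 4 /
#'   0.1).
#' @param seed integer seed.
#' @return object of class `cell_classifier`.
#' @export
train_classifier <- function(train, features, n_trees = 200, max_depth = 4,
                             eta = 0.1, seed = 1) {
  if (inherits(features, "separation_result")) features <- features$selected
  cls <- train$class
  if (is.null(cls) || any(is.na(cls))) {
    stop("parameter error: training profiles must all carry a class label")
  }
  classes <- sort(unique(cls))
  if (length(classes) < 2) stop("parameter error: need at least 2 classes")
  if (any(table(cls) < 2)) {
    stop("parameter error: every class needs at least 2 training cells")
  }
  m <- profile_matrix(train, features)
  m[!is.finite(m)] <- NA
  center <- colMeans(m, na.rm = TRUE)
  center[!is.finite(center)] <- 0
  sdev <- apply(m, 2, stats::sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  ms <- scale_matrix(m, center, sdev)
  y <- match(cls, classes) - 1L
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  max_depth = max_depth, eta = eta,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(ms, label = y),
    nrounds = n_trees, verbose = 0
  )
  structure(list(booster = booster, classes = classes, features = features,
                 center = center, scale = sdev,
                 hyper = list(n_trees = n_trees, max_depth = max_depth,
                              eta = eta, seed = seed),
                 registry_version = REGISTRY_VERSION),
            class = "cell_classifier")
}

#' Predict classes for new profiles
#'
#' @param object a `cell_classifier`.
#' @param newdata profile table containing the training feature columns.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.cell_classifier <- function(object, newdata, ...) {
  m <- profile_matrix(newdata, object$features)
  m[!is.finite(m)] <- NA
  ms <- scale_matrix(m, object$center, object$scale)
  p <- stats::predict(object$booster, xgboost::xgb.DMatrix(ms))
  if (is.null(dim(p))) {
    p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
  }
  object$classes[max.col(p, ties.method = "first")]
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model a `cell_classifier`.
#' @param test labelled profile table; all labels must be classes the model
#'   was trained on.
#' @return object of class `confusion_summary`: `confusion` (true x predicted
#'   count matrix), `tpr` (per-class true positive rate in percent:
#'   100 * diagonal / row sum), `macro_tpr`.
#' @export
evaluate_classifier <- function(model, test) {
  cls <- test$class
  if (is.null(cls) || any(is.na(cls))) {
    stop("parameter error: test profiles must all carry a class label")
  }
  unseen <- setdiff(unique(cls), model$classes)
  if (length(unseen) > 0) {
    stop("parameter error: test set contains unseen class(es): ",
         paste(unseen, collapse = ", "))
  }
  pred <- predict(model, test)
  confusion <- table(true = factor(cls, levels = model$classes),
                     predicted = factor(pred, levels = model$classes))
  confusion <- unclass(confusion)
  rs <- rowSums(confusion)
  tpr <- ifelse(rs > 0, 100 * diag(confusion) / rs, NA_real_)
  structure(list(confusion = confusion, tpr = tpr,
                 macro_tpr = mean(tpr, na.rm = TRUE)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("confusion matrix (true x predicted):\n")
  print(x$confusion)
  cat("per-class TPR (%):\n")
  print(round(x$tpr, 1))
  cat(sprintf("macro-average TPR: %.1f%%\n", x$macro_tpr))
  invisible(x)
}

#' Regroup class labels
#'
#' Maps existing labels onto a coarser (or different) grouping, e.g. cell
#' lines onto disease status. Cells whose class is absent from the mapping
#' are dropped with a warning, supporting analyses that exclude a class.
#'
#' @param profiles labelled profile table.
#' @param mapping named character vector: `old class -> new class`.
#' @return relabelled profile table.
#' @export
regroup_labels <- function(profiles, mapping) {
  cls <- profiles$class
  mapped <- unname(mapping[cls])
  drop <- is.na(mapped) & !is.na(cls)
  if (any(drop)) {
    warning(sum(drop), " cell(s) with unmapped class dropped (",
            paste(unique(cls[drop]), collapse = ", "), ")")
  }
  out <- profiles[!drop, , drop = FALSE]
  out$class <- unname(mapping[out$class])
  if (nrow(out) == 0) stop("parameter error: no cells left after regrouping")
  rownames(out) <- NULL
  out
}

#' Agglomerative clustering of cell profiles
#'
#' Ward-linkage hierarchical clustering on Euclidean distances over z-scored
#' selected features; deterministic.
#'
#' @param profiles profile table.
#' @param features feature names (or a `separation_result`).
#' @param k number of clusters (2 <= k <= number of cells).
#' @return integer cluster assignments (length = rows of `profiles`).
#' @export
hierarchical_clusters <- function(profiles, features, k) {
  if (inherits(features, "separation_result")) features <- features$selected
  if (k < 2) stop("parameter error: k must be >= 2")
  if (k > nrow(profiles)) stop("parameter error: k exceeds number of cells")
  m <- profile_matrix(profiles, features)
  m[!is.finite(m)] <- 0
  sdev <- apply(m, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  ms <- scale_matrix(m, colMeans(m), sdev)
  hc <- stats::hclust(stats::dist(ms), method = "ward.D2")
  unname(stats::cutree(hc, k = k))
}

#' PCA scores of cell profiles
#'
#' Columns are z-scored (zero-variance columns dropped with a warning) and
#' projected onto the leading principal components. Each component's sign is
#' fixed by making its largest-magnitude loading positive, so repeated runs
#' agree.
#'
#' @param profiles profile table.
#' @param features feature names (or a `separation_result`).
#' @param n_components number of components (default 2).
#' @param scale z-score columns before projecting (default TRUE, the shared
#'   preprocessing used for classification and clustering); set FALSE for
#'   covariance PCA, whose explained-variance spectrum is invariant under
#'   orthogonal rotations of the feature space.
#' @return list: `scores` (cells x components), `loadings`,
#'   `explained_variance` (proportions).
#' @export
pca_scores <- function(profiles, features, n_components = 2, scale = TRUE) {
  if (inherits(features, "separation_result")) features <- features$selected
  if (nrow(profiles) < 2) stop("parameter error: need at least 2 cells")
  m <- profile_matrix(profiles, features)
  m[!is.finite(m)] <- NA
  keep <- apply(m, 2, function(col) {
    s <- stats::sd(col, na.rm = TRUE)
    is.finite(s) && s > 0 && !anyNA(col)
  })
  if (sum(keep) < n_components) {
    stop("parameter error: fewer usable features (", sum(keep),
         ") than components (", n_components, ")")
  }
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance or non-finite feature column(s) dropped")
  }
  m <- m[, keep, drop = FALSE]
  sdev <- if (scale) apply(m, 2, stats::sd) else rep(1, ncol(m))
  ms <- scale_matrix(m, colMeans(m), sdev)
  pc <- stats::prcomp(ms, center = FALSE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  sco <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}

#' Seeded stratified train/test split
#'
#' @param labels class label per cell.
#' @param test_fraction fraction of each class assigned to the test set.
#' @param seed integer seed.
#' @return logical vector, TRUE = test.
#' @export
stratified_split <- function(labels, test_fraction = 0.3, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(derive_seed(seed, 424242))
  test <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1, round(length(idx) * test_fraction))
    test[sample(idx, n_test)] <- TRUE
  }
  test
}
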