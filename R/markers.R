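# Random-forest marker ranking and the 10-fold CV error curve.

# Coerce features + labels from an snv_features object or a plain matrix.
resolve_xy <- function(x, labels = NULL, positive = "case") {
  if (inherits(x, "snv_features")) {
    m <- x$values
    labels <- labels %||% x$metadata$label
  } else {
    m <- as.matrix(x)
  }
  if (is.null(labels)) stopf("labels are required")
  if (length(labels) != nrow(m))
    stopf("labels length (%d) != number of samples (%d)", length(labels),
          nrow(m))
  if (anyNA(m) || anyNA(labels)) stopf("missing values are not supported")
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stopf("need exactly 2 classes, got %d (%s)", nlevels(y),
          paste(levels(y), collapse = ", "))
  if (positive %in% levels(y))  # positive class last => votes column order
    y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  if (min(table(y)) < 2L) stopf("need >= 2 samples per class")
  list(x = m, y = y)
}

rf_importance <- function(x, y, ntree, measure = c("permutation", "gini")) {
  measure <- match.arg(measure)
  # fully degenerate design: no split is possible, no feature informative
  if (all(apply(x, 2L, function(v) length(unique(v))) == 1L))
    return(setNames(numeric(ncol(x)), colnames(x)))
  rf <- randomForest::randomForest(x, y, ntree = ntree,
                                   importance = measure == "permutation")
  imp <- if (measure == "permutation") {
    randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
  } else {
    randomForest::importance(rf, type = 2)[, 1L]
  }
  imp
}

#' Rank genes by random-forest importance
#'
#' Fits a random forest to the normalized SNV burdens and ranks genes by
#' permutation importance (mean decrease in accuracy, unscaled - the measure
#' whose magnitude the conventional 0.01 panel cutoff refers to). Ties are
#' broken by gene id.
#'
#' @param x An `snv_features` object or numeric sample-by-gene matrix.
#' @param labels Two-class phenotype labels (taken from `x`'s metadata when
#'   omitted).
#' @param cutoff Importance threshold: genes with score strictly greater are
#'   selected.
#' @param ntree Number of trees.
#' @param measure `"permutation"` (default) or `"gini"`.
#' @param positive Label treated as the positive (case) class.
#' @param seed RNG seed; results are deterministic under it.
#' @return An object of class `marker_panel`: `ranking` (gene ids, best
#'   first), `scores` (importance in ranking order), `selected`, `cutoff`.
#' @export
rank_markers <- function(x, labels = NULL, cutoff = 0.01, ntree = 500L,
                         measure = c("permutation", "gini"),
                         positive = "case", seed = 1L) {
  xy <- resolve_xy(x, labels, positive)
  measure <- match.arg(measure)
  imp <- with_seed(seed, rf_importance(xy$x, xy$y, ntree, measure))
  ord <- order(-imp, names(imp))
  panel <- structure(list(ranking = names(imp)[ord], scores = imp[ord],
                          selected = names(imp)[ord][imp[ord] > cutoff],
                          cutoff = cutoff, measure = measure),
                     class = "marker_panel")
  panel
}

#' Select the marker panel from a ranking
#'
#' Genes with importance strictly greater than the panel's cutoff, optionally
#' truncated to the top `max_size`.
#'
#' @param panel A `marker_panel` from [rank_markers()].
#' @param max_size Optional maximum panel size.
#' @return Character vector of selected gene ids.
#' @export
select_panel <- function(panel, max_size = NULL) {
  sel <- panel$ranking[panel$scores > panel$cutoff]
  if (!is.null(max_size)) sel <- head(sel, max_size)
  sel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d genes ranked, %d selected (%s importance > %g)\n",
              length(x$ranking), length(x$selected), x$measure, x$cutoff))
  k <- min(10L, length(x$ranking))
  print(round(x$scores[seq_len(k)], 5))
  invisible(x)
}

#' @export
plot.marker_panel <- function(x, n = 20L, ...) {
  k <- min(n, length(x$ranking))
  graphics::barplot(rev(x$scores[seq_len(k)]), horiz = TRUE, las = 1,
                    names.arg = rev(x$ranking[seq_len(k)]),
                    xlab = "importance (mean decrease in accuracy)",
                    cex.names = 0.6, ...)
  graphics::abline(v = x$cutoff, lty = 2)
  invisible(x)
}

# Stratified fold assignment: shuffles within each class then deals folds
# round-robin, keeping both classes in every training fold.
stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

default_steps <- function(p) {
  steps <- p
  while (steps[length(steps)] > 1L)
    steps <- c(steps, max(1L, floor(steps[length(steps)] / 2)))
  unique(as.integer(steps))
}

#' 10-fold cross-validation error curve over shrinking marker panels
#'
#' Stratified k-fold cross-validation of the random-forest classifier as a
#' function of the number of top-ranked genes. By default genes are
#' re-ranked on each training fold before evaluation, so the curve carries
#' no selection bias from the held-out samples; `rerank = FALSE` evaluates a
#' fixed ranking instead.
#'
#' @param x An `snv_features` object or numeric sample-by-gene matrix.
#' @param labels Two-class labels (from metadata when omitted).
#' @param steps Decreasing panel sizes to evaluate (default: halving from
#'   all genes down to 1).
#' @param folds Number of folds.
#' @param ranking Fixed gene ranking, required when `rerank = FALSE`.
#' @param rerank Re-rank genes on each training fold (default `TRUE`).
#' @param ntree Trees per forest.
#' @param positive Positive-class label.
#' @param seed RNG seed.
#' @return Object of class `cv_curve`: `feature_counts`, `error` (mean
#'   misclassification per step), `per_fold` (folds x steps matrix).
#' @export
cv_error_curve <- function(x, labels = NULL, steps = NULL, folds = 10L,
                           ranking = NULL, rerank = TRUE, ntree = 500L,
                           positive = "case", seed = 1L) {
  xy <- resolve_xy(x, labels, positive)
  p <- ncol(xy$x)
  steps <- as.integer(steps %||% default_steps(p))
  if (any(diff(steps) >= 0L)) steps <- sort(unique(steps), decreasing = TRUE)
  if (any(steps < 1L) || any(steps > p)) stopf("steps must be in 1..%d", p)
  if (!rerank && is.null(ranking))
    stopf("a fixed ranking is required when rerank = FALSE")
  with_seed(seed, {
    fold_id <- stratified_folds(xy$y, folds)
    per_fold <- matrix(NA_real_, folds, length(steps),
                       dimnames = list(NULL, steps))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(xy$y[tr])) < 2L)
        stopf("fold %d: training portion has a single class", f)
      rk <- if (rerank) {
        imp <- rf_importance(xy$x[tr, , drop = FALSE], xy$y[tr], ntree,
                             "permutation")
        names(imp)[order(-imp, names(imp))]
      } else ranking
      for (j in seq_along(steps)) {
        top <- rk[seq_len(steps[j])]
        rf <- randomForest::randomForest(xy$x[tr, top, drop = FALSE],
                                         xy$y[tr], ntree = ntree)
        pred <- predict(rf, xy$x[!tr, top, drop = FALSE])
        per_fold[f, j] <- mean(pred != xy$y[!tr])
      }
    }
    structure(list(feature_counts = steps, error = colMeans(per_fold),
                   per_fold = per_fold, folds = folds, rerank = rerank),
              class = "cv_curve")
  })
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("cv_curve: %d-fold CV error over panel sizes (%s ranking)\n",
              x$folds, if (x$rerank) "per-fold" else "fixed"))
  print(round(setNames(x$error, x$feature_counts), 4))
  invisible(x)
}

#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(x$feature_counts, x$error, type = "b", log = "x",
                 xlab = "number of top-ranked genes",
                 ylab = sprintf("%d-fold CV error", x$folds), ...)
  invisible(x)
}
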