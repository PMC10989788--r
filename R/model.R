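# Final classifier, ROC/AUC evaluation, and the top-level fitting function.

#' AUC by the Mann-Whitney pairwise identity
#'
#' Probability that a random positive sample scores above a random negative
#' one, with 0.5 credit for score ties (midrank convention) - the
#' concordance form of the area under the ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Two-class labels.
#' @param positive Label of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_mannwhitney <- function(scores, labels, positive = "case") {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L)
    stopf("AUC undefined: need both classes, got %d positive / %d negative",
          n1, n2)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve points
#'
#' (FPR, TPR) at every distinct score threshold, from (0, 0) to (1, 1);
#' tied scores move both coordinates in one step.
#'
#' @inheritParams auc_mannwhitney
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = "case") {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stopf("ROC undefined with a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # one point per distinct score
  data.frame(fpr = c(0, fp[last] / n2), tpr = c(0, tp[last] / n1))
}

#' AUC by trapezoidal integration of the ROC curve
#'
#' @param roc Data frame from [roc_points()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Train the final random-forest classifier on a marker panel
#'
#' @param x An `snv_features` object or numeric matrix (training cohort).
#' @param labels Two-class labels (from metadata when omitted).
#' @param panel Character vector of marker gene ids (columns of the
#'   features), or a `marker_panel` whose selection is used.
#' @param ntree Number of trees.
#' @param positive Positive-class label.
#' @param seed RNG seed; training is deterministic under it.
#' @param train_cohort Tag recorded in evaluation reports.
#' @return Object of class `snv_classifier` wrapping the fitted forest, the
#'   panel and the training data (for out-of-bag evaluation).
#' @export
train_classifier <- function(x, labels = NULL, panel, ntree = 500L,
                             positive = "case", seed = 1L,
                             train_cohort = "discovery") {
  if (inherits(panel, "marker_panel")) panel <- panel$selected
  if (!length(panel)) stopf("empty marker panel")
  xy <- resolve_xy(x, labels, positive)
  miss <- setdiff(panel, colnames(xy$x))
  if (length(miss))
    stopf("panel gene(s) missing from features: %s",
          paste(miss, collapse = ", "))
  rf <- with_seed(seed, randomForest::randomForest(
    xy$x[, panel, drop = FALSE], xy$y, ntree = ntree))
  structure(list(rf = rf, panel = panel, positive = positive,
                 labels = xy$y, train_cohort = train_cohort),
            class = "snv_classifier")
}

#' @export
print.snv_classifier <- function(x, ...) {
  cat(sprintf("snv_classifier: %d-gene panel, %d trees (cohort '%s')\n",
              length(x$panel), x$rf$ntree, x$train_cohort))
  cat("  genes:", paste(x$panel, collapse = ", "), "\n")
  cat(sprintf("  out-of-bag error: %.4f\n",
              tail(x$rf$err.rate[, "OOB"], 1L)))
  invisible(x)
}

#' Case scores from a trained classifier
#'
#' @param object An `snv_classifier`.
#' @param newdata `snv_features` or matrix containing the panel genes;
#'   omitted for out-of-bag scores on the training cohort.
#' @param ... Unused.
#' @return Named numeric vector of positive-class probabilities.
#' @export
predict.snv_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$rf$votes[, object$positive])
  m <- if (inherits(newdata, "snv_features")) newdata$values else
    as.matrix(newdata)
  miss <- setdiff(object$panel, colnames(m))
  if (length(miss))
    stopf("evaluation features lack panel gene(s): %s",
          paste(miss, collapse = ", "))
  predict(object$rf, m[, object$panel, drop = FALSE],
          type = "prob")[, object$positive]
}

classifier_report <- function(scores, labels, positive, mode, train_cohort,
                              eval_cohort) {
  roc <- roc_points(scores, labels, positive)
  structure(list(auc = auc_mannwhitney(scores, labels, positive),
                 roc_points = roc, scores = scores, labels = labels,
                 n_positive = sum(labels == positive),
                 n_negative = sum(labels != positive), mode = mode,
                 train_cohort = train_cohort, eval_cohort = eval_cohort),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report [%s]: %s -> %s\n", x$mode, x$train_cohort,
              x$eval_cohort))
  cat(sprintf("  AUC = %.2f%%  (n = %d positive / %d negative)\n",
              100 * x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.classifier_report <- function(x, ...) {
  graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("AUC = %.2f%%", 100 * x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate a classifier by ROC/AUC
#'
#' `mode = "within"` evaluates on the training cohort with out-of-bag
#' scores (an honest within-cohort estimate); `mode = "transfer"` scores an
#' untouched cohort. Scores are computed before evaluation labels are
#' consulted; AUC uses the Mann-Whitney identity with 0.5 tie credit.
#'
#' @param model An `snv_classifier`.
#' @param x Evaluation features (`snv_features` or matrix); ignored for
#'   `mode = "within"`.
#' @param labels Evaluation labels (metadata labels when omitted and `x` is
#'   an `snv_features`).
#' @param mode `"within"` or `"transfer"`.
#' @param eval_cohort Tag for the report.
#' @return A `classifier_report`: `auc`, `roc_points`, `scores`, class
#'   sizes, mode and cohort tags.
#' @export
evaluate_classifier <- function(model, x = NULL, labels = NULL,
                                mode = c("within", "transfer"),
                                eval_cohort = NULL) {
  mode <- match.arg(mode)
  if (mode == "within") {
    scores <- predict(model)
    labels <- model$labels
    eval_cohort <- eval_cohort %||% model$train_cohort
  } else {
    if (is.null(x)) stopf("transfer evaluation requires features")
    scores <- predict(model, x)
    if (is.null(labels) && inherits(x, "snv_features"))
      labels <- x$metadata$label
    if (is.null(labels)) stopf("transfer evaluation requires labels")
    eval_cohort <- eval_cohort %||% "transfer"
  }
  if (length(unique(labels)) < 2L)
    stopf("AUC undefined: evaluation labels contain a single class")
  classifier_report(scores, labels, model$positive, mode,
                    model$train_cohort, eval_cohort)
}

#' Cross-cohort specificity contrasts
#'
#' Evaluates a trained classifier on a set of declared cohort contrasts,
#' e.g. case samples against an other-disease cohort (specificity) or
#' against an external control cohort. Each contrast names two cohorts; all
#' samples of the first are treated as the positive class and all samples
#' of the second as the negative class. A cohort contrasted with itself is
#' evaluated out-of-bag.
#'
#' @param model An `snv_classifier`.
#' @param cohorts Named list of `snv_features` objects (or matrices).
#' @param contrasts List of length-2 character vectors naming cohorts in
#'   `cohorts` (positive first).
#' @return Named list of `classifier_report`s, one per contrast.
#' @export
specificity_suite <- function(model, cohorts, contrasts) {
  out <- list()
  for (ct in contrasts) {
    if (length(ct) != 2L) stopf("each contrast must name exactly 2 cohorts")
    miss <- setdiff(ct, names(cohorts))
    if (length(miss))
      stopf("contrast references unknown cohort(s): %s",
            paste(miss, collapse = ", "))
    nm <- paste(ct, collapse = "_vs_")
    if (ct[1L] == ct[2L]) {
      out[[nm]] <- evaluate_classifier(model, mode = "within",
                                       eval_cohort = ct[1L])
      next
    }
    m1 <- cohort_matrix(cohorts[[ct[1L]]])
    m2 <- cohort_matrix(cohorts[[ct[2L]]])
    common <- intersect(colnames(m1), colnames(m2))
    x <- rbind(m1[, common, drop = FALSE], m2[, common, drop = FALSE])
    labels <- rep(c(model$positive, paste0("not_", model$positive)),
                  c(nrow(m1), nrow(m2)))
    out[[nm]] <- evaluate_classifier(model, x, labels, mode = "transfer",
                                     eval_cohort = nm)
  }
  out
}

cohort_matrix <- function(x) {
  if (inherits(x, "snv_features")) x$values else as.matrix(x)
}

#' Fit the SNV marker model: ranking, panel, CV curve, final classifier
#'
#' The discovery-stage estimator in one call: (1) genes are ranked by
#' random-forest permutation importance on the full discovery cohort; (2)
#' the panel is selected as the genes with importance above `cutoff`
#' (optionally capped at `max_size`); (3) a stratified `folds`-fold
#' cross-validation error curve over shrinking panels (re-ranked within
#' each training fold) estimates the error at the chosen panel size; (4)
#' the final classifier is trained on the selected panel and evaluated
#' within-cohort by out-of-bag ROC/AUC.
#'
#' @param x An `snv_features` object or numeric sample-by-gene matrix.
#' @param labels Two-class labels (from metadata when omitted).
#' @param cutoff Importance cutoff for panel selection (strict `>`).
#' @param max_size Optional maximum panel size.
#' @param folds Cross-validation folds.
#' @param steps Panel sizes for the CV curve (default: halving sequence,
#'   with the selected panel size included).
#' @param ntree Trees per forest.
#' @param positive Positive-class label.
#' @param seed Master seed; ranking, CV and training are deterministic
#'   under it.
#' @return Object of class `snv_marker_fit` with components `panel`
#'   (`marker_panel`), `curve` (`cv_curve`), `classifier`
#'   (`snv_classifier`), `within_report` (`classifier_report`) and `call`.
#' @seealso [predict.snv_marker_fit()], [plot.snv_marker_fit()]
#' @export
fit_marker_model <- function(x, labels = NULL, cutoff = 0.01,
                             max_size = NULL, folds = 10L, steps = NULL,
                             ntree = 500L, positive = "case", seed = 1L) {
  seeds <- child_seeds(seed, 3L)
  panel <- rank_markers(x, labels, cutoff = cutoff, ntree = ntree,
                        positive = positive, seed = seeds[1L])
  selected <- select_panel(panel, max_size)
  if (!length(selected))
    stopf("no gene exceeds the importance cutoff %g", cutoff)
  xy <- resolve_xy(x, labels, positive)
  if (is.null(steps)) {
    steps <- default_steps(ncol(xy$x))
    steps <- sort(unique(c(steps, length(selected))), decreasing = TRUE)
  }
  curve <- cv_error_curve(x, labels, steps = steps, folds = folds,
                          ntree = ntree, positive = positive,
                          seed = seeds[2L])
  classifier <- train_classifier(x, labels, selected, ntree = ntree,
                                 positive = positive, seed = seeds[3L])
  within <- evaluate_classifier(classifier, mode = "within")
  structure(list(panel = panel, selected = selected, curve = curve,
                 classifier = classifier, within_report = within,
                 cutoff = cutoff, seed = seed, call = match.call()),
            class = "snv_marker_fit")
}

#' @export
print.snv_marker_fit <- function(x, ...) {
  cat("SNV marker model\n")
  cat(sprintf("  panel: %d gene(s) with importance > %g\n",
              length(x$selected), x$cutoff))
  cat("   ", paste(x$selected, collapse = ", "), "\n")
  k <- which(x$curve$feature_counts == length(x$selected))
  if (length(k))
    cat(sprintf("  %d-fold CV error at panel size %d: %.3f\n",
                x$curve$folds, length(x$selected), x$curve$error[k]))
  cat(sprintf("  within-cohort out-of-bag AUC: %.2f%%\n",
              100 * x$within_report$auc))
  invisible(x)
}

#' @export
summary.snv_marker_fit <- function(object, ...) {
  print(object)
  cat("\nImportance of selected genes:\n")
  print(round(coef(object), 5))
  cat("\nCV error curve:\n")
  print(round(setNames(object$curve$error, object$curve$feature_counts), 4))
  invisible(object)
}

#' @export
coef.snv_marker_fit <- function(object, ...) {
  object$panel$scores[object$selected]
}

#' Score new samples with a fitted marker model
#'
#' @param object An `snv_marker_fit`.
#' @param newdata `snv_features` or matrix containing the panel genes;
#'   omitted for out-of-bag scores on the training cohort.
#' @param ... Unused.
#' @return Named vector of positive-class probabilities.
#' @export
predict.snv_marker_fit <- function(object, newdata = NULL, ...) {
  predict(object$classifier, newdata)
}

#' Plot a fitted marker model
#'
#' `which = 1` draws the CV error curve, `which = 2` the importance ranking,
#' `which = 3` the within-cohort ROC curve.
#'
#' @param x An `snv_marker_fit`.
#' @param which Integer subset of `1:3`.
#' @param ... Passed to the underlying plot methods.
#' @export
plot.snv_marker_fit <- function(x, which = 1L, ...) {
  for (w in which) {
    switch(w,
           plot(x$curve, ...),
           plot(x$panel, ...),
           plot(x$within_report, ...))
  }
  invisible(x)
}
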