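# Per-gene Wilcoxon rank-sum enrichment between phenotype groups.

#' Wilcoxon rank-sum test for one gene's burdens
#'
#' Two-sided rank-sum test. `method = "exact"` enumerates the permutation
#' distribution (valid for tie-free samples), `"normal"` uses the
#' tie-corrected normal approximation with continuity correction, and
#' `"auto"` picks the exact test when both groups are small (`n1 + n2 <=
#' 20`) and there are no ties.
#'
#' @param x,y Numeric burdens for the two groups (both nonempty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U` (rank-sum statistic of `x`, in `[0, n1 n2]`) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stopf("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(method,
                  exact = TRUE,
                  normal = FALSE,
                  auto = (length(x) + length(y) <= 20L) && !ties)
  if (exact && ties)
    stopf("exact method is undefined in the presence of ties")
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-gene enrichment of normalized SNV burden between groups
#'
#' Runs the two-sided Wilcoxon rank-sum test on every requested gene and
#' reports the direction of enrichment (the group with the larger mean
#' rank). No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted significance calls.
#'
#' @param x An `snv_features` object or sample-by-gene matrix.
#' @param labels Two-group labels (from metadata when omitted).
#' @param genes Gene ids to test (default: all columns).
#' @param alpha Significance level applied to (possibly adjusted) p values.
#' @param method Passed to [wilcoxon_rank_sum()].
#' @param adjust `"none"` (default) or a method of [stats::p.adjust()].
#' @return Data frame of class `enrichment_result`: `gene_id`, `U`,
#'   `p_value`, (`p_adjusted`,) `direction`, `significant`.
#' @export
enrich_panel <- function(x, labels = NULL, genes = NULL, alpha = 0.05,
                         method = "auto", adjust = "none") {
  if (inherits(x, "snv_features")) {
    m <- x$values
    labels <- labels %||% x$metadata$label
  } else m <- as.matrix(x)
  if (is.null(labels)) stopf("labels are required")
  groups <- unique(labels)
  if (length(groups) != 2L) stopf("need exactly 2 groups")
  genes <- genes %||% colnames(m)
  miss <- setdiff(genes, colnames(m))
  if (length(miss))
    stopf("gene(s) not in feature matrix: %s", paste(miss, collapse = ", "))
  g1 <- labels == groups[1L]
  res <- lapply(genes, function(g) {
    v <- m[, g]
    wt <- wilcoxon_rank_sum(v[g1], v[!g1], method)
    r <- rank(v)
    dir <- if (mean(r[g1]) >= mean(r[!g1])) groups[1L] else groups[2L]
    data.frame(gene_id = g, U = wt$U, p_value = wt$p_value, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
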