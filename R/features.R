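#' Aggregate SNVs to per-gene counts per sample
#'
#' An SNV increments gene `g` for its sample iff it lies on the gene's
#' strain and within the gene's 1-based inclusive span. An SNV inside
#' several overlapping genes increments each of them; SNVs contained in no
#' gene are returned in the `unassigned` attribute.
#'
#' @param snvs [snv_records] for any number of samples.
#' @param genes [gene_models].
#' @param samples Sample ids fixing the row order (default: sorted unique
#'   samples observed in `snvs`).
#' @return Integer matrix (samples x genes) with attribute `unassigned`, the
#'   subset of `snvs` contained in no gene.
#' @export
assign_snvs_to_genes <- function(snvs, genes, samples = NULL) {
  samples <- samples %||% sort(unique(snvs$sample))
  raw <- matrix(0L, length(samples), nrow(genes),
                dimnames = list(samples, genes$gene_id))
  hit <- logical(nrow(snvs))
  for (st in unique(genes$strain)) {
    gi <- which(genes$strain == st)
    si <- which(snvs$strain == st)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(snvs$pos[si], width = 1L),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    if (!length(ov)) next
    qh <- si[S4Vectors::queryHits(ov)]
    hit[qh] <- TRUE
    sidx <- match(snvs$sample[qh], samples)
    gidx <- gi[S4Vectors::subjectHits(ov)]
    keep <- !is.na(sidx)
    key <- (gidx[keep] - 1L) * length(samples) + sidx[keep]
    cnt <- tabulate(key, nbins = length(samples) * nrow(genes))
    raw <- raw + matrix(cnt, length(samples), nrow(genes))
  }
  storage.mode(raw) <- "integer"
  attr(raw, "unassigned") <- snvs[!hit, , drop = FALSE]
  raw
}

#' Count nonredundant SNVs across a cohort
#'
#' A nonredundant SNV is a unique `(strain, pos, ref, alt)` tuple, counted
#' once no matter how many samples carry it.
#'
#' @param snvs [snv_records].
#' @return Integer count.
#' @export
count_nonredundant <- function(snvs) {
  if (!nrow(snvs)) return(0L)
  sum(!duplicated(snvs[c("strain", "pos", "ref", "alt")]))
}

#' Retain strains by cohort-mean abundance and depth
#'
#' Keeps strains whose cohort-mean relative abundance exceeds
#' `min_abundance` and whose cohort-mean depth exceeds `min_depth` (both
#' strict inequalities).
#'
#' @param cohort A `cohort_data` list ([read_cohort_tables()]).
#' @param min_abundance Minimum mean relative abundance (fraction; default
#'   0.005, i.e. half a percent).
#' @param min_depth Minimum mean coverage (fold units; default 10).
#' @return Character vector of retained strain names.
#' @export
filter_strains <- function(cohort, min_abundance = 0.005, min_depth = 10) {
  mean_ab <- colMeans(cohort$abundance)
  mean_dp <- colMeans(cohort$depth)
  keep <- names(mean_ab)[mean_ab > min_abundance & mean_dp > min_depth]
  if (!length(keep))
    stopf(paste0("no strain passes abundance > %g and depth > %g; ",
                 "consider relaxing the thresholds"),
          min_abundance, min_depth)
  keep
}

#' Normalize per-gene SNV counts by strain abundance and depth
#'
#' The normalized burden of gene `g` in sample `s` is
#' `raw[s, g] / (abundance[s, strain(g)] * depth[s, strain(g)])` - raw SNV
#' counts scale with how much of a strain is present and how deeply it was
#' sequenced, and this division removes both factors. Where the strain is
#' absent (`abundance x depth = 0`) a zero count normalizes to zero; a
#' nonzero count there is an inconsistency and raises an error.
#'
#' @param raw Integer sample-by-gene count matrix
#'   ([assign_snvs_to_genes()]).
#' @param genes [gene_models] matching the columns of `raw`.
#' @param cohort `cohort_data` providing abundance and depth for the rows of
#'   `raw`.
#' @param nonredundant_total Optional cohort-wide nonredundant SNV count to
#'   record ([count_nonredundant()]).
#' @return An object of class `snv_features`: list with `values` (normalized
#'   matrix), `raw`, `genes`, `metadata`, `abundance`, `depth`,
#'   `nonredundant_total`.
#' @export
normalize_features <- function(raw, genes, cohort,
                               nonredundant_total = NA_integer_) {
  stopifnot(identical(colnames(raw), genes$gene_id))
  samples <- rownames(raw)
  missing <- setdiff(samples, rownames(cohort$abundance))
  if (length(missing))
    stopf("no abundance/depth for sample(s): %s",
          paste(missing, collapse = ", "))
  strains <- unique(genes$strain)
  if (!all(strains %in% colnames(cohort$abundance)))
    stopf("no abundance/depth for strain(s): %s",
          paste(setdiff(strains, colnames(cohort$abundance)), collapse = ", "))
  ab <- cohort$abundance[samples, genes$strain, drop = FALSE]
  dp <- cohort$depth[samples, genes$strain, drop = FALSE]
  ad <- ab * dp
  bad <- ad == 0 & raw > 0
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("sample '%s', strain '%s': %d SNV(s) but abundance x depth = 0",
          samples[w[1L]], genes$strain[w[2L]], raw[w[1L], w[2L]])
  }
  values <- raw / ad
  values[ad == 0] <- 0
  dimnames(values) <- dimnames(raw)
  meta <- cohort$metadata[match(samples, cohort$metadata$sample), ,
                          drop = FALSE]
  structure(list(values = values, raw = raw, genes = genes,
                 metadata = meta,
                 abundance = cohort$abundance[samples, , drop = FALSE],
                 depth = cohort$depth[samples, , drop = FALSE],
                 nonredundant_total = nonredundant_total),
            class = "snv_features")
}

#' @export
print.snv_features <- function(x, ...) {
  cat(sprintf("snv_features: %d samples x %d genes (%d strains)\n",
              nrow(x$values), ncol(x$values), length(unique(x$genes$strain))))
  if (!is.na(x$nonredundant_total))
    cat(sprintf("  nonredundant SNVs: %d\n", x$nonredundant_total))
  if (!is.null(x$metadata$label))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$metadata$label)),
                                   table(x$metadata$label)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Build the feature matrix of a cohort in one call
#'
#' Convenience wrapper: strain filtering, SNV-to-gene assignment,
#' nonredundant counting and normalization. Accepts either raw SNV records
#' or a `synthetic_cohort` (whose precomputed count matrix is used
#' directly).
#'
#' @param x [snv_records] or a `synthetic_cohort`.
#' @param genes [gene_models] (ignored for a `synthetic_cohort`).
#' @param cohort `cohort_data` (ignored for a `synthetic_cohort`).
#' @param min_abundance,min_depth Strain filter thresholds
#'   ([filter_strains()]); `NULL` disables filtering.
#' @return An `snv_features` object.
#' @export
build_features <- function(x, genes = NULL, cohort = NULL,
                           min_abundance = 0.005, min_depth = 10) {
  if (inherits(x, "synthetic_cohort")) {
    cohort <- cohort_data(x$abundance, x$depth, x$metadata)
    genes <- x$genes
    raw <- x$raw
    nr <- if (!is.null(x$snvs)) count_nonredundant(x$snvs) else NA_integer_
  } else {
    stopifnot(!is.null(genes), !is.null(cohort))
    raw <- assign_snvs_to_genes(x, genes, samples = cohort$metadata$sample)
    nr <- count_nonredundant(x)
  }
  if (!is.null(min_abundance) && !is.null(min_depth)) {
    keep <- filter_strains(cohort, min_abundance, min_depth)
    sel <- genes$strain %in% keep
    genes <- genes[sel, , drop = FALSE]
    class(genes) <- c("gene_models", "data.frame")
    raw <- raw[, sel, drop = FALSE]
  }
  normalize_features(raw, genes, cohort, nonredundant_total = nr)
}
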