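#' Read abundance, depth and sample metadata tables
#'
#' Abundance and depth are TSV matrices (rows = samples, columns = strains):
#' strain relative abundance as fractions in `[0, 1]` and mean mapped
#' coverage in fold units. Metadata is a TSV with columns `sample`, `label`
#' (phenotype) and `cohort`. Samples present in the metadata but absent from
#' abundance/depth are flagged in the `missing_samples` attribute; the
#' returned matrices are row-aligned to the retained metadata.
#'
#' @param abundance_path,depth_path,metadata_path TSV paths with header rows;
#'   abundance/depth have sample ids in the first column.
#' @return A list of class `cohort_data`: `abundance`, `depth` (numeric
#'   matrices), `metadata` (data frame), with attribute `missing_samples`.
#' @export
read_cohort_tables <- function(abundance_path, depth_path, metadata_path) {
  ab <- read_sample_matrix(abundance_path)
  dp <- read_sample_matrix(depth_path)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample", "label", "cohort")
  if (!all(need %in% names(meta)))
    stopf("%s: metadata must have columns %s", metadata_path,
          paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stopf("%s: duplicate sample id(s): %s", metadata_path,
          paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  cohort_data(ab, dp, meta)
}

read_sample_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df[[1L]]))
    stopf("%s: duplicate sample id(s)", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Assemble and validate in-memory cohort data
#'
#' @param abundance,depth Numeric sample-by-strain matrices.
#' @param metadata Data frame with `sample`, `label`, `cohort` columns.
#' @return A validated `cohort_data` list (see [read_cohort_tables()]).
#' @export
cohort_data <- function(abundance, depth, metadata) {
  if (any(abundance < 0) || any(depth < 0))
    stopf("abundance and depth must be nonnegative")
  if (any(abundance > 1))
    stopf("relative abundance > 1 (first offender: sample '%s')",
          rownames(abundance)[which(rowSums(abundance > 1) > 0)[1L]])
  sums <- rowSums(abundance)
  if (any(sums > 1 + 1e-8))
    stopf("per-sample abundances sum to > 1 (sample '%s')",
          rownames(abundance)[which.max(sums)])
  if (!identical(dim(abundance), dim(depth)) ||
      !identical(dimnames(abundance), dimnames(depth)))
    stopf("abundance and depth tables must share samples and strains")
  missing <- setdiff(metadata$sample, rownames(abundance))
  metadata <- metadata[metadata$sample %in% rownames(abundance), ,
                       drop = FALSE]
  if (!nrow(metadata)) stopf("no metadata samples found in abundance table")
  abundance <- abundance[metadata$sample, , drop = FALSE]
  depth <- depth[metadata$sample, , drop = FALSE]
  out <- list(abundance = abundance, depth = depth, metadata = metadata)
  attr(out, "missing_samples") <- missing
  class(out) <- "cohort_data"
  out
}

write_sample_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
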