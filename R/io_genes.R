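#' Construct a table of gene models
#'
#' Gene models are a data frame with one row per CDS gene: `gene_id`,
#' `strain` (contig), `start`, `end` (1-based inclusive genomic extent),
#' `strand` (`+`/`-`) and `cds` (the coding sequence on the coding strand,
#' trailing stop codon trimmed). Multi-segment genes (several CDS features
#' sharing one identifier) keep their per-segment coordinates in the
#' `segments` attribute, a named list of `start`/`end` data frames.
#'
#' @param gene_id,strain,start,end,strand,cds vectors of equal length.
#' @param segments optional named list of per-gene segment tables.
#' @return A `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, strain, start, end, strand, cds,
                        segments = NULL) {
  df <- data.frame(gene_id = as.character(gene_id),
                   strain = as.character(strain),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   cds = as.character(cds), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids")
    if (any(df$start > df$end)) stopf("gene start must be <= end")
    if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    if (any(nchar(df$cds) %% 3L != 0L))
      stopf("cds lengths must be multiples of 3")
  }
  attr(df, "segments") <- segments
  class(df) <- c("gene_models", "data.frame")
  df
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

has_internal_stop <- function(cds) {
  aa <- translate_cds(cds)
  grepl("*", aa, fixed = TRUE)
}

trim_trailing_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && substr(cds, n - 2L, n) %in% STOP_CODONS)
    substr(cds, 1L, n - 3L)
  else cds
}

#' Read gene models from a GFF3 annotation and reference FASTA
#'
#' Extracts CDS features, resolves each gene's coding sequence from the
#' reference contigs (reverse-complemented for minus-strand genes; CDS
#' segments sharing one identifier are concatenated in transcription order),
#' trims a trailing stop codon, and rejects genes whose coding sequence is
#' out of frame or contains an internal stop. Rejections are reported in the
#' `rejected` attribute (`gene_id`, `reason`).
#'
#' @param gff_path Path to a GFF3 file with CDS features carrying `ID`,
#'   `locus_tag` or `gene_id` attributes.
#' @param fasta_path Path to the reference FASTA covering all CDS spans.
#' @return A [gene_models] data frame with attribute `rejected`.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (!length(gff)) stopf("%s: no CDS features found", gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  ids <- as.character(gff$ID %||% rep(NA_character_, length(gff)))
  if (all(is.na(ids)) && !is.null(gff$locus_tag))
    ids <- as.character(gff$locus_tag)
  if (!is.null(gff$locus_tag)) ids <- ifelse(is.na(ids),
                                             as.character(gff$locus_tag), ids)
  if (anyNA(ids)) stopf("%s: CDS features without ID/locus_tag", gff_path)

  seg <- data.frame(id = ids,
                    strain = as.character(GenomicRanges::seqnames(gff)),
                    start = GenomicRanges::start(gff),
                    end = GenomicRanges::end(gff),
                    strand = as.character(GenomicRanges::strand(gff)),
                    stringsAsFactors = FALSE)
  if (any(!seg$strand %in% c("+", "-")))
    stopf("%s: CDS feature without explicit strand", gff_path)

  rows <- list(); segments <- list()
  rejected <- data.frame(gene_id = character(), reason = character())
  for (id in unique(seg$id)) {
    g <- seg[seg$id == id, , drop = FALSE]
    if (length(unique(g$strain)) > 1L || length(unique(g$strand)) > 1L) {
      rejected <- rbind(rejected, data.frame(
        gene_id = id, reason = "segments on multiple contigs/strands"))
      next
    }
    strain <- g$strain[1L]; strand <- g$strand[1L]
    if (!strain %in% names(genome))
      stopf("%s: contig '%s' absent from FASTA", gff_path, strain)
    clen <- Biostrings::width(genome[strain])
    if (any(g$start < 1L) || any(g$end > clen))
      stopf("gene '%s': CDS span %d..%d outside contig '%s' (length %d)",
            id, min(g$start), max(g$end), strain, clen)
    g <- g[order(g$start), , drop = FALSE]
    slices <- substring(as.character(genome[[strain]]), g$start, g$end)
    cds <- if (strand == "+") paste(slices, collapse = "") else
      paste(rev(vapply(slices, revcomp, character(1L))), collapse = "")
    if (nchar(cds) %% 3L != 0L) {
      rejected <- rbind(rejected, data.frame(
        gene_id = id, reason = "length not divisible by 3"))
      next
    }
    cds <- trim_trailing_stop(cds)
    if (has_internal_stop(cds)) {
      rejected <- rbind(rejected, data.frame(
        gene_id = id, reason = "internal stop codon"))
      next
    }
    rows[[id]] <- data.frame(gene_id = id, strain = strain,
                             start = min(g$start), end = max(g$end),
                             strand = strand, cds = cds,
                             stringsAsFactors = FALSE)
    if (nrow(g) > 1L)
      segments[[id]] <- data.frame(start = g$start, end = g$end)
  }
  if (!length(rows)) stopf("%s: no valid gene models", gff_path)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  res <- gene_models(out$gene_id, out$strain, out$start, out$end, out$strand,
                     out$cds,
                     segments = if (length(segments)) segments else NULL)
  if (nrow(rejected))
    warnf("%d gene(s) rejected (%s)", nrow(rejected),
          paste(unique(rejected$reason), collapse = "; "))
  attr(res, "rejected") <- rejected
  res
}

# Map genomic positions to 1-based coding-sequence positions for one gene
# row. Positions outside the coding segments (e.g. the trimmed trailing stop
# codon) return NA.
cds_position <- function(gene, pos, segments = NULL) {
  segs <- segments %||% data.frame(start = gene$start, end = gene$end)
  segs <- segs[order(segs$start), , drop = FALSE]
  widths <- segs$end - segs$start + 1L
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(segs))) {
    inside <- pos >= segs$start[i] & pos <= segs$end[i]
    out[inside] <- offsets[i] + (pos[inside] - segs$start[i] + 1L)
  }
  if (gene$strand == "-") {
    total <- sum(widths)
    out <- total - out + 1L
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits one CDS feature per gene segment with `ID` and `locus_tag`
#' attributes, suitable for re-reading with [read_gene_models()].
#'
#' @param genes A [gene_models] data frame.
#' @param path Output path.
#' @param stop_included If `TRUE` (synthetic references), each gene's
#'   annotated span already includes the trailing stop codon.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path, stop_included = TRUE) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tsnvmark\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
      g$strain, g$start, g$end, g$strand, g$gene_id, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
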