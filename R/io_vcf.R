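#' Construct a table of SNV records
#'
#' The package-wide representation of called variants is a plain data frame
#' with one row per biallelic single-nucleotide variant and columns `strain`
#' (reference contig), `pos` (1-based position), `ref`, `alt` (single bases),
#' and `sample`.
#'
#' @param strain,pos,ref,alt,sample vectors of equal length.
#' @return A `data.frame` of class `snv_records`.
#' @export
snv_records <- function(strain = character(), pos = integer(),
                        ref = character(), alt = character(),
                        sample = character()) {
  df <- data.frame(strain = as.character(strain), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   sample = as.character(sample), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$pos < 1L)) stopf("SNV positions must be >= 1")
    if (!all(df$ref %in% BASES) || !all(df$alt %in% BASES))
      stopf("ref and alt must be single bases A/C/G/T")
    if (any(df$ref == df$alt)) stopf("ref and alt alleles must differ")
  }
  class(df) <- c("snv_records", "data.frame")
  df
}

empty_skip_report <- function() {
  c(kept = 0L, non_snv_alt = 0L, low_qual = 0L, low_dp = 0L,
    unknown_contig = 0L)
}

#' Read biallelic SNVs for one sample from a VCF file
#'
#' Parses a VCF 4.x file, decomposes multi-allelic rows into one record per
#' alternate allele, drops non-SNV alleles (indels, MNVs, symbolic alleles)
#' and records failing the site filters. Dropped records are tallied in the
#' `skip_report` attribute of the result.
#'
#' Site filters default to QUAL >= 20 and INFO/DP >= 10; records with missing
#' QUAL or DP pass the corresponding filter.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample_id Sample identifier attached to every record.
#' @param qual_min,dp_min Minimum QUAL and INFO/DP for a site to be kept.
#' @param contigs Optional character vector of known contig (strain) names;
#'   records on other contigs are skipped with a warning or rejected,
#'   depending on `on_unknown_contig`.
#' @param on_unknown_contig `"skip"` (warn and drop) or `"error"`.
#' @return An [snv_records] data frame with attribute `skip_report`, a named
#'   integer vector counting kept and dropped alleles.
#' @export
read_snv_vcf <- function(path, sample_id, qual_min = 20, dp_min = 10,
                         contigs = NULL,
                         on_unknown_contig = c("skip", "error")) {
  on_unknown_contig <- match.arg(on_unknown_contig)
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  report <- empty_skip_report()
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- snv_records(sample = character())
    attr(out, "skip_report") <- report
    return(out)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- extract_info_dp(fix[, "INFO"])

  # decompose multi-allelic rows: one candidate record per alternate allele
  alts <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_along(chrom), n_alt)
  cand <- data.frame(strain = chrom[idx], pos = pos[idx], ref = ref[idx],
                     alt = unlist(alts, use.names = FALSE),
                     qual = qual[idx], dp = dp[idx],
                     stringsAsFactors = FALSE)

  is_snv <- cand$ref %in% BASES & cand$alt %in% BASES & cand$ref != cand$alt
  report["non_snv_alt"] <- sum(!is_snv)
  cand <- cand[is_snv, , drop = FALSE]

  fail_qual <- !is.na(cand$qual) & cand$qual < qual_min
  report["low_qual"] <- sum(fail_qual)
  cand <- cand[!fail_qual, , drop = FALSE]

  fail_dp <- !is.na(cand$dp) & cand$dp < dp_min
  report["low_dp"] <- sum(fail_dp)
  cand <- cand[!fail_dp, , drop = FALSE]

  if (!is.null(contigs)) {
    unknown <- !(cand$strain %in% contigs)
    if (any(unknown)) {
      if (on_unknown_contig == "error")
        stopf("VCF %s: unknown contig(s): %s", path,
              paste(unique(cand$strain[unknown]), collapse = ", "))
      warnf("VCF %s: skipping %d record(s) on unknown contig(s): %s", path,
            sum(unknown), paste(unique(cand$strain[unknown]), collapse = ", "))
      report["unknown_contig"] <- sum(unknown)
      cand <- cand[!unknown, , drop = FALSE]
    }
  }
  report["kept"] <- nrow(cand)
  out <- snv_records(strain = cand$strain, pos = cand$pos, ref = cand$ref,
                     alt = cand$alt, sample = rep(sample_id, nrow(cand)))
  attr(out, "skip_report") <- report
  out
}

# Cheap structural pre-scan so malformed bodies fail with a line number.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stopf("%s: line 1: missing ##fileformat=VCF header", path)
  body <- which(!startsWith(lines, "#"))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 8L]
    if (length(bad))
      stopf("%s: line %d: expected >= 8 tab-separated VCF fields, found %d",
            path, bad[1L], nf[which(nf < 8L)[1L]])
  }
  invisible(TRUE)
}

extract_info_dp <- function(info) {
  m <- regmatches(info, regexpr("(?:^|;)DP=([0-9.]+)", info))
  dp <- rep(NA_real_, length(info))
  has <- lengths(regmatches(info, gregexpr("(?:^|;)DP=", info))) > 0
  dp[has] <- as.numeric(sub(".*DP=", "", m))
  dp
}

#' Write SNV records for one sample as a minimal VCF 4.2 file
#'
#' Emits a plain-text VCF with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns,
#' one row per record, sorted by contig then position. Per-site depth (if
#' supplied) is written as `INFO/DP`; QUAL is a constant placeholder for
#' synthetic calls.
#'
#' @param records An [snv_records] data frame for a single sample.
#' @param path Output path.
#' @param contig_lengths Named integer vector of contig lengths for the
#'   `##contig` header lines.
#' @param depth Optional named numeric vector (per contig) of mean depth;
#'   rounded and written as each record's `DP`.
#' @param qual QUAL value written for every record.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(records, path, contig_lengths, depth = NULL,
                          qual = 60) {
  stopifnot(inherits(records, "snv_records") || is.data.frame(records))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Mean mapped depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  if (nrow(records)) {
    ord <- order(records$strain, records$pos, records$alt)
    rec <- records[ord, , drop = FALSE]
    info <- if (is.null(depth)) rep(".", nrow(rec)) else
      sprintf("DP=%d", as.integer(round(depth[rec$strain])))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\t%s",
                    rec$strain, rec$pos, rec$ref, rec$alt, qual, info)
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
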