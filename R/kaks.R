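# Nei-Gojobori (NG86) Ka/Ks with Jukes-Cantor correction.
#
# Sites: each codon position contributes (number of synonymous single-base
# changes)/3 synonymous sites; changes creating a stop codon count as
# nonsynonymous. Observed SNVs are classified against the reference codon
# with the other two positions held at reference; multiple SNVs in one codon
# are classified independently (population-level site variants, not an
# evolved pair).

# cache of per-codon site fractions and mutant classifications
.kaks_env <- new.env(parent = emptyenv())

codon_site_table <- function() {
  if (!is.null(.kaks_env$sites)) return(.kaks_env$sites)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  syn <- matrix(0, nrow = length(codons), ncol = 3L,
                dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- code[[cd]]
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(cd, p, p))) {
        mut <- cd
        substr(mut, p, p) <- b
        if (code[[mut]] == aa) syn[cd, p] <- syn[cd, p] + 1
      }
    }
  }
  .kaks_env$sites <- syn / 3
  .kaks_env$sites
}

#' Count potential synonymous and nonsynonymous sites of a coding sequence
#'
#' NG86 site counting: each codon position contributes the fraction of its
#' three possible single-base changes that are synonymous to `S_sites` and
#' the rest to `N_sites`; mutations to stop codons are nonsynonymous. The
#' two totals always sum to the sequence length.
#'
#' @param cds Coding sequence (frame-valid, no internal stops, trailing stop
#'   trimmed).
#' @return Named numeric vector with `S_sites` and `N_sites`.
#' @export
count_potential_sites <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) stopf("cds length must be a positive multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- codon_site_table()
  if (!all(codons %in% rownames(tab)))
    stopf("cds contains stop or ambiguous codon(s): %s",
          paste(unique(codons[!codons %in% rownames(tab)]), collapse = ", "))
  S <- sum(tab[codons, ])
  c(S_sites = S, N_sites = 3 * length(codons) - S)
}

#' Classify observed SNVs of a gene as synonymous or nonsynonymous
#'
#' Each SNV is evaluated against the reference codon with the other
#' positions at reference. For minus-strand genes the VCF alleles (forward
#' strand) are complemented before codon lookup. SNVs falling outside the
#' coding sequence (e.g. in the trimmed trailing stop codon) are labelled
#' `"noncoding"` and excluded from the counts.
#'
#' @param gene One row of a [gene_models] data frame.
#' @param snvs [snv_records] lying within the gene span (any sample).
#' @param segments Optional per-gene segment table for multi-segment genes.
#' @return List with `Sd`, `Nd` and `labels` (per SNV: `"synonymous"`,
#'   `"nonsynonymous"` or `"noncoding"`).
#' @export
classify_substitutions <- function(gene, snvs, segments = NULL) {
  if (!nrow(snvs))
    return(list(Sd = 0L, Nd = 0L, labels = character()))
  if (any(snvs$pos < gene$start | snvs$pos > gene$end))
    stopf("gene '%s': SNV outside gene span", gene$gene_id)
  cpos <- cds_position(gene, snvs$pos, segments)
  ref <- snvs$ref; alt <- snvs$alt
  if (gene$strand == "-") {
    ref <- unname(complement_base(ref))
    alt <- unname(complement_base(alt))
  }
  labels <- rep("noncoding", nrow(snvs))
  inside <- !is.na(cpos) & cpos <= nchar(gene$cds)
  if (any(inside)) {
    ci <- (cpos[inside] - 1L) %/% 3L          # 0-based codon index
    wi <- (cpos[inside] - 1L) %% 3L + 1L      # position within codon
    codon <- substring(gene$cds, ci * 3L + 1L, ci * 3L + 3L)
    ref_base <- substr(codon, wi, wi)
    bad <- ref_base != ref[inside]
    if (any(bad)) {
      k <- which(inside)[which(bad)[1L]]
      stopf("gene '%s': SNV ref allele '%s' at %s:%d disagrees with reference base '%s'",
            gene$gene_id, snvs$ref[k], snvs$strain[k], snvs$pos[k],
            if (gene$strand == "-") complement_base(ref_base[which(bad)[1L]])
            else ref_base[which(bad)[1L]])
    }
    mut <- codon
    substr(mut, wi, wi) <- alt[inside]
    code <- Biostrings::GENETIC_CODE
    labels[inside] <- ifelse(code[mut] == "*" | code[codon] != code[mut],
                             "nonsynonymous", "synonymous")
  }
  list(Sd = sum(labels == "synonymous"),
       Nd = sum(labels == "nonsynonymous"),
       labels = labels)
}

#' Jukes-Cantor-corrected Ka/Ks from site and substitution counts
#'
#' Computes the proportions `pS = Sd/S_sites`, `pN = Nd/N_sites`, the
#' corrected rates `Ks = -3/4 log(1 - 4 pS / 3)` (likewise `Ka`), their
#' ratio, and a selection-regime label: ratio within `neutral_tol` of 1 is
#' `"neutral"`, below is `"purifying"`, above `"positive"`. The ratio is an
#' `NA` sentinel (regime `"undefined"`) when `Ks = 0` or when a proportion
#' reaches 3/4, where the correction diverges; raw proportions are retained.
#'
#' @param S_sites,N_sites Potential site counts (> 0).
#' @param Sd,Nd Observed synonymous / nonsynonymous substitution counts.
#' @param neutral_tol Half-width of the neutral band around ratio 1.
#' @return One-row data frame: `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `ratio`, `regime`.
#' @export
kaks_ratio <- function(S_sites, N_sites, Sd, Nd, neutral_tol = 0.1) {
  if (S_sites <= 0 || N_sites <= 0) stopf("site counts must be positive")
  if (Sd < 0 || Nd < 0) stopf("substitution counts must be nonnegative")
  pS <- Sd / S_sites
  pN <- Nd / N_sites
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  if (is.na(Ks) || is.na(Ka) || Ks == 0) {
    ratio <- NA_real_; regime <- "undefined"
  } else {
    ratio <- Ka / Ks
    regime <- if (abs(ratio - 1) <= neutral_tol) "neutral"
    else if (ratio < 1) "purifying" else "positive"
  }
  data.frame(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
             regime = regime, stringsAsFactors = FALSE)
}

#' Per-gene Ka/Ks over a cohort's SNVs
#'
#' Pools each gene's SNVs across samples as nonredundant substitutions
#' (unique strain/position/alt), classifies them against the reference
#' coding sequence and computes the NG86 Ka/Ks of each gene.
#'
#' @param genes A [gene_models] data frame.
#' @param snvs [snv_records] from any number of samples.
#' @param neutral_tol Passed to [kaks_ratio()].
#' @return Data frame with one row per gene (columns of [kaks_ratio()] plus
#'   `gene_id` and `n_noncoding`, the SNVs excluded as outside the coding
#'   sequence).
#' @export
kaks_for_genes <- function(genes, snvs, neutral_tol = 0.1) {
  segments <- attr(genes, "segments")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sub <- snvs[snvs$strain == g$strain & snvs$pos >= g$start &
                  snvs$pos <= g$end, , drop = FALSE]
    sub <- sub[!duplicated(sub[c("strain", "pos", "alt")]), , drop = FALSE]
    cls <- classify_substitutions(g, sub, segments[[g$gene_id]])
    sites <- count_potential_sites(g$cds)
    row <- kaks_ratio(sites[["S_sites"]], sites[["N_sites"]],
                      cls$Sd, cls$Nd, neutral_tol)
    row$gene_id <- g$gene_id
    row$n_noncoding <- sum(cls$labels == "noncoding")
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  res[c("gene_id", setdiff(names(res), "gene_id"))]
}
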