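#' Configuration for synthetic cohort simulation
#'
#' Defines the generative model for a desk-scale case/control metagenomic
#' cohort: random strain reference genomes with valid CDS genes; per-sample
#' strain relative abundances (lognormal across strains, renormalized to a
#' fixed profiled-community total) and sequencing depths (gamma); per-gene
#' SNV counts Poisson with mean `baseline_snv_rate x (gene length / 1000) x
#' abundance x depth`, multiplied by `effect_multiplier` for marker genes in
#' case samples. The abundance-and-depth factor is the confound that
#' normalization must remove.
#'
#' @param n_strains Number of strain reference genomes.
#' @param genes_per_strain CDS genes per strain.
#' @param gene_length_codons Length-2 range (codons, excluding the stop) from
#'   which gene lengths are drawn uniformly.
#' @param n_case,n_control Group sizes.
#' @param baseline_snv_rate Expected SNVs per kilobase per unit
#'   (abundance x depth).
#' @param n_markers Number of marker genes planted when `marker_genes` is
#'   `NULL`.
#' @param marker_genes Designated marker gene ids, or `NULL` to sample
#'   `n_markers` of them.
#' @param effect_multiplier Fold-increase of the SNV rate in case samples for
#'   marker genes (>= 1).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the
#'   per-strain abundance draws before renormalization.
#' @param total_abundance Fraction of the community covered by the profiled
#'   strains; per-sample abundances sum to this.
#' @param depth_shape,depth_scale Gamma parameters of per-sample per-strain
#'   mean coverage (fold units).
#' @param syn_fraction Target fraction of planted SNVs at synonymous sites,
#'   or `NA` for unbiased alternate alleles.
#' @param segregating_fraction Fraction of each gene's positions that
#'   segregate in the population. Every sample draws its SNVs from the
#'   gene's pool of segregating sites (each with a fixed alternate allele),
#'   so variants recur across samples and the cohort-wide nonredundant
#'   count stays well below the per-sample sum - as in real strain
#'   populations. Per-gene counts are capped at the pool size.
#' @param seed Master RNG seed for the whole simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 2L, genes_per_strain = 100L,
                       gene_length_codons = c(100L, 300L),
                       n_case = 60L, n_control = 30L,
                       baseline_snv_rate = 5, n_markers = 5L,
                       marker_genes = NULL, effect_multiplier = 4,
                       abundance_meanlog = 0, abundance_sdlog = 0.5,
                       total_abundance = 0.2,
                       depth_shape = 4, depth_scale = 5,
                       syn_fraction = NA_real_, segregating_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              genes_per_strain = as.integer(genes_per_strain),
              gene_length_codons = as.integer(gene_length_codons),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              baseline_snv_rate = baseline_snv_rate,
              n_markers = as.integer(n_markers),
              marker_genes = marker_genes,
              effect_multiplier = effect_multiplier,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              total_abundance = total_abundance,
              depth_shape = depth_shape, depth_scale = depth_scale,
              syn_fraction = syn_fraction,
              segregating_fraction = segregating_fraction,
              seed = as.integer(seed))
  if (cfg$n_strains < 1L || cfg$genes_per_strain < 1L)
    stopf("need at least one strain and one gene per strain")
  if (cfg$n_case < 1L || cfg$n_control < 1L)
    stopf("need at least one case and one control sample")
  if (cfg$effect_multiplier < 1) stopf("effect_multiplier must be >= 1")
  if (cfg$baseline_snv_rate < 0) stopf("baseline_snv_rate must be >= 0")
  if (length(cfg$gene_length_codons) != 2L ||
      any(cfg$gene_length_codons < 2L))
    stopf("gene_length_codons must be a range of at least 2 codons")
  if (cfg$total_abundance <= 0 || cfg$total_abundance > 1)
    stopf("total_abundance must be in (0, 1]")
  if (!is.na(cfg$syn_fraction) &&
      (cfg$syn_fraction < 0 || cfg$syn_fraction > 1))
    stopf("syn_fraction must be in [0, 1] or NA")
  if (cfg$segregating_fraction <= 0 || cfg$segregating_fraction > 1)
    stopf("segregating_fraction must be in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

SENSE_CODONS <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Simulate strain reference genomes with annotated CDS genes
#'
#' Generates, deterministically under the config seed, `n_strains` contigs
#' carrying `genes_per_strain` CDS genes each: random sense codons framed by
#' ATG and a stop codon, random strand, separated by random intergenic
#' spacers. Every gene translates without internal stops by construction.
#'
#' @param config A [sim_config].
#' @param outdir If non-`NULL`, `genome.fasta` and `genes.gff3` are written
#'   there.
#' @return List of class `synthetic_genomes`: `genes` ([gene_models], cds
#'   with trailing stop trimmed), `genome` (named character vector of contig
#'   sequences), `marker_genes`, and `files` (paths written, or `NULL`).
#' @export
simulate_genomes <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, 2L)
  sense <- SENSE_CODONS()
  with_seed(seeds[1L], {
    rows <- list()
    genome <- character()
    for (s in seq_len(config$n_strains)) {
      strain <- sprintf("strain_%02d", s)
      pos <- 1L
      contig <- character()
      for (g in seq_len(config$genes_per_strain)) {
        gid <- sprintf("%s_g%03d", strain, g)
        gap <- sample(20:80, 1L)
        spacer <- paste(sample(BASES, gap, replace = TRUE), collapse = "")
        len <- sample(config$gene_length_codons[1L]:config$gene_length_codons[2L], 1L)
        cds <- paste0("ATG",
                      paste(sample(sense, len - 1L, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1L))
        strand <- sample(c("+", "-"), 1L)
        gseq <- if (strand == "+") cds else revcomp(cds)
        start <- pos + gap
        end <- start + nchar(cds) - 1L
        contig <- c(contig, spacer, gseq)
        pos <- end + 1L
        rows[[gid]] <- data.frame(gene_id = gid, strain = strain,
                                  start = start, end = end, strand = strand,
                                  cds = trim_trailing_stop(cds),
                                  stringsAsFactors = FALSE)
      }
      tail_gap <- paste(sample(BASES, 30L, replace = TRUE), collapse = "")
      genome[strain] <- paste(c(contig, tail_gap), collapse = "")
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    genes <- gene_models(df$gene_id, df$strain, df$start, df$end, df$strand,
                         df$cds)
    markers <- config$marker_genes %||%
      sort(sample(genes$gene_id, config$n_markers))
    if (!all(markers %in% genes$gene_id))
      stopf("marker_genes not among generated gene ids")
    files <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      fasta <- file.path(outdir, "genome.fasta")
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
      gff <- file.path(outdir, "genes.gff3")
      write_gene_gff3(genes, gff)
      files <- c(fasta = fasta, gff = gff)
    }
    structure(list(genes = genes, genome = genome, marker_genes = markers,
                   files = files, config = config),
              class = "synthetic_genomes")
  })
}

# Enumerate every possible single-base change of a coding sequence with its
# synonymous/nonsynonymous status under the standard code.
enumerate_codon_changes <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  cds_pos <- rep(seq_len(n), each = 3L)
  ref <- rep(strsplit(cds, "")[[1L]], each = 3L)
  alt <- character(3L * n)
  syn <- logical(3L * n)
  k <- 1L
  for (i in seq_len(n)) {
    ci <- (i - 1L) %/% 3L + 1L
    wi <- (i - 1L) %% 3L + 1L
    codon <- codons[ci]
    for (b in setdiff(BASES, substr(codon, wi, wi))) {
      mut <- codon
      substr(mut, wi, wi) <- b
      alt[k] <- b
      syn[k] <- code[[mut]] != "*" && code[[mut]] == code[[codon]]
      k <- k + 1L
    }
  }
  data.frame(cds_pos = cds_pos, ref = ref, alt = alt, synonymous = syn,
             stringsAsFactors = FALSE)
}

#' Plant a substitution set with a prescribed synonymous fraction
#'
#' Chooses exactly `n_subs` single-base substitutions at distinct positions
#' of `cds`, of which `round(n_subs * syn_fraction)` are synonymous under
#' the standard code. Used to build Ka/Ks test fixtures with known truth.
#'
#' @param cds Coding sequence (valid frame, no internal stops).
#' @param n_subs Number of substitutions.
#' @param syn_fraction Target synonymous fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return Data frame `cds_pos`, `ref`, `alt`, `synonymous`.
#' @export
plant_kaks_gene <- function(cds, n_subs, syn_fraction, seed = 1L) {
  changes <- enumerate_codon_changes(cds)
  n_syn <- round(n_subs * syn_fraction)
  n_non <- n_subs - n_syn
  with_seed(seed, {
    pick <- function(pool, n, used) {
      pool <- pool[!pool$cds_pos %in% used, , drop = FALSE]
      avail <- unique(pool$cds_pos)
      if (length(avail) < n)
        stopf("insufficient eligible sites: need %d, have %d", n,
              length(avail))
      sel_pos <- if (length(avail) == 1L) avail else sample(avail, n)
      out <- pool[pool$cds_pos %in% sel_pos, , drop = FALSE]
      # one change per selected position
      out[!duplicated(out$cds_pos), , drop = FALSE][
        match(sel_pos, unique(out$cds_pos[!duplicated(out$cds_pos)])), ,
        drop = FALSE]
    }
    syn_pool <- changes[changes$synonymous, , drop = FALSE]
    non_pool <- changes[!changes$synonymous, , drop = FALSE]
    # randomize which change represents each position
    syn_pool <- syn_pool[sample(nrow(syn_pool)), , drop = FALSE]
    non_pool <- non_pool[sample(nrow(non_pool)), , drop = FALSE]
    sel_syn <- pick(syn_pool, n_syn, integer())
    sel_non <- pick(non_pool, n_non, sel_syn$cds_pos)
    out <- rbind(sel_syn, sel_non)
    out[order(out$cds_pos), , drop = FALSE]
  })
}

# Convert cds-coordinate substitutions of one gene into genomic forward-strand
# SNV fields.
cds_change_to_genomic <- function(gene, cds_pos, ref, alt) {
  if (gene$strand == "+") {
    data.frame(pos = gene$start + cds_pos - 1L, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = gene$end - cds_pos + 1L,
               ref = unname(complement_base(ref)),
               alt = unname(complement_base(alt)), stringsAsFactors = FALSE)
  }
}

#' Simulate a complete case/control cohort over synthetic genomes
#'
#' Draws per-sample strain abundances and depths, then per-gene SNV counts
#' Poisson with mean `baseline_snv_rate x (span length / 1000) x abundance x
#' depth`, multiplied by `effect_multiplier` for marker genes in cases. With
#' `detail = "snvs"` individual variant sites are planted (distinct
#' positions within each gene per sample; alternate alleles uniform over the
#' three non-reference bases, or biased to hit the configured synonymous
#' fraction) and per-sample VCFs can be emitted along with abundance/depth/
#' metadata tables.
#'
#' @param config A [sim_config].
#' @param genomes Result of [simulate_genomes()] (or `NULL` to generate one).
#' @param detail `"counts"` (fast: per-gene counts only) or `"snvs"` (plant
#'   individual variants).
#' @param outdir If non-`NULL` (requires `detail = "snvs"`), writes
#'   `genome.fasta`, `genes.gff3`, `abundance.tsv`, `depth.tsv`,
#'   `metadata.tsv` and one VCF per sample under `vcf/`.
#' @param cohort Cohort tag recorded in the metadata.
#' @return List of class `synthetic_cohort`: `genes`, `truth` (marker ids +
#'   effect), `abundance`, `depth`, `metadata`, `raw` (sample x gene count
#'   matrix), `snvs` ([snv_records] or `NULL`), `files`.
#' @export
simulate_cohort <- function(config, genomes = NULL,
                            detail = c("counts", "snvs"), outdir = NULL,
                            cohort = "discovery") {
  stopifnot(inherits(config, "sim_config"))
  detail <- match.arg(detail)
  if (!is.null(outdir) && detail != "snvs")
    stopf("writing cohort files requires detail = \"snvs\"")
  if (is.null(genomes)) genomes <- simulate_genomes(config)
  genes <- genomes$genes
  markers <- genomes$marker_genes
  seeds <- child_seeds(config$seed, 3L)
  with_seed(seeds[2L], {
    n <- config$n_case + config$n_control
    samples <- c(sprintf("case_%03d", seq_len(config$n_case)),
                 sprintf("control_%03d", seq_len(config$n_control)))
    label <- rep(c("case", "control"), c(config$n_case, config$n_control))
    strains <- unique(genes$strain)
    ns <- length(strains)

    ab <- matrix(rlnorm(n * ns, config$abundance_meanlog,
                        config$abundance_sdlog), n, ns,
                 dimnames = list(samples, strains))
    ab <- ab / rowSums(ab) * config$total_abundance
    dp <- matrix(rgamma(n * ns, shape = config$depth_shape,
                        scale = config$depth_scale), n, ns,
                 dimnames = list(samples, strains))

    span <- genes$end - genes$start + 1L
    ad <- ab[, genes$strain, drop = FALSE] * dp[, genes$strain, drop = FALSE]
    lambda <- sweep(ad, 2L, config$baseline_snv_rate * span / 1000, `*`)
    is_marker <- genes$gene_id %in% markers
    lambda[label == "case", is_marker] <-
      lambda[label == "case", is_marker] * config$effect_multiplier
    raw <- matrix(rpois(length(lambda), lambda), n,
                  nrow(genes), dimnames = list(samples, genes$gene_id))
    pool_size <- pmax(1L, as.integer(ceiling(
      config$segregating_fraction * span)))
    raw <- pmin(raw, matrix(pool_size, n, nrow(genes), byrow = TRUE))

    snvs <- NULL
    if (detail == "snvs")
      snvs <- with_seed(seeds[3L],
                        plant_snvs(config, genes, raw, genomes$genome,
                                   pool_size))

    metadata <- data.frame(sample = samples, label = label, cohort = cohort,
                           stringsAsFactors = FALSE)
    files <- NULL
    if (!is.null(outdir)) {
      files <- emit_cohort_files(genomes, ab, dp, metadata, snvs, outdir)
    }
    structure(list(genes = genes,
                   truth = list(marker_genes = markers,
                                effect_multiplier = config$effect_multiplier),
                   abundance = ab, depth = dp, metadata = metadata,
                   raw = raw, snvs = snvs, files = files, config = config),
              class = "synthetic_cohort")
  })
}

# Draw the individual variant sites behind a raw count matrix. Each gene
# carries a pool of segregating sites (uniform positions, one fixed
# alternate allele each); every sample draws its SNVs from that pool
# without replacement, so variants recur across samples. With a configured
# syn_fraction the synonymous/nonsynonymous split is matched per draw
# instead (Ka/Ks fixtures).
plant_snvs <- function(config, genes, raw, genome, pool_size) {
  alt_tab <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 4L, byrow = TRUE)  # rows follow BASES
  out <- vector("list", 0L)
  samples <- rownames(raw)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    counts <- raw[, gi]
    if (is.na(config$syn_fraction)) {
      # the gene's segregating-site pool
      pool_pos <- sort(sample(seq.int(g$start, g$end), pool_size[gi]))
      refb <- substring(genome[[g$strain]], pool_pos, pool_pos)
      altb <- alt_tab[cbind(match(refb, BASES),
                            sample.int(3L, pool_size[gi], replace = TRUE))]
    }
    for (si in which(counts > 0L)) {
      k <- counts[si]
      if (is.na(config$syn_fraction)) {
        take <- sort(sample.int(pool_size[gi], k))
        df <- data.frame(pos = pool_pos[take], ref = refb[take],
                         alt = altb[take], stringsAsFactors = FALSE)
      } else {
        sel <- plant_kaks_gene(g$cds, k, config$syn_fraction,
                               seed = sample.int(.Machine$integer.max, 1L))
        df <- cds_change_to_genomic(g, sel$cds_pos, sel$ref, sel$alt)
      }
      df$strain <- g$strain
      df$sample <- samples[si]
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) return(snv_records())
  all <- do.call(rbind, out)
  all <- all[order(all$sample, all$strain, all$pos), , drop = FALSE]
  snv_records(all$strain, all$pos, all$ref, all$alt, all$sample)
}

emit_cohort_files <- function(genomes, ab, dp, metadata, snvs, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes$genome), fasta)
  gff <- file.path(outdir, "genes.gff3")
  write_gene_gff3(genomes$genes, gff)
  ab_path <- file.path(outdir, "abundance.tsv")
  dp_path <- file.path(outdir, "depth.tsv")
  meta_path <- file.path(outdir, "metadata.tsv")
  write_sample_matrix(ab, ab_path)
  write_sample_matrix(dp, dp_path)
  write.table(metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  vcf_dir <- file.path(outdir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  contig_lengths <- setNames(nchar(genomes$genome), names(genomes$genome))
  vcfs <- character()
  for (s in metadata$sample) {
    rec <- snvs[snvs$sample == s, , drop = FALSE]
    p <- file.path(vcf_dir, paste0(s, ".vcf"))
    write_snv_vcf(rec, p, contig_lengths, depth = dp[s, ])
    vcfs[s] <- p
  }
  c(fasta = fasta, gff = gff, abundance = ab_path, depth = dp_path,
    metadata = meta_path, vcfs = list(vcfs))
}
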