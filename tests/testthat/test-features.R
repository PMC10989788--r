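# SNV-to-gene aggregation, abundance x depth normalization and strain
# filtering.

toy_genes <- function() {
  gene_models(gene_id = c("A", "B"), strain = c("chr1", "chr1"),
              start = c(1L, 10L), end = c(20L, 30L), strand = c("+", "+"),
              cds = c(strrep("GCT", 6L) , strrep("GGA", 7L)))
}

test_that("SNVs are assigned by inclusive interval containment, overlaps to both", {
  genes <- toy_genes()
  snvs <- snv_records(strain = rep("chr1", 3), pos = c(5L, 15L, 25L),
                      ref = c("G", "G", "G"), alt = c("A", "A", "A"),
                      sample = rep("s1", 3))
  raw <- assign_snvs_to_genes(snvs, genes)
  expect_equal(raw["s1", "A"], 2L)  # pos 5 and 15
  expect_equal(raw["s1", "B"], 2L)  # pos 15 and 25
  expect_equal(nrow(attr(raw, "unassigned")), 0L)

  # boundary: inclusive end at 20 counts, 31 does not
  snvs2 <- snv_records("chr1", c(20L, 31L), c("G", "G"), c("A", "A"),
                       c("s1", "s1"))
  raw2 <- assign_snvs_to_genes(snvs2, genes)
  expect_equal(raw2["s1", "A"], 1L)
  expect_equal(attr(raw2, "unassigned")$pos, 31L)

  # conservation: column sums equal per-gene assigned totals
  expect_equal(sum(raw), 4L)
})

test_that("nonredundant counting is set cardinality over (strain,pos,ref,alt)", {
  snvs <- snv_records(strain = rep("chrA", 5),
                      pos = c(5L, 5L, 5L, 5L, 9L),
                      ref = c("A", "A", "A", "A", "C"),
                      alt = c("G", "G", "G", "G", "T"),
                      sample = c("s1", "s2", "s3", "s4", "s1"))
  expect_equal(count_nonredundant(snvs), 2L)
  expect_equal(count_nonredundant(snv_records()), 0L)
  two_alts <- snv_records(rep("chrA", 2), c(5L, 5L), c("A", "A"),
                          c("G", "T"), c("s1", "s1"))
  expect_equal(count_nonredundant(two_alts), 2L)
})

test_that("normalization divides by abundance x depth with zero guards", {
  genes <- toy_genes()[1, ]
  class(genes) <- c("gene_models", "data.frame")
  mk_cohort <- function(a, d) cohort_data(
    matrix(a, 1, 1, dimnames = list("s1", "chr1")),
    matrix(d, 1, 1, dimnames = list("s1", "chr1")),
    data.frame(sample = "s1", label = "case", cohort = "x"))
  raw <- matrix(10L, 1, 1, dimnames = list("s1", "A"))
  f <- normalize_features(raw, genes, mk_cohort(0.05, 20))
  expect_equal(f$values[1, 1], 10)        # 10 / (0.05 * 20)
  raw7 <- matrix(7L, 1, 1, dimnames = list("s1", "A"))
  expect_equal(normalize_features(raw7, genes, mk_cohort(1, 1))$values[1, 1], 7)
  raw0 <- matrix(0L, 1, 1, dimnames = list("s1", "A"))
  expect_equal(normalize_features(raw0, genes, mk_cohort(0, 0))$values[1, 1], 0)
  expect_error(normalize_features(raw, genes, mk_cohort(0, 0)),
               "abundance x depth = 0")
})

test_that("strain filtering uses strict cohort-mean thresholds", {
  ab <- matrix(c(0.006, 0.006, 0.005, 0.005, 0.2, 0.2), 2, 3,
               dimnames = list(c("s1", "s2"), c("keep", "edge", "big")))
  dp <- matrix(c(12, 12, 50, 50, 9, 11), 2, 3,
               dimnames = list(c("s1", "s2"), c("keep", "edge", "big")))
  ct <- cohort_data(ab, dp, data.frame(sample = c("s1", "s2"),
                                       label = "case", cohort = "x"))
  kept <- filter_strains(ct)
  expect_true("keep" %in% kept)       # 0.006 > 0.005 and 12 > 10
  expect_false("edge" %in% kept)      # 0.005 is not > 0.005
  expect_false("big" %in% kept)       # mean depth exactly 10 is not > 10
  expect_error(filter_strains(ct, min_abundance = 0.5), "relax")
})

test_that("scaling a sample's depth and raw counts together is an exact no-op", {
  cfg <- small_config(23)
  sc <- simulate_cohort(cfg)
  f1 <- build_features(sc, min_abundance = NULL, min_depth = NULL)
  ct <- cohort_data(sc$abundance, sc$depth * 2, sc$metadata)
  genes <- sc$genes
  f2 <- normalize_features(sc$raw * 2L, genes, ct)
  expect_identical(f2$values, f1$values)
})

test_that("non-marker genes show uniform Wilcoxon p values across case/control", {
  hits <- 0L
  for (s in 1:3) {
    cfg <- small_config(300 + s)
    g <- simulate_genomes(cfg)
    sc <- simulate_cohort(cfg, g)
    f <- build_features(sc, min_abundance = NULL, min_depth = NULL)
    nonmark <- setdiff(colnames(f$values), g$marker_genes)
    enr <- enrich_panel(f, genes = nonmark)
    p <- suppressWarnings(ks.test(enr$p_value, "punif"))$p.value
    if (p > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
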