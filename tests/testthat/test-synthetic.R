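# The synthetic cohort generator: determinism, construction invariants, and
# the generative law the downstream stages rely on.

test_that("genome simulation is deterministic and produces valid CDS genes", {
  cfg <- small_config(3)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- simulate_genomes(cfg, outdir = d1)
  g2 <- simulate_genomes(cfg, outdir = d2)
  expect_identical(g1$genes, g2$genes)
  expect_identical(unname(tools::md5sum(g1$files[["fasta"]])),
                   unname(tools::md5sum(g2$files[["fasta"]])))
  expect_identical(unname(tools::md5sum(g1$files[["gff"]])),
                   unname(tools::md5sum(g2$files[["gff"]])))
  # every gene translates without internal stops
  aa <- vapply(g1$genes$cds, function(s) as.character(
    Biostrings::translate(Biostrings::DNAString(s))), character(1))
  expect_false(any(grepl("*", aa, fixed = TRUE)))
  expect_error(sim_config(genes_per_strain = 0), "at least one")
})

test_that("emitted cohort files re-read into the starting objects", {
  cfg <- small_config(13)
  g <- simulate_genomes(cfg)
  d <- tempfile()
  sc <- simulate_cohort(cfg, g, detail = "snvs", outdir = d)
  gm <- read_gene_models(file.path(d, "genes.gff3"),
                         file.path(d, "genome.fasta"))
  o <- order(gm$gene_id)
  expect_identical(gm$cds[o], g$genes$cds[order(g$genes$gene_id)])
  ct <- read_cohort_tables(file.path(d, "abundance.tsv"),
                           file.path(d, "depth.tsv"),
                           file.path(d, "metadata.tsv"))
  expect_equal(ct$abundance, sc$abundance, tolerance = 1e-12)
  expect_equal(ct$metadata$label, sc$metadata$label)
})

test_that("cohort simulation is deterministic and consistent across detail levels", {
  cfg <- small_config(17)
  g <- simulate_genomes(cfg)
  a <- simulate_cohort(cfg, g)
  b <- simulate_cohort(cfg, g, detail = "snvs")
  expect_identical(a$raw, b$raw)
  tab <- table(b$snvs$sample)
  expect_true(all(tab[rownames(b$raw)] == rowSums(b$raw)))
  c2 <- simulate_cohort(cfg, g, detail = "snvs")
  expect_identical(b$snvs, c2$snvs)
})

test_that("with no planted effect the case/control count laws are exchangeable", {
  # two-sample KS on one non-marker gene's normalized burden, several seeds
  hits <- 0L
  for (s in 1:8) {
    cfg <- sim_config(n_strains = 1L, genes_per_strain = 10L,
                      n_case = 100L, n_control = 100L,
                      effect_multiplier = 1, seed = 100 + s)
    sc <- simulate_cohort(cfg)
    f <- build_features(sc, min_abundance = NULL, min_depth = NULL)
    v <- f$values[, 3L]
    p <- suppressWarnings(
      ks.test(v[f$metadata$label == "case"],
              v[f$metadata$label == "control"]))$p.value
    if (p > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("mean SNV counts follow the Poisson rate law", {
  cfg <- sim_config(n_strains = 1L, genes_per_strain = 5L,
                    n_case = 250L, n_control = 250L, effect_multiplier = 1,
                    seed = 31)
  g <- simulate_genomes(cfg)
  sc <- simulate_cohort(cfg, g)
  gene <- 2L
  span <- g$genes$end[gene] - g$genes$start[gene] + 1L
  ad <- sc$abundance[, g$genes$strain[gene]] * sc$depth[, g$genes$strain[gene]]
  lambda <- cfg$baseline_snv_rate * span / 1000 * ad
  se <- sqrt(sum(lambda)) / length(lambda)
  expect_lt(abs(mean(sc$raw[, gene]) - mean(lambda)), 3 * se)
})

test_that("depth scaling doubles raw counts but leaves normalized burden unchanged", {
  base <- sim_config(n_strains = 1L, genes_per_strain = 20L, n_case = 200L,
                     n_control = 200L, effect_multiplier = 1, seed = 41)
  dbl <- sim_config(n_strains = 1L, genes_per_strain = 20L, n_case = 200L,
                    n_control = 200L, effect_multiplier = 1, seed = 41,
                    depth_scale = 10,       # doubled mean depth
                    segregating_fraction = 1)  # no count cap in the way
  g <- simulate_genomes(base)
  s1 <- simulate_cohort(base, g)
  s2 <- simulate_cohort(dbl, g)
  f1 <- build_features(s1, min_abundance = NULL, min_depth = NULL)
  f2 <- build_features(s2, min_abundance = NULL, min_depth = NULL)
  m1 <- mean(s1$raw); m2 <- mean(s2$raw)
  se_raw <- sqrt(sum(s1$raw) + sum(s2$raw) / 4) / length(s1$raw)
  expect_lt(abs(m2 / 2 - m1), 3 * se_raw)
  v1 <- colMeans(f1$values); v2 <- colMeans(f2$values)
  se_v <- sqrt(var(as.vector(f1$values)) / length(f1$values) +
                 var(as.vector(f2$values)) / length(f2$values))
  expect_lt(abs(mean(v2) - mean(v1)), 3 * se_v)
})

test_that("plant_kaks_gene hits the requested synonymous fraction exactly", {
  cds <- random_cds(120L, seed = 5)
  sel <- plant_kaks_gene(cds, 20L, 0.5, seed = 7)
  expect_equal(nrow(sel), 20L)
  expect_equal(anyDuplicated(sel$cds_pos), 0L)
  # brute-force reclassification of each planted change
  lab <- vapply(seq_len(nrow(sel)), function(i) {
    ci <- (sel$cds_pos[i] - 1) %/% 3
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    oracle_classify(codon, (sel$cds_pos[i] - 1) %% 3 + 1, sel$alt[i])
  }, character(1))
  expect_equal(sum(lab == "synonymous"), 10L)
  expect_identical(lab == "synonymous", sel$synonymous)

  all_syn <- plant_kaks_gene(cds, 10L, 1, seed = 8)
  expect_true(all(all_syn$synonymous))
  none_syn <- plant_kaks_gene(cds, 10L, 0, seed = 9)
  expect_false(any(none_syn$synonymous))
  expect_error(plant_kaks_gene("ATGTGG", 5L, 1, seed = 1), "insufficient")
})
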