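# NG86 site counting, substitution classification and the corrected
# Ka/Ks ratio.

test_that("potential site counts match brute-force mutant enumeration", {
  expect_equal(count_potential_sites("TTT")[["S_sites"]], 1 / 3)
  expect_equal(count_potential_sites("TGG")[["S_sites"]], 0)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cd in sense) {
    got <- count_potential_sites(cd)
    want <- oracle_codon_sites(cd)
    expect_equal(got[["S_sites"]], want[["S"]], tolerance = 1e-12)
    expect_equal(got[["N_sites"]], want[["N"]], tolerance = 1e-12)
  }
})

test_that("site counts always partition three sites per codon", {
  for (s in 1:5) {
    cds <- random_cds(50L, seed = s)
    sites <- count_potential_sites(cds)
    expect_equal(sites[["S_sites"]] + sites[["N_sites"]], nchar(cds))
  }
})

test_that("classification agrees with translate-and-compare on random SNVs", {
  cds <- random_cds(80L, seed = 2)
  gene <- data.frame(gene_id = "g", strain = "c", start = 101L,
                     end = 100L + nchar(cds), strand = "+", cds = cds)
  withr::with_seed(8, {
    cpos <- sample(nchar(cds), 300L, replace = TRUE)
    refb <- substring(cds, cpos, cpos)
    altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                    b), 1L), character(1))
  })
  keep <- !duplicated(cpos)
  snvs <- snv_records("c", 100L + cpos[keep], refb[keep], altb[keep], "s1")
  cls <- classify_substitutions(gene, snvs)
  want <- vapply(which(keep), function(i) {
    ci <- (cpos[i] - 1) %/% 3
    oracle_classify(substr(cds, ci * 3 + 1, ci * 3 + 3),
                    (cpos[i] - 1) %% 3 + 1, altb[i])
  }, character(1))
  expect_identical(cls$labels, unname(want))
})

test_that("minus-strand SNVs are complemented before codon lookup", {
  # coding GCT at genomic 4..6 on the minus strand; genomic A->G is coding
  # T->C at the third codon position: synonymous
  gene <- data.frame(gene_id = "g", strain = "c", start = 4L, end = 6L,
                     strand = "-", cds = "GCT")
  snv <- snv_records("c", 4L, "A", "G", "s1")
  expect_equal(classify_substitutions(gene, snv)$labels, "synonymous")
  # genomic C->T at position 6 is coding G->A (first codon position): Ala->Thr
  snv2 <- snv_records("c", 6L, "C", "T", "s1")
  expect_equal(classify_substitutions(gene, snv2)$labels, "nonsynonymous")
})

test_that("a ref allele disagreeing with the reference sequence is an error", {
  gene <- data.frame(gene_id = "g", strain = "c", start = 1L, end = 9L,
                     strand = "+", cds = "ATGGCTGCT")
  expect_error(classify_substitutions(gene,
                                      snv_records("c", 2L, "A", "G", "s1")),
               "disagrees")
})

test_that("ratio guards: zero numerator, zero denominator, symmetry", {
  r0 <- kaks_ratio(100, 200, Sd = 10, Nd = 0)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$regime, "purifying")
  rs <- kaks_ratio(100, 200, Sd = 0, Nd = 10)
  expect_true(is.na(rs$ratio))
  expect_equal(rs$regime, "undefined")
  rq <- kaks_ratio(100, 100, Sd = 20, Nd = 20)
  expect_equal(rq$ratio, 1)
  expect_equal(rq$regime, "neutral")
  rsat <- kaks_ratio(100, 200, Sd = 80, Nd = 10)
  expect_equal(rsat$regime, "undefined")  # pS >= 3/4, correction diverges
  expect_equal(rsat$pS, 0.8)              # raw proportion retained
  expect_error(kaks_ratio(100, 200, -1, 0), "nonnegative")
})

test_that("the Jukes-Cantor correction vanishes for small proportions", {
  for (pS in c(0.005, 0.01, 0.03, 0.05)) {
    r <- kaks_ratio(1000, 2000, Sd = pS * 1000, Nd = 0)
    expect_lte(abs(r$Ks - pS), 0.01)
  }
})

test_that("per-gene Ka/Ks recovers planted synonymous fractions", {
  cds <- random_cds(150L, seed = 12)
  gene <- gene_models("g1", "c", 101L, 100L + nchar(cds), "+", cds)
  sel <- plant_kaks_gene(cds, 20L, 0.5, seed = 3)
  snvs <- snv_records("c", 100L + sel$cds_pos, sel$ref, sel$alt, "s1")
  res <- kaks_for_genes(gene, snvs)
  expect_equal(res$Sd, 10)
  expect_equal(res$Nd, 10)
  # duplicated observations across samples collapse to the same result
  snvs2 <- rbind(snvs, transform(snvs, sample = "s2"))
  class(snvs2) <- c("snv_records", "data.frame")
  res2 <- kaks_for_genes(gene, snvs2)
  expect_equal(res2$Sd, res$Sd)
  expect_equal(res2$Nd, res$Nd)
  # no SNVs -> undefined sentinel
  res0 <- kaks_for_genes(gene, snv_records())
  expect_true(is.na(res0$ratio))
  expect_equal(res0$regime, "undefined")
})

test_that("planted selection regimes land on the correct side of neutrality", {
  # strongly purifying (syn-heavy) and strongly diversifying (nonsyn-heavy)
  for (cfg in list(list(sf = 0.9, side = "below"),
                   list(sf = 0.1, side = "above"))) {
    ratios <- numeric(5)
    for (s in 1:5) {
      cds <- random_cds(200L, seed = 500 + s)
      gene <- gene_models("g", "c", 1L, nchar(cds), "+", cds)
      sel <- plant_kaks_gene(cds, 30L, cfg$sf, seed = s)
      snvs <- snv_records("c", sel$cds_pos, sel$ref, sel$alt, "s1")
      ratios[s] <- kaks_for_genes(gene, snvs)$ratio
    }
    if (cfg$side == "below") expect_true(all(ratios < 1))
    else expect_true(all(ratios > 1))
  }
})
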