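# Independent oracles used to verify the package's computations. These
# deliberately re-derive results by brute force (enumeration, pairwise
# loops, translate-and-compare) rather than calling the package internals.

BASES4 <- c("A", "C", "G", "T")

# brute-force NG86 site counts of one codon: enumerate the 9 single-base
# mutants and translate each with Biostrings
oracle_codon_sites <- function(codon) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                           no.init.codon = TRUE))
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES4, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      maa <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                no.init.codon = TRUE))
      if (maa != "*" && maa == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# translate-and-compare classification of a single substitution
oracle_classify <- function(codon, pos_in_codon, alt) {
  mut <- codon
  substr(mut, pos_in_codon, pos_in_codon) <- alt
  aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                            no.init.codon = TRUE))
  aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                            no.init.codon = TRUE))
  if (aa2 == "*" || aa1 != aa2) "nonsynonymous" else "synonymous"
}

# exact two-sided rank-sum p value by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments (tie-free data)
oracle_exact_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUC by the explicit pairwise concordance loop
oracle_pairwise_auc <- function(scores, labels, positive = "case") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# random valid coding sequence (no internal stops, ATG start)
random_cds <- function(n_codons, seed = 1L) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  withr::with_seed(seed, paste0(
    "ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                 collapse = "")))
}

# toy classification problem: one perfectly separating feature among noise
make_separable <- function(n = 40L, p = 51L, seed = 1L) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%03d", seq_len(p))))
    y <- rep(c("case", "control"), length.out = n)
    x[, 1L] <- ifelse(y == "case", 1, 0) + rnorm(n, sd = 0.05)
    list(x = x, y = y)
  })
}

# small cohort config used across tests (fast counts-only simulations)
small_config <- function(seed, ...) {
  sim_config(genes_per_strain = 30L, n_case = 24L, n_control = 12L,
             seed = seed, ...)
}
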