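---
title: "Gene-level SNV burden markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level SNV burden markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvmark)
```

## The problem

Species-level relative abundance is an ambiguous disease signal: a depleted
*Faecalibacterium prausnitzii*, for instance, is seen in inflammatory bowel
disease, colorectal cancer and several other conditions, so an abundance
classifier cannot tell these apart. Strains of one species, however, differ
genetically by several percent, and the *positions* at which a strain
population varies - its single-nucleotide variants (SNVs) against a
reference genome - carry disease-specific information. snvmark implements a
marker-discovery workflow on this idea: aggregate per-sample variant calls
to per-gene SNV counts, remove the abundance and depth confound, select
marker genes with a random forest, and validate them across cohorts.

## The model

### Per-gene SNV burden

For sample $s$ and gene $g$ on strain $t$, the raw count $r_{sg}$ is the
number of called SNVs whose position falls inside the gene's 1-based
inclusive span (an SNV inside two overlapping genes counts toward both -
overlap is rare in bacterial genomes and this preserves per-gene
completeness). The normalized burden is

$$x_{sg} = \frac{r_{sg}}{a_{st}\, d_{st}},$$

where $a_{st}$ is the strain's relative abundance in the sample (fraction)
and $d_{st}$ its mean mapped coverage (fold units). Raw counts scale with
both factors - more of a strain, or deeper sequencing, yields more called
variants without any biological difference - and the division removes them.
A strain absent from a sample ($a d = 0$) must have zero counts; a nonzero
count there is treated as an input inconsistency, not silently patched.
Only strains with cohort-mean abundance above 0.5% and cohort-mean depth
above 10x (strict inequalities) enter the feature space; site-level calls
additionally pass QUAL >= 20 and DP >= 10 filters by default. The site
filters are this package's declared choice: depth thresholds of this kind
are conventional for metagenomic variant calling, but any value can be set.

### Marker selection

Genes are ranked by random-forest permutation importance (mean decrease in
accuracy, unscaled), with 500 trees and `sqrt(p)` candidate features per
split - the conventions of the randomForest package. The unscaled
permutation measure is used because the customary panel cutoff of 0.01 is
on the accuracy scale, whereas Gini importances are count-scaled; Gini is
available behind the `measure` argument. The panel is every gene with
importance strictly above the cutoff.

The supporting error curve is stratified 10-fold cross-validation of the
classifier over shrinking panels. Genes are re-ranked *within each training
fold* before evaluation, so the curve is free of selection bias - ranking
once on all data and then cross-validating drives the apparent error of
small panels toward zero on pure noise, a leakage failure the test suite
checks for explicitly. Evaluation of a fixed externally chosen ranking is
available with `rerank = FALSE`. The headline panel itself is ranked once
on the full discovery cohort, as is conventional when a single reported
panel is wanted.

### Evaluation

The final forest is trained on the selected panel. Within-cohort accuracy
is reported from out-of-bag votes - each sample is scored only by trees
that never saw it - rather than resubstitution, which would be trivially
optimistic. Transfer evaluation scores an untouched cohort; scores are
computed before evaluation labels are consulted. AUC is computed by the
Mann-Whitney concordance identity with 0.5 credit for ties, and the
trapezoidal integral of the ROC curve is maintained as an internal
cross-check (the two agree to numerical precision by construction).
Specificity contrasts (e.g. cases against an other-disease cohort) treat
all samples of one cohort as positive and the other as negative.

### Enrichment

Per-gene group differences use the two-sided Wilcoxon rank-sum test: exact
enumeration for small tie-free samples, otherwise the tie-corrected normal
approximation with continuity correction. No multiple-testing correction
is applied by default, matching the raw p < 0.05 convention of the
workflow this package reproduces; Benjamini-Hochberg is available behind
`adjust = "BH"`. Direction of enrichment is the group with the larger mean
rank.

### Ka/Ks

Selection pressure on marker genes is quantified with Nei-Gojobori (1986)
counting: each codon position contributes the fraction of its three
possible changes that are synonymous to the synonymous site total $S$ (the
rest to $N$; mutations creating stop codons count as nonsynonymous), and
each observed SNV is classified against the reference codon with the other
positions held at reference. Proportions $p_S = S_d/S$, $p_N = N_d/N$ are
Jukes-Cantor corrected, $K = -\tfrac34 \ln(1 - \tfrac43 p)$, and the ratio
$K_a/K_s$ is labelled purifying (< 1), neutral (within 0.1 of 1 - exact
equality is measure-zero) or positive (> 1). NG86 with equal mutation
weighting was chosen because it is fully specifiable and canonical; no
transition/transversion weighting or ML codon model is attempted.
Substitutions are pooled across samples as nonredundant strain/position/alt
tuples, because observed SNVs are population-level site variants rather
than a single evolved sequence pair; for the same reason multiple SNVs in
one codon are classified independently against the reference codon, a
documented simplification. Sentinels: $K_s = 0$ or a proportion at or
beyond 3/4 (where the correction diverges) yield an undefined ratio with
raw proportions retained. Trailing stop codons are trimmed before site
counting; genes with internal stops are excluded from Ka/Ks but still
counted in the feature matrix, keeping the feature space complete.

## The synthetic cohort generator

Real inputs to this workflow are per-sample VCFs against strain reference
genomes plus abundance/depth/metadata tables. The generator produces all
of them with known truth so that every stage is testable without
sequencing data.

* **Genomes** - 2 strains x 100 CDS genes of 100-300 codons (uniform),
  random sense codons framed by ATG and a stop, random strand, short
  intergenic spacers. Every gene translates cleanly by construction.
* **Abundance** - per sample, lognormal(0, 0.5) across strains,
  renormalized so the profiled strains total 20% of the community. Two
  gut strains at ~10% mean abundance each is a realistic magnitude for
  dominant commensals, and keeps both well above the 0.5% filter.
* **Depth** - gamma(shape 4, scale 5), mean 20x with realistic spread;
  about one sample-strain pair in seven falls below the 10x site filter,
  which exercises the attrition path.
* **Counts** - gene $g$ in sample $s$ draws
  $r_{sg} \sim \text{Poisson}\!\big(\rho \cdot \tfrac{L_g}{1000} \cdot
  a_{st} d_{st} \cdot m\big)$ with baseline rate $\rho = 5$ SNVs per kb
  per unit abundance x depth, and $m = 4$ for the five designated marker
  genes in case samples ($m = 1$ otherwise). The multiplicative
  $a \cdot d$ term *is* the confound the normalization removes; this is
  the minimal generative model that makes the normalization testable.
* **Sites** - each gene holds a pool of segregating sites (10% of its
  positions, each with a fixed alternate allele); samples draw their SNVs
  from the pool without replacement. Variants therefore recur across
  samples, the cohort-wide nonredundant count stays far below the
  per-sample sum, and pooled Ka/Ks does not saturate - as in real strain
  populations. An optional synonymous-fraction target reroutes planting
  through an exact codon-aware chooser for Ka/Ks fixtures.
* **Cohort** - 60 cases / 30 controls, mirroring a discovery cohort with
  a 2:1 case/control imbalance.

Everything is deterministic under the master seed, and the emitted files
round-trip exactly through the package's readers.

What the generator does *not* emulate: read-level error and mapping bias,
strain phylogenies and co-abundant strain mixtures, compositional coupling
between strains, gene gain/loss (accessory genomes), and linkage between
sites. Passing tests therefore demonstrate that the statistical machinery
behaves correctly under the stated generative law - not that real cohorts
of this size will reach the same accuracies.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching VCF and GFF3;
  any half-open conversion happens at library boundaries only.
* Importance ties are broken by gene id, making rankings reproducible.
* Stratified folds deal shuffled class members round-robin, so every
  training fold keeps both classes or the run aborts.
* The fitting function derives independent child seeds for ranking, CV
  and final training from the master seed, so the stages do not perturb
  each other's streams.
* Degenerate inputs: an all-constant feature matrix yields all-zero
  importances and an empty panel without fitting; single-class labels,
  empty panels, empty groups, and evaluation cohorts with one class are
  hard errors, as is an SNV whose ref allele contradicts the reference.
* Problem sizes in the test-suite simulations (cohorts of 36-90 samples,
  20 seeds for Monte-Carlo claims, 50-gene neutral Ka/Ks batches) were
  chosen to make distributional claims decidable at desk scale while a
  full run stays comfortably interactive.

## Orchestration

`run_discovery()` executes simulate/read -> features -> markers -> model ->
enrichment -> Ka/Ks, writes every stage output under one directory and
records an md5 for each in `manifest.json`; identical configs and seeds
reproduce byte-identical artifacts (the log carries no timestamps; stage
timings go to the console). `run_transfer()` scores an untouched cohort
against a saved model. The package API and these two drivers are the
intended interface; there is no shell wrapper.

## Limitations

* The normalization assumes a single abundance/depth pair per
  sample-strain; per-site coverage variation within a gene is not modelled.
* NG86 equal-weight counting underestimates synonymous rates when
  transitions dominate; with the generator's uniform mutation draw this
  bias is absent, but on real data a ratio near 1 should not be
  over-interpreted.
* Whether a discovery-cohort AUC of this kind is out-of-bag or
  cross-validated is a reporting choice; out-of-bag is used here and
  labelled as such in every report.
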