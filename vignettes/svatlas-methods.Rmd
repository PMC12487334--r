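---
title: "Methods: post-calling analysis of genotyped structural variants"
author: "svatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-calling analysis of genotyped structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svatlas)
```

# Scope and data model

`svatlas` analyses cohorts of genotyped structural variants (SVs) — deletions
(DEL), duplications (DUP), inversions (INV) and breakends/translocations
(BND) — as produced by short-read SV callers and genotypers. The package
starts where calling ends: its inputs are a multi-sample VCF with per-call
depth evidence, gene models, interval tracks (repeats, constrained elements,
assembly gaps), a per-base mean-depth track, and a sample-to-population map.

The central container is `SVCohort`, a `RangedSummarizedExperiment` whose
rows are SV breakpoint intervals (a `GRanges` with an `svtype` column) and
whose columns are samples. The `GT` assay codes diploid genotypes as ALT
dosage (0/1/2, `NA` missing); the `DHFFC` assay carries Duphold-style depth
fold-changes per call. All coordinates are held in the Bioconductor
convention (1-based, closed); VCF, GFF3 and BED inputs are converted at the
file boundary, so interval arithmetic lives on a single convention. The
length of a DEL/DUP/INV is its breakpoint-interval width; BND records have
no length and exist only to be removed by quality control.

# The filter cascade

`runFilterCascade()` applies five steps in a fixed order:

1. **Chromosome whitelist** — off-whitelist records are removed (an empty
   whitelist accepts all chromosomes).
2. **Translocation removal** — all BND records.
3. **Gap / high-depth exclusion** — any record overlapping an assembly gap
   or a high-depth region by at least 1 bp. High-depth regions are maximal
   merged runs of the depth track strictly above 100x (`highDepthRegions()`);
   such regions are dominated by collapsed repeats and mismapped reads.
4. **DHFFC genotype masking** — carrier calls (het or hom-alt) whose depth
   fold-change contradicts the SV type are set to missing: deletions with
   DHFFC > 0.7 (no depth drop), duplications with DHFFC < 1.3 (no gain),
   inversions with DHFFC strictly between 0.7 and 1.3. All thresholds are
   strict inequalities. Masking is restricted to carriers because a hom-ref
   call is expected to sit at DHFFC near 1; applying the deletion rule to
   non-carriers would erase essentially every reference call. Calls with no
   DHFFC value are retained: the filter acts only on positive evidence of
   depth inconsistency.
5. **Allele count / call rate** — after masking, the ALT allele count is
   recomputed over non-missing calls and sites with AC <= 2 or call rate
   < 0.80 are removed; a call rate of exactly 0.80 survives. Recomputing
   after masking (rather than trusting a pre-masking AC field) is the only
   order in which the two steps interact correctly.

The visual curation stage that a production pipeline would run between
steps 4 and 5 is represented as an explicit pass-through step
("curation pending"); scoring images is out of scope. The per-step report
telescopes (input − removed = surviving), the cascade is idempotent, and a
record's removal reason is the first step that catches it.

`computeDHFFC()` can recompute fold-changes from a depth track when the VCF
lacks them: the length-weighted mean depth inside the interval divided by
the length-weighted mean over both 1,000-bp flanks jointly, flanks clipped
at the track extent; a zero flank mean yields "no evidence" rather than a
value.

# Interval arithmetic

`overlapJoin()` reports every same-chromosome pair with at least `minBp`
overlapping bases whose reciprocal fraction (the smaller of the two
overlap/length ratios) reaches `minRecip`; with `minRecip = 0.5` it
reproduces `bedtools intersect -wo -f 0.50 -r`, thresholds inclusive.
Redundancy detection (`findRedundantSVs()`) single-links same-type records
at *strictly* greater than 95% reciprocal overlap — the strict/inclusive
split follows the conventions of the tools being mirrored. Merging two
high-confidence call sets through a jointly genotyped set
(`mergeSVSets()`) demands 100% reciprocal overlap, which is implemented as
exact coordinate equality plus matching SV type; any floating tolerance
would contradict a 100% criterion on both lengths.

# Consequence annotation

`classifySV()` implements a deliberately compact, SnpEff-style vocabulary
at SV granularity. HIGH-impact terms are transcript ablation (DEL spans a
whole transcript), exon loss (DEL fully contains an exon but not the whole
transcript), frameshift (DEL/DUP breakpoint strictly inside CDS with the
affected CDS length not divisible by 3, evaluated per transcript), and
gene fusion / bidirectional gene fusion (one breakpoint inside each of two
genes, same / opposite strand). MODERATE covers exon-containing
duplications and whole-gene inversions; LOW the UTR breakpoints; MODIFIER
intronic, up/downstream (within 5,000 bp, labelled by gene strand) and
intergenic records. A gene-overlapping record that fires no specific rule
receives a generic `gene_variant` catch-all so every SV carries at least
one annotation; `intergenic_region` is emitted exactly when no gene lies
within the up/downstream window. The up/downstream-only associations are
kept in the enrichment background ("genes associated with SVs") because an
annotator reports them; the affected set is the genes with at least one
HIGH term.

# Population genetics

Per-site differentiation uses the Weir & Cockerham (1984) two-population
estimator for diploids: variance components a (among populations), b
(among individuals within populations) and c (within individuals) from the
groups' sample sizes, ALT frequencies and observed heterozygosities, with
theta = a/(a+b+c). Sites monomorphic across both groups are undefined and
flagged rather than zeroed; negative estimates are retained for ranking,
matching what per-site F_ST tools report. The weighted (ratio-of-averages)
estimate `sum(a)/sum(a+b+c)` is attached for diagnostics. Under a
Balding–Nichols simulation the weighted estimate recovers the divergence
parameter F essentially unbiasedly, while the *mean* of per-site theta is
biased downward (a mean of noisy ratios), increasingly so as F grows — at
F = 0.2 the deficit is about 0.05 and does not vanish with sample size.
The package's validation therefore leans on the ratio-of-averages for
parameter recovery and treats the mean-of-ratios as descriptive.

The candidate scan ranks per-site theta within each farmed-versus-wild
comparison, takes the empirical top tail (type-7 interpolated quantile,
membership at >= threshold so ties are all kept), intersects the tails of
all comparisons, and keeps records whose allele-frequency difference
(farmed − wild) has the same non-zero sign everywhere. A zero difference in
any comparison fails the consistency rule — "same direction" is undefined
at zero, and strictness is the conservative choice. The scan is invariant
to comparison and record order and anti-monotone in the quantile.

PCA codes genotypes as dosages, imputes missing calls with the per-SV mean,
centres per SV (scaling off by default, as usual for genotype PCA) and
takes components from the SVD; results are deterministic up to sign.
Density summaries bin SVs by start coordinate into 1-Mb windows with strict
> 80 (HIGH) and < 10 (LOW) per-Mb thresholds; trailing partial windows are
flagged rather than rescaled.

# Enrichment statistics

Domain enrichment compares, per term, the proportion of term-carrying genes
inside the HIGH-affected set against the non-affected background using the
one-sided (enrichment) Fisher exact test computed as a hypergeometric upper
tail, with Benjamini–Hochberg adjustment across terms. Fold enrichment is
`(k/n_affected)/((K−k)/n_background)`, which is `+Inf` exactly when every
term gene is affected — the one definition consistent with both an
"infinite" fold for a fully-affected two-gene domain (one-sided
p = 487·486/(22,969·22,968) ≈ 4.49e-4 at the package's reference set sizes)
and the finite fold/p pair of a six-gene domain with two affected members
(fold ≈ 23.1, p ≈ 0.0063). The generic gene-set test is the same
hypergeometric over-representation against a user-supplied universe and
flat term map; no ontology propagation is attempted.

`subsetProportionTest()` compares a subset's success proportion against its
complement with a Pearson chi-square (no continuity correction, df = 1,
two-sided). On published example counts (17/366 versus 494/21,428) this
construction gives p ≈ 0.0026; other reasonable constructions (Yates
correction, one-sample binomial) give p between roughly 0.003 and 0.008,
so the implementation reports its construction explicitly alongside both
proportions rather than matching any particular printed value.

# The synthetic cohort generator

`simulateReference()`/`simulateCohort()` generate complete, truth-labelled
inputs. Defaults are the package's study conditions: a farmed group of 90
samples and three wild groups of 13, 22 and 37 (plus 8 F1 hybrids that
enter the VCF but are excluded from all statistics); log-normal SV lengths
calibrated so that medians are about 120 bp (DEL), 619 bp (DUP) and
2,456 bp (INV) with spread chosen to match the corresponding mean/median
ratios (about 223, 904 and 52,000 bp means); Balding–Nichols
per-population allele frequencies around an ancestral frequency drawn
uniformly on [0.05, 0.95]; Hardy–Weinberg genotypes within populations.
Per-population F defaults to 0.15 for the farmed group (stronger drift
under domestication) and 0.05–0.10 for the wild groups.

Planted structure, recorded per record in the truth table:

* **Domestication SVs** (default 50, shift 0.5): these bypass the
  Balding–Nichols draw — every wild group sits at the shared ancestral
  frequency and only the farmed group is shifted by ±0.5 (direction chosen
  to stay inside [0,1] and recorded). Anchoring the shift on the wild
  frequency keeps the farmed-versus-wild contrast equal to the planted
  effect size regardless of drift, which is what a recovery experiment
  needs to measure the scan rather than the simulator.
* **Consequence SVs**: deletions placed strictly inside an intron,
  deletions spanning one internal exon, and records with one breakpoint in
  each of two adjacent genes, so the annotator's recovery can be asserted
  at 100%.
* **Filter failures**, one mode each: gap overlap, high-depth overlap,
  DHFFC artifacts, allele count <= 2, call rate < 0.8.

DHFFC values are drawn from truncated normals conditional on SV type and
genotype: non-carriers near 1.0; clean deletion hets near 0.5 and hom-alts
near 0.05 (truncated below the 0.7 threshold); clean duplication carriers
near 1.6 (truncated above 1.3); artifact carriers are drawn strictly inside
their type's masking region. Clean inversion carriers are an equal mixture
of truncated normals below 0.7 and above 1.3: a copy-neutral inversion has
no depth signature, so a depth-consistency rule that keeps inversions only
at extreme fold-changes implies the retained real calls are the ones with
breakpoint-induced depth anomalies — and, more importantly for testing, it
makes clean and artifact calls separable with probability one, so the
masked set can be asserted to equal the planted set exactly. The truth
table's allele-count/call-rate labels are computed by the generator on its
own post-masking genotypes with inline arithmetic, independent of the
filtering module.

Everything is deterministic in the seed. What the generator does *not*
emulate: linkage and recombination (sites are independent), sequence
content (no FASTA or reads), genotyping error beyond the DHFFC artifacts,
overlapping gene models or alternative transcripts (one transcript per
gene), and realistic SV density heterogeneity (placement is uniform
outside gaps and high-depth regions). Green tests therefore demonstrate
correctness of the statistics and rules on data satisfying the model's
assumptions, not robustness to the full messiness of real cohorts.

# Numerical and design choices

* Quantile thresholds use R's type-7 (linear interpolation) definition;
  membership is at >= threshold and ties are all included, so candidate
  sets can exceed an exact 5% count.
* The hypergeometric tail is computed as `phyper(k-1, ..., lower.tail =
  FALSE)`; BH adjustment delegates to `p.adjust(method = "BH")`.
* Undefined per-site theta values are excluded from quantiles and means;
  they are never imputed as zero.
* Problem sizes used by the validation suite: 5,000 SVs x 100 samples for
  parameter recovery; 40,000 + 50 planted SVs x 162 samples for the scan
  recovery; 2,000 SVs x 100 samples for filter truth recovery; 500 x 500
  intervals for the overlap oracle; 200 permutations for null calibration.
  These sizes give stable stochastic checks while keeping a full run of
  the suite in the minutes range on one core.

# Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
ref <- simulateReference(cfg)
sim <- simulateCohort(cfg, ref)

casc <- runFilterCascade(sim$cohort, filterConfig(),
                         gaps = ref$gaps, highDepth = ref$highDepth)
casc$report

ann <- classifySV(rowRanges(casc$cohort), svType(casc$cohort), ref$models)
fst <- lapply(c("WILD_A", "WILD_E", "WILD_W"),
              function(g) wcFst(casc$cohort, sim$panel, "FARMED", g))
candidateScan(fst, quantile = 0.95)
```

# Known limitations

The consequence vocabulary is a simplification of a full effect ontology:
it supports the HIGH/non-HIGH partition and the category summaries the
downstream analyses need, not amino-acid-level consequences. The
two-population F_ST implementation does not generalise to r > 2 groups
(the scan only ever needs pairwise comparisons). The merge criterion is
exact coordinate equality; fuzzy breakpoint-window merging is deliberately
out of scope.
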