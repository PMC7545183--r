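---
title: "Methods: scanning crop cohorts for de-domestication and high-altitude adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning crop cohorts for de-domestication and high-altitude adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feralscan)
library(dplyr)
```

## The problem

Hexaploid bread wheat (*Triticum aestivum*, AABBDD) grown on the Tibetan
Plateau includes a semi-wild, feral form whose rachis shatters at maturity —
a wild-type seed-dispersal trait that was lost during domestication.
Detecting how such a population diverged from its landrace progenitors, and
which structural variants drive the reverted phenotype, requires several
cooperating analyses on resequenced cohorts: windowed differentiation scans,
read-depth copy-number statistics (SNP-based scans are blind to segmental
deletions), split-read genotyping of a transposable-element (TE) insertion,
gene-haplotype classification along an altitude gradient, and mixed-model
association that treats structural variants as pseudo-markers. feralscan
implements that pipeline end to end, together with a probe-read scaffold
anchoring procedure for building pseudomolecules, and — because real wheat
cohorts are hundreds of genomes — a synthetic-data module that generates
ground-truthed miniature cohorts on which every stage is testable.

All user-facing results are tibbles; fitted association models support
`tidy()`/`glance()`; each result type has a ggplot2 plotting function.

## Windowed differentiation scan

Differentiation between two groups (de-domesticated DE, n = 50, versus
domesticated DO, n = 52, in the motivating design) is measured with the
Weir–Cockerham (1984) estimator. For each biallelic site the three variance
components are computed from per-site sample sizes (non-missing calls only):
`a` among populations, `b` among individuals within populations, and `c`
within individuals (observed heterozygosity). The window statistic on the
100 kb / 100 kb grid is the "weighted" ratio of sums

$$F_{ST}(w) = \frac{\sum_{s \in w} a_s}{\sum_{s \in w}(a_s + b_s + c_s)},$$

the form the standard windowed-FST tools report. Negative window values are
reported, not clamped; windows with no usable polymorphic site are missing.
Sites callable in only one group are skipped, and monomorphic sites
contribute nothing (they are excluded from `n_sites`, a choice the windowed
tools leave ambiguous).

Nucleotide diversity per window is
$\pi(w) = \sum_{s \in w} \frac{x_s(n_s - x_s)}{\binom{n_s}{2}} / L_w$
with $x_s$ the alt-allele count among $n_s$ called alleles and $L_w$ the
window width in bp; the diversity ratio between groups
($\pi_{DO}/\pi_{DE}$) flags diversity loss under selection.

Candidate regions are the top 5% of windows, thresholded separately for the
A&B subgenomes and the D subgenome because wild-relative introgression
inflates A/B divergence. The threshold is the k-th largest window value
with `k = max(1, floor(0.05 n))`, so 100 non-missing windows yield exactly
5 candidates; ties can return more.

**Permutation null.** To rule out population-structure artefacts, group
labels are shuffled jointly over the whole cohort — samples, not windows,
are exchangeable — preserving group sizes exactly (the natural reading of a
label shuffle, which the original description leaves implicit), the
genome-wide windowed scan is recomputed, and the per-partition maximum is
recorded; 100 replicates by default. An observed threshold exceeding every
null maximum indicates the candidate set is not explained by expected
genome-wide diversity.

## Depth normalisation, PAV, and the CNV-index

Per-sample window depths on a 5 kb grid are normalised by the sample's
genome-wide mean coverage (NCN, a unitless copy-state proxy). Presence–
absence variation between two genomes is called per window with strict
thresholds: retained in self when NCN > 0.8 while the other genome covers
it at NCN < 0.2; selected windows closer than 10 kb merge into one region
(a gap of exactly 10,000 bp does not merge — the "< 10 kb" rule is taken as
printed). Gene-level PAV applies the same thresholds to gene mean depth,
computed from overlapping windows weighted by overlap length.

The CNV-index per 100 kb window is the group difference of mean NCN,
`NCN_DO − NCN_DE`, positive where more DE accessions carry a deletion; it
is antisymmetric under group swap by construction. Per-sample genotyping of
a known deletion (the chr3D 55.5–56.3 Mb case) thresholds the
width-weighted regional NCN with the same 0.8/0.2 pair — the study states
no per-sample cutoff, so reusing the PAV thresholds is this package's
declared choice, and the intermediate band is reported as `unknown` rather
than forced to a binary call.

## TE-insertion genotyping from soft-clipped reads

A known 161 bp TE insertion (the *TaQ-5A* fifth-exon case at
chr5A:650129563) is genotyped per sample from reads covering the site, with
two strictly ordered rules: (1) at least two reads spanning the site with a
perfect reference match classify the sample `non_insertion`; (2) otherwise
any soft-clipped read whose clip abuts the site (within 2 bp) and matches
the TE sequence with 100% identity over strictly more than 10 bp (either TE
end, either strand) classifies it `insertion`; anything else is `unknown`.
"Perfect match" is evaluated over a site ± 5 bp window — the source
description does not define the spanning window, so ± 5 bp is a declared
choice; mismatches elsewhere in the read are tolerated. A sample satisfying
both rules follows rule 1 and is flagged as a conflict.

## Haplotype classification along the altitude gradient

Per-gene haplotypes are strings over the gene's SNPs: homozygous dosages
map to alleles, heterozygous and missing calls to `N` (wheat accessions are
near-homozygous inbred lines; a `het = "drop"` mode discards heterozygous
samples instead). Samples with more than 50% `N` and genes with fewer than
2 SNPs are dropped — the source says only "without enough sites or poorly
covered", so these defaults are declared here. When merging a resequencing
cohort with an exome panel, only sites polymorphic in both are kept.

A haplotype is high-altitude adapted (HA) when it carries the alternate
allele at a supplied missense site and is strictly more frequent in the HA
group than the LA group; equality (or absence from both) leaves it
unclassified — "more enriched" carries no quantitative margin in the
source, so strict inequality with tie-to-unclassified is the declared rule.
Missense annotation is an input site list; codon-level effect prediction is
out of scope.

## Mixed-model association

Rachis brittleness (binary, brittle = 1) is tested per variant in the
linear mixed model $y = W\alpha + x\beta + u + \varepsilon$, with $u \sim
N(0, \sigma_g^2 K)$, $W$ an intercept plus the first five genotype PCs, and
$K$ the VanRaden centred genomic relationship matrix $ZZ'/2\sum p(1-p)$.
Variance components are estimated once under the null by eigen-rotated REML
and reused for every marker — the P3D/EMMAX approximation, chosen because
the field's association tools default to it; exact per-marker REML is a
flag (`per_marker = TRUE`). With $K = I$ and no covariates the test reduces
exactly to the OLS F test, which the suite verifies to 1e-8. The binary
trait is analysed with the linear model, as those tools do, not logistic
regression.

Structural variants enter as pseudo-markers: presence `1/1`, absence
`0/0`, unknown `./.`, round-tripping losslessly through VCF. "Variance
explained" by a marker is the GLS partial R² on the decorrelated model,
$(RSS_{null} - RSS_{marker})/RSS_{null}$ — the study never defines its
variance-explained computation, so its printed percentages are not
reproduction targets for this estimator. The Bonferroni threshold is
$\alpha/m$ (0.01/35,045,206 = 2.85e-10 at study scale). For
chromosome-local stratification (the chr3B case), five PCs computed from
the target chromosome's sites are concatenated with five genome-wide PCs,
dropping collinear columns.

## Scaffold anchoring and pseudomolecules

Scaffolds are anchored to a reference by simulated probe reads: 500 bp
paired mates at a 1000 bp step. "Insert size 500 bp" is ambiguous between
fragment spacing and inner distance; the default reads it as two abutting
mates (total pair span 1000 bp), with `insert_mode = "inner"` for the
1500 bp reading. Reads map by unique exact match on either strand — at desk
scale this plays the role an aligner plays at genome scale. Each scaffold
goes to the chromosome attracting most of its reads; a best count below 22
reads (single reads, not pairs) reserves it for chrUn, ties break
lexicographically. Placement follows the first-five/last-five rule: the
first and last runs of ≥ 5 consecutive probe ordinals on the same
chromosome and strand with monotone positions (within 2 × step) give the
position key (mean of the two run means) and orientation; scaffolds without
such a run are demoted to chrUn. Pseudomolecules concatenate ordered,
oriented scaffolds with 300 bp N gaps, emitting a consistent AGP v2.1
table, so total placed length is exactly
$\sum L_i + 300\,(n_{placed} - n_{chromosomes})$. `assembly_stats()`
provides N50/N90/max/total and the gap fraction.

Effective population size is recovered from scaled diversity via
$\theta = 4 N_e \mu L$ with $\mu = 6.5 \times 10^{-9}$ per site per
generation and generation time $L = 1$ year for this annual crop.

## The synthetic-data generator

`simulate_cohort()` draws inbred-style genotypes: per site a baseline
alt-allele frequency from a Beta(0.8, 0.8) prior, shifted by ∓δ/2 between
the first two groups inside configured divergent windows (the baseline is
clamped to `[δ/2, 1 − δ/2]`, so δ = 1 yields fixed differences and any δ
keeps frequencies in [0, 1]). Genotypes are homozygous draws except with
probability `het_rate` (default 2% — wheat is selfing and the accessions
are treated as near-homozygous), when a Hardy–Weinberg draw is used;
missingness is 2% by default. Group sizes default to DE = 50 / DO = 52, the
de-domestication design. Phenotypes follow structural-variant carrier
status when deletions/TE truth are configured (with an optional
misclassification rate), else the first group is labelled brittle.

Depth tracks draw the per-window read count as Poisson with mean
`mean_cov × copy × width / read_len` and report `count × read_len / width`:
a Poisson-per-window count model whose read-level granularity gives
per-window mean depth the few-percent relative noise real 10× data shows
over 5 kb windows. The study does not report per-sample coverage variance,
so Poisson is a stand-in, not an inference. TE evidence is noise-free by
construction: carrier junction reads clip exactly into the TE sequence,
non-carriers match the local reference. Scaffold worlds cut scaffolds from
random reference chromosomes, reverse-complementing about half, plus
random-sequence and too-short unplaceable scaffolds.

What the generator does **not** emulate: linkage disequilibrium (sites are
independent draws, so LD pruning is exercised only by planted duplicate
columns), sequencing error in reads, GC-dependent coverage bias, mapping
ambiguity in repeats, and real wheat sequence. Passing tests therefore
demonstrate correctness of the statistics and decision rules under the
stated models, not robustness to alignment artefacts in real data.

## Numerical choices and degenerate inputs

* FST components are undefined (NA) when a site has fewer than one called
  genotype per group or mean sample size ≤ 1; monomorphic sites return
  (0, 0, 0) and are skipped.
* Pruning r² uses pairwise-complete dosages; pairs with zero variance are
  ignored. Greedy left-to-right within a 50-kept-site trailing window keeps
  the earlier site, so output is order-stable.
* PCA signs are fixed by forcing the largest-magnitude loading positive;
  missing dosages are imputed to the site mean before standardisation.
* The kinship eigendecomposition clips slightly negative eigenvalues to
  zero and notes when stabilisation occurred; REML optimises the variance
  ratio on log scale over e^[−12, 12].
* `candidate_regions()` warns on partitions that are entirely missing;
  `normalize_depth()` drops zero-coverage samples with a warning;
  empty-filter results warn rather than error.
* Chromosome-assignment ties break lexicographically and are logged, as the
  source is silent on ties.

## Problem sizes used by the test-suite and the acceptance script

The shipped checks run desk-scale versions of the study design chosen once
as realistic miniatures: scan power and null calibration use 2 × 50
samples, 5,000 sites on a 1 Mb chromosome (10 windows of 100 kb), δ = 0.8,
with 100 permutations per replicate; PAV/CNV recovery uses a 1 Mb
chromosome on the 5 kb grid with three planted deletions at 10× coverage;
the regional-deletion cohort plants 50 carriers among 102 samples; the TE
cohort genotypes 20 samples at 6 reads each; association checks use 50–100
samples and 130–200 markers; anchoring uses a 20-scaffold, 3-chromosome
world. The study's own headline numbers (genome-wide π values, permutation
maxima, PAV megabase totals, variance-explained percentages) derive from
hundreds of resequenced wheat genomes and are not reproducible from
synthetic miniatures; the acceptance script instead reports the quantities
above plus the analytic values that follow directly from printed inputs
(Ne, the Bonferroni cutoff, the assembly gap fraction, the π ratio).

## Known limitations

* Two-population FST only; multi-population estimators and haplotype-based
  statistics (XP-EHH and relatives) are out of scope.
* The unique-exact-substring probe mapper has no mismatch tolerance; real
  scaffold anchoring at genome scale needs an aligner.
* The MLM is linear; case/control imbalance is handled no better than the
  field's standard tools handle it.
* `window_of` mapping assumes a tiling grid (step = size); overlapping
  grids assign each site to one window.
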