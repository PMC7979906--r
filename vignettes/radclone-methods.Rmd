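---
title: "Methods: structure, clonality and F-statistics for RAD-Seq SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure, clonality and F-statistics for RAD-Seq SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radclone)
```

radclone is a post-genotyping toolkit for reduced-representation (RAD-Seq)
SNP panels from collections of perennial plants in which some accessions are
propagated sexually and some asexually (typically by grafting). This
vignette explains the statistical machinery, the defaults, and the choices
made where the methods literature leaves room.

## The data model

All analyses operate on a `genotype_matrix`: individuals by biallelic SNP
sites, each call coded as the count of alternate alleles (0, 1, 2) with `NA`
for missing. Genotypes are unpolarised — no ancestral allele is inferred —
so every statistic below is invariant to swapping REF/ALT at a site. Sites
carry a `locus_id` grouping SNPs that come from the same RAD locus; de novo
genotypers emit each locus as its own "chromosome", which the VCF reader
uses as the default grouping.

## Site filters

Three filters, applied in a fixed order so that the removal counts in the
filter report are reproducible:

1. **Call rate** (default ≥ 0.5): sites typed in fewer than half the
   individuals are dropped. This mirrors the usual requirement that a RAD
   locus be assembled in at least half of the panel.
2. **One SNP per locus** (default on): only the lowest-position SNP of each
   RAD locus is kept (ties broken by input order). This thins the strong
   intra-locus linkage of RAD data; downstream jackknife blocks then
   correlate mainly through genuine genealogy.
3. **Minor allele frequency** (default ≥ 0.05, boundary inclusive): MAF is
   computed over non-missing calls. We read the threshold as a frequency,
   matching the semantics of the `populations --min-maf` flag family, and
   document the inclusive boundary so a singleton heterozygote among ten
   individuals (MAF exactly 0.05) is retained.

The order call-rate → dedup → MAF is a documented convention: the upstream
toolchains do not promise an order, and the counts (not the final site set)
are all that depends on it when thresholds are fixed.

## Identity-by-state, UPGMA and PCA

The IBS similarity of two individuals is the mean over jointly called sites
of $1 - |g_i - g_j|/2$; the distance is one minus that. Missing data are
handled per pair by complete cases — a deliberate asymmetry with the PCA
below, because a pairwise distance needs no imputation model and RAD
missingness is site-sparse. A pair with no jointly called site raises an
error naming the pair rather than producing `NaN`.

Hierarchical clustering uses average linkage (UPGMA) via `stats::hclust`.
The upstream toolchain does not name its linkage; average linkage is the
default behaviour of the IBS dendrogram tools this package follows, and the
implementation is property-tested against a brute-force $O(N^3)$
agglomeration oracle. Trees export to Newick through ape.

Genotype PCA centres each site by twice its sample allele frequency and, by
default, scales by $\sqrt{p(1-p)}$ (Patterson scaling — the variance of one
allele draw), with missing calls mean-imputed, i.e. zero after centring.
Mean imputation is the standard genotype-PCA choice: it shrinks scores of
poorly typed samples toward the origin instead of inventing structure.
Monomorphic sites have no defined scaling and are dropped with one summary
warning. Scores are eigenvectors of the sample covariance scaled by the
square root of their eigenvalues; the contribution ratio of an axis is its
eigenvalue over the sum of positive eigenvalues. An unscaled option
(`scaling = "none"`) exists for sensitivity checks. Group assignment from PC
plots is intentionally not automated; the pipeline reports scores,
contribution ratios, and a dendrogram cut instead.

## The conserved-heterozygosity clonality statistic

Meiosis resegregates heterozygous sites, grafting does not. For a pair of
individuals restricted to jointly called sites (`pairwise_shared_sites`,
the per-pair call-rate-1 view), define

$$\mathrm{CH} = \frac{\#\{\text{sites het in both}\}}
                    {\#\{\text{sites het in at least one}\}}.$$

**Denominator choice.** Published descriptions of this statistic state only
"X of Y sites were conserved heterozygous sites". We take Y to be the
jointly called sites where at least one of the pair is heterozygous: that
makes "conserved" literal (a heterozygote preserved in the partner) and
bounds the fraction at 1. The alternative reading — all jointly called
sites variant within the pair — is available behind
`denominator = "pair_variant"` for sensitivity analysis; it can only lower
the fraction.

**Threshold.** A pair is called clonal when CH ≥ 0.485, boundary inclusive.
The anchor is the lowest conservation observed between plants documented to
come from one graft source (48.5%) rather than the rounded "about 50%";
known graft pairs sit at roughly 48–63% while sexual relatives in the same
populations fall near 30–37%, so any threshold in the gap classifies the
documented material identically. The threshold is a parameter everywhere it
is used.

**Grouping.** `clonal_clusters` places an edge between every clonal pair
and returns connected components: clones of one founder need not all be
pairwise above threshold for the lineage to assemble; transitivity is the
minimal closure that treats a graft lineage as one group. Pairs with a zero
denominator contribute no edge and raise one summary warning.

Fractions are reported both raw and as percentages rounded half-up to one
decimal (`round_half_up`), the convention used when such percentages are
printed.

## Population statistics

**Heterozygosity and Fis.** Per population and site, observed
heterozygosity $H_o$ is the heterozygote fraction among called individuals
and expected heterozygosity uses the small-sample form
$H_e = 2p(1-p)\cdot 2n/(2n-1)$. $F_{IS} = 1 - \bar H_o / \bar H_e$ over
sites polymorphic in that population — a ratio of means, not a mean of
ratios, so low-information sites cannot dominate. Strongly negative values
flag heterozygote excess, the signature of a clonal lineage: every clone
replays the founder's heterozygosity while the allele frequencies sit near
0.5. Which precise estimator upstream AMOVA-based tools print is not
specified anywhere we could verify, so the ratio-of-means form is our
documented convention.

**Fst.** Pairwise Fst is Weir–Cockerham (1984) $\theta$: per-site variance
components $a$ (among populations), $b$ (among individuals), $c$ (within
individuals), combined genome-wide as $\sum a / \sum (a+b+c)$. Sites enter
a pair's estimate when both populations have at least one called individual
(complete case per pair). Slightly negative estimates are reported as-is —
they are information about sampling noise, not errors, and clamping is left
to the caller. Note an important difference from AMOVA-based RAD pipelines:
no p-value-driven zeroing of per-locus Fst is applied, because that
correction is tool-internal and unspecified; on real data our values will
therefore differ from such pipelines even at identical genotypes.

**f3/f4.** Patterson's definitions: $f_3(A;B,C)$ is the mean over sites of
$(a-b)(a-c)$ and is negative when A's frequencies sit systematically
between B's and C's (admixture); $f_4(A,B;C,D)$ is the mean of
$(a-b)(c-d)$. Because sampled frequencies are noisy, $f_3$ subtracts the
unbiased estimate of the target's sampling variance,
$\hat a(1-\hat a)/(n_A - 1)$ with $n_A$ the called chromosome count — this
matters here because analysis populations can be as small as three plants.
The correction vanishes when a bare frequency table (infinite n) is given.
Standard errors come from a delete-one-block jackknife over consecutive
runs of SNPs in matrix order (default 500 SNPs per block; no genetic map
exists for this kind of de novo panel, so physical ordering is the only
available blocking). The trailing partial block is kept and weighted by its
size (the weighted jackknife of Busing et al. 1999); at block size 1 the
formula reduces exactly to the ordinary delete-one jackknife, which is how
it is tested.

## The synthetic-data generator

There is no public genotype-level truth set for a partly clonal orchard
collection, so the package carries a generator whose defaults *are* the
study conditions of its test-suite:

* **Divergence:** the Balding–Nichols model. Ancestral minor allele
  frequencies are uniform on (0.05, 0.5] with random polarity; population
  $k$'s frequency is $\mathrm{Beta}(p(1-F_k)/F_k,\ (1-p)(1-F_k)/F_k)$.
  The default preset uses eight populations (labelled A1, A2, B–F, H, the
  conventional group letters) with $F$ between 0.08 and 0.25, chosen so
  pairwise Fst spans the few-percent to ~0.3 scale reported for diverged
  local crop lineages — the order of magnitude is the target, not any
  specific published value.
* **Individuals:** 90 in the default preset; genotypes are
  $\mathrm{Binomial}(2, \sum_k q_k p_{kl})$ with $q$ the ancestry vector
  (a point mass for unadmixed individuals).
* **Clonality:** population A2 is a graft lineage — one founder and nine
  clonal copies — plus five independent clone pairs seeded into other
  populations, echoing the typical mix of one spread lineage and scattered
  local graftings. A clone copies its source and is then perturbed:
  heterozygous calls collapse to a random homozygote with dropout
  probability $d$ (allelic dropout is modelled het→hom only, the
  directional artifact of reduced-representation data), then any call is
  replaced by one of the other two codes with error probability $e$, then
  missingness applies. Defaults $e = 0.01$, $d = 0.10$, missingness 0.1:
  no published genotyping-error estimate exists for de novo RAD calls in
  this setting, so these are free parameters set once to place simulated
  clone pairs in the empirically reported conservation range (roughly
  50–70%) while leaving sexual pairs far below threshold.
* **Loci:** sites are assigned synthetic locus ids in pairs so the
  one-SNP-per-locus filter is genuinely exercised.

Determinism is part of the contract: identical configs (including the
mandatory seed) produce bit-identical datasets.

What the generator does **not** emulate: linkage disequilibrium (sites are
independent given frequencies), locus dropout correlated with divergence
(missingness is uniform), per-pair de novo locus assembly (one fixed matrix
is simulated and pairs are restricted to co-called sites), sequencing-level
error structure, and selection or spatial models. Passing tests therefore
demonstrate correctness of the estimators under a clean structured model,
not robustness to every artifact of real RAD data. In particular, real
per-pair de novo assemblies recompute the shared-site denominator per pair;
with one fixed matrix the denominators (and slightly the fractions) will
differ from a per-pair pipeline run on the same material.

## Numerical and degenerate-input choices

* Filters on an empty matrix, or removing every site, raise explicit
  errors — never a silent empty result.
* IBS with a zero-overlap pair and conserved-heterozygosity with a zero
  denominator are errors (the latter still reports counts, just no verdict).
* Monomorphic sites are excluded from PCA (undefined scaling) with a
  warning; Fis is `NA` for a population with no polymorphic site; an Fst
  pair with no usable site is `NA`.
* f3/f4 with fewer than two jackknife blocks return the estimate with `NA`
  standard error.
* All tie-breaks are deterministic: first SNP per locus by position then
  input order; clonal groups sorted by first member id; merges at equal
  heights follow `hclust`'s ordering.

## Problem sizes used by the test-suite

The suite runs the default 90 × 4,000 preset for clonality, structure and
Fis checks; 150 × 5,000 for Fst recovery against a 50,000-site Monte-Carlo
expectation of the infinite-sample variance-component ratio; 120 × 5,000
(30 admixed) for f3; and hand-sized fixtures (≤ 10 × ≤ 120) wherever a
brute-force enumeration oracle is the comparator. These sizes were chosen
as the smallest at which the Monte-Carlo tolerances (±0.02 on Fst, |Z| > 3
on f3) are comfortably stable, and they keep the whole suite to seconds.

## Known limitations

* Weir–Cockerham θ, not the AMOVA estimator with p-value correction some
  RAD pipelines print; values on real data will differ.
* No haplotype-based F statistics (phase is unavailable in this data
  class), no kinship/IBD coefficients, no admixture-model fitting, no tree
  or graph inference — only the f3/f4 statistics themselves.
* The clonality statistic does not distinguish grafting from other asexual
  propagation modes; it detects genotype identity up to dropout and error.
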