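---
title: "Region-based rare-variant association testing in family and case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based rare-variant association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvscan)
```

## The problem

Single-variant association tests have essentially no power for variants
with alternate allele frequency (AF) below 1%: the expected carrier count
in any realistic cohort is too small. The standard remedy is to test
*regions* of rare variants jointly. `rvscan` implements a complete
region-based rare-variant analysis for the two cohort designs that
typically make up a discovery/replication pair in late-onset disease
genetics:

* a **family discovery cohort** of multiplex sibships (several siblings,
  at least two affected, parents usually not genotyped), tested with
  burden and variance-component statistics under a within-family
  conditional null that is immune to population stratification; and
* an **unrelated case-control replication cohort**, tested with
  covariate-adjusted score tests (burden, SKAT, SKAT-O) and protected
  against stratification by rare-variant principal components built from
  the Jaccard similarity index.

Evidence from the two stages is combined per region with Fisher's
combined probability test.

## Testing units: windows of ten variants

After quality control, variants are sorted by chromosome and position and
partitioned per chromosome into non-overlapping consecutive sets of ten
(`build_windows()`, `k = 10`). The final partial window of each
chromosome is retained and tested. Windows are defined on variant *order*
rather than base-pair spans; the genomic coordinates of the first and
last variant are reported as metadata. Ten is a deliberate ceiling: the
family-based null is enumerated or simulated over within-family genotype
configurations, and the cost of representing the joint distribution of a
region grows quickly with its variant count.

## The family-based region tests

For sibling $i$ in family $f$ with affection status $y_{fi} \in \{0,1\}$,
the phenotype enters as the residual $t_{fi} = y_{fi} - \mu$, where the
offset $\mu$ is the assumed population prevalence (default `offset =
0.15`, appropriate for late-onset dementia in elderly sibships;
configurable). Subtracting the prevalence lets unaffected siblings
contribute information with the opposite sign instead of being discarded.

With window dosages $g_{fiv} \in \{0,1,2\}$ and non-negative weights
$w_v$ (flat by default), the two statistics are FBAT-style score sums:

* **burden**: $B = \sum_f B_f$, $B_f = \sum_i t_{fi} \sum_v w_v g_{fiv}$ —
  powerful when causal effects share a direction;
* **variance component (SKAT-style)**:
  $Q = \sum_v w_v^2 \big(\sum_f S_{fv}\big)^2$ with
  $S_{fv} = \sum_i t_{fi} (g_{fiv} - \bar g_{fv})$ and $\bar g_{fv}$ the
  within-family mean dosage — powerful under mixed effect directions or
  sparse signals.

### The conditional null

Conditional on the parents, the multi-locus genotype vectors of siblings
are independent and identically distributed, hence *exchangeable*. The
null distribution is therefore obtained by permuting the sibling genotype
**rows** within each family, independently across families, with
phenotypes held fixed. This conditions on the observed multiset of
genotype vectors per family and preserves all linkage disequilibrium
between the variants of a window exactly — nothing about the correlation
structure of rare variants needs to be estimated. Parental genotypes,
when present, are not used by the null; this is a valid (conservative)
choice for the sibship designs the package targets. Families with a
single usable sibling, constant residuals, or identical genotype rows are
non-informative: their contribution is permutation-invariant and they are
held fixed.

If the total number of permutation configurations
$\prod_f s_f!$ is at most `exact_cap` (default $10^5$), the null is
enumerated exhaustively and p-values are exact. Otherwise Monte Carlo is
used with the add-one estimator $\hat p = (1 + \#\text{extreme})/(1 +
n_\text{sims})$, which cannot return zero. Both tests consume the *same*
permutation stream; a useful consequence is that for a single-variant
window the SKAT p-value equals the two-sided burden p-value exactly. The
burden test is two-sided by default, measured as deviation from the exact
permutation mean (computable in closed form from the family-centered
scores); the variance-component test is one-sided upper.

Each window's stream is seeded from `(seed, window index)`, so scan
results are independent of evaluation order and reproducible.

### Sequential simulation budgeting

A genome scan wastes most of a fixed simulation budget on unremarkable
windows. `region_test_config(min_exceed = h)` enables a sequential
stopping rule in the style of Besag–Clifford: the stream stops once both
tests have accumulated `h` exceedances (the p-value is then resolved far
above any interesting threshold), while extreme windows run to the full
`n_sims`. The default (`min_exceed = Inf`) is the fixed-budget estimator,
which is what all calibration and uniformity tests use. With rare
variants the burden statistic lives on a coarse lattice, so its p-values
are discrete and mildly conservative; the quadratic statistic is much
smoother, and the p-value uniformity check in the test suite is therefore
asserted on the variance-component test, with both tests held to the
binomial calibration bound.

## The case-control tests

The replication stage is a standard logistic score-test framework,
re-implemented from its published form. A null model
$\text{logit}\,P(y=1) = X\beta$ (intercept, sequencing center dummies,
age, sex, and optionally top PCs) is fit by IRLS to tolerance $10^{-8}$.
With $\hat\mu$ the fitted means, $V = \text{diag}(\hat\mu(1-\hat\mu))$
and $P_0 = V - VX(X'VX)^{-1}X'V$:

* **burden**: collapse $c_i = \sum_v w_v g_{iv}$; $U = c'(y - \hat\mu)$,
  $\text{Var}(U) = c' P_0 c$, $U^2/\text{Var}(U) \sim \chi^2_1$;
* **SKAT**: $Q = \|Z'(y-\hat\mu)\|^2$ with $Z = GW$; the null is the
  mixture $\sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the eigenvalues of
  $W G' P_0 G W$. Tail probabilities use Liu-type moment matching by
  default; `method = "integration"` switches to characteristic-function
  inversion (Imhof-type quadrature) when higher tail accuracy is wanted;
* **SKAT-O**: $Q_\rho = (1-\rho) Q_\text{SKAT} + \rho\, Q_\text{burden}$
  over the grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$;
  the minimum per-$\rho$ p-value is combined by the one-dimensional
  integral of the optimal-test construction (relative tolerance
  $10^{-6}$), and the result is clamped into
  $[\min_\rho p_\rho,\; 8 \min_\rho p_\rho]$. If the integration fails
  the Bonferroni upper bound is returned with a flag.

The published small-sample moment adjustment for $n < 2000$ is *not*
implemented; `fit_null()` warns when $n < 2000$ so users know the tail
approximation is the large-sample one. At the cohort sizes the package
targets the binomial calibration checks in the test suite pass without
it.

Replication replays each discovery window on the replication cohort using
only the window's variants that are present and pass QC there (absent
variants are dropped, not imputed), so the number of variants actually
used is reported per window.

## Quality control

`filter_variants()` applies a fixed cascade and reports per-stage
attrition: (1) multiallelic records, (2) monomorphic sites, (3) indels,
(4) singletons — total ALT count one *or* all ALT alleles confined to a
single family, (5) any half-called genotype (one missing allele, e.g.
`./1`), (6) Mendel errors (any error removes the variant), (7) call rate
below 95%, (8) Hardy–Weinberg exact p below $10^{-8}$, (9) external
reference AF above 1%, (10) an optional allow-list. Two readings were
genuinely open and are flags:

* the AF clause keeps a variant if **either** reference column
  (`AF_all`, `AF_nfe`) is at or below 1% (disjunctive reading;
  `af_mode = "both"` switches to conjunctive);
* variants absent from the AF reference are removed (the conservative
  choice for a local stand-in of an external database).

The HWE exact test is the conditional test given allele counts, summing
the probabilities of all heterozygote counts no more probable than the
observed one. Because sibships violate the random-sampling assumption of
HWE, the test uses founders, samples outside the pedigree, and one
sibling per family whose parents are not genotyped.

Sample-level QC flags call rate, the inbreeding coefficient
$F = 1 - \text{het}_\text{obs}/\text{het}_\text{exp}$ outside
$[-0.15, 0.15]$, and pedigree-inconsistent relatedness from
method-of-moments IBD estimates ($\widehat{PI} = P_1/2 + P_2$ from
identity-by-state counts): declared siblings below 0.2, declared-unrelated
pairs above 0.9. These thresholds are package defaults, not published
values.

## Rare-variant population structure

Common-variant PCA recovers old ancestry; rare variants carry more recent
structure. The package LD-prunes dosages (greedy windowed pruning, remove
the later variant of the worst pair while any pair exceeds
$r^2 = 0.01$; window 50, step 5), randomly subsamples `m` variants
(100,000 on real WGS data; scaled down in synthetic runs), forms the
Jaccard similarity of carrier sets
$J_{ij} = |C_i \cap C_j| / |C_i \cup C_j|$, double-centers it
(PCoA-style; the uncentered variant is a flag, since either convention is
defensible), and takes the top eigenvectors scaled by the square root of
their eigenvalues. Signs follow the largest-magnitude loading. $r^2$ is
computed on dosages rather than carrier indicators to match conventional
pruning practice.

## Meta-analysis and reporting

Fisher's combined probability test per region:
$X^2 = -2\sum_k \ln p_k \sim \chi^2_{2k}$. The report keeps windows whose
discovery burden or SKAT p-value is at or below the suggestive screening
threshold $5\times10^{-6}$, attaches each replication cohort's p-value
(burden rows pair with the replication burden test, variance-component
rows with SKAT-O), combines discovery with the cohorts configured as
ethnically comparable, and flags regions whose combined p-value passes
the genome-wide Bonferroni threshold ($0.05 / \#\text{windows}$; with the
801,124 windows of a whole-genome sibship scan this is
$6.24\times10^{-8}$).

## The synthetic-cohort generator

`simdata` exists so that every stage of the pipeline runs, and can be
calibrated, with no external data. It emulates exactly the statistical
structure the tests rely on:

* rare variants with true AF uniform in $[1/(2\cdot10^4),\, 0.01]$,
  independent across sites within a subpopulation;
* sibship families: two founder parents per family, fair Mendelian
  transmission of whole parental haplotypes with **no recombination**
  within a chromosome's simulated span — windows are kilobase-scale, so
  preserving within-window LD matters and recombination inside a window
  does not; parents are masked by default (a flag keeps them for
  Mendel-error tests);
* disease via a logistic liability model with prevalence 0.15; the
  intercept is solved by root finding on a simulated population to
  tolerance $10^{-3}$; ascertainment (at least two affected siblings) by
  rejection sampling with a $10^5$-attempt cap per family;
* causal windows with per-allele log-odds `beta`, either all-positive
  (`unidirectional`) or alternating-sign (`mixed`);
* an unrelated case-control cohort from the same panel with center, age
  (controls 60 or older), sex, and optional covariate or subpopulation
  effects on risk;
* optional two-subpopulation structure: a configurable fraction of
  variants is private to one subpopulation.

A fixed seed makes every output file byte-identical. What the generator
deliberately does **not** emulate: realistic human LD maps and
recombination, genotyping error, sequencing depth, and site-frequency
spectra from demographic history. Passing calibration tests on these
cohorts therefore demonstrates the correctness and calibration of the
*statistics* under the stated model, not performance on real WGS data.

## Numerical choices

* Tie handling in permutation tests: exceedance comparisons use a
  relative tolerance of $10^{-9}$ and count ties as extreme
  (conservative).
* The exact permutation mean of the burden statistic is computed in
  closed form, not estimated, so the single-variant burden/SKAT identity
  holds exactly in both engines.
* Eigenvalues below $10^{-10}$ of the leading one are treated as zero.
* Monte-Carlo p-values are bounded below by $1/(n_\text{sims}+1)$;
  degenerate windows (no informative family, zero score variance, no
  polymorphic variant) return $p = 1$ with a flag rather than an error.
* Missing dosages are imputed to the within-family mean (family tests)
  or the column mean (case-control tests) — QC removes most missingness
  before testing.
* Logistic null fits reject rank-deficient designs and (quasi-)perfect
  separation, naming the offending covariate.

## Problem sizes in the test suite

The test suite exercises every claim at sizes chosen to make sampling
error small relative to the assertion while keeping a full run on one
CPU comfortable: family-test null calibration pools 500 windows from
four independent cohorts of 150 families each (sibships of 3–5; windows
within one cohort share its families, so pooling cohorts is what makes
the binomial sampling model for the rejection count hold), and the
case-control engine is calibrated on a 1,000-sample cohort over 2,000
windows; power-ordering comparisons use 200 seeded replicates per effect
configuration; subpopulation-recovery uses 50,000 rare variants per
cohort over 100 seeds; and the end-to-end planted-window run uses 400
ascertained families plus a 1,000/1,000 case-control cohort over 100
seeds with a $2\times10^5$-simulation budget on the causal window. The
same generator settings are used by `scripts/acceptance.R`.

## Known limitations

* The family engine covers sibships (the design it targets); it is not
  the general sufficient-statistic machinery for arbitrary pedigrees,
  and X-chromosome and haploid genotypes are out of scope.
* The burden statistic's lattice discreteness under rare variants makes
  its permutation p-values mildly conservative at small configuration
  counts.
* The SKAT small-sample adjustment is omitted (see above).
* Fisher's method assumes independent stages; it is the user's
  responsibility that discovery and replication cohorts do not share
  samples.
* BCF input, multiallelic decomposition, and gene-based (as opposed to
  positional) grouping are not implemented.
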