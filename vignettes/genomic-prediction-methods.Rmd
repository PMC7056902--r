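---
title: "Methods: marker preselection and GBLUP in small populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker preselection and GBLUP in small populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsel)
```

## The problem

In small resource populations — a few hundred phenotyped birds from an F2
cross, say — the number of genotyped markers (tens of thousands to
hundreds of thousands) vastly exceeds the number of records. Genomic
prediction with GBLUP is robust in this regime, but most markers carry no
information about any given trait, and a large mass of uninformative
markers dilutes the genomic relationship matrix that GBLUP relies on.
`gpsel` implements the full pipeline for asking, on such data, whether
trait-specific marker preselection improves prediction: containers and
quality control for dosage data, phenotype correction, two preselection
screens, exact REML/GBLUP, and a leave-one-out evaluation design that
keeps the screening step honest.

## Phenotype correction

Raw records are adjusted once, before any genomic analysis, by ordinary
least squares on sex (2 levels) and batch (6 levels by default):

$$y_c = y - \widehat{\text{sex effect}} - \widehat{\text{batch effect}}.$$

We use sum-to-zero contrasts so that "effects" are well-defined
deviations from the overall mean and the intercept stays in $y_c$; in a
balanced design the mean of $y_c$ equals the mean of $y$. Correcting once
on the full data — rather than re-estimating inside each cross-validation
fold — is deliberate: the nuisance effects are estimated far more
precisely from all records, and they are not the quantity under
evaluation. Rank-deficient designs (confounded sex/batch) are an error,
reported with the aliased columns named.

## Marker preselection

Two screens operate on a *reference subset* of individuals — in
cross-validation, always the n − 1 training individuals of the fold:

**Homozygote contrast (PMS).** For marker $j$,
$d_j = |\bar{y}_c(\text{dosage } 0) - \bar{y}_c(\text{dosage } 2)|$, the
absolute difference between mean corrected phenotypes of the two
homozygote classes. Heterozygotes and missing genotypes contribute
nothing. Markers missing either homozygote class are *ineligible* and can
never be selected. Scores are normalized by the maximum over eligible
markers, $d'_j = d_j / \max_k d_k \in [0, 1]$, and markers with
$d' > c$ are kept. The default cutoff $c = 0.05$ is the value at which
prediction accuracy peaked in the study this pipeline reproduces; the
cutoff is dimensionless because $d'$ is.

**Single-marker GWAS.** OLS of $y_c$ on dosage with intercept,
$y_c = \mu + xq + \varepsilon$; the two-sided p-value uses a $t$
reference with $n_\text{used} - 2$ degrees of freedom, where
$n_\text{used}$ counts the individuals with a non-missing genotype at
that marker. Markers with $p < \alpha$ (default 0.01) are kept. No
multiple-testing correction is applied: the threshold is a screening
knob, not an inference claim.

Both cutoffs are *strict* inequalities ($d' > c$, $p < \alpha$), so
selection counts are exactly reproducible; both selections are monotone
(nested) in their cutoff. The $d'$ normalization is recomputed within
every cross-validation fold, because $\max d$ depends on the reference
subset. A design question with no stated answer in the source material is
whether the maximum should be taken before or after removing ineligible
markers; we take it after (ineligible markers have no $d$), which is the
only choice under which $d'$ is defined purely on selectable markers.

## GBLUP and REML

The prediction model is $y_c = 1\mu + Zg + e$ with
$g \sim N(0, G\sigma_g^2)$, $e \sim N(0, I\sigma_e^2)$ and VanRaden's
relationship matrix

$$G = \frac{MM'}{\sum_i 2p_i(1-p_i)},$$

where column $i$ of $M$ holds dosages centered by $2p_i$ and $p_i$ is the
observed second-allele frequency. Missing genotypes become 0 after
centering — the expected score — which slightly shrinks relationships
involving poorly genotyped individuals but keeps $G$ well defined without
imputation. Monomorphic markers are dropped (they contribute nothing to
the denominator).

Allele frequencies are computed once, over **all** genotyped individuals,
and are *not* recomputed per cross-validation fold; only the marker
subset changes between folds. Genotypes of validation individuals are
legitimately available at prediction time (it is their phenotypes that
are withheld), and a single frequency vector keeps per-fold matrices
comparable.

REML exploits the single-random-effect structure: with
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$, the covariance
$\sigma_p^2\,[h^2 G + (1-h^2)I]$ is diagonal in the eigenbasis of $G$, so
the restricted likelihood profiled over $\sigma_p^2$ is a smooth
one-dimensional function of $h^2$. We maximize it with Brent's method on
$[10^{-6}, 1-10^{-6}]$ (tolerance $10^{-8}$), probe both box ends, and
flag boundary optima rather than erroring. This is exact — no EM or AI
iteration — and one fit costs a single $n \times n$ eigendecomposition,
which is what makes re-estimating variance components inside each of
hundreds of leave-one-out folds affordable. The standard error of
$\hat h^2$ is taken from the numerical curvature of the profiled
restricted log-likelihood at the optimum; other software may report SEs
from different approximations, so ours are comparable in spirit, not
necessarily in value.

Predictions use the GLS intercept
$\hat\mu = (1'V^{-1}1)^{-1}1'V^{-1}y_t$ with
$V = G_{tt}\sigma_g^2 + I\sigma_e^2$ over training individuals $t$, and

$$\hat g = \sigma_g^2\, G_{\cdot,t}\, V^{-1} (y_t - 1\hat\mu),$$

so every individual in $G$ — phenotyped or not — receives a GEBV. The
solve uses a Cholesky factorization; if $V$ is numerically singular a
diagonal jitter of $10^{-6} \times \overline{\mathrm{diag}(V)}$ is added
once, with a message. GBLUP fitted this way is algebraically identical to
ridge-regression SNP-BLUP with shrinkage
$\lambda = \sigma_e^2 \sum 2p_i(1-p_i) / \sigma_g^2$ on the same centered
markers; the test suite verifies this equivalence to $10^{-6}$ on random
instances, and verifies the REML optimum against a brute-force
restricted-likelihood grid (step $10^{-4}$).

## Leave-one-out evaluation

With only a few hundred individuals, k-fold partitioning noise is a real
nuisance; leave-one-out removes it. For each individual $k$:

1. markers are preselected using only the other n − 1 individuals —
   the left-out bird must not influence the screen that will be used to
   predict it, otherwise selection leaks phenotype information;
2. $G$ is rebuilt on the selected markers (all individuals, fixed
   frequencies);
3. variance components are re-estimated on the n − 1 training
   phenotypes (a `refit_per_fold = FALSE` switch reuses the full-data
   fit for speed; it is off by default because the per-fold marker set
   changes the scale of $G$);
4. $\hat g_k$ is predicted with $y_{c,k}$ withheld.

Accuracy is the *pooled* Pearson correlation between the n out-of-fold
GEBVs and $y_c$ — with one prediction per fold there is no per-fold
correlation to average. Unbiasedness is the OLS slope of $y_c$ on GEBV
(1 = unbiased, < 1 = over-dispersed predictions). Reported "±" values are
bootstrap standard errors over individuals (1,000 resamples, seeded).

Two scenarios are compared with a bootstrapped paired t-test: individuals
are resampled with replacement; both scenario accuracies are recomputed
on each resample (identical index sets, hence paired); and a paired
t-test is applied to the resampled accuracy differences. The cited
bootstrap literature permits variants of this construction; the one
implemented is stated here and fixed by the recorded seed, so results are
bit-reproducible. Degenerate comparisons (all resample differences zero)
return $t = 0$, $p = 1$ by convention.

## The simulator

`simulate_cross()` emulates the data structure of a small broiler F2
resource population: 20 founders (6 males of one line, 14 females of
another), F1 intermediates, 8 paternal half-sib F2 families totalling 395
birds, 28 autosomes of 1 Morgan, Haldane (no-interference) recombination
over uniformly placed markers, sex plus 6 rearing batches as fixed
effects, and a body-weight-like trait scale (mean 2034, SD 360 in trait
units). Founder-line divergence is modelled by drawing each line's allele
frequency from a Beta distribution around a common base frequency
(uniform on [0.05, 0.5]); the Beta precision (`line_divergence`, default
5) is exposed, not calibrated, because the real lines' divergence is
unknown. Defaults chosen where the emulated study is silent: 4 F1 dams
per sire (half-sib families need several dams; litter-type pedigrees are
not avian), sex effect 0.3 trait SD (male broilers are substantially
heavier; the exact dimorphism is trait-dependent), batch deviations
evenly spaced across 0.4 trait SD.

Phenotypes are additive: a random subset of markers becomes QTLs with
normal effects; the true breeding value is rescaled so its sample
variance is exactly $h^2_\text{target} \times \text{SD}^2$, and the
residual variance is $(1 - h^2_\text{target}) \times \text{SD}^2$, so the
realized variance ratio equals the target. Two edge cases are defined
explicitly: at $h^2 = 1$ the phenotype minus fixed effects *is* the TBV;
at $h^2 = 0$ an exact zero ratio with a nonzero TBV is impossible, so the
drawn TBV is kept in the truth output but contributes nothing to the
phenotype (its correlation with the phenotype is then zero in
expectation). Missingness is uniform at random per entry (the emulated
platforms differ mainly in their overall missing rate, roughly 5% for
sequencing vs 0.5% for the chip); per-marker heterogeneity in call rate
is *not* modelled.

What passing tests on these simulations do and do not show: they
demonstrate that the estimators recover known truth under an additive,
linkage-equilibrium-founder, uniform-missingness world. Real data add
genotyping error correlated with coverage, non-additive architecture,
selection in the founder lines, and a sex chromosome — chrZ is
deliberately excluded (hemizygous inheritance in female birds would
require a dosage model the evaluation does not need), so autosomal
conclusions only.

## Numerical and validation choices

- Quality control: call rate strictly greater than 0.70, MAF at least
  0.01 (markers *below* 0.01 are deleted); the filter is idempotent and
  logs a reason per removed marker.
- Missing dosage sentinel: `NA` throughout; every statistic documents its
  missing-data handling (preselection ignores missing genotypes;
  centering replaces them with the expected score).
- MAF spectrum: 0.05-wide half-open bins, final bin closed at 0.5; the
  coefficient of variation of bin counts uses the sample SD. The binning
  of the figure this summary echoes was never published, so the CV is a
  descriptive statistic here, not a target.
- Variance components below $10^{-6}$ of the phenotypic variance are
  boundary-flagged rather than zeroed.
- Validation problem sizes (chosen to exercise the estimators at study
  scale while keeping a laptop run in minutes): SNP-BLUP equivalence at
  n = 60, m = 300 over 20 instances; REML grid oracle at n = 100;
  heritability recovery at n = 400, m = 2000 over 20 replicates;
  preselection-gain and null-calibration runs at n = 200, m = 2000;
  unbiasedness at n = 400 over 5 replicates. The acceptance script runs
  the full pipeline at n = 395, m = 3000.

## Known limitations

- Single trait, single genomic variance component: no multi-trait,
  dominance, or single-step extensions.
- The GWAS screen is plain OLS without a polygenic control, so in
  structured populations it partly selects on family means — acceptable
  for a screening comparison, wrong for association inference.
- Leave-one-out accuracy in low-signal settings can be negative (the
  familiar artifact of predictions shrinking toward fold-specific
  means); the permutation-null test brackets this behavior.
- The simulator's preselection gains are modest compared with gains
  reported on real sequencing panels: with a few thousand simulated
  markers and complete homozygote classes, the normalizing maximum
  contrast is moderate and the default cutoff removes only about half
  the markers. On real panels with one to two orders of magnitude more
  markers and platform missingness, screening is far more aggressive.
  The package reports what its inputs support.
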