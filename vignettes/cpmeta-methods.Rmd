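---
title: "cpmeta: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpmeta: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmeta)
```

## The statistical model

The unit of analysis is a panel of Wald statistics. For SNP `i`, cohort
`j` and trait `k`, a GWAS supplies an effect estimate and its standard
error; the test statistic is `T_jk = beta_jk / se_jk` (or, when only a
two-sided p-value and a direction are published,
`sign(beta) * qnorm(1 - p/2)`; the two constructions agree for normal
Wald tests). Stacking panels gives the vector
`T = (T_11, ..., T_J1, ..., T_1K, ..., T_JK)'`.

Under the null of no association, `T` is modelled as multivariate normal
with mean zero and correlation matrix `R`. `R` is not the identity in
practice: overlapping or related samples between cohorts, and
correlation between traits measured on the same people, both correlate
the statistics. `R` is a nuisance parameter estimated once per study
from null SNPs (below) and then held fixed across the genome.

### Homogeneous combination, S_Hom

With a diagonal weight matrix `W` and `e` a vector of ones,

    S_Hom = [e'(RW)^-1 T]^2 / [e'(WRW)^-1 e]

is the squared standardised linear combination `a'T` with `a = W^-1 e`:
a 1-df chi-squared statistic under the null for any fixed weights,
exactly calibrated because the denominator is `Var(a'T)` under
MVN(0, R). It is powerful when the true standardized effects share one
direction across panels. The default weight scheme is
`w_jk = sqrt(n_j)`; with equal sample sizes and `R = I` the statistic
reduces to the square of the conventional sample-size-weighted meta
Z-score. With unequal `n`, the implemented form (the formula above,
taken literally) weights the components of `T` by `1/w_jk`; the
conventional weighted-Z baseline is computed separately by
`weighted_z_meta()`, so the two conventions can always be compared on
the same data. Both `"n"` and `"unit"` schemes are available, and
multiplying all weights by a constant provably does not change the
statistic.

### Heterogeneous combination, S_Het

When effects differ across panels — different magnitudes, opposite
signs, or effects confined to one sex — a homogeneous combination
dilutes the signal (opposite signs can cancel exactly). `S(tau)`
restricts the quadratic to the active set `{jk : |T_jk| > tau}` and
aligns the weight signs with the observed directions,
`w_jk = sqrt(n_j) sign(T_jk)`, and

    S_Het = max over tau > 0 of S(tau).

`S(tau)` is piecewise constant in `tau`, changing only when the
threshold crosses one of the order statistics of `|T|`; the maximum over
the finite grid `{|T_jk| - 1e-8}` is therefore exact (verified in the
tests against exhaustive evaluation over every threshold-reachable
subset). Ties between thresholds break toward the smaller `tau`, i.e.
the larger active set. An empty active set or a singular restricted
correlation matrix makes that `tau` undefined and it is skipped; an
all-zero `T` gives `S_Het = 0`.

Because of the data-dependent thresholding and sign alignment, `S_Het`
is not chi-squared distributed. Its null distribution is obtained by
Monte Carlo: `B` draws of `T ~ MVN(0, R)` through the Cholesky factor of
(PSD-repaired) `R`, each reduced to `S_Het`. The p-value of an observed
statistic is the add-one empirical tail probability
`(1 + #{draws >= s}) / (B + 1)` while at least 10 draws lie beyond, and
a fitted tail beyond that.

### The beta tail model

Following the convention of approximating the S_Het null with a beta
distribution, the transform `V = exp(-S_Het/2)` maps the statistic to
(0, 1] and a Beta(alpha, beta) is fitted to `V`. Two numerical findings
shaped the implementation:

- a beta fitted by MLE to *all* draws tracks the bulk of the
  distribution and was measured 5-25x conservative at tail probabilities
  of 1e-4 to 2e-6 (against a 2-million-draw reference);
- fitting the same family by censored MLE to only the top 1% of draws
  (the rest entering the likelihood as a censoring mass) reproduces the
  reference tail within a factor of ~1.2-3, always on the conservative
  side in our checks.

The censored fit is the default. The crossover from empirical to fitted
p-values at tail count 10 and the 1% fitting window are package
choices; the recorded diagnostic (`q99_rel_err`, the relative error of
the fitted 99th percentile) must stay below 10%. Extreme S_Het p-values
should be read as conservative: at the genome-wide threshold the fitted
tail may understate significance severalfold, which costs some power
and never inflates type I error.

## Estimating R from null SNPs

`R` is estimated as the Pearson correlation of the Z columns over SNPs
that are (a) approximately independent — LD-pruned at r^2 < 0.2, either
by the built-in greedy window pruner or an externally supplied list —
and (b) plausibly null: any SNP with `|Z| > 1.96` in any panel is
removed, because true associations inflate the apparent correlation.
The boundary is kept (`|Z| <= 1.96` passes).

The |Z| filter truncates both margins of each panel pair, which shrinks
the pairwise correlation by approximately `kappa(a) = Var` of the
standard normal truncated to `[-a, a]` — 0.759 at `a = 1.96`, a bias of
-0.023 on a true correlation of 0.096. Since the estimand is the
correlation of the *untruncated* statistics (the matrix that
parameterises every SNP's null, not just the filtered ones),
`estimate_R()` divides the off-diagonals by `kappa` when the input comes
from `select_null_snps()`. The linear correction is derived from the
small-correlation expansion of the doubly truncated bivariate normal and
is accurate for `|r|` up to about 0.3 — comfortably covering
overlap-induced correlations, which are typically below 0.1. Estimates
are clipped to [-1, 1], the diagonal is fixed at 1, and an indefinite
matrix (possible with pairwise-complete estimation) is projected to the
nearest positive-semidefinite correlation matrix by eigenvalue clipping;
the projection flag and pairwise SNP counts are recorded.

## Downstream scan machinery

- **Baseline**: `z = sum(sqrt(n_j) T_j) / sqrt(sum n_j)`, two-sided
  normal p — the conventional fixed-effect sample-size-weighted
  meta-analysis, assuming independent panels.
- **Genomic control**: `lambda = median(observed 1-df chi-squared) /
  0.4549364`. Values near 1 indicate no global inflation.
- **Loci**: greedy clumping — repeatedly take the most significant
  remaining SNP below 5e-8 as lead and absorb all significant SNPs
  within +/-500 kb on the same chromosome. A locus is *novel* versus the
  baseline iff no baseline-significant SNP lies in the 1.0 Mb region
  around the lead and (optionally) the lead is not in a supplied LD pair
  list with a baseline index SNP. A secondary tier at 1e-7 is reported
  separately and never feeds the novelty calls.
- Q-Q, Manhattan and forest outputs are plain data tables; rendering is
  intentionally out of scope.

## The synthetic generator: what it emulates, what it does not

`simulate_zpanel()` draws summary statistics directly at the Z level:
null rows MVN(0, R_true), causal rows mean-shifted by
`sqrt(n_j / max n) * b_jk * delta`, so `delta` reads as the noncentral
mean of the largest cohort and power scales with `sqrt(n)` as in a real
GWAS. Betas and SEs are back-filled via
`se = 1 / sqrt(2 maf (1 - maf) n)`, `beta = z * se`, so Wald
reconstruction inverts the simulation exactly. The default world is the
sex-stratified anthropometric setting: two cohorts of 60,586 and 73,137
samples, three traits, male-female null correlations 0.0126 (height),
0.096 (BMI) and 0.03 (WHRadjBMI). The residual between-trait correlation
is set to 0.01 — the observed between-trait values were only described
as "much smaller" than the within-trait ones, so one small value was
fixed once and kept.

Deliberate non-realism, hence limits on what a green test establishes:
scan rows are independent (no LD between the M SNPs — locus clumping is
exercised by construction, not by realistic haplotype structure); minor
allele frequency is uniform and uncoupled from effect size; per-SNP
sample sizes are constant per panel. Genotype fixtures for the pruner
are generated separately with block-exchangeable LD
(`simulate_genotypes()`), which validates the pruning logic but is not a
population-genetic model. Calibration results on this generator
establish correctness of the statistics under their stated MVN null,
not robustness to model violations (stratification, cryptic
relatedness beyond exchangeable overlap, winner's curse in the inputs).

## Numerical and design choices

- **Missing panels**: each SNP's `T`, `R`, `W` are subset to its
  observed panels; results record `n_panels_used`. Panel alignment
  defaults to the SNP intersection across panels (union available).
- **Harmonization**: reference effect allele from the first panel
  carrying the SNP; swapped alleles negate `T` and beta; strand
  complements are tried before declaring a mismatch; A/T and C/G SNPs
  are dropped by default as strand-ambiguous.
- **Degenerate inputs**: SE <= 0, p outside (0, 1] and non-numeric
  fields reject the record (counted, line numbers logged); monomorphic
  SNPs are excluded before pruning; an empty null-SNP set or a panel
  pair sharing fewer than 30 null SNPs is an error, not a warning.
- **Weights**: per-SNP sample sizes are used when present, else the
  panel maximum ("up to N" convention of consortium files).
- **Determinism**: every stochastic component (generator, S_Het null)
  requires an explicit seed; the pipeline refuses to run S_Het p-values
  without one. Identical configurations reproduce identical output
  files byte for byte.
- **Tau grid epsilon** 1e-8: far below any meaningful difference of
  Wald statistics, far above double rounding error.
- **PSD repair tolerance** 1e-10 on the smallest eigenvalue; repairs on
  matrices with min eigenvalue >= -0.01 change no entry by more than
  0.05 (tested).

## Known limitations

- S_Het p-values beyond the Monte Carlo range are conservative (see the
  tail model above); analyses chasing borderline S_Het hits should
  increase `B` rather than trust the fitted tail to the last digit.
- The truncation de-attenuation in `estimate_R()` assumes bivariate
  normality of the null statistics and small correlations; it is not
  exact for heavy overlap (|r| >> 0.3).
- The greedy pruner is a window-based approximation of LD pruning, not
  a reimplementation of any specific tool's semantics; window and step
  defaults (50/5 SNPs) follow common practice.
- No liftover, no variant-identifier reconciliation beyond exact id
  match, no sex-chromosome handling (autosomes only by default).
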