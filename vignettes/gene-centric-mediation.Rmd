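---
title: "Gene-centric mediation analysis of DNA methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric mediation analysis of DNA methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmediate)
```

## The problem

Epigenome-wide studies often ask whether DNA methylation sits on the causal
path from an early-life exposure to an adult outcome: does a binary exposure
$X$ (for example, dichotomised childhood maltreatment) alter methylation
$M$, which in turn shifts a psychiatric outcome $Y$?  With a 450K-style
array, the number of CpG sites dwarfs the sample size and CpGs within a
gene are strongly correlated, so `gcmediate` tests mediation *gene by
gene*: the mediator for one test is the whole set of $K$ CpGs falling in a
gene body plus 500 bp upstream of its transcription start site
(strand-aware, so the promoter is included).

For one gene the structural model is

$$ M_k = C\gamma_k + X\alpha_k + \epsilon_k, \qquad
   g(E[Y]) = C\delta + c'X + \sum_{k=1}^K M_k \beta_k, $$

with adjustment covariates $C$ (age, sex, BMI and five measured blood-cell
proportions), direct effect $c'$, and link $g$ identity (continuous
outcome) or logit (binary).  The gene mediates if some $\alpha_k \beta_k
\neq 0$.  The null is therefore *composite*: it is the union of
H00 ($\alpha = 0, \beta = 0$), H01 ($\alpha = 0, \beta \neq 0$) and
H10 ($\alpha \neq 0, \beta = 0$); only H11 is the alternative.

## The two path tests

Testing $K$ coefficients at once with $K$ up to hundreds is hopeless as a
fixed-effect Wald test, so both paths treat the per-CpG coefficients as
random effects, $\alpha_k \sim N(0, \tau_\alpha^2)$ and
$\beta_k \sim N(0, \tau_\beta^2)$, and test the variance component
($\tau^2 = 0$) with a score test in the induced mixed model:

* **Exposure path.**  Because $X$ is a single binary variable and $M$ is
  high-dimensional, the regression is inverted: the logistic null model
  $X \sim C$ is fitted, and the CpG block enters as a random effect.  A
  binomial working model is used rather than a linear one because a binary
  response violates linear-model variance assumptions.
* **Outcome path.**  The null model $Y \sim X + C$ is fitted under the
  outcome family — the exposure stays in the design, so the direct effect
  $c'$ is adjusted and an H10 gene (strong $\alpha$, strong $c'$) cannot
  leak into the outcome-path p-value.

Both reduce to the same statistic: with null-model residuals $r = y -
\hat\mu$ and the column-standardized CpG block $M$,

$$ Q = r^\top M M^\top r, $$

the score statistic of the variance component with an unweighted linear
kernel.  Columns are standardized to unit variance first because M-value
scales differ across probes and nothing in the design justifies implicit
probe weights.  Under the null, $Q \sim \sum_j \lambda_j \chi^2_{1,j}$
where the $\lambda_j$ are the nonzero eigenvalues of $M^\top P_0 M$ under
the family's variance weighting (Gaussian: scaled by $\hat\sigma^2$;
binomial: $P_0 = V - VD(D^\top VD)^{-1}D^\top V$ with $V =
\mathrm{diag}(\hat\mu(1-\hat\mu))$).

### Mixture-of-chi-square tails

The tail probability $P(\sum_j \lambda_j \chi^2_{1,j} > q)$ is computed by
numerical inversion of the characteristic function (Imhof's integral form)
with adaptive quadrature, requested absolute accuracy $10^{-9}$, and the
result clipped to $[10^{-15}, 1]$.  Numerical choices worth knowing:

* Eigenvalues below $10^{-10}\,\lambda_{\max}$ are truncated first — kernel
  matrices are rank-deficient whenever $K$ exceeds the residual degrees of
  freedom or columns are collinear.
* A flat spectrum (all retained $\lambda$ equal, including the single-CpG
  case) is evaluated by the exact scaled-chi-square closed form; the
  oscillatory integrand decays like $u^{-3/2}$ there, too slowly for
  generic quadrature.
* Convergence is judged by the achieved error bound ($\le 10^{-4}$) rather
  than the quadrature library's roundoff flag, which trips spuriously for
  small $r$.
* On non-convergence, or when the inversion bottoms out at the $10^{-15}$
  floor, a four-cumulant (Liu-type) non-central chi-square surrogate takes
  over; the method actually used is recorded per gene.

## Combining the paths under the composite null

The joint-significance idea — the mediation p-value is some function of
$(p_\alpha, p_\beta)$ — must confront the three-part null.  The package
uses a weighted divide-aggregate composite statistic: each sub-null has a
natural case-specific p-value (H01: $p_\alpha$; H10: $p_\beta$; H00:
$\max(p_\alpha, p_\beta)^2$, which is exactly Uniform(0,1) under H00 with
independent inputs), and these are mixed by the estimated probabilities of
the three cases,

$$ p_{\alpha\beta} = \hat\pi_{01}\,p_\alpha + \hat\pi_{10}\,p_\beta +
   \hat\pi_{00}\,\max(p_\alpha, p_\beta)^2 . $$

The weights come from the genome itself.  Each path's p-value series is
transformed to one-sided z-scores $z = \Phi^{-1}(1-p)$ and the null
proportion $\pi_0$ of each series is estimated; the three sub-null
probabilities are composed assuming independence of the two null
indicators, $(\pi_{00}, \pi_{01}, \pi_{10}) \propto (\pi_0^\alpha
\pi_0^\beta,\ \pi_0^\alpha(1-\pi_0^\beta),\ (1-\pi_0^\alpha)\pi_0^\beta)$,
normalized over the three.  Independence is an assumption, not a theorem;
with weights derived this way the H00 weight is biased slightly upward
when genuinely mediating genes exist (they are non-null in both series),
which pushes the statistic toward the conservative squared-maximum rule.

### Empirical-null estimation: a deliberate design choice

The textbook empirical-null fit — truncated-normal maximum likelihood on a
symmetric central window $|z| \le 2$ — is biased upward by roughly +0.05
when a fifth of the series sits at a moderate alternative such as
$N(3,1)$, because the alternative leaks mass into the right half of the
window.  Two facts about *this* pipeline let us do better, and both are
exploited deliberately:

1. The z-scores are one-sided by construction: alternatives shift right
   only, never left.  So `estimate_null_proportion()` fits
   $(\delta, \sigma)$ on an *asymmetric* iterated window
   $(\delta - 2\sigma,\ \delta + 0.8\sigma)$ whose right edge stays clear
   of contamination, and then estimates the null mass from the left of
   center: $\hat\pi_0 = \min(1, \Pr_n(z \le \hat\delta)/0.5)$.  The test
   suite checks recovery under a 0.8/0.2 moderate-alternative mixture to
   within $\pm 0.05$, and that a pure null returns values near 1.
2. The weighted composite statistic is *not* exactly uniform under the
   null mixture (the H01/H10 components are mildly liberal, the H00
   component mildly conservative), so with at least 1,000 genes the final
   p-values are recalibrated: transform to z, fit the empirical null on
   the fixed window $z \in [-1, 2.5]$, and return
   $1 - \Phi((z-\hat\delta)/\hat\sigma)$.  The window is right-of-center
   because the rejection boundary lives there, and capped at 2.5 so strong
   alternatives do not inflate $\hat\sigma$.  The transform is monotone,
   so gene rankings never change.  Below 1,000 genes empirical-null fits
   are too unstable and the raw statistic is returned unchanged.

Benjamini–Hochberg q-values across genes complete the chain.

### What power comparison is fair?

Against the *conservative* joint-significance rule ($p = \max$), the
weighted statistic is uniformly more powerful.  Against the
H00-exactified variant ($p = \max^2$) the comparison is subtler: when the
estimated $\pi_{01}, \pi_{10}$ are non-negligible, the weighted statistic
deliberately spends some of its budget guarding the H01/H10 sub-nulls
(where $\max^2$ is anti-conservative, with type-I error around 0.22 at
level 0.05), and this costs power against H11 in exchange for validity.
The test suite states the dominance property against the squared-maximum
rule at equal nominal level; whether it holds in a given mixture is an
empirical question that the suite answers rather than assumes.

## The synthetic-data generator

No individual-level trauma-cohort data ships with the package, so every
operating characteristic is established on synthetic studies whose
generator mirrors the analysis model:

* **Cohort** — age $N(41.5, 13.2^2)$ years, BMI $N(32.2, 8.4^2)$, sex
  Bernoulli(0.704 female), five blood-cell proportions from a Dirichlet
  over six compartments (granulocytes dropped), and exposure from a
  logistic model on standardized age, sex and BMI with intercept targeting
  43.7% prevalence — the descriptive profile of a trauma-exposed adult
  methylation cohort of this kind.
  The nonzero covariate coefficients make the design confounded on
  purpose, so the adjustment in both path tests is load-bearing.
* **Genes** — each gene draws $\alpha_k, \beta_k$ i.i.d. normal with the
  scenario's variances (dense by default; a sparse variant zeroes a
  configurable fraction, reflecting that real effects are likely sparse);
  residual CpG noise has exchangeable correlation $\rho$ (AR(1)
  available).  Default $K = 16$ matches the typical (median) promoter-
  extended CpG count per gene on a 450K array; defaults $\rho = 0.5$,
  $\sigma_m^2 = 1$,
  $\tau^2 = 0.25$ on active paths are calibration-study choices, not an
  attempt to mimic any cohort's marginals, which the source study does not
  report at this granularity.
* **Outcome** — assembled once per sample as covariate effects plus
  $c'X$ plus the sum of *all* genes' $M\beta$ contributions plus noise, so
  between-gene leakage exists exactly as in real data.  An isolated mode
  (one outcome per gene) is provided for unit-level calibration and power
  studies, where per-gene power must be interpretable.
* **Determinism** — one master seed; gene $g$ draws from the derived
  stream $(s \cdot 1000003 + 7919g) \bmod (2^{31}-1)$, so any gene is
  reproducible in isolation and identical seeds give bit-identical
  studies.

What passing tests on these studies do *not* show: robustness to probe-
type chemistry bias, batch effects, cell-type misestimation, or non-normal
effect-size distributions — none of which the generator emulates.  Batch
correction and cell-type deconvolution are treated as upstream steps whose
outputs (corrected values, measured proportions) the pipeline consumes.

A structural consequence of genome-wide outcome assembly is worth stating
plainly: if $G_a$ genes contribute comparably to the outcome, each gene's
outcome-path non-centrality is capped near $n/G_a$ no matter how large the
per-CpG effects are, because every other active gene acts as noise.  At
$n \approx 350$ and hundreds of active genes, per-gene power at
FDR-adjusted thresholds is accordingly small — mirroring how few genes
survive FDR control in real epigenome-wide mediation scans — and
false-discovery control, not sensitivity, is the property the end-to-end
simulations certify.

## Degenerate inputs and other numerical choices

* Beta values are clipped to $[\epsilon, 1-\epsilon]$, $\epsilon =
  10^{-6}$, before the logit2 transform so M-values stay finite.
* Constant CpG columns are dropped before standardization; a gene with no
  non-constant column is skipped with a recorded reason, never aborting a
  scan.
* Rank-deficient adjustment designs drop aliased columns with a warning;
  perfect separation in a logistic null fit is an error naming the suspect
  covariate.
* Samples missing any analysis variable are dropped listwise, logged per
  variable; samples are aligned between files by id intersection.
* The per-gene CpG count threshold defaults to 1 (every mapped gene is
  tested); the total-effect test is reported but never gates the scan,
  since suppression can hide real mediation behind a null total effect.

## Sizes used by the shipped studies

The analysis scripts and test suite run: path-test calibration at
$n = 300$, $K = 16$, 2,000 replicates; the composite-null chain at 5,000
genes (isolated outcomes, sub-null mix 0.8/0.1/0.1); power studies at
three effect sizes with 2,000 genes each; and twenty end-to-end scans of
2,000 genes at the generator defaults.  These sizes give binomial Monte-
Carlo error well inside the tolerance of each property they certify.
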