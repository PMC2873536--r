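---
title: "Regularized dual CCA for paired omics data: models, choices, limitations"
author: "dualCCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized dual CCA for paired omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualCCA)
```

## The problem

Two omics assays measured on the same samples — say log2 copy-number ratios
(`X`, n variables) and log2 gene-expression values (`Y`, m variables), both
variables x samples with N samples — carry a shared signal: segmental
copy-number alterations that drive expression changes in the affected genes.
Canonical correlation analysis (CCA) is the natural tool: it finds weight
vectors $w_x, w_y$ maximizing the empirical correlation between the
projections $X^T w_x$ and $Y^T w_y$. Classical CCA, however, requires the
sample covariance matrices $C_{xx} = XX^T$ and $C_{yy} = YY^T$ to be
invertible, which fails whenever $n > N$ or $m > N$ — the normal situation in
omics — and it is badly confounded by collinearity, which is the defining
feature of copy-number data (all variables in a segment move together).

## The model

### Penalized correlation

We add a ridge penalty to each covariance matrix and maximize the penalized
correlation

$$
\rho_\tau(w_x, w_y) \;=\;
\frac{w_x^T C_{xy}\, w_y}
{\sqrt{w_x^T\big((1-\tau_x) C_{xx} + \tau_x N I\big) w_x}\;
 \sqrt{w_y^T\big((1-\tau_y) C_{yy} + \tau_y N I\big) w_y}},
$$

with $C_{xy} = XY^T$ and $\tau_x, \tau_y \in [0, 1]$. The factor $N$ makes
the two denominator terms commensurate: with each variable standardized to
unit variance under the population-SD convention (divide by $N$), the
diagonal of $C_{xx}$ is exactly $N$, so for uncorrelated variables
$C_{xx} \approx N I$. At $\tau = (0,0)$ this is classical CCA (pure
correlation); at $\tau = (1,1)$ the denominators no longer depend on the
data covariance and the optimum is the top singular pair of $C_{xy}$ — the
PLS (covariance-maximizing) limit. Intermediate values trade correlation
against variance of the extracted features.

### The dual formulation

With hundreds of thousands of variables, $C_{xx}$ cannot be formed. Writing
$w_x = X\alpha_x$, $w_y = Y\alpha_y$ and substituting, everything collapses
onto the $N \times N$ Gram matrices $K_X = X^TX$, $K_Y = Y^TY$:

$$
\max_{\alpha_x, \alpha_y}\;
\frac{\alpha_x^T K_X K_Y\, \alpha_y}
{\sqrt{\alpha_x^T\big((1-\tau_x) K_X^2 + \tau_x N K_X\big)\alpha_x}\;
 \sqrt{\alpha_y^T\big((1-\tau_y) K_Y^2 + \tau_y N K_Y\big)\alpha_y}},
$$

a generalized eigenproblem whose cost depends on $N$, not on $n$ or $m$.
`solveRccaDual()` implements it; `weightsFromDual()` maps dual coefficients
back to primal weights. The restriction to $w \in \mathrm{range}(X)$ is
lossless: any component of $w_x$ orthogonal to the sample columns
contributes nothing to the numerator and only inflates the ridge term, so
the primal optimum always lies in the span the dual searches.

### Numerical route and degenerate denominators

The package reduces the generalized problem to an SVD: each penalized
denominator matrix $A = (1-\tau)K^2 + \tau N K$ is symmetrically
eigendecomposed, eigenvalues below $10^{-10}$ times the largest are
truncated, and the whitened numerator $B_x^T K_X K_Y B_y$ (with
$B^T A B = I$ on the retained eigenspace) is decomposed; singular values are
the penalized objective values, in nonincreasing order, and successive
components are orthogonal in the penalized metric (which coincides with
empirical uncorrelatedness at $\tau = 0$).

The truncation is not a convenience: the Gram matrix of row-centered data
*always* has the ones-vector in its null space, so $A$ is always singular
and an additive jitter proportional to $K$ would leave it so. Truncation is
exact on the subspace where the objective is defined, because null
directions of $A$ are precisely the $\alpha$ with $X\alpha = 0$. At
$\tau = 0$ with a *full-rank* Gram (more variables than samples) the fit
interpolates the training samples — training correlation 1 regardless of
signal — and the solver warns; this is the overfitting regime that motivates
regularization in the first place.

A dense primal implementation, `primalRccaOracle()` (restricted to
$n, m \le 2000$), solves the same objective by whitening
$(1-\tau)C + \tau N I$ directly. It exists purely as an independent
correctness oracle; the test suite verifies dual/primal agreement of
objective values to $10^{-8}$ across random instances and the whole
$\tau$ grid, plus the classical limit against `stats::cancor` and the PLS
limit against the SVD of $C_{xy}$.

### Conventions

- **Standardization.** Variables are centered and scaled to unit variance
  using the population SD (divide by $N$; `convention = "sample"` gives
  $N-1$). Held-out data are always standardized with *training* statistics.
  Zero-variance variables are dropped and recorded.
- **Sign.** A canonical feature pair has no canonical sign; per component
  the entry of $W_x$ with the largest absolute value is made positive and
  the same flip is applied to $W_y$. All correlations are reported as
  absolute values for the same reason.
- **Normalization.** Weight columns are scaled to unit penalized
  denominator; the penalized objective can exceed 1 when $\tau > 0$ (it is
  a correlation only at $\tau = 0$), while reported *canonical correlations*
  are always empirical absolute Pearson correlations of scores, in [0, 1].
- **Degenerate components** (objective below $10^{-10}$) are truncated with
  a warning.

## PCA+CCA

The second route to high dimensions reduces each side separately to its top
$s$ principal components (computed in the dual as well, through the
eigendecomposition of $K$ — see `dualPca()`), applies classical CCA to the
two $s$-dimensional score sets, and combines the layers into total weights
$W = \Pi\,\hat w$. Correlated variables receive similar loadings in each
principal component and hence similar total weights: the method is less
flexible than regularized dual CCA (it cannot single out a subset of a
correlated block), which shows up as lower training canonical correlations
but similar validation correlations. The default $s = 12$ follows common
practice of retaining the components before the scree flattens;
`fitPcaCca()` reports explained-variance fractions so the choice can be
inspected, and accepts per-side values `s = c(sx, sy)`. Component scores
enter the CCA unscaled (classical CCA is scale-equivariant). PCA is
performed on the standardized matrices, consistent with the global
standardization contract, and on the tuning samples only.

## Choosing the ridge parameters

`makeSplit()` partitions the samples into a tuning set (2/3, stratified by
label when labels exist, each part within one rounding unit of the global
label proportions) and a validation set (1/3) used only for assessing
generalization. Within the tuning set, `cvCanonicalCorrelation()` estimates
the test-set canonical correlation $\rho_{cv}$ by 3-fold cross-validation:
per fold, standardize with training-fold statistics only, fit, project the
held-out fold, take the absolute Pearson correlation, and average the three
folds. `gridSearch()` evaluates $\rho_{cv}$ for the first component on the
default grid $\{0, 0.1, \dots, 1\}^2$ (121 points; the fold assignment is
fixed across the grid so points differ only through $\tau$) and selects the
maximizer, breaking ties toward stronger regularization (larger
$\tau_x + \tau_y$, then larger $\tau_x$) as a stability preference. The
second component's $\rho_{cv}$ is then computed at the optimum only. The
objective uses the first component alone; a mean-of-first-two objective
changes little in practice and is not the default.

`permutationNull()` calibrates the result: the sample order of $Y$ within
the tuning set is permuted (once per instance, shared by all folds; the
identity permutation is excluded), destroying the pairing while preserving
both marginal covariance structures, and $\rho_{cv}$ is recomputed at the
fixed optimum, $B = 50$ times. A real shared signal should exceed the null
mean by several null SDs.

k = 3 balances two concerns: leave-one-out would overestimate
generalization, and the test folds must be large enough (a fold below 3
samples is an error) for a stable correlation.

## Interpretation

Weights are unreliable relevance measures under collinearity — the solver
is free to spread weight arbitrarily within a correlated block. The package
therefore interprets features through **cross-loadings**
(`crossLoadings()`): the correlation of each variable with the feature
extracted from the *other* side. Correlated variables get similar
cross-loadings even when their weights differ; empirically, the
cross-loading profiles of regularized dual CCA and PCA+CCA agree closely
(rank correlation above 0.9 in the test suite) even when the weight vectors
do not. `topVariables()` ranks by absolute loading (ties broken by id for
reproducibility; default list length 150), `genomeOrderedLoadings()` orders
variables along the genome in karyotype order (1..22, X, Y; unannotated
variables appended and flagged), and `redundancy()` summarizes shared
variance per feature as the mean squared loading (the Stewart–Love
redundancy index): $R_j = \frac1m \sum_i c_{ij}^2$. Supplying own-set
loadings gives $R_{x|x}$-type quantities. Loadings are computed on the
tuning samples by default; the evaluation set is an explicit argument.

`sampleCoordinates()` projects samples onto the first two feature pairs of
both sides, standardizes each coordinate column to unit variance, and pairs
the x-point with the y-point per sample; when the canonical correlation is
near 1 the two points nearly coincide. These tables are plain data and can
be drawn with any plotting layer.

## The synthetic generator

There is no desk-scale real data set on which the package's claims could be
verified exactly, so the generator (`generatePaired()`) produces paired
matrices with *known* population canonical structure: independent latent
factors $z_l$, x-side signal on contiguous, disjoint variable blocks with a
common loading per block (segment-like collinearity), y-side driver
$u_l = \rho_l z_l + \sqrt{1-\rho_l^2}\,e_l$ on its own block, optional
discrete groups shifting factor means (subtype-like structure), and i.i.d.
Gaussian noise. For this construction the population canonical correlations
have a closed form (see `populationCanonicalCorrelations()`): per factor,
$\rho_l$ attenuated by the two block signal-to-noise factors
$c = \sqrt{tV/(tV+1)}$, with $t$ the summed squared loadings over the block
divided by the noise variance and $V$ the latent variance including
between-group shift variance. The tests verify this closed form against
block-mean correlations at $N = 20000$.

Two presets encode the package's study conditions:

- **`collinear_blocks`** — the calibration preset. The latent correlations
  are *solved* from the attenuation so the population canonical
  correlations are exactly (0.9, 0.6). The x side has 30-variable blocks at
  noise SD 0.2 (within-block correlation about 0.96 — segment-scale
  collinearity), the y side 60-variable blocks at loading 0.6 and unit
  noise (within-block correlation about 0.27), plus a y-only variance
  factor (40 variables, loading 1.5, roughly a fifth of the total y
  variance) with no x-side counterpart — emulating the dominant
  expression-variance axis that has no copy-number correlate, and the
  reason the expression side tolerates (and prefers) less regularization
  than the collinear copy-number side.
- **`hd50_e2a_tall`** — the subtype-shaped preset: a group with several
  whole-block gains driving factor 1; a group with one large up-block and
  one small down-block driving factor 2; and a group shifting a y-only
  factor, which a correlation-maximizing method should *not* isolate but a
  y-side PCA should. The test suite asserts exactly these outcomes as
  standardized mean differences (above 2 pooled SDs for the shared groups
  on their features, below 1 for the y-only group on both CCA features,
  above 2 on a y-side principal component).

What the generator does **not** emulate: heavy-tailed noise, probe-level
artifacts, batch effects, missing values, nonlinear dose–response between
copy number and expression, and the discreteness of real copy-number
states. Passing tests therefore demonstrate correctness of the machinery
and calibration under the linear-Gaussian assumptions CCA itself makes —
not robustness to violations of them.

## Problem sizes and observed behavior

The shipped tests and the acceptance script run at deliberately moderate
sizes — instance sweeps at $n, m \le 12$, the overfitting demonstration at
$n = m = 1000, N = 30$, the full pipeline (split, 121-point grid search,
fit, validation) at $N = 150$ over 10 seeds, permutation nulls at $B = 50$
— chosen so the whole suite completes in well under a minute of compute
while still exercising every code path at realistic aspect ratios. Under
these conditions the pipeline recovers the first population canonical
correlation to within a few hundredths; the second component is recovered
with slightly more bias (finite-sample leakage from the stronger factor
pulls its validation correlation around), and the preference for stronger
x-side regularization is visible in most but not all seeds — the
cross-validated surface is genuinely flat near its top, so neighboring
$(\tau_x, \tau_y)$ pairs often generalize equally well, as one would expect
when several parameter settings give similar test correlations.

## Known limitations

- Only linear relationships are sought; there is no kernelized variant.
- No sparsity: weights are dense, and variable selection happens only
  through interpretation (cross-loadings), not estimation.
- Missing values are rejected, not imputed.
- The permutation null permutes whole samples, so it calibrates against
  "no pairing" — not against weaker partial-null hypotheses.
- Redundancy coefficients use equal per-variable weights; variable sets
  with wildly different internal correlation structure are summarized
  coarsely.
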