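---
title: "Ome-wide association with additive and epistatic effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ome-wide association with additive and epistatic effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

## The model and its assumptions

`episcan` analyzes a quantitative trait $y$ ($n$ individuals) against an
$m \times n$ panel of omic markers $Z$ — genotype bins coded numerically,
log2 transcript expression, or log2 metabolite abundance — under the linear
mixed model

$$y = X\beta + \sum_{i=1}^m Z_i a_i
      + \sum_{i=1}^{m-1}\sum_{j=i+1}^m W_{ij}\gamma_{ij} + e,
  \qquad W_{ij} = Z_i \circ Z_j,$$

with $X$ the intercept column, $a_i \sim N(0, \sigma_a^2)$,
$\gamma_{ij} \sim N(0, \sigma_{aa}^2)$, $e \sim N(0, I\sigma^2)$, all
effects exchangeable within their class. Marginally
$\mathrm{var}(y) = K_a\sigma_a^2 + K_{aa}\sigma_{aa}^2 + I\sigma^2$ with
trace-normalized kinships

$$K_a = \frac{1}{d_a}\sum_i Z_iZ_i^T,\qquad
  K_{aa} = \frac{1}{d_{aa}}\sum_{i<j} W_{ij}W_{ij}^T,\qquad
  d = \mathrm{tr}(\cdot)/n .$$

The model assumes complete data (missing cells are rejected, not imputed),
a single intercept as the only fixed effect, homoscedastic residuals and no
dominance terms. Markers are used exactly as supplied: no automatic
centering or scaling is applied, because genotype bins coded $\{-1,+1\}$
and log2-scale abundances are already on meaningful scales. An optional
`standardize` flag exists in the pipeline configuration for panels on
heterogeneous scales, but it defaults to off.

### Marker orientation

The panel is stored marker-by-individual (rows are markers, the
conventional orientation for bin-genotype and expression matrices), and
the marker vector
$Z_i$ entering the model is the length-$n$ values of marker $i$ across
individuals — the only dimensionally consistent reading when $y$ is
$n \times 1$.

## Kinship computation

The epistatic kinship naively requires all $m(m-1)/2$ pair outer products;
at transcriptome scale ($m = 22{,}584$, $\sim 2.5\times10^8$ pairs) that is
infeasible. `kinship_epistatic()` instead uses the algebraic identity

$$\Big[\sum_{i<j} W_{ij}W_{ij}^T\Big]_{kl}
  = \tfrac12\big(G_{kl}^2 - S_{kl}\big),\qquad
  G = \textstyle\sum_i Z_iZ_i^T,\;\; S_{kl} = \sum_i Z_{ik}^2 Z_{il}^2,$$

an $O(mn^2)$ computation. The literal double-sum implementation
(`kinship_epistatic_bruteforce()`) is retained purely as the correctness
oracle; the test suite checks exact agreement (max abs diff $<10^{-10}$) on
dozens of random panels, plus symmetry, positive semidefiniteness (relative
eigenvalue tolerance $-10^{-8}\lambda_{max}$, to absorb floating-point
noise) and exact trace normalization.

## REML estimation

With ratios $\lambda_a = \sigma_a^2/\sigma^2$,
$\lambda_{aa} = \sigma_{aa}^2/\sigma^2$ and
$C = \lambda_aK_a + \lambda_{aa}K_{aa} + I$, both $\beta$ and $\sigma^2$
profile out in closed form, leaving a two-parameter restricted
log-likelihood

$$L = -\tfrac12\ln|C| - \tfrac12\ln|X^TC^{-1}X|
      - \tfrac{n-1}{2}\ln\hat\sigma^2 - \tfrac{n-1}{2}.$$

A printed form of this likelihood elsewhere carries the $\ln\sigma^2$ term
with a positive sign, which would make the criterion unbounded; `episcan`
implements the standard (maximizable) profiled REML above and verifies it
in tests against an independent, unprofiled evaluation that plugs
$V = C\hat\sigma^2$ and $\hat\beta$ into the full restricted likelihood.

**Optimization.** Derivative-free Nelder–Mead over
$(\ln\lambda_a, \ln\lambda_{aa})$, five restarts from
$\{(0.01,0.01), (1,1), (10,0.1), (0.1,10), (5,5)\}$, box
$[10^{-6}, 10^{6}]$ on each ratio, convergence tolerance $10^{-9}$ on the
log-likelihood. The surface is cheap at $n$ of a few hundred (one Cholesky
per evaluation) and occasionally multimodal, hence the restarts. Ratios
that end on the lower box bound are reported as exactly 0 with a boundary
flag. Tests require the optimum to dominate a $21\times21$ grid over
$[0,100]^2$.

Variance fractions are $\sigma_x^2 / (\sigma_a^2+\sigma_{aa}^2+\sigma^2)$
and broad-sense heritability is $H = \mathrm{ratio}_a +
\mathrm{ratio}_{aa}$, the model-explained share of phenotypic variance.

## 1D and 2D scanning

After REML the ratios are **fixed** — they are never re-estimated per
marker or pair — so every scan fit shares the covariance
$(H_\lambda + I)\sigma^2$ with
$H_\lambda = \lambda_aK_a + \lambda_{aa}K_{aa}$. One eigen-decomposition
$H_\lambda = UDU^T$ converts each generalized-least-squares fit into
weighted least squares in rotated coordinates: weights
$1/(\delta_i + 1)$, trait $y^* = U^Ty$, design $P^* = U^TP$. Designs are
$[1\,|\,Z_i]$ (model I) and $[1\,|\,Z_i\,|\,Z_j\,|\,W_{ij}]$ (model II);
the focal coefficient is tested with the 1-df Wald statistic
$\hat\theta^2/\mathrm{var}(\hat\theta)$ against $\chi^2_1$. The design
rank ($r(P) = 2$ or $4$) enters only the residual degrees of freedom
$n - r(P)$, not the test's degrees of freedom.

Numerical choices:

* p-values are floored at $10^{-300}$ so $-\log_{10}(p)$ is always finite;
* designs with normal-matrix condition number above $10^{12}$ (constant
  markers, duplicated markers, constant pair products under $\pm1$ coding)
  yield `status = "singular"` rows — the scan continues, and thresholded
  outputs exclude them;
* pairs are enumerated row-major with $i<j$; each pair product is rotated
  individually, so the `chunk_size` argument batches output assembly only
  and results are bit-identical for every chunk size (the deterministic
  chunking contract — chunk-parallel or distributed execution is out of
  scope);
* dense 2D output is capped at $m \le 2000$ markers; larger panels must
  set a `store_threshold`, which materializes only pairs at or above that
  $-\log_{10}(p)$;
* the polygenic covariance always uses the full $H_\lambda$, including the
  tested marker's own contribution, as the scan equations imply.

The eigen path is verified everywhere against a direct dense
$(H_\lambda+I)^{-1}$ GLS oracle to $10^{-8}$, and the identity-weight limit
against ordinary least squares.

## Predictability (PRED / PRESS)

Each transcript or metabolite $w$ is treated as an intermediate phenotype
and scored by leave-one-out predictability from genotype:
$\mathrm{PRED} = 1 - \mathrm{PRESS}/\mathrm{SS}$. Writing $C = H_\lambda + I$
and the REML projection
$Q = C^{-1} - C^{-1}X(X^TC^{-1}X)^{-1}X^TC^{-1}$, the BLUP-inclusive
smoother $S$ (fitted values = fixed effect + BLUP genetic values) satisfies
$I - S = Q$, and the leverage-corrected residual
$(w_i - \hat w_i)/(1 - S_{ii}) = (Qw)_i / Q_{ii}$ is *exactly* the
leave-one-out residual in which $\beta$ is refit and the held-out
individual is BLUP-predicted from the rest — at fixed ratios. The test
suite confirms this against $n$ explicit refits to $10^{-6}$.

Design choices here: the smoother includes the BLUP part by default (a
fixed-effect-only hat matrix would ignore the genetic prediction that is
the point of the score); ratios are re-estimated by REML per intermediate
marker by default, with a fast mode that reuses fixed ratios (used in the
tests, flagged approximate); both kinship components enter by default,
with an `additive_only` flag. PRED can be negative — the model predicting
worse than the mean — and is reported unclamped; it is bounded above
by 1. The heritability-vs-threshold curve (`pred_threshold_curve()`)
rebuilds both kinships from each selected subset and re-runs REML, so its
$H$ values are genuine re-fits, not interpolations.

## Synthetic data: what it emulates and what it does not

`simulate_ril_genotypes()` emulates recombinant-inbred-line bin genotypes:
per individual and chromosome a two-state $\{-1,+1\}$ Markov chain with
transition probability `switch_prob` (default 0.1, i.e., expected LD-block
length of 10 markers — a realistic bin-level linkage scale for an RIL
cross; 0.5 gives independent markers). `simulate_quantitative_markers()`
emulates log2 expression/abundance panels as standardized Gaussian rows
with optional within-block correlation. `simulate_trait()` draws causal
sets uniformly and effects from the model's normals at the per-effect
variance $\sigma_x^2/d$ implied by the trace normalizer of the causal set;
by default each component is then rescaled so its realized sample variance
hits the target exactly (`scale_exact = TRUE`), because parameter-recovery
tests need controlled truth; the raw-draw mode remains behind the flag.

What the generator does **not** emulate: coalescent-grade population
structure, genotyping error, microarray/mass-spectrometry noise and batch
effects, or upstream preprocessing (replicate averaging, normalization).
Passing tests therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not robustness to real-data
artifacts.

## Problem sizes used in the checks

The package's own verification uses simulation scales chosen to make each
check informative: oracle equivalences on panels up to $m = 50$,
$n = 40$; REML recovery at $n = 300$, $m = 200$ with target fractions
$(0.4, 0.3, 0.3)$ averaged over 20 seeds (tolerance $\pm 0.1$); null
calibration with $n = 400$, $m = 20$ and 200 replicates. The
null-calibration sample size is deliberately large: with $\sim 400$
residual degrees of freedom the $\chi^2_1$ reference for the squared
$t$-statistic is accurate to about $6\times10^{-4}$ at $\alpha = 0.05$, so
the check measures the implementation rather than the small-sample
$t$-vs-$\chi^2$ gap.

## Known limitations

* Two variance components beside the residual; no dominance or
  higher-order interaction kinships, no covariates beyond the intercept.
* No multiple-testing correction is built in: thresholds on
  $-\log_{10}(p)$ (default 3.0, i.e., $p = 0.001$) are descriptive
  conventions, not family-wise guarantees.
* Standard errors / likelihood-ratio tests for the variance components
  themselves are not provided.
* Dense 2D storage is quadratic in $m$; very large panels require the
  sparse thresholded mode.
* REML and the scans are exact only under the fixed-ratio plug-in: the
  uncertainty of $\hat\lambda$ is not propagated into the scan p-values
  (the usual two-stage mixed-model approximation).
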