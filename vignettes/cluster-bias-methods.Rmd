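---
title: "Multilevel factor models and the test for cluster bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel factor models and the test for cluster bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterbias)
```

## The model

Observations are continuous indicator vectors $y_{ijk}$ (student $i$ in
class $j$ in school $k$, $p$ indicators). The package works with the
random-effects decomposition

$$y_{ijk} = \mu + u_k + v_{jk} + e_{ijk}, \qquad
\mathrm{cov}(u) = \Sigma_3,\;
\mathrm{cov}(v) = \Sigma_2,\;
\mathrm{cov}(e) = \Sigma_1,$$

with all components independent multivariate normal, so the total
covariance is $\Sigma_3 + \Sigma_2 + \Sigma_1$. Each level carries a linear
factor structure $\Sigma_m = \Lambda_m \Phi_m \Lambda_m' + \Theta_m$ with
diagonal $\Theta_m$. Strong factorial invariance across clusters at level
$m$ means the loadings are equal across levels and $\Theta_m = 0$: the
common factor is the only source of variance at that level. Conversely,
nonzero higher-level residual variance is structural by construction —
random measurement error averages out within clusters (up to $O(1/n)$
aggregation noise in very small clusters) — so it is read as measurement
bias with respect to some variable at that level. The test cannot say
*which* variable, and it cannot distinguish a violation of strong
invariance (unequal intercepts) from a violation of weak invariance
(unequal loadings): both surface as higher-level residual variance.

## Model specifications

Specifications are pattern matrices: every entry of
$\Lambda_m, \Phi_m, \Theta_m$ and the intercept vector is either fixed at a
value or free with a label; shared labels impose equality, and cross-level
loading equality is one shared label per indicator. Degrees of freedom are
counted against $p + L\,p(p+1)/2$ sample moments ($p$ means plus one
covariance matrix per level).

`build_cluster_bias_models()` encodes the testing sequence:

* **Baseline**: one common factor, loadings label-tied across levels,
  residual variances free everywhere, intercepts free (the mean structure
  is saturated and never constrained).
* **Level-2 constrained**: all $p$ Level-2 residual variances fixed at 0.
* **Level-3 constrained**: all $p$ Level-3 residual variances fixed at 0,
  Level-2 residuals free.

**Identification.** The common-factor variance is fixed at 1 at Level 1 and
free at Levels 2–3. The alternative — fixing the first loading at 1 and
freeing all factor variances — is available via
`identification = "first_loading"`; both give the same fit and df, and the
factor-variance convention keeps the latent intraclass correlations
directly interpretable because cross-level loading equality already puts
the factor on one scale at every level.

**Doublet factors.** A residual covariance between two indicators cannot
be expressed at higher levels when $\Theta_m$ is diagonal, so a shared
specific component is reparameterized as an extra orthogonal factor with
both loadings fixed at 1 and a free variance at every level — the variance
estimate equals the residual covariance it replaces. The constrained models
keep doublet variances free: only the $p$ unique residual variances are
zeroed, which is why each constraint step costs exactly $p$ df.

The saturated model (unstructured $\mu$ and $\Sigma_m$ per level, df 0) and
the independence model (diagonal $\Sigma_m$, free means) are expressed in
the same pattern language ($\Lambda = I$ with full free symmetric $\Phi_m$,
resp. $\Lambda = 0$ with free diagonal $\Theta_m$), so one engine fits all
models.

## The likelihood and its exact reduction

The log-likelihood is the exact joint normal log-density of all $Np$
observations, constant included. Rather than assembling each school's full
stacked covariance matrix, the engine splits each class orthogonally into
within-class contrasts and its mean. The $N - C$ contrast vectors are
i.i.d. $N(0, \Sigma_1)$ and enter only through the pooled within-class
scatter $S_W$:

$$\ell_{\text{within}} = -\tfrac12\left[(N-C)\,p\log 2\pi +
(N-C)\log|\Sigma_1| + \mathrm{tr}(\Sigma_1^{-1} S_W)\right].$$

The class means $\bar y_{jk}$ of one school are jointly normal with
covariance $\mathrm{blockdiag}_j(\Sigma_2 + \Sigma_1/n_j) + \mathbf{1}
\mathbf{1}' \otimes \Sigma_3$, and a Jacobian term
$-\tfrac{p}{2}\sum_j \log n_j$ returns the mean-vector density to raw-data
scale. The reduction is lossless: the test suite holds the structured value
to the brute-force stacked-normal density within $10^{-8}$ on a battery of
random unbalanced instances, and the sufficient statistics
(`compute_sufficient_stats()`) are computed once per dataset. Schools are
grouped by their multiset of class sizes so the mean-part Cholesky factor
is computed once per group — in balanced designs, once per likelihood
evaluation. Two-level data are the special case where every class is its
own top-level cluster and $\Sigma_3 = 0$; with $\Sigma_3 = 0$ the
three-level likelihood provably collapses to the two-level one, which the
suite also checks.

## Optimization and standard errors

`fit_ml()` maximizes the likelihood with L-BFGS-B under nonnegativity
bounds on all variances, using analytic gradients: the derivative with
respect to each $\Sigma_m$ is accumulated from the within part and the
per-school mean part, then chained through
$\partial\Sigma_m/\partial(\Lambda, \Phi, \Theta)$ and summed over
equality-tied slots. The gradient is verified against central differences
in the tests.

* **Start values** come from a moment decomposition: $S_W/(N-C)$ for
  Level 1, covariance of class means minus the within-level sampling share
  for Level 2, covariance of school means similarly for Level 3, floored at
  positive semidefinite; loadings start at half the Level-1 diagonal.
* **Convergence**: relative likelihood change about $2\times10^{-9}$
  (`factr = 1e7`), projected gradient tolerance $10^{-5}$, at most 500
  iterations. A failed attempt triggers up to three restarts with
  seed-controlled multiplicative jitter (default seed 0), after which the
  fit is returned with `converged = FALSE` — nonconvergence is surfaced,
  never patched over. The saturated top-level covariance is the typical
  victim when there are few schools; the report marks the affected
  comparisons unavailable instead of substituting a corrected statistic.
* **Non-PD excursions** during line search are handled by returning a
  large penalty scaled by the eigenvalue violation; bounds and
  moment-based starts keep the optimum itself interior or exactly on the
  variance boundary.
* **Standard errors** invert the observed information, obtained by central
  differences of the analytic gradient at the optimum (one-sided next to a
  bound). Parameters pinned at zero are flagged `boundary` and excluded:
  a Wald statistic has no standard null distribution there.

## The testing sequence and the boundary caveat

`cluster_bias_test()` fits the five models and assembles: a fit table
(chi-square against the saturated model, RMSEA, CFI), the two difference
tests with verdicts at the configured `alpha` (default 0.05), per-indicator
Wald tests of the higher-level residual variances, bias proportions, and
latent plus observed intraclass correlations. Both constrained models are
compared against the baseline, so each difference test has $\Delta df = p$.

Zeroing a variance places the null hypothesis on the boundary of the
parameter space, so the likelihood-ratio statistic is asymptotically a
mixture of chi-squares, not the central $\chi^2_p$ used here. Deriving the
mixture weights for $p$ simultaneous variance restrictions in an unbalanced
three-level design is out of scope; the central reference is used
deliberately, every affected result carries a conservativeness note, and
the package quantifies the effect instead: under the bundled null
simulation the Level-3 test rejects far below nominal (about 0–2% at
nominal 5% with 200 replicates). A conservative test loses power, not
validity — detected bias stands, absence of detection is weaker evidence.

**Fit-index conventions** (both deliberate, both recorded in the report):
$N$ in the RMSEA is the total number of Level-1 units, which reproduces the
customary single-number summary in multilevel software output; the CFI
baseline is the independence model at every level with free means.

## Interpretive summaries

With loadings equal across levels the factor variances $\phi_1, \phi_2,
\phi_3$ are on one scale, and `factor_icc()` returns
$\phi_m / (\phi_1 + \phi_2 + \phi_3)$ — the share of construct variance at
each clustering level. `observed_icc()` gives the analogous per-indicator
shares from the level-wise covariance diagonals. `bias_proportions()`
divides each indicator's higher-level residual variance by the
model-implied variance at that level (common factor + doublet + residual)
and by the implied total, quantifying how much of the cluster-level
variation in an indicator is bias rather than construct.

## The simulator and the Monte-Carlo harnesses

`simulate_dataset()` draws data exactly from the generative model: factor
components per student/class/school, doublet components, and level-wise
residuals, with fixed or distribution-drawn (unbalanced) cluster sizes.
`design_implied_sigma()` exposes the targeted level-wise covariance
matrices; the tests verify empirical convergence to them.

The default design — 50 schools × 3 classes × 10 students, $p = 4$,
loadings 0.7, $\phi = (1, 0.3, 0.1)$, Level-1 residual variance 0.5,
no higher-level residuals — is a deliberately modest cohort: class- and
school-level factor ICCs around 0.21 and 0.07, squarely in the range seen
in educational screening instruments, and few enough top-level clusters
that the power limitations the method faces in practice are visible rather
than assumed away. Bias is injected either as higher-level residual
variance (a strong-invariance violation) or as a per-class loading
perturbation (`loading_sd2`, a weak-invariance violation); the test flags
both the same way, which is a property of the method, not a defect of the
generator.

`type1_error_study()` and `power_study()` spawn per-replicate seeds from a
master seed, fit the baseline and constrained model per replicate, and
report rejection rates with Monte-Carlo standard errors
$\sqrt{r(1-r)/M}$; runs are reproducible bit-for-bit and flagged
unreliable above 20% nonconvergence.

What the generator does *not* emulate: non-normal or categorical
indicators, missing indicator values, informative cluster sizes, crossed
(non-nested) classifications, and real instruments' idiosyncratic residual
structure beyond explicit doublets. Passing simulation studies therefore
establish the engine's correctness under the model's own assumptions, not
robustness to their violation.

## Problem sizes

The test suite works at deliberately small scales: oracle checks on 3-school
unbalanced toys, recovery at 60–200 schools, Monte-Carlo blocks of 6–200
replicates; the full suite runs in well under a minute and the acceptance
script in under one. Parameter recovery at 200 schools × 4 classes × 25
students returns loadings within 0.05 of truth; a single fit at that size
takes a fraction of a second thanks to the sufficient-statistic reduction.

## Known limitations

* Complete-case handling of missing indicator values; the full information
  in "FIML" refers to the multilevel structure, not item missingness.
* No sandwich/robust corrections, no chi-bar-square mixture p-values, no
  modification indices, no categorical indicators, at most three levels,
  strictly nested classifications.
* The method tests strong invariance globally per level; it cannot
  attribute detected bias to specific intercept or loading differences,
  and with few top-level clusters its power at that level is low.
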