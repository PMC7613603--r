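---
title: "Pairwise joint modelling of clustered binary care indicators with multilevel multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise joint modelling of clustered binary care indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairjmm)
```

## The problem

Quality-of-care audits record, for every admission, a vector of binary
indicators — was the respiratory rate documented, was oxygen saturation
measured, was the correct antibiotic dose prescribed — and those indicators
are correlated because the same clinician admits many patients. The setting
this package emulates is a cluster-randomized audit-and-feedback trial in 12
hospitals: about 378 admitting clinicians, about 2 127 analyzable pediatric
pneumonia admissions, nine binary indicators spanning assessment, diagnosis
and treatment, and partially observed covariates at two levels of the
hierarchy (patient sex in under 1% of records; clinician sex and cadre in
about 22% of clinicians, almost always missing together).

Two questions need a *joint* model: does a covariate affect all nine
indicators simultaneously, and how strongly are the indicators associated
with one another at the clinician level? Nine separate logistic mixed models
answer neither.

## The joint model and the pairwise route

For outcome $r$ of patient $i$ under clinician $j$, the analysis model is a
logistic random-intercept regression

$$\operatorname{logit} P(Y_{rij} = 1) = \mathbf{x}_{ij}'\boldsymbol\beta_r + b_{rj},$$

with the thirteen fixed-effect terms: intercept, infant age group, patient
sex, three comorbidity-count contrasts (0/1/2 versus 3+), clinician cadre,
clinician sex, hospital admission workload, hospital malaria endemicity,
follow-up time in months, trial arm, and the arm-by-time interaction. The
joint model ties the outcomes together through the clinician intercepts,
$\mathbf{b}_j = (b_{1j}, \dots, b_{pj})' \sim N(\mathbf{0}, \mathbf{D})$, with
outcomes conditionally independent given $\mathbf{b}_j$. The scaled
off-diagonals of $\mathbf{D}$ are the between-outcome associations.

A direct nine-dimensional fit needs a 9-dimensional integral per clinician
and a 126-parameter optimization, which is what the pairwise strategy
avoids: fit all $Q = p(p-1)/2$ bivariate models (36 for $p = 9$) by maximum
likelihood, stack the per-pair parameter vectors
($36 \times 26 = 936$ fixed effects), and average the $p-1$ duplicate copies
of each coefficient with a weight matrix $\mathbf{A}$ whose nonzero entries
are $1/(p-1)$: $\boldsymbol\beta^* = \mathbf{A}\hat{\boldsymbol\beta}$,
117 combined coefficients. Equal weights are used; the product of pairwise
likelihoods is a pseudo-likelihood, so the stacked estimator is consistent
and asymptotically normal with a sandwich covariance
$\mathbf{H}^{-1}\mathbf{G}\mathbf{H}^{-1}$. `pairjmm` builds
$\mathbf{H}$ block-diagonally from the per-pair observed-information
matrices and $\mathbf{G}$ from per-clinician score vectors concatenated
across pairs — the cross-pair blocks of $\mathbf{G}$ are exactly what carries
the dependence between pairs sharing an outcome. In finite-sample form the
covariance of the stacked estimate is
$(\sum_j \mathbf{H}_j)^{-1} (\sum_j \mathbf{g}_j \mathbf{g}_j') (\sum_j \mathbf{H}_j)^{-1}$,
and $\boldsymbol\Sigma^* = \mathbf{A}\,\widehat{\mathrm{Var}}\,\mathbf{A}'$.

A second covariance engine, `sandwich_printed_recipe()`, implements verbatim a
printed four-step recipe in which the middle matrix is
$\mathbf{T} = \mathbf{Z}\mathbf{D}\mathbf{Z}'$ with no inverse and no
Bernoulli-variance term. As written, that $\mathbf{J} = \sum_i
\mathbf{X}_i'\mathbf{T}_i\mathbf{X}_i$ is not an information-matrix
analogue (and is exactly singular when $\mathbf{D} = 0$). The engine is kept
behind a flag, warns on use, and exists for comparability only; the
empirical cluster sandwich is the default and is the one validated by the
coverage experiments below.

### Maximum likelihood by adaptive quadrature

Each bivariate (or univariate, or the trivariate testing oracle) likelihood
integrates the random intercepts out with adaptive Gauss–Hermite quadrature:
per cluster, a damped Newton search finds the conditional mode of
$\mathbf{b}_j$, the integrand is re-centred and re-scaled by the mode and
curvature, and a tensor grid of Hermite nodes is applied (15 nodes per
dimension by default — where the log-likelihood at the optimum differs from
the 25-node value by well under $10^{-4}$ — and 3 per dimension in the
replicate studies below, where the adaptive recentring carries the accuracy
and hundreds of fits are needed). The per-cluster score is computed on the same grid through the
posterior-expectation identity
$\nabla_\theta \log L_j = E[\nabla_\theta \log f(\mathbf{y}, \mathbf{b})
\mid \mathbf{y}]$. Because the identity is exact only under exact
integration, the optimizer finishes with Newton steps that solve the score
equation itself (step-halving on the score max-norm), and convergence is
declared when $\max|\text{score}|/J < 10^{-5}$, $J$ the number of clusters.

Other numerical choices, all surfaced in the code:

* $\mathbf{D}$ is parameterized by its log-Cholesky factor, so any iterate
  is a valid covariance; a soft box $|\log L_{rr}| \le 4$ bounds the
  variances to roughly $[3 \times 10^{-4}, 3 \times 10^{3}]$ — far outside
  any plausible log-odds-scale heterogeneity — which keeps the information
  matrix conditioned when a variance collapses. Fixed effects are bounded
  to $|\beta| \le 10$ on the log-odds scale (odds ratios beyond $2 \times
  10^4$) so that a separated cell in a small dataset parks at the bound
  instead of running away along a flat likelihood. Boundary solutions
  (variance at the floor, $|\rho| \to 1$ — e.g. when an outcome is paired
  with itself — or a coefficient at the bound) are *flagged*, never
  silently repaired.
* Starting values: outcome-wise plain logistic regressions, variances 0.5,
  covariance 0. The pipeline warm-starts each pair's fit in imputed dataset
  $m$ from the complete-case solution of the same pair.
* Total and per-cluster Hessians are central finite differences of the
  (analytic) score with step $10^{-5}(1 + |\theta|)$.
* A boundary fit has a singular information matrix in the collapsed
  direction. `sandwich_empirical()` refuses singular input by default
  (reporting the condition number); with `singular = "pseudo"` — the
  pipeline's setting — the pair's information is inverted on its
  non-degenerate eigenspace, which leaves the fixed-effect inference intact
  and keeps one degenerate pair from aborting an entire multiply-imputed
  analysis.

## Multiple imputation

Missing covariates are handled by a two-level latent-normal joint model: a
binary variable is the sign of an underlying normal variable. Patient-level
latents follow
$Y^{(1)*}_{ij} = \mathbf{x}^{(1)\prime}_{ij}\boldsymbol\beta^{(1)} + b^{(1)}_{j} + e_{ij}$,
$e_{ij} \sim N(0, 1)$ (residual variance fixed at 1 for probit-style
identifiability), and clinician-level latents follow
$Y^{(2)*}_{j} = \mathbf{x}^{(2)\prime}_{j}\boldsymbol\beta^{(2)} + b^{(2)}_{j}$
with no separate residual — the level-2 variability is carried entirely by
$b^{(2)}_{j}$, which is how the emulated study states the model and how it
is implemented here. All clinician effects
$(b^{(1)}_j, b^{(2)}_j) \sim N(\mathbf{0}, \boldsymbol\Sigma_b)$ jointly,
which is what lets the fully observed outcomes and covariates inform the
imputations: the nine outcomes enter the level-1 predictors directly and the
level-2 predictors as cluster means (the aggregation is not stated in the
source; cluster means are the standard choice).

The Gibbs sampler alternates truncated-normal draws of the latents
(observed categories constrain the sign; missing cells are drawn free and
thresholded at zero at imputation time), conjugate normal updates of
$\boldsymbol\beta^{(1)}$ and $\boldsymbol\beta^{(2)}$ (flat priors), normal
updates of the clinician effects, and an inverse-Wishart update of
$\boldsymbol\Sigma_b$ (identity scale, $d + 1$ degrees of freedom — the
source does not print priors; these are the minimal proper defaults).
Completed datasets are drawn at iterations
$\text{burn-in}, \text{burn-in} + \text{between}, \dots$; the study-scale
setting is $M = 20$, burn-in 500, 500 between (draws at 500, 1000, …,
10000). Observed cells are never altered, the first $M'$ draws do not
depend on $M > M'$, and `convergence_report()` emits per-parameter traces,
lag-1 autocorrelations and drift flags for the usual visual assessment.

The analysis model treats the four-level cadre variable collapsed to two
cadres (clinical versus medical officers), so the generator emits and the
imputation model sees a binary cadre; a multinomial-probit extension
(K−1 latents) would be needed only for an uncollapsed analysis and is not
implemented.

Per completed dataset the full pairwise analysis runs unchanged; Rubin's
rules pool the $M$ combined vectors: $\bar{\boldsymbol\beta}$ the mean,
$\mathbf{W}$ the mean covariance, $\mathbf{B}$ the between-imputation
covariance (full matrix, divisor $M-1$), total
$\mathbf{V} = \mathbf{W} + (1 + 1/M)\mathbf{B}$.

## Joint Wald tests

The joint null that one term is zero in all $p$ outcomes uses the selector
contrast $\mathbf{L}$ (one 1 per row) and
$(\mathbf{L}\boldsymbol\beta)'(\mathbf{L}\mathbf{V}\mathbf{L}')^{-1}
(\mathbf{L}\boldsymbol\beta) \sim \chi^2_p$ — nine degrees of freedom in the
nine-outcome configuration. No small-sample or
between-imputation degrees-of-freedom adjustment is applied, and no
multiplicity correction across the per-term tests, matching the emulated
analysis; both are noted limitations. The comorbidity covariate has three
contrasts, so a one-row-per-outcome selector cannot test it jointly;
`build_L()` follows the one-coefficient convention and the report's
comorbidity row stacks the three selectors (27 degrees of freedom).

## Association and PCA

`assemble_D()` rebuilds the $9 \times 9$ $\mathbf{D}$: each variance is the
mean of its $p-1$ pairwise estimates, each covariance comes from its unique
pair, with per-cell provenance recorded. Assembly does not guarantee
positive semidefiniteness — the shipped published matrices are in fact
indefinite — so negative eigenvalues are flagged, proportions are still
reported against the trace, and no nearest-PSD projection is applied unless
requested. Correlations are $\sigma_{b_rb_s}/\sqrt{\sigma^2_{b_r}
\sigma^2_{b_s}}$, emitted in the variance-diagonal/correlation-lower-triangle
layout.

`pca_correlation()` offers two conventions. `"direct"` eigendecomposes the
correlation matrix (eigenvalues sum to $p$; component $r$ explains
$\lambda_r/p$). `"column"` treats the correlation matrix as a data matrix —
each outcome's row of correlations is an observation — and runs a
column-standardized PCA. The reported variation percentages of the emulated
study (57.6%/24.6% complete-case, 60.3%/26.2% after imputation) are
reproduced by the `"column"` convention (57.6/24.6 exactly; 61.1/25.9 for
the imputation matrix, inside table-rounding error), not by the direct
eigendecomposition (42.1/23.8), so the column convention is what the
reproduction checks use. The direct convention remains the default because
it is the standard definition of PCA on a correlation matrix. Loadings are
eigenvectors scaled by $\sqrt\lambda$, signs fixed so each component's
largest-magnitude loading is positive.

## The synthetic-data generator

The trial's raw data are not public, so the generator reproduces the
printed structure, and its defaults *are* the study conditions:

* 12 hospitals, half in the intervention arm, 5 of 12 in high-malaria
  regions, half high-workload; clinicians per hospital from a shifted
  negative binomial with mean 32; patients per clinician from a shifted
  negative binomial with mean 5.63 bounded to [3, 46] (the printed mean and
  range; the true distributions are not printed).
* Covariate marginals as printed: infants 42.5%, male patients 55.1%,
  comorbidity counts 46.8/29.8/17.9/5.5%, clinical officers 64.4% (after
  collapsing), female clinicians 43.2%. Covariates are sampled
  independently within level — the joint distribution (e.g. cadre by
  hospital) is not printed, so independence is assumed. Admission time is
  uniform over 0–8 months (the trial ran nine calendar months; the
  admission-time distribution is not printed).
* One intercept vector $\mathbf{b}_j \sim N(\mathbf{0}, \mathbf{D})$ per
  clinician; $\mathbf{D}$ defaults to the published after-imputation
  variance-correlation matrix converted to covariance and eigenvalue-clipped
  to the nearest PSD matrix (the assembled published matrix is slightly
  indefinite; the clip changes no diagonal entry by more than 0.03).
* Fixed-effect intercepts are calibrated (by integrating over the covariate
  distribution and the random intercept) so marginal prevalences match the
  printed documentation/adherence rates — respiratory rate 88.8%, oxygen
  saturation 61.0%, correct diagnosis 69.3%, correct prescription 48.7%,
  correct dose 24.6%; rates not printed (cough, difficult breathing, AVPU,
  indrawing) are set to plausible high-documentation values (97/95/85/80%).
  Covariate effects are modest common values, with a +0.15 log-odds/month
  arm-by-time interaction for the six indicators the study found to improve
  and zero for the other three.
* Missingness defaults: MCAR at the printed rates (patient sex 17/2127,
  clinician sex 83/378, cadre 82/378) with
  $P(\text{sex missing} \mid \text{cadre missing}) = 0.95$; a MAR option
  makes missingness logistic in stated fully observed covariates with the
  intercept calibrated to the marginal rate. A share 172/2299 of records
  lacks a clinician identifier and is removed by the exclusion filter,
  which reports `172/2299 (7.5%)`-style labels.

What the generator does *not* emulate: the raw clinical measurements and
the coding rules that derive the indicators (doses, weights, respiratory
rates — indicators are generated directly as Bernoulli draws), hospital-level
random effects (the analysis model has none), dependence between covariates,
and any outcome-side missingness (the indicators are fully observed in the
emulated study). Passing tests on this generator therefore validates the
*estimation machinery* under the stated hierarchy, effect sizes and
missingness — not the clinical coding pipeline of real audit data.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
quadrature against brute-force Monte-Carlo integration ($10^6$ draws on a
5-cluster fixture), degenerate reductions against closed forms and `glm()`,
the single-pair sandwich against the directly computed cluster-robust
sandwich, the printed-recipe sandwich against a hand-materialized matrix
oracle, pooling and weight-matrix arithmetic against hand fixtures to
$10^{-12}$. The replicate studies use sizes chosen to finish in minutes on
one core, and are stated here as the package's validation conditions:

* *Oracle equivalence*: 30 replicates, 3 outcomes, 200 clusters × 8
  patients; the pairwise-combined estimates agree with the full-joint MLE
  within 3 empirical standard errors per coefficient, and the mean
  pairwise-vs-joint gap is under half the sampling SD (the small-efficiency-
  loss property of the pairwise route).
* *Recovery and SE calibration*: 50 replicates, 100 clusters × 10 patients;
  bias within 3 empirical SEs, sandwich SEs within 20% of the empirical
  sampling SDs.
* *Imputation calibration*: 100 replicates of a 3-outcome trial
  (6 hospitals, ~55 clinicians, ~270 patients), clinician sex and cadre
  ~22% MAR in workload, $M = 5$ with a shortened chain (burn-in 60, 15
  between); pooled 95% intervals cover the generating coefficients at a
  rate inside [0.90, 0.98], and the mean pooled SE on the
  missingness-affected covariates is no larger than the complete-case mean
  SE — the qualitative precision gain of imputation. Replicates whose
  complete-case design is inestimable (a small hospital losing every
  clinician to covariate missingness) are redrawn deterministically —
  estimability is a design restriction of the study, and such redraws are
  rare (a few per hundred).

## Known limitations

* MAR is assumed and untestable from observed data; no MNAR sensitivity
  analysis is provided.
* Wald tests use $\chi^2$ reference distributions without small-sample df
  corrections; with 12 hospitals the hospital-level covariate tests are
  optimistic.
* The assembled $\mathbf{D}$ can be indefinite; it is reported as assembled.
* Random intercepts only (no random slopes, no hospital level), logit link
  only, binary outcomes only.
* Multiple outputation, an alternative to pairwise fitting, is not
  implemented.
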