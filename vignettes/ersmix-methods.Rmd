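---
title: "Mixture random-effect IRT models for extreme response style: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture random-effect IRT models for extreme response style: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Self-report instruments with Likert-type items are vulnerable to *response
styles*: stable respondent tendencies to use the rating scale itself in a
particular way, independent of item content.  Two styles matter most in
practice: extreme response style (ERS), a preference for the endpoint
categories, and its opposite, mild response style (MRS), a preference for
the middle categories.  Left unmodelled, response styles contaminate the
estimated trait, spuriously violate measurement invariance, and distort
rank orders of respondents.

`ersmix` implements a family of models that address this by combining two
devices:

1. a **person-level threshold weight** $\omega_n > 0$ that contracts
   ($\omega < 1$, ERS) or expands ($\omega > 1$, MRS) the distances
   between category thresholds, quantifying each respondent's style on a
   continuum; and
2. **finite mixtures of latent classes** (normal / ERS / MRS), each with
   its own set of item difficulties, so that latent differential item
   functioning (DIF) induced by response style can be detected at the
   same time.

## The model family

All models are adjacent-category logit models.  Categories are scored
$0,\dots,J-1$ internally (file formats use $1..J$).  The generalized
partial credit model (GPCM) is the base:

$$\log\frac{P_{nij}}{P_{ni(j-1)}} = \alpha_i \theta_n - (\beta_i + \tau_{ij}).$$

The ERS-GPCM multiplies the thresholds by the person weight,
$\alpha_i\theta_n - (\beta_i + \omega_n \tau_{ij})$, with
$\log\omega_n \sim N(0, \sigma^2_\omega)$.  The mixture ERS-GPCM adds
latent classes $g$ with class-specific overall difficulties $\beta_{ig}$
and class-specific latent distributions
$\theta_{ng} \sim N(\mu_{\theta g}, \sigma^2_{\theta g})$,
$\log\omega_{ng} \sim N(\mu_{\omega g}, \sigma^2_{\omega g})$.

A fully general version with free item discriminations on the style
dimension, $\alpha_{i1}\theta - (\beta_{ig} + \alpha_{i2}\,\omega\,\tau_{ij})$,
is **not identifiable** (three multiplied parameter types) and is provided
only as documentation.  The identifiable *constrained-discrimination* (CD)
variant fixes the total discriminating power at a multidimensional
discrimination parameter (MDP) shared by the items of a subscale and
splits it on a circle:

$$\alpha_{i2} = \sqrt{\mathrm{MDP}^2 - \alpha_{i1}^2}, \qquad
  \eta_{ni} = \exp\!\big(\alpha_{i2}\log\omega_n\big) = \omega_n^{\alpha_{i2}},$$

so the effective weight on item $i$'s thresholds is $\eta_{ni}$ rather
than $\omega_n$.  An item with $\alpha_{i2}$ near zero is immune to
response style ($\eta \approx 1$ for every $\omega$): $\alpha_{i2}$ is
therefore an *ERS-elicitation score* for the item
(`item_ers_elicitation()`).  For example, with $\alpha_{i2} = 0.2$,
respondents with $\omega = 0.5$, $1$, $1.5$ have
$\eta = 0.87, 1.00, 1.08$: the style effect is strongly damped.

Multidimensional versions assign each item to one subscale; a common
$\omega_n$ is shared across subscales (styles are content-independent by
assumption).  Restrictions produce the usual submodels: common thresholds
(GRSM), unit discriminations (PCM), or both (RSM); see
`restrict_model()`.

### Identification

* Normal class (class 1): $\theta \sim N(0,1)$ and $\omega \equiv 1$.
* Mean item difficulty is zero within every class (common metric across
  classes, as in latent-DIF analysis).
* Thresholds sum to zero per item (the overall difficulty absorbs
  location).
* Mixing proportions keep the normal class dominant, and the ERS class's
  $\mu_\omega$ is kept below the MRS class's — together these pin the
  class labels and prevent label switching.

One notational wrinkle deserves a flag for users: in some statements of
the mixture model the trait distribution is written lognormal, while the
identification and all surrounding usage treat $\theta$ as normal.  This
package takes $\theta$ as **normal in every class**.

## Estimation

`fit_ersmix()` runs an adaptive Metropolis-within-Gibbs sampler with the
adjacent-category likelihood kernels in compiled code.  Priors (the
package defaults, `prior_spec()`):

| parameter | prior |
|---|---|
| difficulties $\beta_{ig}$, thresholds $\tau_{ij}$ | $N(0, 4)$ |
| discriminations $\alpha_{i}$, MDP | lognormal$(0, 1)$ |
| class trait means $\mu_{\theta g}$ | $N(0, 10)$ |
| class precisions | Gamma$(0.01, 0.01)$ |
| $\mu_{\omega g}$ (ERS / MRS) | $N(-0.5, 10)$ / $N(+0.5, 10)$ |
| class indicators | categorical, ordered mixing proportions |

The reference schedule is 15,000 iterations per chain with the first
5,000 discarded and three chains (`mcmc_config()`); proposal scales adapt
toward a 35% acceptance rate during burn-in only, so the post-burn-in
kernel is fixed and valid.

Design choices worth recording:

* **Explicit class indicators with a pseudo-prior.**  Because $\omega$ is
  exactly 1 in the normal class, the class-membership conditional is made
  a valid Gibbs step by giving every respondent a latent $\log\omega_n$
  at all times; under normal-class membership it follows a fixed
  two-component pseudo-prior (equal mixture of normals at the ERS and MRS
  prior centers, sd 0.6).  The pseudo-prior is a sampler device in the
  Carlin–Chib sense — it cancels from the posterior of everything else —
  but choosing it to cover the style-class range lets respondents move
  freely between classes.  Membership probabilities are Rao-Blackwellized
  averages of the per-draw conditional probabilities.
* **Hard constraints instead of post-hoc centering.**  The sum-to-zero
  difficulty and threshold identifications are maintained by paired
  proposals (a move on one element is mirrored on the last), so they hold
  exactly in every retained draw.  The dominance constraint on the mixing
  proportions is an independence Metropolis step (propose from the
  unconstrained Dirichlet conditional; reject violations), and the
  ERS-below-MRS ordering of $\mu_\omega$ is enforced with truncated
  conjugate draws.  Consequently no relabelling pass is needed and label
  switching cannot occur across or within chains.
* **Initialization.** Latent weights start from each respondent's
  observed endpoint-response rate (standardized, scaled by $-0.7$,
  clamped to $\pm 1.5$ on the log scale); classes start from the
  quartiles of that rate; class $\omega$ log-means start at the mean of
  their members' starting weights.  Mixture posteriors are multimodal,
  and a data-driven start plus multiple chains with the Brooks–Gelman
  diagnostic is the package's defence; a fit whose PSRF exceeds 1.10 is
  flagged with a warning, never silently accepted.
* **Numerical guards.**  All category probabilities use log-sum-exp
  normalization; class standard-deviation draws are clamped to
  $[0.03, 5]$ (an inert bound in any realistic fit, preventing transient
  degeneracy when a class is momentarily empty).
* **Convergence threshold.**  "Close to unity" is operationalized as
  multivariate PSRF $\le 1.10$, computed per parameter block
  (`psrf()`, `psrf_univariate()`).
* **EAP estimates** are marginal posterior means (person parameters
  average over class membership; the effective $\omega$ is 1 whenever the
  respondent sits in the normal class in a draw).  The spread of the
  marginal posterior is reported as the SE used by the naive
  $\pm 1.96$ screening rule.
* **Sample-size guard.**  Mixture fits warn below 1,000 respondents or 20
  items — with three latent classes and multiple person parameters,
  smaller designs recover poorly.

### Model comparison

`model_bic()` computes $-2\log L + k \log N$ with the observed-data
likelihood at the EAP structural estimates: class membership is summed
out and the person random effects are integrated by Gauss–Hermite
quadrature adapted to each class's latent distribution (15 nodes per
dimension; the subscale likelihoods factor given $\omega$, so
multidimensional models need only nested one-dimensional rules).  $k$
counts free structural parameters only — constrained elements (the last
difficulty per class, the last threshold per item, derived $\alpha_{i2}$)
are excluded.  For multidimensional mixtures the quadrature currently
uses the leading subscale's class hyper-parameters for all subscales; BIC
comparisons across multidimensional fits should be read with that
approximation in mind.

## The simulator and what it emulates

`sim_design()` defaults encode the recovery-study conditions this package
targets:

* three classes with proportions 0.50 / 0.25 / 0.25 (normal dominant);
* $\theta \sim N(0,1)$ in every class; $\omega = 1$ (normal),
  $\log\omega \sim N(-1, 0.4^2)$ (ERS, central 95.4% interval
  $0.17$–$0.82$) and $N(1, 0.4^2)$ (MRS);
* discriminations lognormal with meanlog 0 and sdlog 0.2.  (The
  parameterization with meanlog 1 is available via
  `alpha1_meanlog`; meanlog 0 is the default because it reproduces the
  reported draw range 0.62–1.45 and keeps $\alpha_1 \le \mathrm{MDP} =
  1.5$ feasible.  Note that $e^{1 \pm 0.8}$ would also be inconsistent
  with a printed MRS interval upper bound of 2.72; intervals are computed
  from the distributions, not copied.);
* normal-class difficulties uniform on $(-1.5, 1.5)$, centered; style
  classes shifted by $\pm 0.5$ with a random *balanced* sign assignment
  (half the items each way; for an odd item count the extra sign is drawn
  and the vector re-centered), so mean difficulty stays equal across
  classes;
* thresholds fixed at $(-0.6, 0, 0.6)$ for 4 categories and
  $(-0.8,-0.4,0,0.4,0.8)$ for 6;
* CD designs set MDP $= 1.5$ and derive $\alpha_{i2}$ from the split;
  discrimination draws at or above the MDP are redrawn.

What the simulator does **not** emulate: correlated $\theta$–$\omega$
(independence is assumed), item-content effects on style, missing data,
and within-person instability of style.  Passing recovery tests therefore
says the estimator works *when the model is true*; it does not validate
the model against violations of those assumptions.

## Problem sizes used in the test suite

The automated checks run the full simulate → fit → evaluate pipeline at
the reference condition $N = 1000$, $L = 20$, $J = 4$ together with
matched 6-category, 40-item, and $N = 500$ (paired subsample) conditions,
using two replications and a reduced smoke schedule of 1,500 iterations
(600 burn-in) with two chains.  At that schedule the suite asserts the
directional structure of the results — trait recovered better than
weight, more categories and longer tests better, smaller samples worse,
mixture classification beating the naive single-class $\pm 1.96$
screening by more than 0.1 — and checks the reference-condition means
(classification rate, trait and weight RMSE) within Monte-Carlo error of
the full-schedule values.  The $N = 500$ condition is deliberately
*paired* (the first 500 respondents of each replication) so the
sample-size comparison is not confounded by item-bank draws.

## Known limitations

* Multidimensional estimation treats latent dimensions as independent
  within class (the simulator can generate correlated traits; the fitted
  covariance is not estimated).
* The naive screening SE is the marginal posterior SD of $\omega$; with
  strong multimodality of membership this overstates certainty less than
  a conditional SD would, but it remains a convention.
* Smoke-length chains flag non-convergence by PSRF; publication-grade
  runs should use the reference schedule.
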