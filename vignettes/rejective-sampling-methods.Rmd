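---
title: "Rejective multi-phase sampling: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rejective multi-phase sampling: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tprs)
```

## The inferential setting

Everything in this package is design-based: a finite population of $N$ units
carries fixed values — a $p$-vector of auxiliaries $x_i$, a study variable
$y_i$, optionally a second tier $z_i$ — and the only randomness is the
sampling mechanism. The target is the finite-population mean
$\bar y_0 = N^{-1}\sum_i y_i$ (and, more generally, any parameter defined as
the root of a population-averaged estimating function).

Two-phase (double) sampling measures the cheap auxiliaries on a large
phase-I sample $A$ (size $n_I$) and the expensive study variable on a
phase-II subsample $B \subseteq A$ (size $n_{II}$). Rejective sampling adds
a quality gate at phase II: a candidate subsample is accepted only when the
Mahalanobis-type balance statistic

$$Q_I = (\bar x_{II} - \bar x_I)^\top
  \{(n_{II}^{-1} - n_I^{-1}) V_{xx,I}\}^{-1} (\bar x_{II} - \bar x_I)$$

falls strictly below a threshold $\gamma^2$ (SRS-within-SRS form;
$V_{xx,I}$ is the phase-I sample covariance with divisor $n_I - 1$). For
general unequal-probability phases the same statistic is standardised by the
linearised design covariance of the Hájek mean difference, built from
second-order inclusion probabilities. Without rejection, $Q_I$ is
asymptotically $\chi^2_p$, so `gamma_from_acceptance(p, a)` converts a
target acceptance rate $a$ into a threshold; $a = 0.001$ gives tight
balance at the cost of roughly $1/a$ candidate draws.

## The limit law and why rejection helps

Conditioning on $\{Q_I < \gamma^2\}$ replaces the balanced component of the
estimator error by a *truncated* variable. The scaled error of the phase-II
mean converges to

$$a\,L_{p,\gamma^2} + b\,Z_1 + c\,Z_2,$$

where $Z_1, Z_2$ are standard normal,
$L_{p,\gamma^2} = \chi_{p,\gamma}\, S\, \Gamma_p^{1/2}$ is a $\chi_p$
variable truncated to $\chi_p^2 \le \gamma^2$ times a random sign and the
first coordinate of a uniform point on the unit sphere, and the
coefficients carry the design fractions, the population variance $V_{yy}$,
and the squared correlation $R^2$ between $x$ and $y$. The variance of the
truncated part is the chi-square CDF ratio

$$v_{p,\gamma^2} = P(\chi^2_{p+2} \le \gamma^2) / P(\chi^2_p \le \gamma^2)
  \in (0, 1],$$

implemented in `v_p_gamma()` and verified in the tests against the sample
variance of `sample_L()` draws. For $p = 1$ the spherical factor is the
point mass at one (the 0-sphere has coordinates $\pm 1$), so
$L_{1,\gamma^2}$ is a standard normal truncated to $(-\gamma, \gamma)$; the
Beta$(1/2, (p-1)/2)$ form is degenerate there and the code special-cases it.

Because $v_{p,\gamma^2} < 1$, rejection shrinks the asymptotic variance of
the plain phase-II mean by the closed-form percentage implemented in
`theoretical_reduction()`: the smaller $\gamma^2$ and the larger $R^2$, the
larger the gain, with the plain mean approaching the regression estimator's
variance as $\gamma^2 \to 0$. The regression estimator itself is
asymptotically unaffected by rejection — its appeal under rejective designs
is operational (fewer negative implied weights, `regression_weights()`
counts them).

## Estimators

* `hajek_mean()` / `pistar_mean()`: inverse-probability means normalised by
  the sum of weights, with weights $1/\pi^*$, the cumulative product of
  per-phase conditional inclusion probabilities. The Hájek normalisation is
  used everywhere, including when $N$ is known: it is exact under SRS
  (where it reduces to the unweighted phase-II mean) and scale-stable under
  Poisson phases, whose realized size is random.
* `ree_mean()`: the reweighted expansion estimator for stratified second
  phases, which *does* use the known $N$, as its formula requires.
* `regression_estimate()`: $\bar y_{II} - (\bar x_{II} - \bar
  x_I)^\top\hat\beta_{II}$ with the slope from the centered, optionally
  $\pi^*$-weighted, normal equations. Weighted fits center by weighted
  means.

## Variance estimation and intervals

Two routes, never silently interchanged:

* **SRS route** (`var_hat_srs()`): plug-in $\hat R^2$ and $\hat V_{yy} =
  \hat\beta^\top \hat V_{xx}\hat\beta + \hat V_{ee}$ with the residual
  variance divided by $n_{II} - p - 1$ (the slope is estimated). The same
  degrees-of-freedom correction is applied in the general route, on the
  same bias argument, although it only matters at second order.
* **General route** (`ht_components()`, `syg_components()`): the three
  components of $n_{II}\times$variance — the balanced part $V_1$, the
  phase-II residual part $V_2$, and the phase-I part $V_3$ — as double sums
  over phase-II pairs with exact closed-form second-order inclusion
  probabilities (SRS, Poisson, stratified). The Sen–Yates–Grundy
  pairwise-difference forms are nonnegative for fixed-size phases and are
  the default recommendation there; Horvitz–Thompson forms remain available
  and are the only option under Poisson phases. Cross-phase joint
  probabilities multiply the conditional second-order terms exactly; no
  approximation of the conditional pairwise probabilities is attempted.

Intervals for the phase-II mean use Monte Carlo quantiles of the mixture
law (`mixture_quantile()`, default $2\times 10^6$ draws under a fixed,
documented seed so reported intervals are reproducible; linear
interpolation between order statistics, which moves only the last digit).
$\hat R^2$ is clipped at $1 - 10^{-10}$ so the normal component of the
plug-in law never degenerates. Intervals for the regression estimator are
normal. The Monte Carlo harness precomputes the quantiles on an $R^2$ grid
from one shared draw set and interpolates per replicate — the quantile is a
smooth function of $R^2$, and this keeps a 1000-replicate coverage study in
seconds.

## Numerical choices and degenerate inputs

* A balance metric whose reciprocal condition number falls below $10^{-12}$
  is a hard error, not a pseudo-inverse: silently projecting out a
  direction would change the law of $Q$. The same threshold guards the
  regression normal equations (the error names the null direction).
* Acceptance uses the strict inequality $Q < \gamma^2$.
* Empty Poisson candidates are redrawn inside the rejective loop and
  counted in `draws_used`; estimators are undefined on empty samples and
  the event has negligible probability at design sizes.
* One seeded generator serves a whole `rejective_draw()` call; candidates
  consume it sequentially, so realized draw counts are reproducible. The
  population generators document their RNG consumption order.
* `max_draws` defaults to $10^6$; the failure message reports the running
  acceptance rate so a user can rescale $\gamma^2$.
* Under Poisson phases, sample-size normalisations use the realized size:
  the statistic and the weights then refer to the sample actually in hand.

## Two conditioning conventions

The operational procedure holds the phase-I sample fixed and redraws only
phase II until acceptance — auxiliaries already collected are not thrown
away. On tiny populations this *per-A* conditional law differs from the
joint law of $(A, B)$ given $\{Q_I < \gamma^2\}$, because the acceptance
probability varies with $A$; asymptotically the two coincide. The package
implements both: `rejective_draw()` is the operational sampler, and
`rejective_two_phase()` redraws the whole chain, sampling the joint
conditional exactly. The exhaustive-enumeration oracle
(`enumerate_two_phase_oracle()`) tabulates the joint law, and the test
suite checks each sampler against the law it actually targets.

## Estimating-equation parameters

`builtin_ee()` provides the standard menu (mean, proportion below a
threshold, mean–variance pair, quantile). Smooth kinds are solved from the
$\pi^*$-weighted Hájek estimating equation (closed forms where they exist,
bracketed root-finding to $10^{-10}$ otherwise); the quantile kind uses the
exact generalized inverse on the sorted support — no iteration, and the
step-function bracketing $\bar s(\hat\xi^-) < 0 \le \bar s(\hat\xi)$ holds
exactly. The variance is the M-estimation sandwich: the same three
double-sum components applied to $s_i(\hat\xi)$ and its $x$-projection
residuals, pre- and post-multiplied by the inverse derivative of the
limiting estimating function. For the quantile kind that derivative is the
density of $y$ at the solution, estimated by a $\pi^*$-weighted Gaussian
kernel with Silverman's bandwidth — this is the one genuinely modelling
choice in the module, isolated behind `derivative_mode` semantics, and the
projection coefficient uses $\pi^*$-weighted phase-II sums because
population $x$-moments are unobservable under a two-phase design.

## Three-phase designs

`draw_three_phase()` composes SRS (phase I), Poisson
probability-proportional-to-$x$ with rejection on $x$-balance (phase II,
threshold $\gamma_1^2$), and Poisson proportional to the row sums of $z$
with rejection on the balance of the *residualized* block $a_i = z_i -
\bar z_{II} - (x_i - \bar x_{II})^\top\hat\beta_{zx,II}$ (phase III,
threshold $\gamma_2^2$). Balancing only the orthogonalized block follows
the block-wise Gram–Schmidt idea: $x$ was already balanced at phase II, so
the new information in $z$ is its component orthogonal to $x$. Joint
$(x, a)$ balancing is available via `balance_mode = "joint"`. The size
measure for phase III is shifted to positivity when the synthetic $z$
produces non-positive row sums, and the shift is reported in the output.
Cumulative weights compose exactly, $\pi^{***} = \pi_I\,\pi_{II|A}\,
\pi_{III|B}$.

Analytic variance estimators for three-phase estimators are not provided;
the design is compared by Monte Carlo (the ordering tests assert that the
rejective design's triple-expansion mean has smaller variance than the
non-rejective one at matched sizes, with thresholds at the 0.001 chi-square
quantiles).

## The synthetic populations

`make_simulation_population()` generates the two-phase study conditions:
$x \sim \sqrt{0.5}(\chi^2_1 - 1)$ (mean 0, variance 1, right-skewed),
$y = 1 + \beta x + e$, $e \sim N(0,1)$, so $R^2 = \beta^2/(\beta^2+1)$ and
$\beta \in \{0.5, 1, 2\}$ spans $R^2 \in \{0.2, 0.5, 0.8\}$. The design
sizes are $N = 10^5$, $n_I = 5000$, $n_{II} = 200$.

`make_threephase_population()` is an explicitly synthetic stand-in for a
school-performance style frame: one positive auxiliary $x$ (shifted gamma,
$5 + \Gamma(2, 1)$ — scores sit well above zero with a small coefficient of
variation, which also keeps $\pi_i \le 1$ feasible for
probability-proportional-to-$x$ sampling at realistic fractions), a
3-column $z$ correlated with $x$, and $y$ linear in both. It reproduces the
*structure* of such data, not any real joint distribution: covariances are
homogeneous and linear, there are no strata, clusters, measurement error or
nonresponse. Tests passing on these populations demonstrate design-law
correctness and the predicted efficiency orderings; they do not certify
behaviour under model misspecification in real frames.

## Problem sizes used in the validation

The full-scale Monte Carlo comparisons use the study conditions above with
1000 replicates. Distributional checks use moderate designs (populations of
$2\,000$–$20\,000$, phase sizes in the hundreds) where the asymptotics are
already accurate; exhaustive-enumeration checks use $N \le 9$ where every
outcome can be tabulated. The three-phase ordering study uses $N = 3000$,
$n_I = 800$, expected phase sizes 300 and 100, and 500 replicates per
design.

## Known limitations

* Fixed-size unequal-probability (conditional Poisson) phases, multistage
  cluster designs, and cube-method balancing are out of scope.
* The simplified variance estimators that avoid conditional pairwise
  probabilities are not implemented; the exact closed forms are.
* Quantile variance estimation inherits the usual sensitivity of kernel
  density plug-ins at small $n_{II}$.
* The three-phase path reports Monte-Carlo-calibrated uncertainty only.
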