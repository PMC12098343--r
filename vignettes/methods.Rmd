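---
title: "Measuring health-system efficiency with medeff: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health-system efficiency with medeff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medeff)
```

## The problem

Regional health systems convert inputs — healthcare institutions, hospital
beds, technical personnel — into services: outpatient and emergency visits,
bed utilization. Some of what they produce is undesirable: a high share of
household consumption absorbed by medical expenses signals a costly system,
so more of it should count against efficiency, not for it. `medeff`
benchmarks decision-making units (DMUs: cities observed in particular
years) against each other with data envelopment analysis (DEA), follows
productivity over time with the Malmquist index, and regresses the
resulting efficiency scores on socio-economic covariates with a censored
(Tobit) panel model.

## The SBM model and the two-stage scoring protocol

The slacks-based measure (SBM) scores a DMU by how much slack — input
excess, desirable-output shortfall, undesirable-output excess — separates
it from the best-practice frontier. For evaluated unit $o$ with $m$
inputs $x$, $q$ desirable outputs $y$ and $h$ undesirable outputs $b$,
the standard program is

$$\rho^* = \min_{\lambda, s}
 \frac{1 - \tfrac1m \sum_i s_i^-/x_{io}}
      {1 + \tfrac{1}{q+h}\left(\sum_r s_r^+/y_{ro} + \sum_k s_k^b/b_{ko}\right)}$$

subject to $x_o = X\lambda + s^-$, $y_o = Y\lambda - s^+$,
$b_o = B\lambda + s^b$, with all weights and slacks nonnegative.
$\rho^* \in (0,1]$, and $\rho^* = 1$ exactly when no reference combination
dominates the unit in any dimension. Because every frontier unit scores 1,
the standard model cannot rank them; the super-efficiency variant excludes
unit $o$ from its own reference set and measures how far the frontier
would have to reach to absorb it:

$$\sigma^* = \min_{\lambda, s}
 \frac{1 + \tfrac1m \sum_i s_i^-/x_{io}}
      {1 - \tfrac{1}{q+h}\left(\sum_r s_r^+/y_{ro} + \sum_k s_k^-/b_{ko}\right)}
 \qquad (\lambda_o \equiv 0),$$

which is $\ge 1$ for standard-efficient units. `efficiency_score()`
composes the two: a unit strictly inside the frontier keeps its standard
score; a frontier unit is re-scored by the super-efficiency program. This
two-stage protocol is what produces comprehensive efficiency tables in
which inefficient cities score below 1 and efficient ones above it. The
super-efficiency program alone would be useless for that purpose — it
evaluates to 1 for every dominated unit.

Both fractional programs are linearized by the Charnes–Cooper
transformation (a scaling variable $t > 0$ multiplies every variable, the
denominator is normalized to 1) and solved as linear programs.

### Returns to scale, frontier scope, undesirable outputs

* **CRS vs VRS.** Under constant returns to scale the reference technology
  is a cone; variable returns add the convexity constraint
  $\sum_j \lambda_j = 1$ ($= t$ after linearization). Scale efficiency is
  the ratio `crste / vrste`.
* **`decompose_scale(stage=)`.** With `"two_stage"` (default) both crste
  and vrste come from the two-stage protocol, so frontier units can
  exceed 1 — the form published benchmarking tables report. With
  `"standard"` only the standard SBM is run; scores are capped at 1 and
  `scale` is guaranteed to lie in $(0,1]$. The textbook closed-form
  decomposition example (one frontier unit, one dominated unit:
  crste 0.5, vrste 1.0, scale 0.5) holds in the standard mode; under the
  two-stage protocol the same frontier unit's vrste is its VRS
  super-efficiency (2.0 in that instance). Both are exposed because the
  two conventions answer different questions and conflate badly if mixed.
* **Frontier scope.** `contemporaneous` (default) builds each year its own
  frontier, matching year-by-year score tables; `global` pools all
  unit-periods into one frontier, which is the literal reading of a
  pooled-sum formulation. Year-specific published scores imply the
  contemporaneous convention, so it is the default; the pooled mode is
  retained as an option.
* **Undesirable outputs.** `undesirable_mode = "eq1"` applies the bad-output
  slack constraints exactly as printed in the model above; `"none"` drops
  the bads for sensitivity analysis.

### Numerical choices

* The linear programs are solved by a dense two-phase primal simplex with
  Bland's anti-cycling rule, written for this package. The programs are
  small (one variable per reference DMU plus one slack per indicator), so
  a careful dense implementation is faster than its overhead would suggest
  and is fully deterministic. It is validated in the test suite against
  brute-force minimization of the fractional objective over reference
  weights (random instances with $n \le 4$, $m+q+h \le 3$, agreement
  within $10^{-4}$).
* Columns are rescaled by reference-set means before solving. SBM scores
  are mathematically invariant to column scaling, so this changes nothing
  in exact arithmetic while conditioning the tableau; it also makes the
  units-invariance property hold to near machine precision.
* Scores within $10^{-6}$ of 1 are snapped to 1, stabilizing the
  standard/super switch; the super-efficiency denominator is kept above
  $10^{-9}$ (`denominator_floor`) so the linearized program stays bounded.
* Super-efficiency infeasibility (possible under VRS, and for a single-DMU
  reference set) is reported as a status, never imputed; summaries count
  and exclude such records.

## Malmquist productivity index

Productivity change between consecutive periods is measured from Shephard
output-distance functions $D^s(x^t, y^t)$ (period-$s$ technology,
period-$t$ data), each computed from an output-oriented radial LP with the
evaluated unit included in its own period's frontier:

$$M_i = \left[\frac{D^t(x^{t+1},y^{t+1})}{D^t(x^t,y^t)} \cdot
        \frac{D^{t+1}(x^{t+1},y^{t+1})}{D^{t+1}(x^t,y^t)}\right]^{1/2},$$

with $M_i > 1$ indicating improvement. The decomposition is
`effch` $= D^{t+1}(x^{t+1},y^{t+1})/D^t(x^t,y^t)$ (catch-up),
`techch` $= M_i/\text{effch}$ (frontier shift), `pech` the VRS analogue of
effch, and `sech` $=$ effch/pech. The identities
$M_i = \text{effch}\times\text{techch}$ and
$\text{effch} = \text{pech}\times\text{sech}$ therefore hold exactly by
construction — techch and sech are defined residually, which is the
standard convention and puts all VRS content into pech.

Design points:

* **Orientation.** Output orientation is the default (how much more output
  the technology supports at given inputs — the natural question for
  service delivery); input orientation is available as an option.
* **Undesirable outputs.** The Malmquist literature offers no single
  convention; the default `bad_mode = "as_input"` enters bads into the
  input constraints (less bad is better, like less input), and `"ignore"`
  drops them. The bads-aware Malmquist–Luenberger directional index is out
  of scope.
* **Cross-period VRS infeasibility** is genuine (a later-period bundle may
  be unreachable under an earlier period's convexity constraint); affected
  components are reported missing, never silently replaced by CRS values.
* **Aggregation.** Malmquist components are index numbers, so all
  summaries use geometric means; efficiency scores (level quantities) are
  aggregated arithmetically in the reporting module. City ranks order by
  mean $M_i$, descending.

## Panel Tobit second stage

Two-stage efficiency analysis regresses scores on covariates. Because
scores are bounded below by 0, least squares is biased; the Tobit model
maximizes a censored-normal likelihood instead — tail mass for censored
observations, density for interior ones. `medeff` fits:

* `fit_tobit_pooled()`: censored-normal MLE with analytic gradient
  (BFGS, relative log-likelihood tolerance $10^{-10}$, max 500
  iterations); with zero censored observations it coincides with least
  squares, which the tests verify, and the pooled fit is cross-checked
  against the independent left-censored Gaussian fit of
  `survival::survreg`.
* `fit_tobit_re()`: adds a unit-level normal random effect
  $u_i \sim N(0, \sigma_u^2)$, integrated by Gauss–Hermite quadrature
  (`quad_nodes = 12` by default; doubling the nodes moves the
  log-likelihood by less than $10^{-3}$ on the default synthetic panel).
  It reduces to the pooled fit as $\sigma_u \to 0$, and with one period
  per unit $\sigma_u$ is flagged unidentified.

Censoring defaults to lower = 0, upper = $+\infty$: super-efficiency
scores exceed 1, so the common $[0,1]$ upper censoring would be wrong
here; only non-negativity is imposed. Covariates are standardized
internally and mapped back through the Jacobian, which conditions the
optimizer and makes z, p and Wald statistics exactly invariant to
covariate rescaling. The joint Wald test is $b'V^{-1}b$ against
$\chi^2_{df}$; restricting a single slope reproduces $z^2$ identically.
Starting values are least-squares slopes, the residual SD for
$\sigma_e$, and $0.1\,\sigma_e$ for $\sigma_u$. Two-sided normal
p-values are reported per coefficient with conventional significance
stars; no multiple-testing adjustment is applied, matching common
practice in this literature. Both pooled and random-effects variants are
provided because published second stages rarely state which they used;
random effects is the default for panel data.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces city-by-year panels with a known truth so that
every stage can be validated end to end:

* inputs are log-normal (means staggered across the $m$ inputs, log-SD
  0.3 — dispersion typical of city-level administrative counts);
* latent efficiency is
  $\theta_{it} = \mathrm{logistic}(1 + z_{it}'\beta + u_i + \epsilon_{it})$
  with $u_i \sim N(0, 0.2^2)$, $\epsilon_{it} \sim N(0, 0.15^2)$; the
  logistic link keeps $\theta \in (0,1)$ without truncation artifacts,
  and with `anchor_frontier = TRUE` each period's $\theta$ column is
  divided by its maximum so one unit per period sits exactly on the
  frontier ($\theta = 1$), which pins the DEA frontier to a known unit;
* outputs follow a Cobb–Douglas frontier
  $y = \gamma_r\,\mathrm{drift}_t \prod_j x_j^{a_j}\,\theta\,e^{\nu}$
  (exponents default to equal shares summing to 1, output noise SD 0.05,
  technology drift 3 % per year), and the undesirable output rises
  proportionally with the first output with 10 % multiplicative noise —
  mirroring medical expense scaling with service volume;
* covariates are standard normal with true coefficients
  $\beta = (0.5, -0.5, 0.3, 0, \ldots)$ on the latent scale;
* default dimensions mirror the study design this package serves:
  41 units, 6 periods, $m = 3$, $q = 2$, $h = 1$, $p = 8$. One integer
  seed drives a single generator stream; regeneration is bit-identical.

What passing tests on this generator show: the LP machinery, the two-stage
protocol, the index decomposition and the censored-likelihood estimation
recover a known truth under a data-generating process with the right
qualitative structure (frontier + multiplicative inefficiency + covariate
link + bad output tied to the good output). What they do not show: that
real yearbook panels satisfy those assumptions. Real administrative data
have serial correlation in inputs, non-lognormal tails, measurement error
correlated with city size, and covariates that are anything but
independent normals. Recovery rates measured here are upper bounds on
what field data would yield.

## Problem sizes used in validation

The test suite exercises random instances of up to 4 units and 3
indicators wherever a brute-force oracle must also run; the end-to-end
checks run the full default 41-unit × 6-year panel; the Tobit recovery
study uses 100 replicates of a 200-unit × 6-period panel. The packaged
fixture of published efficiency values (41 cities × 6 years) validates the
aggregation arithmetic: all 41 published ranks reproduce exactly, and
every recomputed mean lies within 0.0005 of its published counterpart
(the published averages were computed from unrounded scores, so means of
the published 3-decimal values can land exactly half an ulp away).

## Known limitations

* Network, dynamic, bootstrapped and weight-restricted DEA variants are
  out of scope, as are Malmquist–Luenberger indices and the
  Simar–Wilson truncated-regression second stage.
* Whether published crste/vrste decompositions derive from radial CCR/BCC
  or SBM models is rarely stated; this package uses SBM under both
  returns-to-scale assumptions throughout.
* Fixed-effects Tobit is deliberately absent (incidental-parameters
  problem); adaptive quadrature is not implemented — 12 fixed
  Gauss–Hermite nodes are accurate for the variance ratios typical of
  efficiency panels, and the node count is configurable.
* The simplex solver is dense and single-threaded; it is sized for panels
  of hundreds of DMUs, not tens of thousands.
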