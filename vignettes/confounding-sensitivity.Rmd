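---
title: "Methods: E-values, bounding factors, and the confounding-sensitivity pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: E-values, bounding factors, and the confounding-sensitivity pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasbound)
```

## The problem

Prospective cohort studies of diet and weight gain can adjust only for the
confounders they measured. `biasbound` quantifies the *plausibility* that
confounders they did not measure explain an observed association: it pools
study-level relative risks, converts every scenario onto a common
risk-ratio scale, and asks how strong a hypothetical confounder would need
to be — jointly with exposure and with outcome — to account for part or
all of the pooled effect. Nothing here estimates what confounding *did*
occur; the outputs are worst-case bounds under the bounding-factor model.

## The random-effects model

Each study contributes a log risk ratio $y_i$ with standard error $s_i$
(recovered from the reported confidence interval as
$(\log u_i - \log l_i)/(2z)$, with $z$ the full-precision normal quantile,
1.959964 at 95%, never the rounded 1.96). The model is normal–normal:

$$y_i \sim N(\mu_i, s_i^2), \qquad \mu_i \sim N(\theta, \tau^2).$$

$\tau^2$ is estimated by restricted maximum likelihood. The profiled
restricted log-likelihood

$$\ell_R(\tau^2) = -\tfrac12\Big[\sum_i \log(s_i^2+\tau^2)
  + \log \sum_i w_i + \sum_i w_i (y_i - \hat\theta)^2\Big],
  \quad w_i = \frac{1}{s_i^2+\tau^2},$$

is maximised by bounded derivative-free scalar optimisation on
$[0,\ 10\max_i s_i^2]$ with convergence tolerance $10^{-10}$. A
derivative-free bracket was chosen over Fisher scoring because it cannot
step outside the parameter space and behaves well when the maximum sits at
the $\tau^2 = 0$ boundary; since the bracketing optimiser never returns an
exact endpoint, the boundary value is compared explicitly and wins ties.
The pooled effect is the inverse-variance weighted mean with weights
$w_i$, and the interval is Wald-type on the log scale (the convention of
standard meta-analysis tooling) rather than Hartung–Knapp. Cochran's $Q$
is computed from fixed-effect weights and
$I^2 = \max(0, (Q - (k-1))/Q)$ is reported as a diagnostic. A single-study
"meta-analysis" returns that study unchanged with $\tau^2 = 0$ and a
warning instead of an error, so subset analyses cannot crash on sparse
quantiles. Hazard- and odds-ratio studies are converted to risk ratios
*before* pooling, never pooled on their native scale.

The test suite validates the optimiser two independent ways: against a
dense brute-force grid search of $\ell_R$ (step $10^{-5}$ in $\tau^2$,
with one refinement pass around the argmax so the pooled estimate is
resolved to $10^{-6}$), and against `metafor::rma(method = "REML")` run at
a comparable convergence threshold.

## Effect-measure conversions

All downstream machinery consumes risk ratios, so three conversion routes
are provided.

* **OR → RR**: $\mathrm{RR} = \mathrm{OR} / (1 - p_0 + p_0\,\mathrm{OR})$,
  where $p_0$ is the baseline (unexposed) outcome risk. $p_0$ is a
  *required* input wherever this conversion is needed — there is no silent
  default, because the conversion is sensitive to it (an OR of 2.88 maps
  to RR 1.48 at $p_0 = 0.5$ but to RR 2.59 at $p_0 = 0.05$). The bundled
  example scenario file documents the $p_0$ values behind each of its
  rows; $0.5$ is the conservative choice when nothing better is known,
  since it shrinks the OR the most.
* **HR → RR**: for rare outcomes the hazard ratio passes through; for
  common outcomes the standard approximation
  $(1 - 0.5^{\sqrt{\mathrm{HR}}})/(1 - 0.5^{\sqrt{1/\mathrm{HR}}})$ is
  used. The rare/common cut is an outcome proportion of 15% by end of
  follow-up.
* **r → OR (→ RR)**: a correlation is first mapped to a standardised mean
  difference, $d = 2r/\sqrt{1-r^2}$, then to a log odds ratio via the
  logistic-variance factor $\pi/\sqrt3$. This chain reproduces the widely
  used $r = 0.28 \leftrightarrow \mathrm{OR} = 2.88$ correspondence to two
  decimals. No confidence-interval propagation is attempted for this
  route; it serves point scenarios only.

Conversions run at full precision throughout; rounding to two decimals
(E-values, bounds) or whole percent (proportions) happens only at render
time.

## E-value and joint bounding factor

For an observed risk ratio $\mathrm{RR} \ge 1$,
$E = \mathrm{RR} + \sqrt{\mathrm{RR}(\mathrm{RR}-1)}$, with closed-form
inverse $\mathrm{RR} = E^2/(2E-1)$. Protective estimates are reciprocated
first, so results always live on the $\ge 1$ side. The confidence-limit
E-value uses the limit closer to the null; when the interval spans the
null it is defined as exactly 1 — no confounding is needed to explain a
non-significant interval.

A confounder with associations $\mathrm{RR}_{EU}$ (exposure side) and
$\mathrm{RR}_{UD}$ (outcome side), both oriented $\ge 1$, biases the
observed risk ratio by at most
$B = \mathrm{RR}_{UD}\mathrm{RR}_{EU} /
(\mathrm{RR}_{UD} + \mathrm{RR}_{EU} - 1)$. Two definitional choices were
genuinely open and are resolved as follows:

* **Total confounding** is declared when $B \ge \mathrm{RR}_{obs}$, not
  when $B \ge E$. The two readings circulate, but only the first is
  self-consistent: at the symmetric point
  $\mathrm{RR}_{UD} = \mathrm{RR}_{EU} = E$ the bound equals the observed
  risk ratio exactly ($B(E, E) = \mathrm{RR}$, an identity the tests
  verify to $10^{-9}$), so "bound reaches the observed RR" is the
  statement the E-value itself instantiates.
* **Proportion explained** is computed on the excess-relative-risk scale,
  $100\,(B-1)/(\mathrm{RR}-1)$, capped at 100. A reading proportional to
  $B/\mathrm{RR}$ would be incoherent for $B \ge 1$ and does not reproduce
  the standard worked examples; the excess-risk reading does.

The complementary strength needed for total confounding given one known
side is the closed form
$x = \mathrm{RR}\,(\mathrm{RR}_{known}-1)/(\mathrm{RR}_{known}-\mathrm{RR})$,
defined only when $\mathrm{RR}_{known} > \mathrm{RR}$ — since
$B \le \min(\mathrm{RR}_{UD}, \mathrm{RR}_{EU})$, a known side at or below
the observed risk ratio can never produce total confounding and the
function returns `NA` ("unattainable"), which the report renders as such
rather than dropping the scenario.

**Bounding curves** sample the contour $B = b^\*$ with
$\mathrm{RR}_{UD}$ log-spaced on $(b^\*, 10\,b^\*]$ (200 points by
default). Log spacing concentrates points near the vertical asymptote at
$\mathrm{RR}_{UD} = b^\*$, where the required $\mathrm{RR}_{EU}$ diverges;
uniform spacing would waste most of the budget on the flat tail. Every
emitted point satisfies the contour equation to $10^{-9}$.

**A note on rounding of inputs.** These formulas are steep enough near the
null that second-decimal changes in inputs move second-decimal outputs:
the E-value of 1.14 is 1.539 (1.54), while an unrounded pooled estimate
near 1.145 gives 1.55; a bound of 1.1248 against 1.14 explains 89% of the
excess risk, but against an unrounded 1.145 about 86%. When reproducing
published sensitivity analyses from their *printed* (rounded) estimates,
discrepancies of this size are expected and are not evidence of a
computational difference. `biasbound` therefore keeps full precision
internally and rounds only at the rendering step.

## Synthetic-data generators

Two generators make every pipeline stage testable against known truth.

* `simulate_meta_sample()` draws directly from the normal–normal model
  above: per-study standard errors uniform on a range (default
  0.05–0.30, typical of published cohort quartile contrasts), study
  effects $N(\theta, \tau^2)$, observations around them. It emulates
  exactly the structure the REML fitter assumes — which is the point: it
  supports calibration checks (bias of the pooled estimate, interval
  coverage), not robustness claims.
* `simulate_confounded_cohort()` generates individual-level data with a
  binary confounder $U$ under a *log-linear* (risk-ratio)
  parameterisation: $U \sim \mathrm{Bern}(p_U)$, exposure probability
  $p_E\,\mathrm{RR}_{EU}^{U}$, outcome probability
  $p_D\,\mathrm{RR}_{UD}^{U}\,\mathrm{RR}_{true}^{E}$. A logistic
  parameterisation would be more conventional for data generation, but the
  log-linear form makes the generative parameters *identical* to the risk
  ratios the bounding factor consumes, so the bound-compliance test — the
  crude risk ratio of a null-effect cohort never exceeds
  $B(\mathrm{RR}_{UD}, \mathrm{RR}_{EU})$ beyond Monte-Carlo noise — is a
  direct check of the bound, with no model-translation slack. Defaults
  $p_U = 0.2$, $p_E = 0.2$, $p_D = 0.1$ keep all cell probabilities below
  1 across the tested grid of confounder strengths up to 3; the generator
  refuses, naming the offending product, rather than silently truncating.
  Zero case cells in the resulting 2×2 tables get a flagged 0.5 continuity
  correction, never a silent one.

Both generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible under a fixed seed. What they do **not** emulate:
within-study covariate adjustment, correlated quantile contrasts from a
shared reference group, censoring or survival time (hazard-ratio studies
are handled by conversion, not simulation), non-binary or multiple
simultaneous confounders, and publication selection. Passing tests
therefore show the estimators are correct *under the stated models*, not
that real cohort literatures satisfy those models.

## Validation problem sizes

The suite's stochastic checks use: 200 replicate meta-analyses of $k = 20$
studies at $\theta = \log 1.14$, $\tau^2 = 0.01$ for bias (< 0.005 on the
log scale) and 90–98% interval coverage; 50 random small instances
($k \le 8$) for optimiser-vs-grid agreement; and cohorts of $n = 200{,}000$
over a grid of confounder strengths in $\{1.2, 1.5, 2, 3\}$ for bound
compliance at three Monte-Carlo standard errors. These sizes give
Monte-Carlo noise well below the tested tolerances while keeping the whole
suite fast enough to run habitually.

## Pipeline conventions

`run_full_analysis()` validates both input tables up front and fails with
itemised row-level errors before producing any output; `emit_report()`
checks writability before touching `report.json`, so a failed run never
leaves a partial report that could be mistaken for results. The focus
quantile defaults to the largest pooled point estimate — the conventional
highest-vs-lowest contrast — and is overridable. The subset analysis is a
generic predicate on a free-text study tag rather than a hard-coded
outcome category. Reports carry input-file hashes, the configuration echo
and the package version, and identical inputs produce byte-identical
`report.json` files.

## Known limitations

The bounding factor treats the confounder scenario's two associations as
exact; uncertainty in them is not propagated (scenario confidence
intervals enter only through which point value you choose to analyse).
The E-value addresses a single unmeasured confounder or a bundle acting
jointly — it says nothing about bias amplification among several.
Conversions inherit their usual approximation error for common outcomes.
And all outputs are bounds: a large explainable proportion means
confounding of that size *could* account for the association, not that it
does.
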