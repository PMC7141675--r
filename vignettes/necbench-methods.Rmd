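---
title: "Methods: benchmarking threshold estimators for binomial survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking threshold estimators for binomial survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ecotoxicological risk assessment increasingly asks for a *threshold*
concentration — a no-effect concentration (NEC) below which exposed
organisms suffer only background mortality — rather than the traditional
NOEC or an ECx. Several estimators of such thresholds are in routine use,
and they disagree: model-based maximum likelihood, Bayesian posterior
inference, and piecewise (segmented) regression all produce a threshold
estimate from the same survival experiment, each with different bias and
variance, and each can "find" a threshold in data generated without one.
`necbench` implements a Monte Carlo framework to quantify those behaviours.

## The two generating models

Survival of $n = 10$ organisms per experimental unit is binomial,
$y_i \sim \mathrm{Bin}(10, p(x_i))$, where $x_i$ is the effluent
concentration as a fraction of full strength. Two survival-probability
curves are used:

* **Threshold (NEC) curve** with intercept $l$, decay rate $m$ and
  threshold $c$:
  $$p(x) = l\, e^{-m (x - c) I(x > c)}.$$
  Survival equals the control level $l$ at every concentration up to $c$
  and decays exponentially beyond it.

* **Three-parameter log-logistic curve** with upper asymptote $d$, slope
  $b$ and inflection (EC50) $e$:
  $$p(x) = \frac{d}{1 + \exp\{b(\log x - \log e)\}},$$
  with $p(0) = d$ taken as the $x \to 0$ limit. This curve has no
  threshold: the effect is strictly positive at every $x > 0$.

ECx values are defined *relative to the curve's own intercept*: the ECq is
the concentration at which survival equals $(1-q)\,\times$ intercept.
This is the only convention under which the analytic inversions
$\mathrm{EC}q_{\mathrm{NEC}} = c + \log(1/(1-q))/m$ and
$\mathrm{EC}q_{\mathrm{LL3}} = e\,(q/(1-q))^{1/b}$ reproduce the
benchmark's reference table of true values with non-unit intercepts (true
EC50 of the shallow pair: 43.10% effluent), and it is what
`ecx()` implements. Concentrations are stored as fractions in $[0, 1]$;
percent is purely a display scale.

Matched curve pairs share the intercept and the EC50: the log-logistic
comparison curve for a given NEC curve takes $d = l$, $b = m$ (same slope
class) and $e$ equal to the NEC curve's analytic EC50
(`matched_loglogistic()`).

## The stated simulation world

The generator (`scenario()`, `simulate_dataset()`) defines the benchmark
grid; none of these values are tuning knobs:

* slopes $m = b \in \{3, 5, 10\}$ (shallow, intermediate, steep);
* control survival intercepts $\{0.95, 0.90, 0.85\}$ (low, medium, high
  background mortality);
* threshold fixed at $c = 0.20$ (20% effluent) in all NEC curves;
* two designs of 18 units / 180 organisms: *categorical*
  (0, 6.25, 12.5, 25, 50, 100% with 3 replicates each) and *continuous*
  (3 control replicates plus 15 single units equally spaced in $\log_e$
  from 100% down to 3.94%);
* datasets with mean control survival below 80% are rejected and redrawn
  (the rejection count is recorded);
* 1000 datasets per scenario in the full study, 36 scenarios in total.

Two points were genuinely open and resolved as follows. First, the
continuous design's levels are generated as $2^{-k/3}$, $k = 0, \dots,
14$: the stated endpoints imply a spacing ratio within $10^{-4}$ of
$2^{1/3}$, and taking it to be exactly $2^{1/3}$ makes the five non-zero
categorical levels reappear exactly, which the design description
requires; the lowest level $2^{-14/3} = 0.03937$ prints as 3.94%. Second,
the control filter applies to the *mean* of the three control units
(at least 8 survivors of 10 on average), following the stated wording
rather than a per-replicate rule.

What the generator deliberately does not emulate: overdispersion
(beta-binomial noise), time-to-death structure, non-independence between
units, or thresholds at other locations. A green simulation test
therefore establishes estimator behaviour under ideal binomial sampling
from these curve families only.

## The four estimators

**Log-logistic ECx analysis** (`fit_loglogistic3()`): bounded quasi-Newton
maximization of the binomial log-likelihood on a logit/log-transformed
scale, with a heuristic start (intercept from the control mean, $e$ from
the concentration nearest 50% relative kill, $b = 5$) plus fixed
perturbed restarts. Standard errors come from the inverse observed
information; ECx confidence intervals use the delta method with the
analytic gradient (zero with respect to $d$ under the relative ECx
definition) and a 1.96 normal quantile.

**NEC maximum likelihood** (`fit_nec_mle()`): the likelihood is
piecewise-smooth in $c$ with kinks at the observed concentrations, so the
optimizer profiles $c$ over candidates at the observed concentrations and
their midpoints with an inner smooth $(l, m)$ optimization, then refines
$c$ by 1-D search inside the bracketing kink-free interval. The test
suite holds this to a dense profile-grid oracle within $10^{-4}$
log-likelihood units. The delta-method SE of $c$ uses a numerical Hessian
at the optimum; an indefinite Hessian (possible at a kink) flags the fit
rather than silently excluding or fabricating an SE.

**Bayesian NEC** (`fit_nec_bayes()`): adaptive Metropolis-within-Gibbs
(per-parameter Gaussian random walks, Robbins–Monro step adaptation
during warm-up only), three chains. Priors: $l \sim U(0,1)$,
$m \sim U(0,20)$, $c \sim \mathrm{Gamma}(0.001, \mathrm{rate}=0.001)$.
The gamma prior is read in the shape/rate convention: a *scale* of 0.001
would put the prior mean at $10^{-6}$ and effectively forbid thresholds
near 0.2, which is incompatible with the setting. A fit is acceptable
only if split-$\hat R < 1.05$ for all parameters; the point estimate is
the posterior mean (median also reported) and the interval the 95% HDI.
The DIC comparator is a Bayesian log-logistic fit with mirrored priors
($d \sim U(0,1)$, $b \sim U(0,20)$, $e \sim$ the same gamma) — an
assumption, since only the NEC priors are fully specified.

**Piecewise logistic regression** (`fit_piecewise()`): the binomial GLM
$\mathrm{logit}(p) = \beta_0 + \beta_2 (x - \psi)_+$ with the pre-break
slope fixed at zero, fitted with Firth's Jeffreys-prior penalty
(`fit_firth_logistic()`, penalized IRLS) so that complete separation —
routine in steep survival data — still yields finite estimates and SEs.
The breakpoint is estimated by the classic segmented linearization (gap
covariate, update $\psi$ by gap/slope ratio) from four starts (10, 15,
20, 25%), with step halving whenever the constrained penalized likelihood
would decrease; a kink-aware profile search over $\psi$ always competes
with the iterative solutions, so the reported optimum matches a dense
profile-grid oracle within $10^{-3}$. The no-threshold comparator for
AICc is the two-parameter Firth logistic in $x$.

## Model selection and evaluation

Threshold vs non-threshold evidence uses AIC for the MLE pair (both have
3 parameters), DIC (Spiegelhalter $p_D$) for the Bayesian pair, and AICc
for the piecewise pair (3 vs 2 parameters), with $n = 18$ experimental
units in the small-sample correction — the likelihood is specified over
units, not organisms (the organism-level alternative is a one-line
change). Evidence weights are $\exp(-\Delta/2)$ normalized over the pair;
weight $\ge 0.9$ (boundary inclusive, with a $10^{-9}$ float guard)
counts as strong evidence.

Accuracy is the RMSE of the point-estimate distribution against the true
threshold (NEC scenarios) or an *apparent* threshold of 20% (log-logistic
scenarios; the EC5-referenced alternative is implemented but off by
default since it would inherently favour ECx analysis). Fits are excluded
— counted, never silently dropped — when they fail to converge or when a
reported interval exceeds 100 percentage points, a proxy for degenerate
fits. RMSE ratios (categorical / continuous) above 1 favour the
continuous design. HDIs of empirical estimate distributions reuse the
same shortest-contiguous-interval routine as the posterior summaries;
multimodal distributions are deliberately not split, so their HDIs can be
overestimated.

## Numerical choices

* Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside all
  likelihoods.
* The segmented iteration converges on $|\Delta\psi| < 10^{-5}$; the
  Firth IRLS on a score norm below $10^{-6}$ (both configurable).
* Delta-method intervals use 1.96 rather than a $t$ quantile.
* The per-dataset RNG seed is derived deterministically from the master
  seed, the scenario id string and the dataset index, so scenarios can be
  run separately or jointly with identical results, and every dataset
  records its seed.
* MCMC budgets: the desk default is 5,000 warm-up + 20,000 sampling
  iterations thinned by 10, three chains; the full-fidelity profile
  (200,000 + 100,000, thin 10) is `mcmc_config("paper")`. The warm-up
  length is configuration, not a constant.

## Known limitations

Desk-scale simulation sizes (hundreds of datasets, reduced MCMC budgets)
reproduce directions and coarse magnitudes, not full-scale rates to the
decimal; the `"paper"` presets exist for full-fidelity runs but
take hours. The Firth-penalized likelihood is used both for breakpoint
estimation and (unpenalized, at the bias-reduced estimates) inside AICc —
information criteria on bias-reduced fits are known to be debatable, and
this package follows the benchmarked practice rather than adjudicating
it. Only single-breakpoint piecewise models, binomial noise and the two
stated designs are supported.
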