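---
title: "Planning multiplier-method population size estimation studies with RDS surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning multiplier-method population size estimation studies with RDS surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psemult)
```

## The problem

Key populations for HIV surveillance — female sex workers, people who
inject drugs, men who have sex with men — are stigmatized, often
criminalized, and lack a sampling frame, so their size cannot be counted
directly. Multiplier methods estimate it indirectly from two data sources:

1. a count $M$ of unique members of the population touched by something
   countable — unique attenders on a service roster over a reference
   period (service multiplier), or unique objects distributed
   (unique-object multiplier); and
2. the proportion $P$ of a representative survey of the population who
   report receipt of that service or object.

If the survey is representative, $P$ estimates the fraction of the
population covered by the count, so the population size estimate is

$$\widehat{\mathrm{PSE}} = \frac{M}{P}.$$

The representative survey is typically respondent-driven sampling (RDS), a
structured peer-referral design whose weighting approximates a random
sample but whose clustering inflates sampling variance. `psemult` supports
the *design* of such studies: how large should the RDS survey be, and how
long a reference period should the roster count use, for the confidence
interval around the estimate to be usefully narrow?

## The variance model

Two independent sources of uncertainty enter the ratio.

**The count.** $M$ is modelled as Poisson: unique individuals accrue onto
a roster (or objects are handed out) approximately independently, so
$\operatorname{var}(M) = \mu_M$. `count_estimate()` lets the user override
`var_m` to explore overdispersed rosters, but Poisson is the default.

**The proportion.** A simple random sample of size $n$ would give
$\operatorname{var}(P) = P(1-P)/n$. Two corrections apply:

* a *design effect* $\mathrm{DEFF} \ge 1$, the ratio of the actual
  design's sampling variance to the simple-random-sampling variance.
  Empirical reviews of RDS surveys place most design effects between 2 and
  4, and that is the default grid in `scenario_grid()`; users with reason
  to expect higher homophily (for example when the survey measures
  attendance of the very programme whose roster supplies $M$) should use
  larger values.
* a *finite population correction* when the survey samples a
  non-negligible fraction of a population of size $N$:

$$\mathrm{se}(P) = \sqrt{\frac{\mathrm{DEFF}\; P(1-P)}{n}}
  \sqrt{\frac{N-n}{N-1}}.$$

The two are combined by the first-order delta method for a ratio of
independent quantities:

$$\operatorname{var}\!\left(\frac{M}{P}\right)
  = \frac{\operatorname{var}(M)}{P^2}
  + \frac{\mu_M^2\,\mathrm{se}(P)^2}{P^4},$$

and the interval is $\widehat{\mathrm{PSE}} \pm z_{1-\alpha/2}
\sqrt{\operatorname{var}(M/P)}$. The $P^4$ denominator is the central
design message: uncertainty explodes when the survey proportion is small,
which is why a longer reference period (larger $M$, hence larger $P$) buys
precision — at the cost of recall bias, which is outside this package's
scope.

### Planning direction

For sample-size calculation the same algebra is run forwards:
$n = \mathrm{DEFF}\,P(1-P)/\mathrm{se}(P)^2$ (`required_n_srs()`, reported
as a ceiling — conservative integer sample sizes, exact algebra
internally), deflated for a finite population by
$n_\mathrm{adj} = n_0 / (1 + (n_0-1)/N)$ (`fpc_adjust_n()`, kept
real-valued). The finite-population correction acts in one direction only:
it *reduces* the sample size needed, and equivalently *reduces* the
standard error achieved by a given $n$; at a census ($n = N$) the survey
contribution vanishes entirely. Both the planning direction
(`required_n_srs()` then `fpc_adjust_n()`) and the evaluation direction
(`se_p_achieved()`) are exposed because protocols need each at different
stages.

### Numerical and interface choices

* The normal quantile is computed from the requested confidence level
  (`qnorm(0.975)` = 1.9600 at the default 0.95) rather than hard-coding
  1.96; at the default level the two agree to the precision any planning
  table prints.
* Lower confidence bounds may be negative when $P$ and $n$ are small.
  They are reported as computed by default, so planning-table widths are
  exactly $2z\,\mathrm{se}$; `truncate_lower = TRUE` floors the bound at
  $M$, below which the population logically cannot be (since $P \le 1$).
* $P = 1$ is allowed for estimation (the roster covers everyone:
  $\mathrm{PSE} = M$) but rejected by the sample-size formulas, which
  have no sampling-variance model at the boundary.
* Planning curves (`build_curves()`) fix the point estimate: for each
  scenario the count is set to $m = p \cdot \mathrm{PSE}_\mathrm{assumed}$
  so every row estimates the same population, and the finite-population
  correction uses the assumed population itself as $N$. Curves are emitted
  as tidy tables, one row per (DEFF, $p$, $n$) cell, rather than figures;
  plotting them is a one-liner the user controls.
* The census helper `plausible_population_range()` multiplies a prevalence
  range by a demographic denominator (fraction of the census population in
  the group the prevalences refer to), keeping full precision until a
  final rounding to whole persons and returning the exact endpoints
  alongside, because published ranges are often themselves rounded at
  intermediate steps.

## What the Monte-Carlo generator simulates

`sim_config()` + `run_validation()` provide the brute-force check of the
analytic machinery, simulating exactly the process the formulas assume:

* $M \sim \mathrm{Poisson}(\mu_M)$ with $\mu_M = P \cdot \mathrm{PSE}$;
* the survey proportion from $n$ subjects in clusters of `cluster_size`
  (default 10). Each cluster's success probability is drawn from a beta
  distribution with mean $P$ and variance $\rho P(1-P)$, where the
  intraclass correlation $\rho = (\mathrm{DEFF}-1)/(\mathrm{cluster\
  size}-1)$; within clusters draws are Bernoulli. The pooled proportion
  then has sampling variance exactly $\mathrm{DEFF} \cdot P(1-P)/n$ — the
  definition of the design effect. When the cluster size does not divide
  $n$ the final cluster is truncated and the realized design effect is
  recomputed and stored in the config.
* optionally, with a finite `pop_n` (and $\mathrm{DEFF} = 1$), the survey
  is drawn without replacement from a synthetic roster — hypergeometric
  sampling — which realizes the finite-population correction factor. There
  is no standard generative model that yields both a controlled design
  effect and without-replacement sampling at once, so the two modes are
  separate.

Each replicate forms the estimate and its analytic interval the way a
field analyst would — plugging the *observed* count and proportion into
the formulas, with the design's DEFF and $N$ — and the run reports the
empirical standard errors, the empirical coverage of the nominal interval
with its Monte-Carlo standard error, and the analytic counterparts
evaluated at the truth. Replicates in which no sampled subject reports the
service ($\hat P = 0$) leave the estimate undefined; they are excluded and
counted, and if they exceed 1% of replicates the run aborts — at such a
small $P$ the analytic method should not be trusted, and the simulator
says so rather than papering over it. Runs are bitwise reproducible from
the config's seed.

Beta-binomial clustering is a *realization* of a design effect, not a
model of RDS itself: no referral chains, seeds, waves, or homophily are
simulated, so passing validation shows the analytic formulas are faithful
to their own assumptions, not that an RDS survey will achieve the assumed
DEFF.

## What validation shows — and the known limits of the delta method

At the package's reference design ($P = 0.063$, $n = 1500$,
$\mathrm{DEFF} = 3$, true population 15,000, $10^5$ replicates) the
simulated se($P$) matches the analytic value to within Monte-Carlo noise
and the nominal 95% interval covers about 94.9% of the time. Two
second-order effects are visible, are expected, and are asserted as such
in the test suite:

* the first-order delta standard deviation sits below the brute-force
  standard deviation of $M/P$ — by roughly 9% at this design — because the
  omitted terms of order $(\mathrm{se}(P)/P)^2$ grow as $P$ shrinks;
* the ratio estimator is biased upward by approximately the factor
  $1 + \mathrm{cv}(P)^2$, about +3% here.

Both shrink quadratically as $\mathrm{cv}(P) = \mathrm{se}(P)/P$ falls; at
$P = 0.4$ designs the analytic and brute-force values agree within 2%. At
very small $P$ (the 1-month reference period, $P \approx 0.006$) coverage
degrades and zero-proportion replicates appear; the validation layer
reports or aborts rather than asserting nominal behaviour there.

Simulation sizes used by the test suite ($10^5$ replicates for the
standard-error comparison, $10^4$ for coverage, a few thousand for
property checks) were chosen so Monte-Carlo error is well below the
tolerances being checked while a full test run stays interactive.

## Limitations

* DEFF is an input. The package neither estimates it from RDS data nor
  simulates referral dynamics; if the achieved design effect exceeds the
  assumed one, intervals will be anti-conservative.
* Independence of $M$ and $P$ is assumed (no covariance term in the delta
  variance). Dependence between service attendance and survey recruitment
  is a bias issue the method cannot see.
* Intervals are normal-approximation and symmetric; at small $P$ the true
  sampling distribution of $M/P$ is right-skewed, and a log-scale interval
  would be a reasonable future option.
* Bias sources — recall error in the reference period, duplicate roster
  identifiers, non-representative RDS recruitment — are out of scope;
  only random error is quantified.
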