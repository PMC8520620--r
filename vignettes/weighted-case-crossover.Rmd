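---
title: "Removing within-subject exposure-dependency bias in case-crossover studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing within-subject exposure-dependency bias in case-crossover studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccxover)
```

## The design and the bias

A unidirectional case-crossover study compares, within each case, the
exposure at the period in which the outcome occurred (the case period,
$m = 0$) with the exposure at $M$ earlier control periods
($m = 1, \dots, M$, counted backward in time). Because the comparison is
within-person, time-invariant confounding cancels. The conventional
analysis treats the case period as the "case" of a 1:M matched set and
maximises the conditional logistic likelihood

$$L_{SCL} = \prod_{i=1}^{N} \frac{e^{\beta x_{i0}}}{\sum_{j=0}^{M} e^{\beta x_{ij}}}.$$

This likelihood is correct only under *global exchangeability*: every
permutation of a person's exposure sequence must be equally probable.
Pharmacological exposure is usually autocorrelated — a person on a cyclic
regimen who is exposed today was predictably exposed or unexposed on
specific recent days — and then $OR_{SCL}$ is biased even when the
population prevalence of exposure is constant over time. The bias grows
with the number of control periods; it vanishes at $M = 1$, where pairwise
and global exchangeability coincide.

More generally, the likelihood that is valid under arbitrary dependency
weights each permutation $\kappa$ of the observed periods by its population
probability:

$$L_{VF} = \prod_i \frac{e^{\beta x_{i0}} \sum_{\kappa^*} P\{X_{i\kappa^*}\}}
  {\sum_{\kappa} e^{\beta x_{i\kappa(0)}} P\{X_{i\kappa}\}},$$

the sums running over permutations (numerator: those placing a value equal
to the observed case-period value at $m = 0$). This estimator
(`cc_fit(..., "vf")`) needs the full distribution of exposure sequences in
the source population — rarely available — and fails entirely for strata
where all admissible arrangements share one case-period value (the
*positivity* condition).

## The weighting method

The package's central estimator assumes only *pairwise exchangeability*,

$$P(X_0 = 1, X_m = 0) = P(X_0 = 0, X_m = 1), \quad m = 1, \dots, M,$$

which is implied by a stationary exposure process (no time trend). Summing
the paired identity over $m$ and estimating each side by observed person-
time gives an estimate of the relative probability of being exposed at the
case period that uses the cases alone. With $a_1$ discordant cases exposed
at the case period, carrying $PT_{10,i}$ unexposed control periods each,
and $a_0$ discordant cases unexposed at the case period with $PT_{01,i}$
exposed control periods:

$$\pi_{10} = \frac{\pi_1}{\pi_0}
  = \frac{\overline{PT_{01}}}{\overline{PT_{10}}},
  \qquad \overline{PT_{10}} = \tfrac{1}{a_1}\textstyle\sum_i PT_{10,i},
  \quad \overline{PT_{01}} = \tfrac{1}{a_0}\textstyle\sum_i PT_{01,i}.$$

Each exposed period of case $i$ is then weighted $w_{i1} = \pi_{10}/m^1_i$
and each unexposed period $w_{i0} = 1/m^0_i$, where $m^1_i + m^0_i = M+1$
are the case's exposed/unexposed period counts, and the weighted
conditional likelihood

$$L_G = \prod_i \frac{e^{\beta x_{i0}}}{\sum_j w_{ij} e^{\beta x_{ij}}}$$

is maximised. The weights collapse the denominator of every binary-exposure
case to $1 + \pi_{10} e^{\beta}$, which yields the closed form

$$OR_G = e^{\hat\beta} = \frac{a_1}{a_0}\,\frac{1}{\pi_{10}}
  = \frac{\sum_i PT_{10,i}}{\sum_i PT_{01,i}} = OR_{MH},$$

the matched Mantel–Haenszel odds ratio. `cc_fit(..., "greenland")` computes
both the closed form and the weighted Newton–Raphson fit and reports a
diagnostic if they disagree beyond $10^{-6}$; `cc_fit(..., "mh")` computes
the Mantel–Haenszel ratio directly from per-case $2\times2$ strata.

With a binary time-varying confounder $z$ the linear predictor becomes
$\beta x + \gamma z$ while the weights are still computed from the exposure
alone; this keeps all periods in the analysis, unlike Maclure-style
stratification of the Mantel–Haenszel estimator
(`stratify_by_confounder = TRUE`), which deletes control periods whose
confounder state differs from the case period's and can introduce bias of
its own. Cases that are exposure-concordant but confounder-discordant stay
in the adjusted fit: their period weight is constant within the case and
cancels from the conditional likelihood.

Because the model-based variance $v(\hat\beta) = 1/a_0 + 1/a_1$ treats
$\pi_{10}$ as known, the recommended interval is a case-resampling
percentile bootstrap (`cc_boot_control()`), which re-estimates $\pi_{10}$
and refits in every replicate.

## Diagnosing the bias

Since $OR_{MH}$ is unbiased under pairwise exchangeability while $OR_{SCL}$
is not, their relative discrepancy $|OR_{SCL} - OR_{MH}|/OR_{MH}$ is a
practical pre-analysis diagnostic. `cc_diagnose()` reports it and flags
values above a pre-specified threshold; 5–10% is a sensible range and the
default is 10%. A time-varying confounder, if present, is ignored for this
comparison — it affects both estimators similarly and would only blur the
signal of interest.

```{r diagnose}
cases <- cc_expected_cases(cc_population())
cc_diagnose(cases)
```

## What the simulator emulates

`cc_population()` builds a dynamic population on a cyclic regimen: by
default a 7-day cycle with drug taken on days 1 and 4, observed over the
case day and 21 daily control periods, 10,000 patients per subgroup. One
subgroup exists per cycle phase, and treatment churn is represented by a
*stopper* (follows its phase in all control periods, unexposed at the case
period) and a *starter* (exposed at the case period only). This
construction makes the exposed fraction exactly 1/4 on every single day —
stationarity holds exactly, hence pairwise exchangeability holds exactly,
so any bias observed in $OR_{SCL}$ is attributable to within-subject
dependency alone. Requesting only one of the stopper/starter pair breaks
stationarity and is refused.

Cases are generated as *expected counts*, not sampled: a subgroup exposed
at the case period contributes $N \cdot RR \cdot r_0$ cases and an
unexposed subgroup $N \cdot r_0$, each emitted as one history with a
frequency multiplicity. Defaults $r_0 = 0.001$ and $RR = 4$ give 140 cases
and make every binary-exposure result bit-for-bit deterministic; non-integer
expected counts are refused rather than rounded. The confounder scenario
(`cc_expected_cases_confounded()`) splits each subgroup by the case-period
confounder state with rates scaled by $RR_z = 2$ and confounder prevalences
$f_0 = 0.2$ (unexposed periods) and $f_1 = 0.4$ (exposed periods), giving
184 cases; control-period confounder states are drawn independently as
Bernoulli($f_1$) or Bernoulli($f_0$), the only stochastic ingredient in the
package's simulations, under an explicit seed.

What the simulator does *not* emulate: exposure time trends (so it cannot
probe case-time-control territory), carry-over effects, event rates that
change within an exposed spell, within-subject dependency of the
confounder, measurement error, or the irregular exposure patterns of real
claims data. Passing tests on these simulations therefore demonstrate
correctness of the estimators under the stated exchangeability assumptions,
not robustness to their violation.

```{r headline}
cc_fit(cases, "scl")$or        # biased upward
cc_fit(cases, "greenland")$or  # recovers the true rate ratio 4
```

## Multi-day periods

Real analyses rarely use 1-day periods. `cc_aggregate()` collapses daily
histories into periods of $d$ days, counting backward from the case day so
the case day is always the most recent day of period 0; only complete
periods are kept and the oldest leftover days are dropped. Four exposure
definitions are supported: last day for all periods (I); last day for the
case period with half-or-more days (II) or any day (III) for control
periods; any day for all periods (IV). "Half" is read inclusively
($\ge d/2$ exposed days), the literal reading of the rule; a 2-day period
with one exposed day is exposed under II. Definitions III and IV differ
only at the case period. Since the period's exposure is set by its last
day under I–III, any multi-day period acts like a built-in washout for the
earlier days of the period.

## Numerical choices

* **Optimisation.** All likelihood fits use Newton–Raphson from
  $\beta = \gamma = 0$, tolerance $10^{-10}$ on the parameter change,
  at most 100 iterations, with step-halving whenever a step would decrease
  the log-likelihood. The conditional likelihoods here are concave, so this
  is reliable; a singular one-parameter Hessian falls back to bisection on
  the score. Parameters running past $|\theta| > 30$ are reported as
  separation (unbounded estimate) with `converged = FALSE` rather than an
  arbitrary large number being returned silently.
* **Degenerate inputs.** $\pi_{10}$ requires discordance in both directions
  ($a_1 > 0$ and $a_0 > 0$); otherwise the weighting method raises a
  degenerate-data error. A Mantel–Haenszel ratio with an empty numerator or
  denominator is reported as $0$ or $\infty$ with a diagnostic rather than
  an error, since it can arise in legitimate bootstrap replicates.
  Concordant cases are retained in datasets but contribute to no
  likelihood; their count is reported.
* **Mantel–Haenszel variance.** The matched-pair variance
  $1/a_1 + 1/a_0$ is exact at $M = 1$. For $M > 1$ the package uses the
  Robins–Breslow–Greenland variance over the per-case strata — an
  implementation choice, since no formula is forced by the estimator — which
  reduces to the matched-pair variance at $M = 1$.
* **Permutation probabilities.** The Vines–Farrington fit groups the
  permutations of each case's observed periods by the value placed at the
  case period. For a binary exposure the group masses are sums of table
  probabilities over support sequences with the case's exposed-period
  count; with a confounder, the confounder-given-exposure factor is common
  to all permutations of the observed $(x, z)$ pairs and cancels, so the
  group masses are the exposure-sequence masses scaled by the share of
  observed pairs carrying each $(x, z)$ value. The test suite validates
  this reduction against an oracle that enumerates every permutation
  explicitly with the confounder factors carried through.
* **Bootstrap.** Resampling is of cases (multiplicity-expanded) with
  replacement; percentiles use `quantile(type = 6)`. Replicates that fail
  (e.g. a resample with one-sided discordance) are skipped and counted,
  with a warning diagnostic above 10% failures. Resampling is seeded
  explicitly and leaves the caller's RNG state untouched, so identical
  seeds give identical intervals.

## Problem sizes

The simulations used by the tests and the acceptance script run the
8-subgroup population at $M$ up to 139 daily control periods (8 distinct
histories, 140 cases via multiplicities), the confounder scenario with 184
individually drawn cases at $M = 21$, bootstrap intervals at $B = 1000$,
and a 20-seed replication of the confounder-adjusted fit. All run in
seconds; brute-force oracles (explicit permutation enumeration, likelihood
grid search) are kept at $N \le 8$, $M \le 3$.

## Limitations

The weighting method presumes pairwise exchangeability; under exposure time
trends $\pi_{10}$ is no longer estimable from cases alone and the method is
not valid (checking stationarity needs population or time-control data).
The confounder extension assumes the confounder has no within-subject
dependency of its own. The model-based variance ignores the uncertainty in
$\pi_{10}$ — hence the bootstrap default — and no analytic variance
accounting for the estimated weights is provided. Only binary exposures are
supported; multi-level exposures would need a generalised weight.
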