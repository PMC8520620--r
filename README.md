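# ccxover

Case-crossover analysis that stays honest when a person's exposure history
is autocorrelated.

## The problem

In a case-crossover study each case acts as its own control: the period in
which the outcome occurred (the *case period*, m = 0) is compared with M
earlier *control periods* of the same person. The standard analysis is
conditional logistic regression (CLR) with likelihood

    L = prod_i  exp(b x_i0) / sum_{j=0..M} exp(b x_ij)

This is only valid when every permutation of a person's exposure sequence is
equally probable (*global exchangeability*). Drug exposure rarely works that
way: regimens are cyclic (say, on days 1 and 4 of a 7-day cycle), so the
exposure status of neighbouring days is strongly dependent, and OR_SCL can
be badly biased even when the population exposure prevalence is perfectly
stationary — in the package's built-in cyclic simulation the true rate ratio
4.0 is estimated as 6.02 with 21 daily control periods, rising to 8.71 as
the study period is extended.

## The estimator

Under the weaker assumption of *pairwise exchangeability* — P(exposed at
case period, unexposed at control m) = P(unexposed at case period, exposed
at control m), which holds whenever exposure has no time trend — the
relative probability of being exposed at the case period can be estimated
from the cases alone. With a1 discordant cases exposed at the case period
(carrying PT10_i unexposed control periods each) and a0 discordant cases
unexposed at the case period (PT01_i exposed control periods):

    pi10 = mean(PT01) / mean(PT10)

Each exposed period of case i is then weighted w_i1 = pi10 / m1_i and each
unexposed period w_i0 = 1 / m0_i (m1_i, m0_i = exposed/unexposed period
counts), and the weighted conditional likelihood

    L = prod_i  exp(b x_i0) / sum_j w_ij exp(b x_ij)

yields an unbiased odds ratio OR_G. For a binary exposure it has the closed
form OR_G = (a1/a0) / pi10, identical to the matched Mantel-Haenszel odds
ratio OR_MH = sum PT10_i / sum PT01_i; unlike OR_MH it extends cleanly to a
binary time-varying confounder (linear predictor b x + g z with weights
still computed from the exposure alone). Confidence intervals come from a
case-resampling percentile bootstrap that re-estimates pi10 in every
replicate.

The package also implements the Vines–Farrington estimator (permutation
probabilities supplied as a pattern table, with its positivity diagnostic),
Maclure-stratified Mantel-Haenszel, a bias diagnostic comparing OR_SCL with
OR_MH, a deterministic cyclic-exposure population simulator, and collapsing
of daily histories into multi-day periods under four exposure definitions.

## Worked example

```r
library(ccxover)

pop   <- cc_population()          # 8 subgroups, 7-day cycle, drug on days 1 & 4
cases <- cc_expected_cases(pop)   # 140 expected cases, M = 21

cc_fit(cases, "scl")
#> Case-crossover fit: standard conditional logistic regression
#>   OR(exposure) = 6.022  [4.142, 8.754] (wald, 95%)
#>   informative cases: 140 (0 dropped)

cc_fit(cases, "greenland", boot = cc_boot_control(B = 1000, seed = 7))
#> Case-crossover fit: weighting method (weighted Greenland likelihood)
#>   OR(exposure) = 4.000  [2.880, 5.602] (bootstrap_percentile, 95%)
#>   informative cases: 140 (0 dropped)
#>   pi10 = 0.333

cc_diagnose(cases)
#> Within-subject exposure dependency diagnostic
#>   OR (conditional logistic) = 6.022
#>   OR (Mantel-Haenszel)      = 4.000
#>   relative discrepancy      = 50.5% (threshold 10%)
#>   FLAG: discrepancy exceeds threshold; do not rely on standard
#>   conditional logistic regression  [output wrapped]
```

The standard analysis overestimates the true rate ratio (4.0) by half; the
weighting method recovers it exactly (pi10 = 1/3 matches the population's
stationary 25% exposure prevalence), and the diagnostic flags the
discrepancy that should steer an analyst away from plain CLR.

A command-line front end is installed with the package
(`system.file("cli", "ccxover", package = "ccxover")`) with subcommands
`simulate`, `aggregate`, `estimate`, `diagnose` and `reproduce` over CSV
files.

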