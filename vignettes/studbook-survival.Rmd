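---
title: "Median life expectancy from studbook records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median life expectancy from studbook records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(studbookMLE)
```

## The estimation problem

Studbooks record the dated life events of every animal in a cooperatively
managed *ex situ* population. Two features make naive lifespan averages
unusable. First, many animals are still alive when the data are analyzed:
their lifespans are *right-censored* at the end of the analysis window.
Second, many animals enter observation after birth — they were acquired
later, or were already alive when the analysis window opens — so they are
*left-truncated*: had they died before entering, they would never have been
in the data, and treating them as observed from birth would overstate
survival at young ages. The product-limit (Kaplan-Meier) estimator handles
both, because each animal contributes to the risk set \(N_i\) only over the
ages it was actually under observation (`entry_age` \(< t \le\)
`exit_age`).

Survivorship is anchored at 1.0 at age 365 days. First-year mortality
depends heavily on husbandry and on species-specific rearing, so the
estimates answer the question "given an animal survived its first year,
at what age does half the cohort remain?" Animals that never survive past
365 days of age inside the window contribute nothing.

## Estimator, median and confidence limits

At every age (in whole days) at which some animal dies or is censored, the
deaths \(d_i\) and the number at risk \(N_i\) are tallied (tied deaths are
processed before tied censorings, the standard convention) and

\[\hat L(t) = \prod_{t_i \le t}\bigl[1 - d_i/N_i\bigr], \qquad
\hat V(t) = \hat L(t)^2 \sum_{t_i \le t} \frac{d_i}{N_i (N_i - d_i)}.\]

When an entire risk set dies (\(N_i = d_i\)) the Greenwood summand is
undefined and the variance is flagged unavailable from that age onward.

The median is interpolated linearly between the last estimate above 0.5 and
the first below it, unless some estimate is exactly 0.5, in which case the
earliest such age is used (conservative: the step function's first
crossing). Only ages at which the estimate changes (death ages) take part;
a censoring between the bracketing deaths repeats the previous estimate and
must not shift the interpolation anchor.

Confidence limits invert the log-log-transformed test of
\(L(t) = 0.5\):

\[Z(t) = \bigl\{\ln[-\ln \hat L] - \ln[-\ln 0.5]\bigr\}\,
\hat L \ln \hat L \,/\, \sqrt{\hat V}.\]

Dividing by \(\sqrt{\hat V}\) makes \(Z\) asymptotically standard normal,
which is what gives the \(\pm 1.96\) cutoffs their meaning. The 95%
confidence set is the set of death ages with \(|Z| < 1.96\); the limits are
its smallest and largest members. The endpoints are restricted to observed
event ages — the estimate only changes there, so the test-inversion set is
only evaluated there. A limit is undefined when the curve never becomes
significantly different from 0.5 on that side (for the upper limit, no age
has \(Z \le -1.96\)); this feeds quality test 4. Restricting endpoints to
event ages makes the interval, if anything, slightly narrower than an
interpolated one; measured coverage at the default study conditions is
about 93% (see below), within the accepted 92–98% band around the nominal
95%.

## The five data-quality tests

A stratum's MLE is flagged *data deficient* unless all five pass:

1. **calculable** — the curve reaches 0.5 at all;
2. **first_class_n** — strictly more than 30 animals at risk in the first
   one-year age class (ages 365–729 days);
3. **median_n** — strictly more than 20 at risk at the median;
4. **ci_defined** — both 95% limits defined;
5. **ci_precise** — interval length at most 33% of the maximum longevity
   observed in the stratum.

Two quantities in these tests are not fully pinned down by convention and
were fixed as package design choices. The "first age class" count
`n_start` is the *maximum* at-risk count over \([365, 730)\) days — the
one-year age-class reading used in life tables — because with delayed entry
the at-risk count can peak anywhere in that interval; the choice is
recorded in the curve object. The count "at the median", `n_at_median`, is
\(N_i\) at the event age used as the lower interpolation anchor's partner
(the first age with \(\hat L < 0.5\), or the exact-0.5 age). Test 5 uses
the analyzed stratum's own maximum exit age as "maximum longevity" rather
than the whole studbook's, so a sex stratum is judged against its own data.
A failing stratum still reports its (unreliable) value alongside the flag.

## Record validation and exposure

Records with an unknown birth date, unknown entry or end date, an unknown
institution, or events dated before birth are excluded before analysis,
each with a logged reason code; validation never hard-fails on content.
Only structural file problems (missing columns, duplicated identifiers)
are errors. Animals of unknown sex are retained and contribute to the
overall stratum only, so the overall sample size equals male + female +
unknown-sex exposures exactly. A recorded death after the window end is
unobserved within the window and is treated as censoring at the window
end; a death exactly on the window end date counts as an event (window
boundaries are inclusive). Ages are whole-day differences between calendar
dates with no further leap-year adjustment. Animals acquired from the wild
with estimated birth dates are not given partial credit: a known birth
date is required.

## What the synthetic generator emulates

`generate_studbook()` produces studbooks with a known survival law so every
downstream stage is testable without real data: birth dates spread across
decades, first-year deaths (default probability 0.2, a realistic managed-
population figure; these are excluded downstream by the starting age),
adult lifespans \(365 + \mathrm{Weibull}(k, \lambda)\) days, right
censoring arising naturally from deaths falling past the window end, and
left truncation from animals acquired 1–5 years after their first
birthday. The Weibull was chosen for its flexible hazard shapes; the
default \(k = 1\), \(\lambda = 3650\) days gives exponential adult
mortality with true conditional median \(365 + \lambda(\ln 2)^{1/k} =
2895\) days \(= 7.93\) years. The default window (1980-01-01 to
2018-12-31) with births uniform over 1983-06-01 to 2013-06-01 yields
roughly 20% censoring among adult deaths — computable in closed form for
the exponential as the average of \(e^{-t/\lambda}\) over the available
observation spans — and the default import fraction is 0.2.

One subtlety matters for correctness: an animal that dies before its drawn
acquisition date never appears in the generated studbook. Keeping such
animals (observed from birth instead) would make entry times depend on
lifespans — informative truncation — and biases the estimated median
downward by several percent; dropping them reproduces the sampling scheme
under which the delayed-entry product-limit estimator is consistent.

The generator does *not* emulate realistic features such as pedigree
structure, transfer networks, cohort effects in mortality, estimated birth
dates, or recording errors. Passing tests therefore demonstrate the
statistical machinery, not robustness to the data-quality issues real
studbooks need human vetting for.

## Verification and measured behaviour

The test suite checks, among others: exact agreement of the curve with the
empirical survivor fraction when there is no truncation or censoring;
agreement with an independent survival library (`survival::survfit`) to
within \(10^{-10}\) on 100 random small cohorts with ties, delayed entry
and censoring, for both the curve and the Greenwood variance; median and
confidence limits within one event age of that library (interpolation and
step conventions differ at the crossing); a four-animal cohort worked by
hand (\(\hat L(400) = 0.75\), \(\hat V(400) = 0.046875\),
\(\hat L(700) = 0.375\), median \(= 600\) days); the quality-test
thresholds exactly at 30/31, 20/21 and 33%/34%; 92–98% coverage of the
true conditional median over 500 replicate studbooks of 500 animals at the
default conditions; and recovery of the true conditional median by the
median of 200 replicate estimates to within 3%. Replicate counts (500 and
200, with 500 animals per studbook) were chosen to make the Monte-Carlo
standard error of a coverage proportion about one percentage point.

Numerical choices: exact-0.5 detection uses a \(10^{-12}\) absolute
tolerance on the survival estimate (products of small integer ratios);
events on the same day are aggregated; curves extend to the largest
observed exit age and no further.

## Known limitations

- The confidence limits are asymptotic; in tiny strata the inversion set
  can be empty or one-sided, which the quality tests then flag.
- Ages are whole days; sub-day event ordering is not represented beyond
  the deaths-before-censorings convention.
- The per-species dataset reader validates schema and numbers but taxon
  labels outside the six named vertebrate/invertebrate classes are grouped
  as "other" rather than rejected.
- The overall stratum has no data-deficiency flag of its own in the
  dataset schema; taxon summaries therefore always include all non-missing
  overall values, and exclude flagged sex-specific values by default.
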