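# studbookMLE

Median life expectancy from *ex situ* population records by left-truncated,
right-censored Kaplan-Meier analysis.

Zoo and aquarium populations are tracked in *studbooks*: individual-level
registries of every animal's birth, transfers and death. Longevity in such
populations is best summarized not by the single longest-lived animal but by
the **median life expectancy (MLE)** — the age at which estimated
survivorship falls to 0.5, conditional on surviving the first year of life.
`studbookMLE` estimates sex-specific MLEs with 95% confidence limits from
studbook-like delimited-text files, applies the five data-quality tests that
decide whether an estimate is reliable, and reads/writes a per-species MLE
dataset schema with taxon-level summaries. It is aimed at population
biologists working with managed-population records and at comparative
demographers who need statistically derived longevity estimates.

## The model

Survivorship is estimated with the product-limit (Kaplan-Meier) estimator
over age in days,

L̂(t) = ∏_{tᵢ ≤ t} (1 − dᵢ/Nᵢ),

where dᵢ is the number of deaths at age tᵢ and Nᵢ the number at risk
(animals with entry age < tᵢ ≤ exit age). Animals alive at the end of the
analysis window are right-censored; animals entering observation after birth
(acquisitions, or a window starting after their birth) are left-truncated
and join risk sets only past their entry age. Survivorship is anchored at
1.0 at age 365 days: first-year mortality is strongly management-dependent,
and animals that did not survive to their first birthday are excluded.

The MLE is read off the curve by linear interpolation: with [x₀, L₀] the
last (age, survival) pair above 0.5 and [x₁, L₁] the first below,

MLE = x₀ + (L₀ − 0.5)(x₁ − x₀)/(L₀ − L₁),

divided by 365 to give years. 95% confidence limits come from inverting the
log-log-transformed statistic

Z = {ln[−ln L̂] − ln[−ln 0.5]} · L̂ ln L̂ / √V̂,

with V̂ the Greenwood variance V̂ = L̂² Σ dᵢ/(Nᵢ(Nᵢ−dᵢ)): the limits are the
smallest and largest death ages at which |Z| < 1.96.

Five data-quality tests gate each stratum: (1) the median is calculable;
(2) more than 30 animals at risk in the first one-year age class; (3) more
than 20 at risk at the median; (4) both confidence limits defined; (5) the
interval no longer than 33% of the maximum observed longevity. A stratum
failing any test is flagged *data deficient* (the value is still reported).

## Worked example

Simulate a studbook with known survival structure (500 animals, exponential
adult lifespans with a 10-year scale, ~20% censoring, 20% delayed entry),
then analyze it per sex:

```r
library(studbookMLE)

cfg <- synthetic_config(seed = 42)
write_studbook(generate_studbook(cfg), "demo_studbook.csv")

records <- parse_studbook("demo_studbook.csv")
v <- validate_records(records)          # exclusion log in v$exclusions
analysis <- analyze_population(v$records,
                               analysis_window("1980-01-01", "2018-12-31"))
analysis
#> overall MLE 8.0 yr (95% CL 6.9-9.3), n = 367, n_start = 296
#>   quality tests: all pass
#> male    MLE 7.5 yr (95% CL 6.3-10.3), n = 171, n_start = 143
#>   quality tests: all pass
#> female  MLE 8.0 yr (95% CL 6.8-9.3), n = 175, n_start = 136
#>   quality tests: all pass
```

The overall stratum uses all 367 usable exposures (males, females and
unknown-sex animals); each MLE is the age at which that stratum's curve
crosses 0.5, in years. The generator's true conditional median here is
`to_years(true_conditional_median(cfg))` = 7.93 years, inside every
stratum's confidence limits. `report_table(analysis)` returns the same
figures as a data frame together with the five quality-test outcomes.

The same pipeline is available from a shell through the installed script:

```sh
studbook-mle analyze --studbook demo_studbook.csv --window window.cfg
studbook-mle simulate --config sim.cfg --seed 7 --out sim.csv
studbook-mle summarize --dataset mle_dataset.csv --exclude-deficient
studbook-mle validate --studbook demo_studbook.csv
```

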