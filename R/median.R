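# Median life expectancy (MLE) and its 95% confidence limits.  The median
# is read off the product-limit curve by linear interpolation between the
# last estimate above 0.5 and the first below it; the confidence limits come
# from inverting the log-log-transformed Z statistic at +/-1.96.

.EXACT_TOL <- 1e-12

# (age, survival) pairs at which the estimate changes: death ages only,
# prefixed with the anchor (start_age, 1); censoring-only ages repeat the
# previous estimate and take no part in interpolation
.curve_steps <- function(curve) {
  d <- curve$n_event > 0L
  list(age = c(curve$start_age, curve$age[d]), surv = c(1, curve$surv[d]))
}

#' Median of a product-limit survival curve
#'
#' Returns the age at which the estimated survivorship equals 0.5.  If some
#' estimate falls exactly on 0.5, the earliest such age is returned;
#' otherwise, with \eqn{[x_0, L_0]} the last (age, survival) pair above 0.5
#' and \eqn{[x_1, L_1]} the first below, the median is interpolated as
#' \deqn{x_0 + (L_0 - 0.5)(x_1 - x_0)/(L_0 - L_1).}
#'
#' @param curve A [km_curve()].
#' @return Age in days, or `NA` when the curve never reaches 0.5 (the median
#'   cannot be calculated; quality test 1 fails).
#' @export
median_from_curve <- function(curve) {
  st <- .curve_steps(curve)
  exact <- which(abs(st$surv - 0.5) <= .EXACT_TOL)
  if (length(exact) > 0L) return(st$age[exact[1L]])
  below <- which(st$surv < 0.5)
  if (length(below) == 0L) return(NA_real_)
  i1 <- below[1L]
  x0 <- st$age[i1 - 1L]; L0 <- st$surv[i1 - 1L]
  x1 <- st$age[i1];      L1 <- st$surv[i1]
  x0 + (L0 - 0.5) * (x1 - x0) / (L0 - L1)
}

#' Convert an age in days to years
#'
#' Ages are divided by 365 (the analysis works in whole days; reported life
#' expectancies are in years).  `NA` propagates.
#'
#' @param age_days Age(s) in days.
#' @return Age(s) in years.
#' @export
to_years <- function(age_days) age_days / 365

#' Log-log Z statistic for testing L(t) = 0.5
#'
#' \deqn{Z = \{\ln[-\ln \hat L] - \ln[-\ln 0.5]\}\,\hat L \ln \hat L /
#' \sqrt{\hat V}} with \eqn{\hat V} Greenwood's variance.  Undefined (`NA`)
#' unless \eqn{0 < \hat L < 1} and \eqn{\hat V} is available and positive.
#'
#' @param curve A [km_curve()].
#' @param i Index (or indices) into the curve's event ages.
#' @return Z value(s); `NA` where undefined.
#' @export
z_statistic <- function(curve, i = seq_along(curve$age)) {
  L <- curve$surv[i]; V <- curve$var[i]
  ok <- curve$var_defined[i] & !is.na(V) & V > 0 & L > 0 & L < 1
  z <- rep(NA_real_, length(i))
  z[ok] <- (log(-log(L[ok])) - log(-log(0.5))) * (L[ok] * log(L[ok])) /
    sqrt(V[ok])
  z
}

#' 95% confidence limits for the median by test inversion
#'
#' The confidence set is the set of death ages whose survival estimate is
#' not significantly different from 0.5 on the log-log scale
#' (\eqn{|Z| < 1.96}); the limits are its smallest and largest members.  A
#' limit is undefined when the curve never becomes significantly different
#' from 0.5 on that side: the lower limit requires some age with
#' \eqn{Z \ge 1.96} (survival clearly above 0.5), the upper limit some age
#' with \eqn{Z \le -1.96} (survival clearly below 0.5).
#'
#' @param curve A [km_curve()].
#' @param z_crit Critical value (default 1.96 for 95% limits).
#' @return List with `lcl` and `ucl` in days (`NA` when undefined).
#' @export
median_ci <- function(curve, z_crit = 1.96) {
  deaths <- which(curve$n_event > 0L)
  z <- z_statistic(curve, deaths)
  ages <- curve$age[deaths]
  inside <- !is.na(z) & abs(z) < z_crit
  if (!any(inside)) return(list(lcl = NA_real_, ucl = NA_real_))
  lcl <- if (any(!is.na(z) & z >= z_crit)) min(ages[inside]) else NA_real_
  ucl <- if (any(!is.na(z) & z <= -z_crit)) max(ages[inside]) else NA_real_
  list(lcl = lcl, ucl = ucl)
}

#' The five data-quality tests for a median life expectancy estimate
#'
#' A stratum's MLE is considered reliable only if all five pass:
#' 1. `calculable` — the median can be calculated (the curve reaches 0.5);
#' 2. `first_class_n` — more than 30 individuals at risk in the first
#'    one-year age class;
#' 3. `median_n` — more than 20 individuals at risk at the median;
#' 4. `ci_defined` — both 95% confidence limits are defined;
#' 5. `ci_precise` — the confidence interval is no longer than 33% of the
#'    maximum longevity observed in the stratum.
#'
#' A failing stratum is flagged data-deficient; the (possibly unreliable)
#' MLE value is still reported alongside the flag.
#'
#' @param curve A [km_curve()] (supplies `n_start` and `max_longevity`).
#' @param mle,lcl,ucl Median and confidence limits in days (`NA` allowed).
#' @param n_at_median Number at risk at the median age (`NA` allowed).
#' @return Named logical vector `calculable`, `first_class_n`, `median_n`,
#'   `ci_defined`, `ci_precise`.
#' @export
quality_tests <- function(curve, mle, lcl, ucl, n_at_median) {
  ci_defined <- !is.na(lcl) && !is.na(ucl)
  c(calculable    = !is.na(mle),
    first_class_n = curve$n_start > 30L,
    median_n      = !is.na(n_at_median) && n_at_median > 20L,
    ci_defined    = ci_defined,
    ci_precise    = ci_defined && (ucl - lcl) <= 0.33 * curve$max_longevity)
}

# number at risk at the event age used for the median: the first age with
# L < 0.5, or the exact-0.5 age
.n_at_median <- function(curve) {
  exact <- which(abs(curve$surv - 0.5) <= .EXACT_TOL)
  i <- if (length(exact) > 0L) exact[1L] else which(curve$surv < 0.5)[1L]
  if (is.na(i)) NA_integer_ else curve$n_risk[i]
}

#' Full median-life-expectancy result for one stratum
#'
#' Runs the whole chain — event table, product-limit curve, median,
#' confidence limits, quality tests — on a set of exposures.
#'
#' @param exposures Exposure data frame (possibly zero rows).
#' @param start_age_days Starting age in days (default 365).
#' @return Object of class `mle_result`: a list with `sample_size`,
#'   `n_start`, `n_at_median`, `mle_days`, `mle_years`, `lcl_years`,
#'   `ucl_years`, `max_longevity`, `tests` (five named booleans),
#'   `data_deficient`, and the fitted `curve` (`NULL` for an empty stratum,
#'   whose tests all fail).
#' @export
mle_result <- function(exposures, start_age_days = 365L) {
  empty_tests <- c(calculable = FALSE, first_class_n = FALSE,
                   median_n = FALSE, ci_defined = FALSE, ci_precise = FALSE)
  if (is.null(exposures) || nrow(exposures) == 0L)
    return(structure(list(sample_size = 0L, n_start = 0L,
                          n_at_median = NA_integer_,
                          mle_days = NA_real_, mle_years = NA_real_,
                          lcl_years = NA_real_, ucl_years = NA_real_,
                          max_longevity = NA_integer_, tests = empty_tests,
                          data_deficient = TRUE, curve = NULL),
                     class = "mle_result"))
  curve <- km_curve(build_event_table(exposures, start_age_days))
  mle <- median_from_curve(curve)
  ci <- median_ci(curve)
  n_med <- .n_at_median(curve)
  tests <- quality_tests(curve, mle, ci$lcl, ci$ucl, n_med)
  structure(list(sample_size = curve$n, n_start = curve$n_start,
                 n_at_median = n_med,
                 mle_days = mle, mle_years = to_years(mle),
                 lcl_years = to_years(ci$lcl), ucl_years = to_years(ci$ucl),
                 max_longevity = curve$max_longevity, tests = tests,
                 data_deficient = !all(tests), curve = curve),
            class = "mle_result")
}

#' @export
print.mle_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f", v)
  cat(sprintf("MLE %s yr (95%% CL %s-%s), n = %d, n_start = %d\n",
              fmt(x$mle_years), fmt(x$lcl_years), fmt(x$ucl_years),
              x$sample_size, x$n_start))
  cat(sprintf("  quality tests: %s%s\n",
              paste(names(x$tests)[!x$tests], collapse = ", "),
              if (all(x$tests)) "all pass" else " FAIL"))
  if (x$data_deficient) cat("  flagged data deficient\n")
  invisible(x)
}
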