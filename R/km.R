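# Product-limit (Kaplan-Meier) machinery for left-truncated, right-censored
# exposures measured in whole days of age.  Risk-set membership uses the
# standard delayed-entry convention entry_age < t <= exit_age, and tied
# deaths are processed before tied censorings.

# count of values < t for each t, both integer-valued
.count_below <- function(sorted_vals, t) findInterval(t - 0.5, sorted_vals)

#' Tally deaths, censorings and risk sets at event ages
#'
#' Builds the event table underlying the product-limit estimator: for every
#' age (in days) at which an individual dies or is censored, the number of
#' deaths \eqn{d_i}, censorings \eqn{c_i}, and the number at risk \eqn{N_i}
#' (individuals with `entry_age < t <= exit_age`; an entrant at age `a` is
#' not at risk for an event at exactly `a`).  Censoring-only ages are
#' retained.
#'
#' @param exposures Exposure data frame from [compute_exposure()].
#' @param start_age_days Starting age of the analysis (days); survivorship
#'   is 1.0 here.  Default 365.
#' @return A data frame of class `km_table` with columns `age`, `n_risk`,
#'   `n_event`, `n_censor`, carrying attributes `start_age`, `n` (number of
#'   exposures), `max_longevity` (largest exit age) and `n_start` (maximum
#'   at-risk count over the first one-year age class,
#'   `[start_age, start_age + 365)`).
#' @export
build_event_table <- function(exposures, start_age_days = 365L) {
  if (is.null(exposures) || nrow(exposures) == 0L)
    stop("no usable individuals")
  stopifnot(all(exposures$entry_age < exposures$exit_age),
            all(exposures$entry_age >= start_age_days))

  entry_s <- sort(as.numeric(exposures$entry_age))
  exit_s  <- sort(as.numeric(exposures$exit_age))

  ages <- sort(unique(exposures$exit_age))
  n_event  <- vapply(ages, function(a)
    sum(exposures$exit_age == a & exposures$event), 0L)
  n_censor <- vapply(ages, function(a)
    sum(exposures$exit_age == a & !exposures$event), 0L)
  # N_i counts everyone with entry < t <= exit; ties at t (deaths and
  # censorings alike) are still at risk at t
  n_risk <- .count_below(entry_s, ages) -
    .count_below(exit_s, ages)          # exits strictly before t
  n_risk <- as.integer(n_risk)

  # n_start: maximum at-risk count over the first one-year age class; the
  # step function N(t) changes only just after an entry or exit
  first_class <- c(start_age_days, start_age_days + 365L)
  cand <- unique(c(start_age_days + 1L,
                   exposures$entry_age + 1L, exposures$exit_age + 1L))
  cand <- cand[cand > first_class[1L] & cand < first_class[2L]]
  n_start <- if (length(cand) == 0L) 0L else
    max(as.integer(.count_below(entry_s, cand) - .count_below(exit_s, cand)))

  structure(
    data.frame(age = as.integer(ages), n_risk = n_risk,
               n_event = as.integer(n_event), n_censor = as.integer(n_censor)),
    class = c("km_table", "data.frame"),
    start_age = as.integer(start_age_days),
    n = nrow(exposures),
    max_longevity = as.integer(max(exposures$exit_age)),
    n_start = n_start
  )
}

#' Product-limit survival curve with Greenwood variance
#'
#' Computes the Kaplan-Meier estimator
#' \eqn{\hat L(t) = \prod_{t_i \le t} (1 - d_i/N_i)} over the event table,
#' anchored at \eqn{\hat L = 1} at the starting age, together with
#' Greenwood's variance (see [greenwood_variance()]).  Censoring-only ages
#' leave the estimate unchanged but are retained in the curve.
#'
#' @param table A `km_table` from [build_event_table()].
#' @return An object of class `km_curve`: a list with vectors `age`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `var`, `var_defined`
#'   (Greenwood variance is unavailable from the first age at which all at
#'   risk die), and scalars `start_age`, `max_longevity`, `n_start`, `n`.
#' @export
km_curve <- function(table) {
  stopifnot(inherits(table, "km_table"))
  frac <- ifelse(table$n_event > 0L, table$n_event / table$n_risk, 0)
  surv <- cumprod(1 - frac)
  curve <- structure(
    list(age = table$age, n_risk = table$n_risk, n_event = table$n_event,
         n_censor = table$n_censor, surv = surv,
         var = NULL, var_defined = NULL,
         start_age = attr(table, "start_age"),
         max_longevity = attr(table, "max_longevity"),
         n_start = attr(table, "n_start"),
         n = attr(table, "n")),
    class = "km_curve")
  gw <- greenwood_variance(curve, table)
  curve$var <- gw$var
  curve$var_defined <- gw$defined
  curve
}

#' Greenwood's variance of the product-limit estimator
#'
#' \eqn{\hat V(t) = \hat L(t)^2 \sum_{t_i \le t} d_i / (N_i (N_i - d_i))}.
#' When every individual at risk dies at some age (\eqn{N_i = d_i}) the
#' summand is undefined and the variance is flagged unavailable from that
#' age onward.
#'
#' @param curve A `km_curve` (its `surv` component is used).
#' @param table The `km_table` the curve was built from.
#' @return A list with numeric `var` and logical `defined`, parallel to the
#'   table's ages.
#' @export
greenwood_variance <- function(curve, table) {
  stopifnot(length(curve$surv) == nrow(table))
  d <- table$n_event; n <- table$n_risk
  term <- numeric(length(d))
  saturated <- d > 0L & d == n
  ok <- d > 0L & !saturated
  term[ok] <- d[ok] / (n[ok] * (n[ok] - d[ok]))
  defined <- !cumsum(saturated) > 0L
  v <- curve$surv^2 * cumsum(term)
  v[!defined] <- NA_real_
  list(var = v, defined = defined)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Product-limit survival curve: %d exposures, start age %d d, %d event ages\n",
    x$n, x$start_age, length(x$age)))
  cat(sprintf("  deaths %d, censored %d, max longevity %d d, n_start %d\n",
              sum(x$n_event), sum(x$n_censor), x$max_longevity, x$n_start))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(age_days = x$age, at_risk = x$n_risk, deaths = x$n_event,
             censored = x$n_censor, survival = x$surv, variance = x$var)
}

#' Export a survival curve as delimited text
#'
#' Writes columns `age_days`, `at_risk`, `deaths`, `censored`, `survival`,
#' `variance` (tab-separated; unavailable variances are empty cells).
#'
#' @param curve A `km_curve`.
#' @param path Output file path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
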