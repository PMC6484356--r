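# Synthetic studbooks with known survival structure.  Lifespans beyond the
# first year follow 365 + Weibull(shape k, scale lambda) days, so the true
# median conditional on first-year survival has the closed form
# 365 + lambda * (log 2)^(1/k).  Censoring arises from the analysis window
# (deaths after its end appear as alive), truncation from late acquisition.

#' Configuration for the synthetic studbook generator
#'
#' Defaults describe a mid-sized managed population analyzed over a modern
#' window: 500 individuals born across three decades, 20% first-year
#' mortality, adult lifespans exponential with a 10-year scale (Weibull
#' shape 1), 20% of animals acquired after their first birthday (left
#' truncated), an even sex ratio with 5% unknown-sex animals, and roughly
#' 20% of adult deaths falling past the window end (right censored).
#'
#' @param n_individuals Number of animals to generate.
#' @param window An [analysis_window()].
#' @param birth_range Two dates bounding the (uniform) birth dates.
#' @param first_year_mortality Probability of death before age 365 days.
#' @param shape,scale_days Weibull shape \eqn{k} and scale \eqn{\lambda}
#'   (days) of the post-first-year lifespan.
#' @param import_fraction Probability an animal is acquired after birth
#'   (entry 1-5 years after its first birthday).
#' @param sex_ratio Probability male (among animals of known sex).
#' @param unknown_sex_fraction Probability the sex is unrecorded.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 500L,
                             window = analysis_window("1980-01-01",
                                                      "2018-12-31"),
                             birth_range = as.Date(c("1983-06-01",
                                                     "2013-06-01")),
                             first_year_mortality = 0.2,
                             shape = 1, scale_days = 3650,
                             import_fraction = 0.2,
                             sex_ratio = 0.5,
                             unknown_sex_fraction = 0.05,
                             seed = 1L) {
  probs <- c(first_year_mortality, import_fraction, sex_ratio,
             unknown_sex_fraction)
  stopifnot(n_individuals >= 1L, inherits(window, "analysis_window"),
            all(probs >= 0 & probs <= 1), shape > 0, scale_days > 0)
  structure(list(n_individuals = as.integer(n_individuals), window = window,
                 birth_range = as.Date(birth_range),
                 first_year_mortality = first_year_mortality,
                 shape = shape, scale_days = scale_days,
                 import_fraction = import_fraction, sex_ratio = sex_ratio,
                 unknown_sex_fraction = unknown_sex_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic studbook
#'
#' Deterministic given `config$seed`.  Deaths after the window end are
#' recorded as alive at the window end (right censoring); imported animals
#' have an entry date after birth (left truncation), and an animal that
#' dies before its drawn acquisition date never appears in the studbook, so
#' delayed entry is non-informative.  First-year deaths are generated (they
#' occur in real studbooks) and are excluded downstream by the 365-day
#' starting age.
#'
#' @param config A [synthetic_config()].
#' @return A record data frame in the layout of [parse_studbook()]; may
#'   hold fewer than `n_individuals` rows when imports die before
#'   acquisition.
#' @export
generate_studbook <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  w <- config$window

  span <- as.integer(config$birth_range[2L] - config$birth_range[1L])
  birth <- config$birth_range[1L] + sample.int(span + 1L, n, replace = TRUE) - 1L

  infant <- stats::runif(n) < config$first_year_mortality
  lifespan <- integer(n)
  lifespan[infant] <- sample.int(365L, sum(infant), replace = TRUE) - 1L
  lifespan[!infant] <- 365L + as.integer(round(
    stats::rweibull(sum(!infant), shape = config$shape,
                    scale = config$scale_days)))
  lifespan[!infant] <- pmax(lifespan[!infant], 366L)
  death <- birth + lifespan

  # acquisition delay is drawn independently of lifespan; an animal that
  # dies before it would have been acquired never appears in this studbook
  # (left truncation must be non-informative for the product-limit
  # estimator to be consistent)
  imported <- stats::runif(n) < config$import_fraction
  delay <- 365L + sample.int(4L * 365L, n, replace = TRUE)
  keep <- !imported | delay < lifespan
  entry <- birth
  entry[imported] <- birth[imported] + delay[imported]

  censored <- death > w$end_date
  end_date <- death
  end_date[censored] <- w$end_date
  fate <- ifelse(censored, "alive_or_lost", "dead")

  u <- stats::runif(n)
  sex <- ifelse(u < config$unknown_sex_fraction, "unknown",
                ifelse(stats::runif(n) < config$sex_ratio, "male", "female"))

  out <- data.frame(individual_id = sprintf("SB%05d", seq_len(n)),
                    sex = sex, birth_date = birth, entry_date = entry,
                    end_date = end_date, fate = fate,
                    institution_known = TRUE, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' True median lifespan conditional on first-year survival
#'
#' Closed form for the generator's lifespan law:
#' \eqn{365 + \lambda (\ln 2)^{1/k}} days.
#'
#' @param config A [synthetic_config()].
#' @return Median age at death in days among animals surviving their first
#'   year, absent censoring and truncation.
#' @export
true_conditional_median <- function(config) {
  365 + config$scale_days * log(2)^(1 / config$shape)
}

#' Write records as a studbook file
#'
#' Emits the delimited-text studbook format read by [parse_studbook()]
#' (comma-separated, ISO-8601 dates, `"UNK"` for unknown values).
#'
#' @param records Record data frame ([generate_studbook()] output or
#'   compatible).
#' @param path Output file path.
#' @export
write_studbook <- function(records, path) {
  out <- data.frame(
    id = records$individual_id,
    sex = records$sex,
    birth_date = ifelse(is.na(records$birth_date),
                        "UNK", format(records$birth_date)),
    entry_date = ifelse(is.na(records$entry_date),
                        "UNK", format(records$entry_date)),
    end_date = ifelse(is.na(records$end_date),
                      "UNK", format(records$end_date)),
    fate = records$fate,
    institution = ifelse(records$institution_known, "INST1", "UNK"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a synthetic-generator configuration file
#'
#' Key-value file with any of the [synthetic_config()] fields
#' (`n_individuals`, `window_start`, `window_end`, `start_age_days`,
#' `birth_start`, `birth_end`, `first_year_mortality`, `shape`,
#' `scale_days`, `import_fraction`, `sex_ratio`, `unknown_sex_fraction`,
#' `seed`); omitted keys take the defaults.
#'
#' @param path Path to the configuration file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  kv <- .read_keyvalue(path)
  args <- list()
  num <- function(key) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else NULL
  for (key in c("first_year_mortality", "shape", "scale_days",
                "import_fraction", "sex_ratio", "unknown_sex_fraction"))
    args[[key]] <- num(key)
  if (!is.null(kv$n_individuals))
    args$n_individuals <- as.integer(kv$n_individuals)
  if (!is.null(kv$seed)) args$seed <- as.integer(kv$seed)
  if (!is.null(kv$window_start) && !is.null(kv$window_end))
    args$window <- analysis_window(kv$window_start, kv$window_end,
                                   if (is.null(kv$start_age_days)) 365L
                                   else as.integer(kv$start_age_days))
  if (!is.null(kv$birth_start) && !is.null(kv$birth_end))
    args$birth_range <- as.Date(c(kv$birth_start, kv$birth_end))
  do.call(synthetic_config, args[!vapply(args, is.null, TRUE)])
}
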