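test_that("the median uses the exact-0.5 estimate when one exists", {
  cv <- km_curve(build_event_table(make_exposures(c(365, 365), c(500, 600),
                                                  c(TRUE, FALSE))))
  expect_equal(cv$surv[cv$age == 500L], 0.5)
  expect_equal(median_from_curve(cv), 500)
  # a plateau at exactly 0.5 returns its earliest age
  ex <- make_exposures(rep(365L, 4), c(500L, 500L, 800L, 900L),
                       c(TRUE, TRUE, FALSE, TRUE))
  cv <- km_curve(build_event_table(ex))
  expect_equal(median_from_curve(cv), 500)
})

test_that("the median interpolates between the estimates bracketing 0.5", {
  cv <- km_curve(build_event_table(worked_cohort()))
  expect_equal(median_from_curve(cv), 600)
  # the censoring at 500 d between the bracketing deaths must not shift x0
  expect_equal(cv$surv[cv$age == 500L], 0.75)
  # curve never reaching 0.5 has no median
  ex <- make_exposures(rep(365L, 5), c(400L, 500L, 600L, 700L, 800L),
                       c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(is.na(median_from_curve(km_curve(build_event_table(ex)))))
})

test_that("ages convert to years by division by 365 and NA propagates", {
  expect_equal(to_years(600), 600 / 365)
  expect_equal(to_years(365), 1)
  expect_true(is.na(to_years(NA_real_)))
})

test_that("the log-log Z statistic matches direct evaluation and its guards", {
  cv <- km_curve(build_event_table(worked_cohort()))
  z400 <- z_statistic(cv, which(cv$age == 400L))
  L <- 0.75; V <- 0.046875
  expect_equal(z400, (log(-log(L)) - log(-log(0.5))) * (L * log(L)) / sqrt(V))
  expect_gt(z400, 0)   # survival above 0.5 gives positive Z
  # exactly 0.5 gives Z = 0
  cv2 <- km_curve(build_event_table(make_exposures(rep(365, 4),
                                                   c(500, 500, 700, 800),
                                                   c(TRUE, TRUE, FALSE, FALSE))))
  expect_equal(z_statistic(cv2, 1), 0)
  # L = 1 (censoring-only age) is undefined
  cvc <- km_curve(build_event_table(make_exposures(c(365, 365), c(500, 600),
                                                   c(FALSE, TRUE))))
  expect_true(is.na(z_statistic(cvc, 1)))
})

test_that("test-inversion limits agree with the survival package within one event age", {
  skip_if_not_installed("survival")
  set.seed(97)
  for (rep in 1:20) {
    n <- 200
    life <- 365L + as.integer(stats::rexp(n, 1 / 2000))
    cens <- stats::runif(n) < 0.2
    exit <- ifelse(cens, 365L + sample(1:3000, n, replace = TRUE), life)
    ex <- make_exposures(rep(365L, n), exit, !cens)
    ex <- ex[ex$exit_age > ex$entry_age, ]
    cv <- km_curve(build_event_table(ex))
    ci <- median_ci(cv)
    fit <- survival::survfit(
      survival::Surv(entry_age, exit_age, event) ~ 1, data = ex,
      conf.type = "log-log")
    st <- summary(fit)$table
    deaths <- cv$age[cv$n_event > 0L]
    step_apart <- function(a, b) {
      abs(match(a, deaths) - match(b, deaths)) <= 1L
    }
    if (!is.na(st["0.95LCL"])) expect_true(step_apart(ci$lcl, st["0.95LCL"]))
    if (!is.na(st["0.95UCL"])) expect_true(step_apart(ci$ucl, st["0.95UCL"]))
    # the interpolated median sits within one step of the survfit median
    med <- median_from_curve(cv)
    i <- match(st[["median"]], deaths)
    expect_true(med <= deaths[i] &&
                  med >= if (i > 1L) deaths[i - 1L] else cv$start_age)
  }
})

test_that("confidence limits are undefined when the curve never leaves the band", {
  # curve ends while |Z| < 1.96: the upper limit cannot be bounded
  set.seed(5)
  n <- 40
  exit <- 365L + sample(50:400, n, replace = TRUE)
  event <- stats::runif(n) < 0.5
  ex <- make_exposures(rep(365L, n), exit, event)
  cv <- km_curve(build_event_table(ex))
  z <- z_statistic(cv, which(cv$n_event > 0L))
  ci <- median_ci(cv)
  if (!any(z[!is.na(z)] <= -1.96)) expect_true(is.na(ci$ucl))
  # degenerate curve with a single death: variance undefined, CI undefined
  cv1 <- km_curve(build_event_table(make_exposures(365L, 700L, TRUE)))
  ci1 <- median_ci(cv1)
  expect_true(is.na(ci1$lcl) && is.na(ci1$ucl))
})

test_that("limits bracket the median whenever all three are defined", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(c(50, 200, 500), 1)
    life <- 365L + as.integer(stats::rweibull(n, shape = 1.5, scale = 2500))
    cens <- stats::runif(n) < 0.3
    exit <- pmax(ifelse(cens, 365L + sample(1:4000, n, replace = TRUE), life),
                 366L)
    ex <- make_exposures(rep(365L, n), exit, !cens)
    cv <- km_curve(build_event_table(ex))
    med <- median_from_curve(cv)
    ci <- median_ci(cv)
    if (!is.na(med) && !is.na(ci$lcl) && !is.na(ci$ucl)) {
      expect_lte(ci$lcl, med)
      expect_gte(ci$ucl, med)
    }
  }
})

test_that("quality tests fail exactly at their printed thresholds", {
  fake <- function(n_start, max_long) {
    structure(list(n_start = n_start, max_longevity = max_long),
              class = "km_curve")
  }
  base <- fake(100L, 10000L)
  all_pass <- quality_tests(base, mle = 2000, lcl = 1500, ucl = 2500,
                            n_at_median = 50L)
  expect_true(all(all_pass))
  expect_named(all_pass, c("calculable", "first_class_n", "median_n",
                           "ci_defined", "ci_precise"))
  # test 1: median must be calculable
  expect_false(quality_tests(base, NA, 1500, 2500, 50L)["calculable"])
  # test 2: strictly more than 30 in the first age class
  expect_false(quality_tests(fake(30L, 10000L), 2000, 1500, 2500,
                             50L)["first_class_n"])
  expect_true(quality_tests(fake(31L, 10000L), 2000, 1500, 2500,
                            50L)["first_class_n"])
  # test 3: strictly more than 20 at the median
  expect_false(quality_tests(base, 2000, 1500, 2500, 20L)["median_n"])
  expect_true(quality_tests(base, 2000, 1500, 2500, 21L)["median_n"])
  # test 4: both limits defined
  expect_false(quality_tests(base, 2000, 1500, NA, 50L)["ci_defined"])
  # test 5: CI longer than 33% of the maximum longevity is too imprecise
  expect_false(quality_tests(base, 2000, 1000, 1000 + 3400, 50L)["ci_precise"])
  expect_true(quality_tests(base, 2000, 1000, 1000 + 3300, 50L)["ci_precise"])
})

test_that("a data-deficient stratum still reports its (unreliable) estimate", {
  # 10 animals: median calculable but first-age-class count is far below 30
  set.seed(3)
  exit <- 365L + sample(100:2000, 10)
  ex <- make_exposures(rep(365L, 10), exit, rep(TRUE, 10))
  r <- mle_result(ex)
  expect_true(r$data_deficient)
  expect_false(r$tests["first_class_n"])
  expect_true(r$tests["calculable"])
  expect_false(is.na(r$mle_years))
})
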