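# Shared fixture builders.  All synthetic data is generated in code under
# fixed seeds; nothing is read from disk except files the tests write.

make_exposures <- function(entry, exit, event, sex = "unknown") {
  data.frame(individual_id = sprintf("X%03d", seq_along(entry)),
             sex = rep_len(sex, length(entry)),
             entry_age = as.integer(entry), exit_age = as.integer(exit),
             event = event, stringsAsFactors = FALSE)
}

# the four-animal worked cohort: two deaths (400, 700 d), two censorings
worked_cohort <- function() {
  make_exposures(entry = rep(365L, 4), exit = c(400L, 500L, 700L, 900L),
                 event = c(TRUE, FALSE, TRUE, FALSE))
}

# random small cohort with ties, delayed entry and censoring
random_cohort <- function(n = sample(5:50, 1)) {
  entry <- 365L + ifelse(stats::runif(n) < 0.3,
                         sample(0:60, n, replace = TRUE), 0L)
  exit <- entry + sample(1:40, n, replace = TRUE)
  make_exposures(entry, exit, event = stats::runif(n) < 0.7)
}

write_studbook_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a small per-species dataset in the deposited schema, with one taxon that
# has no male data (empty cells) and one data-deficient male estimate
toy_dataset <- function() {
  data.frame(
    common_name = c("species a", "species b", "species c", "spider d"),
    scientific_name = paste("Genus", letters[1:4]),
    taxon_group = c("Mammalia", "Mammalia", "Mammalia", "Arachnida"),
    overall_sample_size = c(100, 200, 150, 40),
    overall_mle = c(2, 4, 6, 17.2),
    overall_lcl = c(1.5, 3.5, 5.5, NA),
    overall_ucl = c(2.5, 4.5, 6.5, NA),
    male_sample_size = c(50, 90, 70, NA),
    male_mle = c(2.1, 3.9, 6.2, NA),
    male_lcl = c(1.6, 3.4, 5.6, NA),
    male_ucl = c(2.6, 4.4, 6.8, NA),
    female_sample_size = c(50, 110, 80, 40),
    female_mle = c(1.9, 4.1, 5.8, 17.2),
    female_lcl = c(1.4, 3.6, 5.2, NA),
    female_ucl = c(2.4, 4.6, 6.4, NA),
    male_data_deficient = c(FALSE, FALSE, TRUE, FALSE),
    female_data_deficient = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}
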