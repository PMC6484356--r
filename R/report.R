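# Per-sex orchestration and the per-species MLE dataset schema: one row per
# population with overall / male / female sample sizes, MLE and 95% limits
# (years), and per-sex data-deficiency flags.

.taxon_levels <- c("Amphibia", "Arachnida", "Aves", "Chondrichthyes",
                   "Mammalia", "Reptilia")

.dataset_columns <- c(
  "common_name", "scientific_name", "taxon_group",
  "overall_sample_size", "overall_mle", "overall_lcl", "overall_ucl",
  "male_sample_size", "male_mle", "male_lcl", "male_ucl",
  "female_sample_size", "female_mle", "female_lcl", "female_ucl",
  "male_data_deficient", "female_data_deficient")

#' Analyze a studbook population by sex
#'
#' Runs the median-life-expectancy analysis on three strata: overall (all
#' exposures, including unknown-sex animals), male, and female.  The
#' stratum sample size is the number of individuals whose partial or full
#' lifespans were used.  A stratum with no exposures yields an empty result
#' with all quality tests failed.
#'
#' @param records Validated records (see [validate_records()]).
#' @param window An [analysis_window()].
#' @return List of class `population_analysis` with [mle_result()] elements
#'   `overall`, `male`, `female`, plus the `exposures` used.
#' @export
analyze_population <- function(records, window) {
  exp_all <- compute_exposure(records, window)
  res <- list(
    overall = mle_result(exp_all, window$start_age_days),
    male = mle_result(exp_all[exp_all$sex == "male", , drop = FALSE],
                      window$start_age_days),
    female = mle_result(exp_all[exp_all$sex == "female", , drop = FALSE],
                        window$start_age_days),
    exposures = exp_all)
  class(res) <- "population_analysis"
  res
}

#' @export
print.population_analysis <- function(x, ...) {
  for (s in c("overall", "male", "female")) {
    cat(sprintf("%-8s", s)); print(x[[s]])
  }
  invisible(x)
}

#' Tabulate a population analysis as a per-stratum report
#'
#' One row per stratum in an "Expert Survival Statistics" layout: sample
#' size, first-age-class count, count at the median, MLE and 95% limits in
#' years (rounded to 1 decimal), the five quality-test outcomes, and the
#' data-deficiency flag.
#'
#' @param analysis A [analyze_population()] result.
#' @return A data frame with rows `overall`, `male`, `female`.
#' @export
report_table <- function(analysis) {
  strata <- c("overall", "male", "female")
  rows <- lapply(strata, function(s) {
    r <- analysis[[s]]
    data.frame(stratum = s, sample_size = r$sample_size,
               n_start = r$n_start, n_at_median = r$n_at_median,
               mle_years = round(r$mle_years, 1),
               lcl_years = round(r$lcl_years, 1),
               ucl_years = round(r$ucl_years, 1),
               as.list(r$tests),
               data_deficient = r$data_deficient,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read a per-species MLE dataset
#'
#' Reads a delimited-text table in the deposited-dataset schema (see
#' [write_mle_dataset()] for the column list).  Empty cells are missing
#' values; a malformed numeric cell is an error naming the row and column.
#'
#' @param path Path to the dataset file.
#' @param sep Field delimiter; `NULL` auto-detects comma vs tab.
#' @return Data frame with one row per species/subspecies; taxa outside the
#'   six named classes are grouped as `"other"`.
#' @export
read_mle_dataset <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.dataset_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  num_col <- function(col) {
    x <- trimws(raw[[col]])
    x[x %in% c("", "NA")] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0L)
      stop(sprintf("malformed numeric value %s in row %d, column %s",
                   dQuote(x[bad[1L]]), bad[1L], col))
    v
  }
  yesno <- function(col) tolower(trimws(raw[[col]])) %in% "yes"

  out <- data.frame(common_name = raw$common_name,
                    scientific_name = raw$scientific_name,
                    taxon_group = ifelse(raw$taxon_group %in% .taxon_levels,
                                         raw$taxon_group, "other"),
                    stringsAsFactors = FALSE)
  for (col in grep("sample_size|mle|lcl|ucl", .dataset_columns, value = TRUE))
    out[[col]] <- num_col(col)
  out$male_data_deficient <- yesno("male_data_deficient")
  out$female_data_deficient <- yesno("female_data_deficient")
  out
}

#' Write a per-species MLE dataset
#'
#' Columns: `common_name`, `scientific_name`, `taxon_group`, then per
#' stratum (`overall_`, `male_`, `female_`) `sample_size`, `mle`, `lcl`,
#' `ucl` in years, and `male_data_deficient` / `female_data_deficient`
#' (`yes`/`no`).  Missing values are written as empty cells, so writing
#' then reading reproduces the rows.
#'
#' @param rows Data frame as returned by [read_mle_dataset()].
#' @param path Output file path.
#' @export
write_mle_dataset <- function(rows, path) {
  out <- rows[, intersect(.dataset_columns, names(rows)), drop = FALSE]
  out$male_data_deficient <- ifelse(rows$male_data_deficient, "yes", "no")
  out$female_data_deficient <- ifelse(rows$female_data_deficient, "yes", "no")
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Summarize MLEs by taxonomic group and sex
#'
#' Per taxon and stratum, the count, arithmetic mean and sample (n-1)
#' standard deviation of the MLE values (years).  Sex-specific estimates
#' flagged data-deficient are excluded by default, matching the
#' recommendation that such values be left out of formal analysis; the
#' overall stratum carries no deficiency flag and always summarizes all
#' non-missing values.
#'
#' @param rows Dataset rows (see [read_mle_dataset()]).
#' @param exclude_deficient Drop data-deficient sex-specific MLEs
#'   (default `TRUE`).
#' @return Data frame with columns `taxon_group`, `stratum`, `n`,
#'   `mean_mle`, `sd_mle` (`NA` mean/SD for empty strata).
#' @export
summarize_by_taxon <- function(rows, exclude_deficient = TRUE) {
  taxa <- sort(unique(rows$taxon_group))
  grid <- expand.grid(taxon_group = taxa,
                      stratum = c("overall", "male", "female"),
                      stringsAsFactors = FALSE)
  cells <- mapply(function(taxon, stratum) {
    v <- rows[[paste0(stratum, "_mle")]][rows$taxon_group == taxon]
    if (exclude_deficient && stratum != "overall") {
      flag <- rows[[paste0(stratum, "_data_deficient")]][rows$taxon_group ==
                                                           taxon]
      v <- v[!flag]
    }
    v <- v[!is.na(v)]
    c(n = length(v),
      mean_mle = if (length(v) > 0L) mean(v) else NA_real_,
      sd_mle = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }, grid$taxon_group, grid$stratum)
  cbind(grid, as.data.frame(t(cells), row.names = seq_len(nrow(grid))))
}
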