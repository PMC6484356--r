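#' @keywords internal
"_PACKAGE"

# Studbook input format: delimited text (comma or tab), one row per animal,
# required columns id, sex, birth_date, entry_date, end_date, fate,
# institution.  Dates are ISO-8601; the token "UNK" (or an empty cell) marks
# an unknown value.  `fate` is "dead" or "alive_or_lost".

.required_columns <- c("id", "sex", "birth_date", "entry_date",
                       "end_date", "fate", "institution")

.parse_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "UNK", "NA")] <- NA_character_
  # unparseable dates become unknown, never a hard failure
  as.Date(x, format = "%Y-%m-%d", optional = TRUE)
}

.parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out
}

#' Read a studbook file into individual records
#'
#' Parses a delimited-text studbook (one row per animal) into a data frame of
#' individual records.  Unparseable or `"UNK"` dates are kept as unknown
#' (`NA`) so that [validate_records()] can exclude and log them; only
#' structural problems (missing columns, duplicated animal identifiers) are
#' hard errors.
#'
#' @param path Path to a studbook file.
#' @param sep Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A data frame with one row per animal and columns `individual_id`,
#'   `sex` (`"male"`, `"female"` or `"unknown"`), `birth_date`, `entry_date`,
#'   `end_date` (`Date`, `NA` when unknown), `fate` (`"dead"` or
#'   `"alive_or_lost"`) and `institution_known` (logical).
#' @seealso [validate_records()], [compute_exposure()]
#' @export
parse_studbook <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("studbook file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols) > 0L)
    stop("studbook is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  ids <- trimws(raw$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))

  fate <- tolower(trimws(raw$fate))
  fate[fate %in% c("alive", "lost", "alive_or_lost", "ltf")] <- "alive_or_lost"
  fate[fate %in% c("dead", "death", "died")] <- "dead"
  bad_fate <- setdiff(unique(fate), c("dead", "alive_or_lost"))
  if (length(bad_fate) > 0L)
    stop("unrecognized fate value(s): ", paste(bad_fate, collapse = ", "))

  inst <- trimws(raw$institution)
  data.frame(
    individual_id     = ids,
    sex               = .parse_sex(raw$sex),
    birth_date        = .parse_date(raw$birth_date),
    entry_date        = .parse_date(raw$entry_date),
    end_date          = .parse_date(raw$end_date),
    fate              = fate,
    institution_known = !(inst %in% c("", "UNK", "NA")),
    stringsAsFactors  = FALSE
  )
}

#' Validate studbook records and log exclusions
#'
#' Applies the record-level exclusion rules used before survival analysis:
#' records with an unknown birth date, unknown entry or end date, an unknown
#' institution, or life events dated before birth are excluded.  Validation
#' never hard-fails on record content; every exclusion is logged with a
#' reason code.
#'
#' @param records Data frame of records as returned by [parse_studbook()].
#' @return A list with elements `records` (the retained rows) and
#'   `exclusions`, a data frame with columns `individual_id`, `reason`
#'   (one of `"unknown_birthdate"`, `"unknown_entry_date"`,
#'   `"unknown_end_date"`, `"unknown_institution"`, `"event_before_birth"`)
#'   and `message`.
#' @export
validate_records <- function(records) {
  log_id <- character(0); log_reason <- character(0); log_msg <- character(0)
  flag <- function(which, reason, msg) {
    ids <- records$individual_id[which]
    log_id <<- c(log_id, ids)
    log_reason <<- c(log_reason, rep(reason, length(ids)))
    if (length(ids) > 0L) log_msg <<- c(log_msg, paste0(ids, ": ", msg))
    which
  }

  drop <- flag(is.na(records$birth_date), "unknown_birthdate",
               "birth date unknown")
  drop <- drop | flag(!is.na(records$birth_date) & is.na(records$entry_date),
                      "unknown_entry_date", "entry date unknown")
  drop <- drop | flag(!is.na(records$birth_date) & is.na(records$end_date),
                      "unknown_end_date", "death or last-known date unknown")
  drop <- drop | flag(!records$institution_known, "unknown_institution",
                      "event at unknown or unrecognized institution")
  chron <- !is.na(records$birth_date) &
    ((!is.na(records$end_date) & records$end_date < records$birth_date) |
     (!is.na(records$entry_date) & records$entry_date < records$birth_date))
  drop <- drop | flag(chron, "event_before_birth",
                      "life event dated before birth")

  list(
    records    = records[!drop, , drop = FALSE],
    exclusions = data.frame(individual_id = log_id, reason = log_reason,
                            message = log_msg, stringsAsFactors = FALSE)
  )
}

#' Define an analysis window
#'
#' The analysis window restricts the survival analysis to a calendar period
#' (typically 1980 or later to the present, reflecting modern husbandry) and
#' sets the starting age at which survivorship is anchored at 1.0 (365 days
#' by default: first-year mortality is management-dependent and individuals
#' that did not survive their first year are excluded).
#'
#' @param start_date,end_date Calendar dates (coerced with [as.Date()])
#'   bounding the window, inclusive on both ends.
#' @param start_age_days Starting age in days (default 365).
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(start_date, end_date, start_age_days = 365L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) stop("window dates must be valid")
  if (!(start_date < end_date)) stop("window start_date must precede end_date")
  start_age_days <- as.integer(start_age_days)
  if (is.na(start_age_days) || start_age_days < 1L)
    stop("start_age_days must be a positive integer")
  structure(list(start_date = start_date, end_date = end_date,
                 start_age_days = start_age_days),
            class = "analysis_window")
}

#' Read an analysis-window configuration file
#'
#' The file holds `key = value` lines for `start_date`, `end_date`
#' (ISO-8601) and optionally `start_age_days`.
#'
#' @param path Path to the configuration file.
#' @return An `analysis_window` object.
#' @export
read_window <- function(path) {
  kv <- .read_keyvalue(path)
  if (is.null(kv$start_date) || is.null(kv$end_date))
    stop("window config must define start_date and end_date")
  analysis_window(kv$start_date, kv$end_date,
                  if (is.null(kv$start_age_days)) 365L
                  else as.integer(kv$start_age_days))
}

.read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  stats::setNames(lapply(m, function(x) trimws(x[3L])),
                  vapply(m, function(x) x[2L], ""))
}

#' Compute exposure intervals inside the analysis window
#'
#' Converts validated records to per-individual exposures: (entry age, exit
#' age, death observed) in whole days since birth, after clipping to the
#' analysis window and the starting age.  Entry age is the latest of the
#' starting age, the age at the window start, and the age at the recorded
#' entry date (delayed entry / left truncation).  Exit age is the age at the
#' earlier of the end date and the window end; an individual alive at the
#' window end, or whose death falls after it, is right-censored there.
#' Individuals with no exposure past the starting age inside the window
#' (including all first-year deaths) contribute no row.
#'
#' @param records Validated records (see [validate_records()]).
#' @param window An [analysis_window()].
#' @return A data frame of exposures with columns `individual_id`, `sex`,
#'   `entry_age`, `exit_age` (integer days) and `event` (logical, `TRUE` for
#'   a death observed inside the window).  Zero rows when no individual has
#'   usable exposure.
#' @export
compute_exposure <- function(records, window) {
  stopifnot(inherits(window, "analysis_window"))
  if (nrow(records) == 0L)
    return(data.frame(individual_id = character(0), sex = character(0),
                      entry_age = integer(0), exit_age = integer(0),
                      event = logical(0), stringsAsFactors = FALSE))
  if (anyNA(records$birth_date) || anyNA(records$entry_date) ||
      anyNA(records$end_date))
    stop("records must be validated before computing exposure")

  age_at <- function(d) as.integer(d - records$birth_date)
  entry_age <- pmax(window$start_age_days,
                    age_at(window$start_date),
                    age_at(records$entry_date))
  exit_age <- age_at(pmin(records$end_date, window$end_date))
  event <- records$fate == "dead" &
    records$end_date <= window$end_date &
    records$end_date >= window$start_date

  keep <- exit_age > window$start_age_days & entry_age < exit_age
  data.frame(individual_id = records$individual_id[keep],
             sex = records$sex[keep],
             entry_age = entry_age[keep],
             exit_age = exit_age[keep],
             event = event[keep],
             stringsAsFactors = FALSE)
}
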