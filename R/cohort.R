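#' Study window for cohort definition
#'
#' The analysis cohort is restricted to diagnoses falling inside a fixed
#' calendar window, with follow-up complete to a later fixed date. The
#' defaults describe a screening-era registry cohort: diagnoses from
#' 1 April 1989 to 31 March 2011, followed up to 31 July 2012.
#'
#' @param diagnosis_start,diagnosis_end First and last admissible dates of
#'   diagnosis (anything coercible by [as.Date()]).
#' @param followup_end Administrative censoring date; must fall after
#'   `diagnosis_end`.
#' @return An object of class `study_window`: a list with the three dates.
#' @export
#' @examples
#' study_window()
study_window <- function(diagnosis_start = "1989-04-01",
                         diagnosis_end = "2011-03-31",
                         followup_end = "2012-07-31") {
  w <- list(diagnosis_start = as.Date(diagnosis_start),
            diagnosis_end = as.Date(diagnosis_end),
            followup_end = as.Date(followup_end))
  if (!(w$diagnosis_start < w$diagnosis_end && w$diagnosis_end < w$followup_end))
    stop("study_window requires diagnosis_start < diagnosis_end < followup_end")
  structure(w, class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("Study window: diagnoses %s to %s, follow-up to %s\n",
              x$diagnosis_start, x$diagnosis_end, x$followup_end))
  invisible(x)
}

ETHNICITY_GROUPS <- c("Asian", "Black", "White")
SCREENING_STATUSES <- c("screen_detected", "interval", "lapsed_attender",
                        "non_attender", "other_unresolvable")
EXTENT_LEVELS <- c("localised", "regional", "distant")
DEPRIVATION_GROUPS <- c("less_deprived", "middle_more_deprived")

#' Resolve a single ethnicity code from repeated observations
#'
#' Registry patients can carry several ethnicity self-reports (repeat
#' hospital admissions, screening visits), not always in agreement. A
#' deterministic hierarchy reduces them to one code: (i) the most common
#' code wins; (ii) among codes tied on count, the one with the most recent
#' observation date wins; (iii) if count and latest date are both tied, the
#' first code in case-insensitive alphanumeric order wins.
#'
#' @param observations A data frame with columns `code` (character,
#'   non-empty) and `record_date` (coercible to `Date`); a `source` column
#'   is permitted and ignored.
#' @return A single character ethnicity code.
#' @export
#' @examples
#' obs <- data.frame(code = c("A", "A", "B"),
#'                   record_date = as.Date(c("2001-01-01", "2003-01-01", "2002-01-01")))
#' resolve_ethnicity(obs)  # "A": modal code
resolve_ethnicity <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0L)
    stop("no ethnicity observations supplied for this patient")
  code <- as.character(observations$code)
  if (anyNA(code) || any(!nzchar(code)))
    stop("ethnicity observations must carry non-empty codes")
  date <- as.Date(observations$record_date)
  counts <- table(code)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  latest <- vapply(top, function(cd) max(date[code == cd]), as.Date("1900-01-01"))
  latest <- as.Date(latest, origin = "1970-01-01")
  top <- top[latest == max(latest)]
  if (length(top) == 1L) return(top)
  top[order(tolower(top), top)][1L]
}

#' Default ethnicity code dictionary
#'
#' Maps census-style ethnicity codes to the three broad analysis groups
#' Asian, Black and White. Mixed-heritage codes involving a Black or Asian
#' background are assigned to that minority group; all remaining mixed
#' codes and 'other' codes are assigned to White. The dictionary ships as
#' an editable CSV (`system.file("extdata", "ethnicity_codes.csv",
#' package = "netsurv")`); pass your own mapping to [group_ethnicity()] to
#' override it.
#'
#' @return A named character vector: names are codes, values are groups.
#' @export
default_ethnicity_codes <- function() {
  path <- system.file("extdata", "ethnicity_codes.csv", package = "netsurv")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$group, d$code)
}

#' Group an ethnicity code into Asian / Black / White
#'
#' @param code Character vector of ethnicity codes.
#' @param dict Named character vector mapping codes to groups; defaults to
#'   [default_ethnicity_codes()]. Matching is case-insensitive on trimmed
#'   codes.
#' @return Character vector of groups, each one of `"Asian"`, `"Black"`,
#'   `"White"`.
#' @export
#' @examples
#' group_ethnicity("Mixed White and Black Caribbean")  # "Black"
group_ethnicity <- function(code, dict = default_ethnicity_codes()) {
  key <- tolower(trimws(code))
  names(dict) <- tolower(trimws(names(dict)))
  out <- unname(dict[key])
  if (anyNA(out)) {
    bad <- unique(code[is.na(out)])
    stop("unmapped ethnicity code(s): ", paste(sQuote(bad), collapse = ", "))
  }
  if (!all(out %in% ETHNICITY_GROUPS))
    stop("dictionary maps to groups outside Asian/Black/White")
  out
}

#' Derive extent of disease from registry spread fields
#'
#' Collapses tumour spread information into the registry 'extent of
#' disease' variable: `distant` when distant metastases are present;
#' otherwise `regional` when the tumour has spread to adjacent tissue or
#' regional lymph nodes; otherwise `localised` when known to be confined
#' to the organ of origin. Information insufficient to rule out a more
#' advanced category propagates to `NA`.
#'
#' @param organ_confined,regional_spread,distant_metastasis Logical
#'   vectors (NA allowed), recycled to a common length.
#' @return Character vector with values `"localised"`, `"regional"`,
#'   `"distant"` or `NA`.
#' @export
classify_extent <- function(organ_confined, regional_spread, distant_metastasis) {
  n <- max(length(organ_confined), length(regional_spread), length(distant_metastasis))
  oc <- rep_len(as.logical(organ_confined), n)
  rs <- rep_len(as.logical(regional_spread), n)
  dm <- rep_len(as.logical(distant_metastasis), n)
  out <- rep(NA_character_, n)
  out[!is.na(dm) & dm] <- "distant"
  reg <- !is.na(dm) & !dm & !is.na(rs) & rs
  out[reg] <- "regional"
  loc <- !is.na(dm) & !dm & !is.na(rs) & !rs & !is.na(oc) & oc
  out[loc] <- "localised"
  out
}

#' Collapse deprivation quintiles into two analysis groups
#'
#' Quintiles 1-2 (least deprived 40% of areas) form the `less_deprived`
#' group; quintiles 3-5 form `middle_more_deprived`. Missing quintiles
#' yield a missing group.
#'
#' @param quintile Integer vector with values in 1..5 or NA.
#' @return Character vector of groups (or NA).
#' @export
#' @examples
#' group_deprivation(c(1, 2, 3, 5, NA))
group_deprivation <- function(quintile) {
  q <- as.integer(quintile)
  bad <- !is.na(q) & (q < 1L | q > 5L)
  if (any(bad))
    stop("deprivation quintile outside 1..5: ", paste(unique(quintile[bad]), collapse = ", "))
  ifelse(is.na(q), NA_character_,
         ifelse(q <= 2L, "less_deprived", "middle_more_deprived"))
}

#' Apply cohort eligibility rules
#'
#' Keeps primary, invasive, non-recurrent tumours diagnosed inside the
#' study window in women aged 50-70 at diagnosis, and logs one exclusion
#' reason per dropped record. Records with malformed dates are logged and
#' skipped; processing continues.
#'
#' Exclusion reasons are checked in order: `malformed_date`,
#' `not_invasive`, `recurrence`, `outside_diagnosis_window`,
#' `age_outside_50_70`, `exit_before_diagnosis`.
#'
#' @param records Data frame with (at least) columns `diagnosis_date`,
#'   `exit_date`, `age_at_diagnosis`, `behaviour` (`"invasive"` /
#'   `"in_situ"`), `recurrence_flag` (logical). If a
#'   `continuously_eligible` logical column is present, records with
#'   `FALSE` are excluded with reason `not_continuously_eligible`
#'   (eligibility is an upstream flag, not re-derived here).
#' @param window A [study_window()].
#' @return A list of class `cohort_selection`: `included` (data frame),
#'   `excluded` (data frame with extra column `exclusion_reason`), and
#'   `log` (named integer vector of reason counts).
#' @export
select_cohort <- function(records, window = study_window()) {
  stopifnot(is.data.frame(records), inherits(window, "study_window"))
  n <- nrow(records)
  dx <- suppressWarnings(as.Date(as.character(records$diagnosis_date),
                                 format = "%Y-%m-%d"))
  ex <- suppressWarnings(as.Date(as.character(records$exit_date),
                                 format = "%Y-%m-%d"))
  age <- records$age_at_diagnosis
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  mark(is.na(dx) | is.na(ex), "malformed_date")
  if (!is.null(records$continuously_eligible))
    mark(!records$continuously_eligible, "not_continuously_eligible")
  mark(records$behaviour != "invasive", "not_invasive")
  mark(as.logical(records$recurrence_flag), "recurrence")
  mark(dx < window$diagnosis_start | dx > window$diagnosis_end,
       "outside_diagnosis_window")
  mark(age < 50 | age > 70, "age_outside_50_70")
  mark(ex < dx, "exit_before_diagnosis")
  keep <- is.na(reason)
  included <- records[keep, , drop = FALSE]
  included$diagnosis_date <- dx[keep]
  included$exit_date <- ex[keep]
  excluded <- records[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  out <- list(included = included, excluded = excluded,
              log = c(table(reason[!keep])))
  class(out) <- "cohort_selection"
  out
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("Cohort selection: %d included, %d excluded\n",
              nrow(x$included), nrow(x$excluded)))
  if (length(x$log)) {
    for (r in names(x$log)) cat(sprintf("  %-28s %d\n", r, x$log[[r]]))
  }
  invisible(x)
}

#' Read / write a patient cohort CSV
#'
#' One row per patient with ISO-8601 dates. Expected columns:
#' `patient_id`, `diagnosis_date`, `age_at_diagnosis`, `exit_date`,
#' `vital_status` (`"D"`/`"A"`), `ethnicity_group`,
#' `deprivation_quintile`, `screening_status`, `extent`, `behaviour`,
#' `recurrence_flag`. A `deprivation_group` column is derived from the
#' quintile when absent.
#'
#' @param file Path to a CSV file.
#' @return A data frame with dates parsed as `Date`.
#' @export
read_cohort <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("patient_id", "diagnosis_date", "age_at_diagnosis", "exit_date",
           "vital_status", "ethnicity_group", "deprivation_quintile",
           "screening_status")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  d$diagnosis_date <- as.Date(d$diagnosis_date)
  d$exit_date <- as.Date(d$exit_date)
  if (is.null(d$deprivation_group))
    d$deprivation_group <- group_deprivation(d$deprivation_quintile)
  d
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Observed survival time in years
#'
#' Days between diagnosis and exit divided by 365.25. Registry dates carry
#' day-level precision, so time is computed on the day scale and reported
#' in years.
#'
#' @param cohort Cohort data frame (or any data frame with
#'   `diagnosis_date` / `exit_date`), or `NULL` if `diagnosis_date` and
#'   `exit_date` are given directly.
#' @param diagnosis_date,exit_date Optional date vectors overriding the
#'   cohort columns.
#' @return Numeric vector of survival times in years.
#' @export
survival_years <- function(cohort = NULL, diagnosis_date = NULL, exit_date = NULL) {
  if (!is.null(cohort)) {
    diagnosis_date <- cohort$diagnosis_date
    exit_date <- cohort$exit_date
  }
  as.numeric(as.Date(exit_date) - as.Date(diagnosis_date)) / 365.25
}
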