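#' Stratified background-mortality life table
#'
#' A life table holds annual probabilities of death `qx` indexed by single
#' year of age, calendar year and (optionally) ethnicity group and
#' deprivation group. It supplies the expected (population) mortality used
#' to weight the net-survival estimator; net survival is only as good as
#' the match between the life table and the cohort's true background
#' mortality, which is why stratified tables matter.
#'
#' @param data Data frame with columns `age`, `year`, `qx` and optionally
#'   `ethnicity_group`, `deprivation_group`. Every (age, year) cell must be
#'   present for each stratum; `qx` must lie in `[0, 1]`.
#' @param source Optional character note on provenance, kept as metadata.
#' @return An object of class `life_table` with elements `ages`, `years`,
#'   `strata` and the `qx` array (age x year x stratum).
#' @seealso [read_life_table()], [interpolate_life_tables()],
#'   [expected_survival()]
#' @export
life_table <- function(data, source = NULL) {
  stopifnot(is.data.frame(data),
            all(c("age", "year", "qx") %in% names(data)))
  if (any(is.na(data$qx)) || any(data$qx < 0 | data$qx > 1))
    stop("life-table qx values must be in [0, 1] and non-missing")
  eth <- if (is.null(data$ethnicity_group)) "all" else as.character(data$ethnicity_group)
  dep <- if (is.null(data$deprivation_group)) "all" else as.character(data$deprivation_group)
  stratum <- lt_stratum_label(eth, dep)
  ages <- sort(unique(as.integer(data$age)))
  years <- sort(unique(as.integer(data$year)))
  strata <- sort(unique(stratum))
  if (!identical(ages, seq(min(ages), max(ages))))
    stop("life-table ages must form a contiguous range")
  q <- array(NA_real_, dim = c(length(ages), length(years), length(strata)),
             dimnames = list(age = ages, year = years, stratum = strata))
  q[cbind(match(as.integer(data$age), ages),
          match(as.integer(data$year), years),
          match(stratum, strata))] <- data$qx
  if (anyNA(q))
    stop("life table has missing (age, year) cells in at least one stratum")
  structure(list(ages = ages, years = years, strata = strata, qx = q,
                 source = source),
            class = "life_table")
}

lt_stratum_label <- function(ethnicity_group, deprivation_group) {
  e <- ifelse(is.na(ethnicity_group), "all", as.character(ethnicity_group))
  d <- ifelse(is.na(deprivation_group), "all", as.character(deprivation_group))
  ifelse(e == "all" & d == "all", "all", paste(e, d, sep = "|"))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, years %d-%d, %d stratum(s)\n",
              min(x$ages), max(x$ages), min(x$years), max(x$years),
              length(x$strata)))
  cat("  strata:", paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname life_table
#' @param file CSV file with columns `age`, `year`, `qx` and optional
#'   `ethnicity_group`, `deprivation_group`.
#' @export
read_life_table <- function(file) {
  life_table(utils::read.csv(file, stringsAsFactors = FALSE), source = file)
}

#' @rdname life_table
#' @param table A `life_table`.
#' @export
write_life_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  g <- expand.grid(age = x$ages, year = x$years, stratum = x$strata,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$qx <- as.vector(x$qx)
  parts <- strsplit(ifelse(g$stratum == "all", "all|all", g$stratum),
                    "|", fixed = TRUE)
  g$ethnicity_group <- vapply(parts, `[`, "", 1L)
  g$deprivation_group <- vapply(parts, `[`, "", 2L)
  g[, c("age", "year", "ethnicity_group", "deprivation_group", "qx")]
}

# Annual death probability with age clamped into the table's range
# (terminal open age band) and calendar year clamped likewise. All three
# index arguments are recycled to a common length.
lt_q <- function(table, age, year, stratum) {
  n <- max(length(age), length(year), length(stratum))
  age <- pmin(pmax(rep_len(as.integer(age), n), min(table$ages)), max(table$ages))
  year <- pmin(pmax(rep_len(as.integer(year), n), min(table$years)), max(table$years))
  stratum <- rep_len(stratum, n)
  si <- match(stratum, table$strata)
  if (anyNA(si))
    stop("stratum not present in life table: ",
         paste(unique(stratum[is.na(si)]), collapse = ", "))
  yi <- match(year, table$years)
  if (anyNA(yi))
    stop("calendar year(s) not present in life table: ",
         paste(unique(year[is.na(yi)]), collapse = ", "))
  table$qx[cbind(age - min(table$ages) + 1L, yi, si)]
}

# Annual hazard -log(1-q), with q capped just below 1 to keep it finite.
lt_hazard <- function(table, age, year, stratum) {
  -log1p(-pmin(lt_q(table, age, year, stratum), 1 - 1e-12))
}

#' Interpolate a stratified base-year life table across calendar years
#'
#' Stratified tables are typically available for a single census-anchored
#' year (2001 here), while national all-population tables exist annually.
#' The stratified table is carried to other years by proportional scaling
#' on the hazard scale: for stratum *s*,
#' `h_s(age, y) = h_s(age, 2001) * h_nat(age, y) / h_nat(age, 2001)`,
#' converted back to probabilities via `q = 1 - exp(-h)`. The base year is
#' returned exactly. Years before the base year use the same ratio
#' construction against the national tables for those years.
#'
#' @param base A stratified [life_table()] containing the base year.
#' @param national An unstratified [life_table()] covering every target
#'   year (including the base year).
#' @param years Integer vector of target calendar years (default: all
#'   years of `national`).
#' @param base_year Calendar year the stratified table refers to.
#' @return A stratified `life_table` spanning `years`.
#' @export
interpolate_life_tables <- function(base, national, years = national$years,
                                    base_year = 2001L) {
  stopifnot(inherits(base, "life_table"), inherits(national, "life_table"))
  years <- sort(as.integer(years))
  if (!base_year %in% base$years)
    stop("base life table does not contain the base year ", base_year)
  missing_years <- setdiff(years, national$years)
  if (length(missing_years))
    stop("national life tables missing year(s): ",
         paste(missing_years, collapse = ", "))
  if (!base_year %in% national$years)
    stop("national life tables missing the base year ", base_year)
  ages <- intersect(base$ages, national$ages)
  nat_stratum <- national$strata[1L]
  h_nat_base <- lt_hazard(national, ages, base_year, nat_stratum)
  out <- vector("list", length(years) * length(base$strata))
  i <- 0L
  for (s in base$strata) {
    q_base <- lt_q(base, ages, base_year, s)
    h_base <- lt_hazard(base, ages, base_year, s)
    for (y in years) {
      i <- i + 1L
      if (y == base_year) {
        q_y <- q_base
      } else {
        h_nat_y <- lt_hazard(national, ages, y, nat_stratum)
        bad <- h_nat_base == 0 & h_nat_y > 0
        if (any(bad))
          stop("zero national base-year hazard with nonzero target-year hazard at age(s) ",
               paste(ages[bad], collapse = ", "))
        ratio <- ifelse(h_nat_base == 0, 1, h_nat_y / h_nat_base)
        q_y <- -expm1(-h_base * ratio)
      }
      out[[i]] <- data.frame(age = ages, year = y, stratum = s, qx = q_y,
                             stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  parts <- strsplit(ifelse(d$stratum == "all", "all|all", d$stratum),
                    "|", fixed = TRUE)
  d$ethnicity_group <- vapply(parts, `[`, "", 1L)
  d$deprivation_group <- vapply(parts, `[`, "", 2L)
  d$ethnicity_group[d$ethnicity_group == "all"] <- NA
  d$deprivation_group[d$deprivation_group == "all"] <- NA
  life_table(d[, c("age", "year", "ethnicity_group", "deprivation_group", "qx")],
             source = sprintf("interpolated from base %d", base_year))
}

# Stratum labels for a cohort, resolved against a table: a cohort stratum
# absent from a stratified table is an error; an unstratified table serves
# every patient.
cohort_strata <- function(table, ethnicity_group, deprivation_group) {
  if (identical(table$strata, "all"))
    return(rep("all", max(length(ethnicity_group), length(deprivation_group))))
  lt_stratum_label(ethnicity_group, deprivation_group)
}

#' Per-patient annual expected-hazard paths
#'
#' For each patient, the background hazard on the interval `[k-1, k)`
#' years since diagnosis is the life-table hazard at attained age
#' `age_at_diagnosis + k - 1` and calendar year `year(diagnosis) + k - 1`
#' (both clamped into the table's range; the terminal age band is open).
#' Within-year hazards are constant; age and calendar year advance
#' together at whole-year offsets from diagnosis.
#'
#' @param cohort Cohort data frame with `age_at_diagnosis`,
#'   `diagnosis_date` (or `diagnosis_year`), `ethnicity_group`,
#'   `deprivation_group`.
#' @param table A [life_table()].
#' @param n_years Number of annual intervals to tabulate.
#' @return Numeric matrix, patients x years, of annual hazards.
#' @export
hazard_paths <- function(cohort, table, n_years) {
  n <- nrow(cohort)
  year0 <- if (!is.null(cohort$diagnosis_year)) as.integer(cohort$diagnosis_year)
           else as.integer(format(as.Date(cohort$diagnosis_date), "%Y"))
  age0 <- as.integer(cohort$age_at_diagnosis)
  stratum <- cohort_strata(table, cohort$ethnicity_group, cohort$deprivation_group)
  lam <- matrix(0, n, n_years)
  for (k in seq_len(n_years)) {
    lam[, k] <- lt_hazard(table, age0 + k - 1L, year0 + k - 1L, stratum)
  }
  lam
}

#' Expected (population) survival along a patient's age/calendar path
#'
#' `S_P(t) = exp(-integral of the background hazard)` with the hazard
#' piecewise constant on annual intervals since diagnosis (see
#' [hazard_paths()] for the path convention). This is the survival the
#' patient would experience under her stratum's life table alone.
#'
#' @param patient A one-row data frame (or list) with `age_at_diagnosis`,
#'   `diagnosis_date` or `diagnosis_year`, `ethnicity_group`,
#'   `deprivation_group`.
#' @param t Non-negative time(s) since diagnosis, in years.
#' @param table A [life_table()].
#' @return Numeric vector of survival probabilities in `(0, 1]`.
#' @export
#' @examples
#' lt <- life_table(expand.grid(age = 0:99, year = 2000:2012, qx = 0.01))
#' p <- list(age_at_diagnosis = 60, diagnosis_year = 2005,
#'           ethnicity_group = NA, deprivation_group = NA)
#' expected_survival(p, t = 5, lt)  # exp(-5 * (-log(0.99)))
expected_survival <- function(patient, t, table) {
  stopifnot(all(t >= 0))
  patient <- as.data.frame(patient[c("age_at_diagnosis",
                                     intersect(c("diagnosis_date", "diagnosis_year"),
                                               names(patient)),
                                     "ethnicity_group", "deprivation_group")])
  n_years <- max(1L, ceiling(max(t) + 1e-12))
  lam <- hazard_paths(patient, table, n_years)[1L, ]
  cum <- c(0, cumsum(lam))
  k <- pmin(floor(t), n_years - 1L)
  exp(-(cum[k + 1L] + lam[k + 1L] * (t - k)))
}

#' Remaining life expectancy under a life table
#'
#' Expected number of further years lived from a starting age and
#' calendar year, integrating the piecewise-exponential survival curve
#' implied by the annual hazards; the terminal hazard is carried forward
#' to `max_age`. Used by the over-diagnosis rule: a predicted lead time
#' longer than the woman's life expectancy at diagnosis means her tumour
#' would never have surfaced in her lifetime.
#'
#' @param age,year,stratum Vectors (recycled) giving the starting state.
#' @param table A [life_table()].
#' @param max_age Age at which the integration stops.
#' @return Numeric vector of expected remaining years.
#' @export
life_expectancy <- function(age, year, stratum, table, max_age = 110) {
  n <- max(length(age), length(year), length(stratum))
  age <- rep_len(age, n); year <- rep_len(year, n); stratum <- rep_len(stratum, n)
  horizon <- max(1L, ceiling(max_age - min(age)))
  S <- rep(1, n)
  e <- rep(0, n)
  for (k in seq_len(horizon)) {
    lam <- lt_hazard(table, age + k - 1L, year + k - 1L, stratum)
    live <- (age + k - 1L) < max_age
    contrib <- ifelse(lam > 0, (1 - exp(-lam)) / lam, 1)
    e <- e + ifelse(live, S * contrib, 0)
    S <- S * exp(-lam)
  }
  e
}
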