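AGE_BANDS <- c("50-54", "55-59", "60-64", "65-70")
PERIOD_BANDS <- c("1989-1994", "1995-2000", "2001-2006", "2007-2011")

#' Age and period bands used in descriptive reports
#'
#' @param age Ages in completed years.
#' @return Character vector of band labels.
#' @export
age_band <- function(age) {
  as.character(cut(age, breaks = c(50, 55, 60, 65, 71), labels = AGE_BANDS,
                   right = FALSE, include.lowest = TRUE))
}

#' @rdname age_band
#' @param date Diagnosis dates.
#' @export
period_band <- function(date) {
  y <- as.integer(format(as.Date(date), "%Y"))
  as.character(cut(y, breaks = c(1988, 1994, 2000, 2006, 2011),
                   labels = PERIOD_BANDS, right = TRUE))
}

#' Descriptive cohort cross-tabulation
#'
#' Counts and column percentages of cohort characteristics by ethnic
#' group (plus a Total column), with a chi-square test per characteristic
#' computed on non-missing cells only. Characteristics: age band, period
#' of diagnosis, vital status, deprivation quintile, deprivation group,
#' extent of disease, screening status.
#'
#' @param cohort Cohort data frame.
#' @param by Grouping column (default `"ethnicity_group"`).
#' @return An object of class `descriptive_table`: list with `table`
#'   (characteristic, level, then `<group>_n` / `<group>_pct` columns and
#'   Total) and `tests` (characteristic, statistic, df, p_value).
#' @export
descriptive_table <- function(cohort, by = "ethnicity_group") {
  stopifnot(nrow(cohort) > 0, by %in% names(cohort))
  g <- as.character(cohort[[by]])
  groups <- sort(unique(g))
  vars <- list(
    age_group = if (!is.null(cohort$age_at_diagnosis))
      age_band(cohort$age_at_diagnosis),
    period = if (!is.null(cohort$diagnosis_date))
      period_band(cohort$diagnosis_date),
    vital_status = cohort$vital_status,
    deprivation_quintile = if (!is.null(cohort$deprivation_quintile))
      as.character(cohort$deprivation_quintile),
    deprivation_group = cohort$deprivation_group,
    extent = cohort$extent,
    screening_status = cohort$screening_status
  )
  vars <- Filter(Negate(is.null), vars)
  denom <- c(table(factor(g, groups)), Total = length(g))
  rows <- list(); tests <- list()
  for (v in names(vars)) {
    x <- vars[[v]]
    levs <- unique(x[!is.na(x)])
    levs <- levs[order(levs)]
    if (anyNA(x)) levs <- c(levs, NA)
    counts <- table(factor(x, levels = levs, exclude = NULL),
                    factor(g, groups), useNA = "no")
    counts <- counts[seq_along(levs), , drop = FALSE]
    tot <- rowSums(counts)
    tab <- data.frame(characteristic = v,
                      level = ifelse(is.na(levs), "missing", as.character(levs)),
                      stringsAsFactors = FALSE)
    for (gr in groups) {
      tab[[paste0(gr, "_n")]] <- as.integer(counts[, gr])
      tab[[paste0(gr, "_pct")]] <- 100 * counts[, gr] / denom[[gr]]
    }
    tab$Total_n <- as.integer(tot)
    tab$Total_pct <- 100 * tot / denom[["Total"]]
    rows[[v]] <- tab
    nonmiss <- counts[!is.na(levs), , drop = FALSE]
    if (nrow(nonmiss) >= 2 && ncol(nonmiss) >= 2 && all(colSums(nonmiss) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(nonmiss, correct = FALSE))
      tests[[v]] <- data.frame(characteristic = v,
                               statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_value = unname(ct$p.value))
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 groups = groups, n = length(g)),
            class = "descriptive_table")
}

#' @export
print.descriptive_table <- function(x, ...) {
  tab <- x$table
  pct <- grep("_pct$", names(tab))
  tab[pct] <- lapply(tab[pct], round, 1)
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nChi-square tests (non-missing cells only):\n")
    print.data.frame(transform(x$tests, statistic = round(statistic, 2),
                               p_value = signif(p_value, 3)),
                     row.names = FALSE)
  }
  invisible(x)
}

#' Specification of a stratified net-survival analysis
#'
#' @param stratifiers Character vector drawn from `ethnicity_group`,
#'   `deprivation_group`, `deprivation_quintile`, `screening_status`,
#'   `extent`, `period`. Empty means a single overall stratum. When
#'   stratifying on `screening_status`, non-attenders and unresolvable
#'   histories are pooled into one `non_attender_other` category.
#' @param times Report times in years (positive, increasing; default 1
#'   and 5).
#' @param correct_leadtime Apply the lead-time / over-diagnosis
#'   correction. Default `NULL` means: on exactly when `screening_status`
#'   is a stratifier (any comparison of screen-detected and non
#'   screen-detected women must be corrected; an explicit `FALSE` with
#'   that stratifier is rejected).
#' @param smoothing Smooth uncorrected curves with [smooth_curve()]?
#'   Corrected curves are never smoothed unless `smooth_corrected = TRUE`
#'   (with few corrected data points smoothing hides what variability
#'   there is).
#' @param smooth_corrected Override allowing smoothing of corrected
#'   curves.
#' @param conf_level Confidence level.
#' @param leadtime A [leadtime_config()].
#' @param smooth A [smoothing_config()].
#' @param grid Optional output time grid (years).
#' @param window A [study_window()].
#' @return An object of class `analysis_spec`.
#' @export
analysis_spec <- function(stratifiers = character(),
                          times = c(1, 5),
                          correct_leadtime = NULL,
                          smoothing = TRUE,
                          smooth_corrected = FALSE,
                          conf_level = 0.95,
                          leadtime = leadtime_config(),
                          smooth = smoothing_config(),
                          grid = NULL,
                          window = study_window()) {
  allowed <- c("ethnicity_group", "deprivation_group", "deprivation_quintile",
               "screening_status", "extent", "period")
  bad <- setdiff(stratifiers, allowed)
  if (length(bad)) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  if (!(length(times) >= 1 && all(times > 0) && !is.unsorted(times, strictly = TRUE)))
    stop("report times must be positive and strictly increasing")
  if ("screening_status" %in% stratifiers && isFALSE(correct_leadtime))
    stop("comparisons involving screening status must apply the lead-time ",
         "and over-diagnosis corrections (correct_leadtime cannot be FALSE)")
  if (is.null(correct_leadtime))
    correct_leadtime <- "screening_status" %in% stratifiers
  structure(list(stratifiers = stratifiers, times = times,
                 correct_leadtime = correct_leadtime, smoothing = smoothing,
                 smooth_corrected = smooth_corrected, conf_level = conf_level,
                 leadtime = leadtime, smooth = smooth, grid = grid,
                 window = window),
            class = "analysis_spec")
}

ns_at_or_na <- function(curve, t) {
  if (is.null(curve) || t > max(curve$time) + 1e-9)
    return(data.frame(time = t, ns = NA_real_, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_))
  net_survival_at(curve, t)
}

#' Run a stratified net-survival analysis
#'
#' The end-to-end pipeline: splits the cohort by the requested
#' stratifiers, applies (when required) the over-diagnosis exclusion and
#' lead-time correction with Rubin's-rules pooling, estimates net
#' survival per stratum, optionally smooths uncorrected curves, and
#' assembles a report table (n, %, net survival with CI at the report
#' times, on the percent scale) plus the per-stratum curves and a run
#' log.
#'
#' @param cohort Cohort data frame (or a path to a cohort CSV).
#' @param table A [life_table()] (or a path to a life-table CSV).
#' @param spec An [analysis_spec()].
#' @return An object of class `netsurv_analysis`: list with `table`
#'   (one row per stratum), `curves` (named list of `net_survival`
#'   objects), `corrected` (named list of `corrected_net_survival`
#'   results where applicable) and `log`.
#' @export
run_analysis <- function(cohort, table, spec = analysis_spec()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(table)) table <- read_life_table(table)
  stopifnot(inherits(spec, "analysis_spec"), nrow(cohort) > 0)
  ch <- cohort
  if ("period" %in% spec$stratifiers)
    ch$period <- period_band(ch$diagnosis_date)
  if ("screening_status" %in% spec$stratifiers) {
    ch$screening_status <- ifelse(
      ch$screening_status %in% c("non_attender", "other_unresolvable"),
      "non_attender_other", ch$screening_status)
  }
  if (length(spec$stratifiers)) {
    vals <- lapply(spec$stratifiers, function(s) {
      v <- as.character(ch[[s]])
      if (s == "screening_status")
        levs <- c("screen_detected", "interval", "lapsed_attender",
                  "non_attender_other")
      else levs <- sort(unique(v[!is.na(v)]))
      factor(ifelse(is.na(v), "missing", v),
             levels = c(levs, if (anyNA(v)) "missing"))
    })
    strata <- interaction(vals, sep = " / ", drop = FALSE)
    labels <- levels(strata)
  } else {
    strata <- factor(rep("all", nrow(ch)))
    labels <- "all"
  }

  curves <- list(); corrected <- list(); rows <- list(); log <- list()
  for (lab in labels) {
    sub <- ch[strata == lab, , drop = FALSE]
    n_sub <- nrow(sub)
    row <- data.frame(stratum = lab, n = n_sub,
                      pct = 100 * n_sub / nrow(ch))
    est <- NULL
    is_missing_stratum <- grepl("(^| )missing($| )", lab) ||
      grepl(" / missing", lab, fixed = TRUE) || lab == "missing"
    if (n_sub > 0 && !is_missing_stratum) {
      maxt <- max(if (!is.null(sub$time)) sub$time else survival_years(sub))
      grid <- spec$grid
      if (is.null(grid))
        grid <- sort(unique(c(seq(0, floor(maxt * 12) / 12, by = 1 / 12),
                              spec$times[spec$times <= maxt])))
      apply_corr <- spec$correct_leadtime &&
        any(sub$screening_status == "screen_detected")
      if (apply_corr) {
        corr <- corrected_net_survival(sub, table, leadtime = spec$leadtime,
                                       window = spec$window,
                                       grid = grid[grid <= maxt],
                                       conf_level = spec$conf_level)
        corrected[[lab]] <- corr
        est <- corr$curve
        log[[lab]] <- list(n = n_sub,
                           n_overdiagnosed = nrow(corr$exclusion$excluded),
                           n_floored = corr$n_floored)
        if (spec$smoothing && spec$smooth_corrected)
          est <- smooth_curve(est, spec$smooth)
      } else {
        est <- pohar_perme(sub, table, grid = grid,
                           conf_level = spec$conf_level)
        log[[lab]] <- list(n = n_sub, n_overdiagnosed = 0L, n_floored = 0L)
        if (spec$smoothing) est <- smooth_curve(est, spec$smooth)
      }
      curves[[lab]] <- est
    }
    for (t in spec$times) {
      at <- ns_at_or_na(est, t)
      row[[sprintf("ns_%gy", t)]] <- 100 * at$ns
      row[[sprintf("ci_low_%gy", t)]] <- 100 * at$ci_low
      row[[sprintf("ci_high_%gy", t)]] <- 100 * at$ci_high
    }
    rows[[lab]] <- row
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 curves = curves, corrected = corrected,
                 log = list(spec = spec, strata = log,
                            seed = spec$leadtime$seed)),
            class = "netsurv_analysis")
}

#' @export
print.netsurv_analysis <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "n"
  tab[num] <- lapply(tab[num], round, 1)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Writes the report table (`table.csv`, percentages rounded to 1
#' decimal), one curve CSV per stratum, and a JSON run manifest with the
#' configuration and per-stratum exclusion counts.
#'
#' @param x A `netsurv_analysis` object.
#' @param dir Output directory (created if needed).
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "netsurv_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "n"
  tab[num] <- lapply(tab[num], round, 1)
  utils::write.csv(tab, file.path(dir, "table.csv"), row.names = FALSE)
  for (lab in names(x$curves)) {
    safe <- gsub("[^A-Za-z0-9_.-]+", "_", lab)
    write_curve(x$curves[[lab]], file.path(dir, paste0("curve_", safe, ".csv")))
  }
  spec <- x$log$spec
  manifest <- list(
    stratifiers = spec$stratifiers, times = spec$times,
    correct_leadtime = spec$correct_leadtime, smoothing = spec$smoothing,
    conf_level = spec$conf_level,
    leadtime = list(mst = spec$leadtime$mst, m = spec$leadtime$m,
                    variant = spec$leadtime$variant,
                    seed = spec$leadtime$seed),
    strata = x$log$strata)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
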