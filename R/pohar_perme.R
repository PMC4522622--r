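#' netsurv: net survival for screening-eligible cancer cohorts
#'
#' @keywords internal
#' @useDynLib netsurv, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Non-parametric net-survival estimator
#'
#' Estimates net survival — survival from the cancer itself, with the
#' effect of background (other-cause) mortality removed — by the
#' inverse-expected-survival-weighted (Pohar Perme) estimator. Each
#' patient's event and at-risk processes are weighted by
#' `w_i(s) = 1/S_Pi(s)`, the reciprocal of her expected survival under her
#' stratum's life table. The cumulative excess hazard accumulates a
#' discrete observed part, `dL_O(s) = sum(w_i dN_i) / sum(w_i Y_i)` at
#' each death time, minus a continuous population part,
#' `integral of sum(w_i Y_i lam_Pi) / sum(w_i Y_i)`, integrated exactly
#' over the piecewise-constant annual expected hazards. Net survival is
#' the product-integral
#' `NS(t) = prod(1 - dL_O(s)) * exp(+L_pop(t))`,
#' which reduces exactly to Kaplan-Meier when the life table carries zero
#' mortality, and can exceed 1 when a group experiences fewer deaths than
#' its background mortality predicts. The stored cumulative excess hazard
#' is `-log(NS)`, so `NS = exp(-cumhaz)` holds identically.
#'
#' The variance of the cumulative excess hazard is the weighted
#' counting-process estimator `sum(w_i^2 dN_i) / (sum(w_i Y_i))^2`,
#' accumulated over event times. Confidence limits are computed on the
#' cumulative-hazard scale and transformed, so they may exceed 100%:
#' that indicates survival not significantly different from background
#' mortality. Ties are handled by the standard counting-process
#' convention: deaths at a time point are processed before censorings at
#' the same time.
#'
#' @param cohort Cohort data frame. Follow-up time in years is taken from
#'   a `time` column if present, else computed from `diagnosis_date` /
#'   `exit_date`; the event indicator from a `status` column (1 = death)
#'   if present, else from `vital_status` (`"D"` = death).
#' @param table A [life_table()] supplying expected mortality; strata are
#'   matched on `ethnicity_group` x `deprivation_group` (an unstratified
#'   table serves all patients).
#' @param grid Optional increasing vector of output times (years). By
#'   default the curve is reported at 0 and every distinct death time.
#'   Grid points beyond the last observed follow-up time are dropped with
#'   a warning (empty risk set).
#' @param conf_level Two-sided confidence level (default 0.95).
#' @param max_step Maximum integration step in years for the population
#'   hazard term (default 1/12); event times, censoring times and
#'   whole-year boundaries are always integration breakpoints.
#' @return An object of classes `net_survival` and `data.frame` with
#'   columns `time`, `ns`, `cumhaz`, `cumhaz_pop`, `se`, `ci_low`,
#'   `ci_high`, `n_risk`, `n_event`. `se` is the standard error of the
#'   cumulative excess hazard. Attributes: `conf_level`, `n`, `truncated`.
#' @references Perme, M. P., Stare, J. and Esteve, J. (2012) On estimation
#'   in relative survival. Biometrics 68, 113-120.
#' @export
pohar_perme <- function(cohort, table, grid = NULL, conf_level = 0.95,
                        max_step = 1 / 12) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            inherits(table, "life_table"))
  times <- if (!is.null(cohort$time)) as.numeric(cohort$time)
           else survival_years(cohort)
  status <- if (!is.null(cohort$status)) as.integer(cohort$status)
            else as.integer(cohort$vital_status %in% c("D", "dead", "Dead", "1"))
  if (anyNA(times) || any(times < 0))
    stop("follow-up times must be non-negative and non-missing")
  times <- pmax(times, 0.5 / 365.25)  # same-day events kept at half a day
  ord <- order(times)
  times <- times[ord]
  status <- status[ord]
  n <- length(times)
  tmax <- max(times)
  K <- max(1L, ceiling(tmax - 1e-9))
  lam <- hazard_paths(cohort[ord, , drop = FALSE], table, K)

  truncated <- FALSE
  if (!is.null(grid)) {
    grid <- sort(unique(as.numeric(grid)))
    if (any(grid < 0)) stop("grid times must be non-negative")
    if (any(grid > tmax + 1e-9)) {
      warning("curve truncated at last observed time ", signif(tmax, 6),
              "; grid points beyond it dropped (empty risk set)")
      truncated <- TRUE
      grid <- grid[grid <= tmax + 1e-9]
    }
  }
  brk <- sort(unique(c(times, seq_len(K), grid[grid > 0],
                       seq(0, tmax, by = max_step))))
  brk <- brk[brk > 0 & brk <= tmax + 1e-12]

  acc <- .pp_accumulate(times, status, lam, brk)
  d1 <- ifelse(acc$s1 > 0, acc$dnw / acc$s1, 0)
  dlog1 <- ifelse(d1 < 1, -log1p(-d1), Inf)
  cumhaz_obs <- cumsum(dlog1)
  cumhaz_pop <- cumsum(acc$dlam2)
  cumvar <- cumsum(ifelse(acc$s1 > 0, acc$dvar / acc$s1^2, 0))
  cumhaz <- cumhaz_obs - cumhaz_pop
  se <- sqrt(cumvar)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out_t <- if (is.null(grid)) c(0, brk[acc$nevent > 0]) else grid
  idx <- findInterval(out_t + 1e-12, brk)  # 0 for t = 0
  val <- function(v, zero) ifelse(idx == 0L, zero, v[pmax(idx, 1L)])
  curve <- data.frame(
    time = out_t,
    ns = val(exp(-cumhaz), 1),
    cumhaz = val(cumhaz, 0),
    cumhaz_pop = val(cumhaz_pop, 0),
    se = val(se, 0),
    ci_low = val(exp(-(cumhaz + z * se)), 1),
    ci_high = val(exp(-(cumhaz - z * se)), 1),
    n_risk = val(as.numeric(acc$nrisk), n),
    n_event = ifelse(idx == 0L, 0, cumsum(acc$nevent)[pmax(idx, 1L)])
  )
  structure(curve, class = c("net_survival", "data.frame"),
            conf_level = conf_level, n = n, truncated = truncated)
}

#' Look up a net-survival curve at given times
#'
#' The curve is a step function: the value at `t` is the value at the
#' greatest reported grid point not exceeding `t`.
#'
#' @param curve A `net_survival` curve (from [pohar_perme()] or
#'   [pool_curves()]).
#' @param t Times in years, within the curve's range.
#' @return A data frame with one row per `t`: `time`, `ns`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
net_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "net_survival"))
  if (any(t < min(curve$time) - 1e-12))
    stop("lookup time before the curve's first grid point")
  if (any(t > max(curve$time) + 1e-9))
    stop("lookup time beyond the curve's last grid point",
         if (isTRUE(attr(curve, "truncated"))) " (curve was truncated)" else "")
  idx <- findInterval(t + 1e-12, curve$time)
  data.frame(time = t, ns = curve$ns[idx], se = curve$se[idx],
             ci_low = curve$ci_low[idx], ci_high = curve$ci_high[idx])
}

#' @export
print.net_survival <- function(x, digits = 4, ...) {
  cat(sprintf("Net survival curve (n = %s, %.0f%% CI)%s\n",
              attr(x, "n"), 100 * attr(x, "conf_level"),
              if (isTRUE(attr(x, "truncated"))) " [truncated]" else ""))
  show <- x[, c("time", "ns", "se", "ci_low", "ci_high", "n_risk", "n_event")]
  print.data.frame(utils::tail(show, 10), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a net-survival curve to CSV
#'
#' Columns `time, ns, se, ci_low, ci_high, n_risk, n_event`, plus
#' `smoothed` and pooling columns (`B`, `T`, `nu`) when present.
#'
#' @param curve A `net_survival` curve.
#' @param file Output path.
#' @export
write_curve <- function(curve, file) {
  keep <- intersect(c("time", "ns", "se", "ci_low", "ci_high",
                      "n_risk", "n_event", "smoothed", "B", "T", "nu"),
                    names(curve))
  utils::write.csv(as.data.frame(curve)[, keep], file, row.names = FALSE)
  invisible(file)
}
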