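#' Configuration for the lead-time correction
#'
#' Screen detection advances diagnosis by the lead time, inflating
#' apparent survival with no change in prognosis. Under an exponential
#' preclinical sojourn-time model with mean sojourn time `mst`, a
#' screen-detected woman's expected lead time given her observed survival
#' can be computed in closed form; sampling from the implied distribution
#' across `m` datasets propagates the uncertainty in the unknown lead
#' time.
#'
#' @param mst Mean sojourn time in years (default 4): mean duration of the
#'   preclinical screen-detectable phase.
#' @param m Number of corrected datasets to generate (default 10).
#' @param variant Which closed-form expectation to use for the expected
#'   lead time given observed survival `t`:
#'   `"conditional_truncated"` (default), `E[L | L <= t]`, or
#'   `"expected_min"`, `E[min(L, t)]`, with `L ~ Exponential(1/mst)`.
#' @param seed Optional integer seed fixing the corrected-dataset draws.
#' @param epsilon Floor for corrected survival times, in years (default
#'   one day): a drawn lead time exceeding the observed time is floored,
#'   not re-drawn.
#' @return An object of class `leadtime_config`.
#' @export
leadtime_config <- function(mst = 4, m = 10,
                            variant = c("conditional_truncated", "expected_min"),
                            seed = NULL, epsilon = 1 / 365.25) {
  variant <- match.arg(variant)
  if (!(is.numeric(mst) && mst > 0)) stop("mean sojourn time must be > 0")
  if (!(is.numeric(m) && m >= 2)) stop("at least 2 corrected datasets required")
  structure(list(mst = mst, rate = 1 / mst, m = as.integer(m),
                 variant = variant, seed = seed, epsilon = epsilon),
            class = "leadtime_config")
}

#' Expected lead time given observed survival
#'
#' With sojourn time `L ~ Exponential(rate = 1/mst)`, the additional
#' survival time attributable to earlier (screen) detection, given an
#' observed survival time `t`, is
#' `E[L | L <= t] = 1/rate - t * exp(-rate*t) / (1 - exp(-rate*t))`
#' (variant `"conditional_truncated"`) or
#' `E[min(L, t)] = (1 - exp(-rate*t)) / rate`
#' (variant `"expected_min"`). Both are 0 at `t = 0`, strictly increasing
#' in `t` and in `mst`, and approach `mst` as `t` grows.
#'
#' @param t_obs Observed survival time(s) in years, non-negative.
#' @param config A [leadtime_config()].
#' @return Numeric vector of expected lead times (years).
#' @export
#' @examples
#' expected_lead_time(c(0, 4, 100), leadtime_config(mst = 4))
expected_lead_time <- function(t_obs, config = leadtime_config()) {
  stopifnot(all(t_obs >= 0))
  r <- config$rate
  x <- r * t_obs
  if (config$variant == "expected_min") {
    return(-expm1(-x) / r)
  }
  # E[L | L <= t]; series limit t/2 as t -> 0
  out <- ifelse(x < 1e-8, t_obs / 2,
                1 / r - t_obs * exp(-x) / -expm1(-x))
  out[t_obs == 0] <- 0
  out
}

#' Exclude over-diagnosed screen-detected tumours
#'
#' A screen-detected tumour is treated as over-diagnosed when its expected
#' lead time exceeds the woman's actual observed survival time: either the
#' predicted symptomatic diagnosis date (diagnosis date + expected lead
#' time) falls after the end of the diagnosis window, or the expected lead
#' time exceeds her life-table remaining life expectancy at diagnosis
#' (evaluated in her own stratum). Women whose cancers were not
#' screen-detected are never excluded.
#'
#' @param cohort Cohort data frame.
#' @param e_s Numeric vector of expected lead times, aligned with
#'   `cohort` rows (values for non-screen-detected rows are ignored).
#' @param window A [study_window()].
#' @param table A [life_table()] for the life-expectancy condition.
#' @return A list of class `overdiagnosis_exclusion`: `kept`, `excluded`
#'   (data frames) and `flag` (logical vector over the input rows).
#' @export
exclude_overdiagnosed <- function(cohort, e_s, window = study_window(), table) {
  stopifnot(nrow(cohort) == length(e_s))
  screen <- cohort$screening_status == "screen_detected"
  window_left <- as.numeric(window$diagnosis_end -
                              as.Date(cohort$diagnosis_date)) / 365.25
  year0 <- as.integer(format(as.Date(cohort$diagnosis_date), "%Y"))
  stratum <- cohort_strata(table, cohort$ethnicity_group, cohort$deprivation_group)
  le <- life_expectancy(cohort$age_at_diagnosis, year0, stratum, table)
  flag <- screen & !is.na(e_s) & (e_s > window_left | e_s > le)
  structure(list(kept = cohort[!flag, , drop = FALSE],
                 excluded = cohort[flag, , drop = FALSE],
                 flag = flag),
            class = "overdiagnosis_exclusion")
}

#' @export
print.overdiagnosis_exclusion <- function(x, ...) {
  cat(sprintf("Over-diagnosis exclusion: %d kept, %d excluded\n",
              nrow(x$kept), nrow(x$excluded)))
  invisible(x)
}

#' Generate lead-time-corrected datasets
#'
#' For each of `m` datasets and each screen-detected woman `i`, draws a
#' lead time `s_ij ~ Exponential(mean = E_s[i])` (degenerate at 0 when
#' `E_s[i] = 0`), independently across women and datasets, and subtracts
#' it from her observed survival time; results below `epsilon` (one day
#' by default) are floored there rather than re-drawn. Women whose
#' cancers were not screen-detected keep their observed times.
#'
#' Each corrected dataset is indexed from the woman's *predicted
#' symptomatic diagnosis*: besides shortening her survival time by the
#' drawn lead time, her diagnosis date and age at diagnosis are advanced
#' by it, so that the expected-mortality path used to weight the
#' net-survival estimator starts at the age she actually had when the
#' corrected clock starts. Without this shift the background hazard is
#' evaluated at too young an age over the corrected follow-up and the
#' deficit is misattributed to the cancer.
#'
#' @param cohort Cohort data frame (after over-diagnosis exclusion).
#' @param e_s Expected lead times aligned with `cohort` rows.
#' @param config A [leadtime_config()]; its `seed`, if non-`NULL`, makes
#'   the draws reproducible.
#' @return A list of `m` data frames, each the input cohort with a `time`
#'   column holding corrected survival times (years) and shifted
#'   `diagnosis_date` / `age_at_diagnosis` for screen-detected women.
#'   Attributes: `draws` (matrix of drawn lead times, screen-detected
#'   rows x m) and `n_floored` (number of corrected times floored at
#'   `epsilon`).
#' @export
generate_corrected_datasets <- function(cohort, e_s, config = leadtime_config()) {
  stopifnot(nrow(cohort) == length(e_s))
  if (!is.null(config$seed)) set.seed(config$seed)
  t_obs <- if (!is.null(cohort$time)) as.numeric(cohort$time)
           else survival_years(cohort)
  screen <- which(cohort$screening_status == "screen_detected")
  m <- config$m
  draws <- matrix(0, length(screen), m)
  if (length(screen))
    draws[] <- stats::rexp(length(screen) * m) * e_s[screen]
  n_floored <- 0L
  datasets <- vector("list", m)
  for (j in seq_len(m)) {
    tj <- t_obs
    if (length(screen)) {
      corrected <- t_obs[screen] - draws[, j]
      n_floored <- n_floored + sum(corrected < config$epsilon)
      tj[screen] <- pmax(corrected, config$epsilon)
    }
    dj <- cohort
    dj$time <- tj
    if (length(screen)) {
      s <- draws[, j]
      if (!is.null(dj$diagnosis_date))
        dj$diagnosis_date[screen] <- as.Date(dj$diagnosis_date[screen]) +
          round(s * 365.25)
      if (!is.null(dj$diagnosis_year))
        dj$diagnosis_year[screen] <- dj$diagnosis_year[screen] + floor(s)
      dj$age_at_diagnosis[screen] <- floor(dj$age_at_diagnosis[screen] + s)
    }
    datasets[[j]] <- dj
  }
  structure(datasets, draws = draws, n_floored = n_floored)
}

#' Pool estimates across multiply-imputed datasets (Rubin's rules)
#'
#' Combines `m` per-dataset estimates `Q_j` with within-dataset variances
#' `U_j`: pooled point `Qbar = mean(Q_j)`; within-variance
#' `Wbar = mean(U_j)`; between-variance `B = var(Q_j)`; total variance
#' `T = Wbar + (1 + 1/m) B`; degrees of freedom
#' `nu = (m - 1) (1 + Wbar / ((1 + 1/m) B))^2` (infinite when `B = 0`),
#' with a t reference for the confidence interval.
#'
#' @param q Numeric vector of per-dataset point estimates (length >= 2).
#' @param u Numeric vector of per-dataset variances (same length, >= 0).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `pooled_estimate`: a list with `qbar`,
#'   `wbar`, `b`, `t` (total variance), `nu`, `se`, `ci_low`, `ci_high`,
#'   `m`.
#' @export
#' @examples
#' rubin_pool(q = c(0.80, 0.90), u = c(0.01, 0.01))
rubin_pool <- function(q, u, conf_level = 0.95) {
  m <- length(q)
  stopifnot(m >= 2, length(u) == m, all(u >= 0))
  qbar <- mean(q)
  wbar <- mean(u)
  b <- stats::var(q)
  tot <- wbar + (1 + 1 / m) * b
  nu <- if (b == 0) Inf else (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = nu)
  se <- sqrt(tot)
  structure(list(qbar = qbar, wbar = wbar, b = b, t = tot, nu = nu, se = se,
                 ci_low = qbar - crit * se, ci_high = qbar + crit * se,
                 m = m, conf_level = conf_level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.5f (SE %.5f, %0.f%% CI %.5f to %.5f)\n",
              x$m, x$qbar, x$se, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  within %.6f, between %.6f, total %.6f, df %.1f\n",
              x$wbar, x$b, x$t, x$nu))
  invisible(x)
}

#' Pool net-survival curves across corrected datasets
#'
#' Applies Rubin's rules per time point on the cumulative-excess-hazard
#' scale (where the estimator is approximately normal), then transforms
#' back: `NS = exp(-Qbar)` with confidence limits
#' `exp(-(Qbar +/- t_nu * sqrt(T)))`. All curves must share the same time
#' grid.
#'
#' @param curves List of `net_survival` curves on a common grid.
#' @param conf_level Confidence level (default 0.95).
#' @return A `net_survival` data frame with additional columns `B`
#'   (between-imputation variance), `T` (total variance) and `nu`
#'   (Rubin degrees of freedom), all on the cumulative-hazard scale.
#' @export
pool_curves <- function(curves, conf_level = 0.95) {
  m <- length(curves)
  stopifnot(m >= 2)
  t0 <- curves[[1]]$time
  for (cv in curves)
    if (!isTRUE(all.equal(cv$time, t0)))
      stop("curves must share a common time grid for pooling")
  H <- do.call(rbind, lapply(curves, function(cv) cv$cumhaz))
  V <- do.call(rbind, lapply(curves, function(cv) cv$se^2))
  ok <- apply(is.finite(H), 2, all)
  qbar <- colMeans(H)
  wbar <- colMeans(V)
  b <- colSums(sweep(H, 2, qbar)^2) / (m - 1)
  b[!ok] <- NA
  tot <- wbar + (1 + 1 / m) * b
  nu <- ifelse(is.na(b) | b == 0, Inf,
               (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = nu)
  se <- sqrt(tot)
  curve <- data.frame(
    time = t0,
    ns = exp(-qbar),
    cumhaz = qbar,
    cumhaz_pop = colMeans(do.call(rbind, lapply(curves, function(cv) cv$cumhaz_pop))),
    se = se,
    ci_low = exp(-(qbar + crit * se)),
    ci_high = exp(-(qbar - crit * se)),
    n_risk = colMeans(do.call(rbind, lapply(curves, function(cv) cv$n_risk))),
    n_event = colMeans(do.call(rbind, lapply(curves, function(cv) cv$n_event))),
    B = b, T = tot, nu = nu
  )
  structure(curve, class = c("net_survival", "data.frame"),
            conf_level = conf_level, n = attr(curves[[1]], "n"),
            truncated = any(vapply(curves, function(cv)
               isTRUE(attr(cv, "truncated")), TRUE)),
            m = m)
}

#' Lead-time- and over-diagnosis-corrected net survival
#'
#' End-to-end correction for one cohort (or stratum subset): computes each
#' screen-detected woman's expected lead time, excludes over-diagnosed
#' tumours, generates `m` corrected datasets, estimates net survival on
#' each, and pools by Rubin's rules on the cumulative-hazard scale.
#'
#' @param cohort Cohort data frame.
#' @param table A [life_table()].
#' @param leadtime A [leadtime_config()].
#' @param window A [study_window()].
#' @param grid Output time grid in years; defaults to monthly steps up to
#'   the shortest maximum corrected follow-up across datasets.
#' @param conf_level Confidence level.
#' @return A list of class `corrected_net_survival`: `curve` (pooled
#'   `net_survival`), `exclusion` (the [exclude_overdiagnosed()] result),
#'   `e_s` (expected lead times on the kept cohort), `n_floored`, and
#'   `per_dataset` (list of per-dataset curves).
#' @export
corrected_net_survival <- function(cohort, table, leadtime = leadtime_config(),
                                   window = study_window(), grid = NULL,
                                   conf_level = 0.95) {
  t_obs <- if (!is.null(cohort$time)) as.numeric(cohort$time)
           else survival_years(cohort)
  e_s_all <- ifelse(cohort$screening_status == "screen_detected",
                    expected_lead_time(pmax(t_obs, 0), leadtime), NA_real_)
  excl <- exclude_overdiagnosed(cohort, e_s_all, window, table)
  kept <- excl$kept
  if (nrow(kept) == 0L) stop("no patients left after over-diagnosis exclusion")
  e_s <- e_s_all[!excl$flag]
  e_s[is.na(e_s)] <- 0
  datasets <- generate_corrected_datasets(kept, e_s, leadtime)
  tmax <- min(vapply(datasets, function(d) max(d$time), 0))
  if (is.null(grid)) {
    grid <- seq(0, floor(tmax * 12) / 12, by = 1 / 12)
  } else {
    grid <- grid[grid <= tmax + 1e-9]  # corrected follow-up is shorter
  }
  per <- lapply(datasets, pohar_perme, table = table, grid = grid,
                conf_level = conf_level)
  pooled <- pool_curves(per, conf_level = conf_level)
  structure(list(curve = pooled, exclusion = excl, e_s = e_s,
                 n_floored = attr(datasets, "n_floored"),
                 per_dataset = per),
            class = "corrected_net_survival")
}

#' @export
print.corrected_net_survival <- function(x, ...) {
  cat(sprintf("Lead-time-corrected net survival (m = %d datasets, %d over-diagnosed excluded)\n",
              attr(x$curve, "m"), nrow(x$exclusion$excluded)))
  print(x$curve)
  invisible(x)
}
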