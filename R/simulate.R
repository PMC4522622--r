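#' Flat life table (constant hazard) for testing and examples
#'
#' Builds a [life_table()] with a single annual hazard everywhere —
#' including zero, under which net survival reduces exactly to
#' Kaplan-Meier.
#'
#' @param hazard Constant annual background hazard; the annual death
#'   probability is `1 - exp(-hazard)`.
#' @param ages,years Index ranges.
#' @param stratified If `TRUE`, the table carries all six
#'   ethnicity-by-deprivation strata; otherwise a single unstratified
#'   stratum.
#' @return A `life_table`.
#' @export
flat_life_table <- function(hazard = 0, ages = 0:109, years = 1980:2020,
                            stratified = FALSE) {
  q <- -expm1(-hazard)
  if (stratified) {
    g <- expand.grid(age = ages, year = years,
                     ethnicity_group = ETHNICITY_GROUPS,
                     deprivation_group = DEPRIVATION_GROUPS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(age = ages, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  g$qx <- q
  life_table(g, source = sprintf("flat hazard %g", hazard))
}

#' Synthetic ethnic/deprivation life tables
#'
#' Builds a plausible England-and-Wales-like system of life tables for the
#' study years: a Gompertz baseline hazard `a * exp(b * age)` (about
#' 0.0065 at age 60 and 0.038 at age 80 in 2001, typical of female
#' all-cause mortality), an annual relative mortality improvement, and
#' multiplicative stratum effects (slightly lower background mortality in
#' the Asian and Black groups, lower in less deprived areas). Returns the
#' stratified base-year table, the national annual tables, and the
#' interpolated stratified system produced by [interpolate_life_tables()].
#'
#' @param years Calendar years to cover.
#' @param ages Ages to cover.
#' @param a,b Gompertz level and slope of the 2001 national hazard.
#' @param improvement Annual proportional hazard decline (default 1.5%).
#' @param ethnicity_mult,deprivation_mult Named hazard multipliers.
#' @param base_year Census anchor year for the stratified table.
#' @return A list with elements `base`, `national`, `interpolated`.
#' @export
synthetic_life_tables <- function(years = 1989:2012, ages = 0:99,
                                  a = 3.3e-5, b = 0.088, improvement = 0.015,
                                  ethnicity_mult = c(Asian = 0.90, Black = 0.95,
                                                     White = 1.00),
                                  deprivation_mult = c(less_deprived = 0.85,
                                                       middle_more_deprived = 1.12),
                                  base_year = 2001L) {
  h_age <- a * exp(b * ages)
  nat <- do.call(rbind, lapply(years, function(y) {
    data.frame(age = ages, year = y,
               qx = -expm1(-h_age * exp(-improvement * (y - base_year))))
  }))
  national <- life_table(nat, source = "synthetic national")
  combos <- expand.grid(ethnicity_group = names(ethnicity_mult),
                        deprivation_group = names(deprivation_mult),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    mult <- ethnicity_mult[[combos$ethnicity_group[i]]] *
      deprivation_mult[[combos$deprivation_group[i]]]
    data.frame(age = ages, year = base_year,
               ethnicity_group = combos$ethnicity_group[i],
               deprivation_group = combos$deprivation_group[i],
               qx = -expm1(-h_age * mult))
  }))
  base <- life_table(base, source = "synthetic ethnic/deprivation base")
  list(base = base, national = national,
       interpolated = interpolate_life_tables(base, national, years, base_year))
}

#' Configuration of the synthetic registry cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' women aged 50-70, diagnosed inside the study window, invited to
#' 3-yearly screening rounds from age 50 (or from the programme start),
#' an exponential preclinical sojourn time with mean `mst` years, and a
#' constant per-stratum excess (cancer) mortality hazard whose clock
#' starts at *symptomatic* diagnosis — so under the default
#' `benefit_hr = 1`, screen detection confers pure lead time and no
#' prognostic benefit, the null the lead-time correction must recover.
#'
#' Categorical mixes default to the observed registry margins: ethnic mix
#' 590/191/19502 of 20283 (Asian/Black/White), and age, period,
#' deprivation-quintile and extent distributions matching the registry
#' cohort's published margins. Default excess hazards give 5-year net
#' survival of about 90% (less deprived) and 87% (middle/more deprived).
#'
#' @param n_patients Number of women to simulate.
#' @param ethnic_mix Named probabilities over Asian/Black/White.
#' @param deprivation_mix Named list (per ethnicity) of probabilities over
#'   quintiles 1..5.
#' @param age_mix Probabilities over age bands 50-54, 55-59, 60-64, 65-70
#'   (uniform within band).
#' @param period_mix Probabilities over diagnosis-period bands 1989-1994,
#'   1995-2000, 2001-2006, 2007-2011 (uniform within band, clipped to the
#'   study window).
#' @param extent_mix Named list (per ethnicity) of probabilities over
#'   localised/regional/distant/missing.
#' @param screening_interval Years between screening invitations.
#' @param mst Mean sojourn time (years) of the preclinical phase.
#' @param attendance_prob Probability a woman attends any given
#'   invitation (independent across rounds).
#' @param p_other_unresolvable Probability a non-screen-detected woman's
#'   screening history is unresolvable (ceased/not known).
#' @param excess_hazard Named per-deprivation-group constant excess
#'   hazards (per year).
#' @param benefit_hr Hazard ratio applied to the excess hazard of
#'   screen-detected women (1 = pure lead time, no real benefit).
#' @param p_recurrence,p_in_situ Contamination fractions of recurrent and
#'   in-situ tumours (flagged, to be removed by [select_cohort()]).
#' @param window A [study_window()].
#' @param seed Optional integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 20000,
    ethnic_mix = c(Asian = 590, Black = 191, White = 19502) / 20283,
    deprivation_mix = list(
      Asian = c(48, 52, 86, 113, 291) / 590,
      Black = c(10, 20, 25, 33, 103) / 191,
      White = c(4420, 4542, 4065, 3400, 3057) / 19484),
    age_mix = c(6881, 6345, 4865, 2192) / 20283,
    period_mix = c(801, 3841, 7792, 7849) / 20283,
    extent_mix = list(
      Asian = c(329, 211, 18, 32) / 590,
      Black = c(89, 87, 3, 12) / 191,
      White = c(11758, 6066, 462, 1216) / 19502),
    screening_interval = 3,
    mst = 4,
    attendance_prob = 0.75,
    p_other_unresolvable = 0.028,
    excess_hazard = c(less_deprived = 0.0211, middle_more_deprived = 0.0285),
    benefit_hr = 1,
    p_recurrence = 0.03,
    p_in_situ = 0.006,
    window = study_window(),
    seed = NULL) {
  cfg <- list(n_patients = as.integer(n_patients), ethnic_mix = ethnic_mix,
              deprivation_mix = deprivation_mix, age_mix = age_mix,
              period_mix = period_mix, extent_mix = extent_mix,
              screening_interval = screening_interval, mst = mst,
              attendance_prob = attendance_prob,
              p_other_unresolvable = p_other_unresolvable,
              excess_hazard = excess_hazard, benefit_hr = benefit_hr,
              p_recurrence = p_recurrence, p_in_situ = p_in_situ,
              window = window, seed = seed)
  probsum1 <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop(what, " probabilities must be non-negative and sum to 1")
  }
  probsum1(cfg$ethnic_mix, "ethnic mix")
  probsum1(cfg$age_mix, "age mix")
  probsum1(cfg$period_mix, "period mix")
  for (e in names(cfg$deprivation_mix)) probsum1(cfg$deprivation_mix[[e]],
                                                 paste(e, "deprivation mix"))
  for (e in names(cfg$extent_mix)) probsum1(cfg$extent_mix[[e]],
                                            paste(e, "extent mix"))
  if (any(cfg$excess_hazard < 0)) stop("excess hazards must be >= 0")
  if (!all(DEPRIVATION_GROUPS %in% names(cfg$excess_hazard)))
    stop("excess_hazard must be named by deprivation group")
  if (cfg$mst <= 0 || cfg$screening_interval <= 0)
    stop("mst and screening_interval must be positive")
  if (cfg$attendance_prob < 0 || cfg$attendance_prob > 1)
    stop("attendance_prob must be a probability")
  structure(cfg, class = "simulation_config")
}

# Inversion sampling of a death time (years) from piecewise-constant
# annual hazards: find the year in which the cumulative hazard crosses
# -log(U). Rows beyond the tabulated horizon return Inf.
sample_piecewise_exponential <- function(lam, u = stats::runif(nrow(lam))) {
  target <- -log(u)
  cum <- t(apply(lam, 1, cumsum))
  k0 <- rowSums(cum < target)
  K <- ncol(lam)
  over <- k0 >= K
  k0c <- pmin(k0, K - 1L)
  cum0 <- ifelse(k0c == 0L, 0, cum[cbind(seq_len(nrow(lam)), pmax(k0c, 1L))])
  lam_next <- lam[cbind(seq_len(nrow(lam)), k0c + 1L)]
  tt <- k0c + (target - cum0) / lam_next
  tt[over] <- Inf
  tt
}

#' Simulate a registry-like cohort with known ground truth
#'
#' See [simulation_config()] for the generative model. Each woman's
#' natural history is: symptomatic diagnosis date and age drawn from the
#' configured mixes; preclinical onset at an exponential sojourn time
#' before symptomatic diagnosis; 3-yearly screening invitations from age
#' 50 (not before the programme start), each attended independently; if
#' an attended invitation falls inside the preclinical window she is
#' screen-detected there, and her recorded diagnosis is advanced by the
#' (recorded) true lead time. Death is the earlier of a cancer death
#' drawn from the stratum excess hazard (clock at symptomatic diagnosis)
#' and a background death drawn by inversion from her life-table hazard
#' path; follow-up is censored at the window's end.
#'
#' @param config A [simulation_config()].
#' @param table A [life_table()] providing background mortality.
#' @return A list of class `synthetic_cohort`: `cohort` (a patient data
#'   frame in the package's cohort schema) and `truth` (class
#'   `synthetic_truth`: per-stratum excess hazards, per-patient true lead
#'   times, the seed and the config).
#' @export
simulate_cohort <- function(config = simulation_config(), table) {
  stopifnot(inherits(config, "simulation_config"), inherits(table, "life_table"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  w <- config$window

  ethnicity <- sample(names(config$ethnic_mix), n, TRUE, config$ethnic_mix)
  quintile <- integer(n)
  for (e in unique(ethnicity)) {
    idx <- ethnicity == e
    quintile[idx] <- sample(1:5, sum(idx), TRUE, config$deprivation_mix[[e]])
  }
  dep_group <- group_deprivation(quintile)

  age_lo <- c(50, 55, 60, 65)
  age_hi <- c(55, 60, 65, 71)
  band <- sample(seq_along(config$age_mix), n, TRUE, config$age_mix)
  age_sympt <- age_lo[band] + stats::runif(n) * (age_hi[band] - age_lo[band])

  period_start <- as.Date(c("1989-04-01", "1995-01-01", "2001-01-01", "2007-01-01"))
  period_end <- as.Date(c("1994-12-31", "2000-12-31", "2006-12-31", "2011-03-31"))
  pb <- sample(seq_along(config$period_mix), n, TRUE, config$period_mix)
  span <- as.numeric(period_end[pb] - period_start[pb])
  sympt_date <- period_start[pb] + round(stats::runif(n) * span)

  birth_date <- sympt_date - round(age_sympt * 365.25)
  sojourn <- stats::rexp(n, rate = 1 / config$mst)
  onset_date <- sympt_date - sojourn * 365.25

  # screening invitations every `screening_interval` years from age 50,
  # anchored at the programme start for women already over 50 then
  anchor <- pmax(birth_date + ceiling(50 * 365.25), w$diagnosis_start)
  max_rounds <- ceiling(21 / config$screening_interval) + 1L
  detect_date <- rep(as.Date(NA), n)
  any_attended <- rep(FALSE, n)
  last_attended <- rep(NA, n)  # did she attend the most recent invitation?
  for (k in 0:max_rounds) {
    inv <- anchor + round(k * config$screening_interval * 365.25)
    age_at_inv <- as.numeric(inv - birth_date) / 365.25
    valid <- inv < sympt_date & age_at_inv <= 70
    att <- valid & stats::runif(n) < config$attendance_prob
    hit <- att & inv > onset_date & is.na(detect_date)
    detect_date[hit] <- inv[hit]
    any_attended <- any_attended | att
    last_attended[valid] <- att[valid]
  }
  screen <- !is.na(detect_date)
  status_cat <- ifelse(screen, "screen_detected",
                ifelse(!is.na(last_attended) & last_attended, "interval",
                ifelse(any_attended, "lapsed_attender", "non_attender")))
  to_other <- !screen & stats::runif(n) < config$p_other_unresolvable
  status_cat[to_other] <- "other_unresolvable"

  dx_date <- as.Date(ifelse(screen, detect_date, sympt_date),
                     origin = "1970-01-01")
  lead_time <- as.numeric(sympt_date - dx_date) / 365.25
  age_dx <- floor(as.numeric(dx_date - birth_date) / 365.25)

  lam_e <- unname(config$excess_hazard[dep_group]) *
    ifelse(screen, config$benefit_hr, 1)
  t_cancer <- ifelse(lam_e > 0, stats::rexp(n, rate = 1) / pmax(lam_e, 1e-300), Inf)
  cancer_death <- sympt_date + t_cancer * 365.25

  path_cohort <- data.frame(age_at_diagnosis = age_dx,
                            diagnosis_year = as.integer(format(dx_date, "%Y")),
                            ethnicity_group = ethnicity,
                            deprivation_group = dep_group)
  horizon <- max(60L, ceiling(110 - min(age_dx)))
  lam_bg <- hazard_paths(path_cohort, table, horizon)
  t_bg <- sample_piecewise_exponential(lam_bg)
  bg_death <- dx_date + ifelse(is.finite(t_bg), t_bg * 365.25, 1e7)

  death_date <- pmin(cancer_death, bg_death)
  dead <- death_date <= w$followup_end
  exit_date <- as.Date(pmin(as.numeric(death_date), as.numeric(w$followup_end)),
                       origin = "1970-01-01")

  extent <- rep(NA_character_, n)
  for (e in unique(ethnicity)) {
    idx <- ethnicity == e
    extent[idx] <- sample(c(EXTENT_LEVELS, NA), sum(idx), TRUE,
                          config$extent_mix[[e]])
  }
  behaviour <- ifelse(stats::runif(n) < config$p_in_situ, "in_situ", "invasive")
  recurrence <- stats::runif(n) < config$p_recurrence

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    diagnosis_date = dx_date,
    age_at_diagnosis = age_dx,
    exit_date = exit_date,
    vital_status = ifelse(dead, "D", "A"),
    ethnicity_group = ethnicity,
    deprivation_quintile = quintile,
    deprivation_group = dep_group,
    screening_status = status_cat,
    extent = extent,
    behaviour = behaviour,
    recurrence_flag = recurrence,
    continuously_eligible = TRUE,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(lambda_e = config$excess_hazard,
                          benefit_hr = config$benefit_hr,
                          lead_time = lead_time,
                          sojourn = sojourn,
                          screen_detected = screen,
                          seed = config$seed, config = config),
                     class = "synthetic_truth")
  structure(list(cohort = cohort, truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d women (%d screen-detected)\n",
              nrow(x$cohort),
              sum(x$cohort$screening_status == "screen_detected")))
  invisible(x)
}

#' True net survival of a simulated stratum
#'
#' The generator's ground truth: `NS*(t) = exp(-lambda_E * t)` for the
#' stratum's configured constant excess hazard.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param stratum A deprivation group name used in the configuration.
#' @param t Time(s) in years.
#' @return Numeric vector of true net-survival probabilities.
#' @export
truth_net_survival <- function(truth, stratum, t) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!stratum %in% names(truth$lambda_e))
    stop("unknown stratum: ", stratum)
  exp(-truth$lambda_e[[stratum]] * t)
}

#' Write a simulated cohort and its truth sidecar
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed). Writes `cohort.csv`,
#'   `truth_strata.csv` (stratum, lambda_e) and `truth_patients.csv`
#'   (patient_id, lead_time, screen_detected).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(data.frame(stratum = names(sim$truth$lambda_e),
                              lambda_e = unname(sim$truth$lambda_e)),
                   file.path(dir, "truth_strata.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = sim$cohort$patient_id,
                              lead_time = sim$truth$lead_time,
                              screen_detected = sim$truth$screen_detected),
                   file.path(dir, "truth_patients.csv"), row.names = FALSE)
  invisible(dir)
}
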