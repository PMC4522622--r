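# Shared fixtures and independent oracles for the test suite.

# Minimal cohort with explicit follow-up times (years) and event status,
# placed in a fixed stratum so any life table can serve it.
mk_cohort <- function(time, status, age = 60, year = 2000,
                      ethnicity = NA, deprivation = NA) {
  data.frame(time = time, status = status,
             age_at_diagnosis = age, diagnosis_year = year,
             ethnicity_group = ethnicity, deprivation_group = deprivation,
             stringsAsFactors = FALSE)
}

# Life table whose hazard depends on (age, year) through a supplied
# function, single unstratified stratum.
fn_life_table <- function(hfun, ages = 0:109, years = 1990:2020) {
  g <- expand.grid(age = ages, year = years, KEEP.OUT.ATTRS = FALSE)
  g$qx <- -expm1(-hfun(g$age, g$year))
  life_table(g)
}

# Brute-force expected survival: daily-step product of conditional
# survival along the patient's annual hazard path, with steps split at
# whole-year boundaries so the piecewise-constant hazard is integrated
# exactly.
oracle_expected_survival <- function(lam_path, t, step = 1 / 365.25) {
  if (t == 0) return(1)
  brk <- sort(unique(c(seq(0, t, by = step), t,
                       seq_len(ceiling(t)))))
  brk <- brk[brk > 0 & brk <= t + 1e-15]
  a <- 0
  logS <- 0
  for (b in brk) {
    k <- min(floor(a + 1e-12) + 1, length(lam_path))
    logS <- logS - lam_path[k] * (b - a)
    a <- b
  }
  exp(logS)
}

# Independent step-by-step evaluation of the weighted net-survival
# estimator at daily increments: per-patient weights 1/S_P updated
# multiplicatively, observed part as a product over deaths, population
# part accumulated with left-endpoint weighted sums.
oracle_pohar_perme <- function(time, status, lam, t_eval,
                               step = 1 / 365.25) {
  maxt <- max(t_eval)
  brk <- sort(unique(c(seq(0, maxt, by = step), time[time <= maxt], maxt,
                       seq_len(ceiling(maxt)), t_eval)))
  brk <- brk[brk > 0 & brk <= maxt + 1e-15]
  n <- length(time)
  E <- rep(1, n)
  a <- 0
  log_prod <- 0  # sum of log(1 - dLambda_O)
  lam2 <- 0
  out <- numeric(length(t_eval))
  for (b in brk) {
    k <- min(floor(a + 1e-12) + 1, ncol(lam))
    risk <- time >= b - 1e-12
    if (any(risk)) {
      num <- sum(E[risk] * lam[risk, k]) * (b - a)
      den <- sum(E[risk])
      lam2 <- lam2 + num / den
    }
    E <- E * exp(lam[, k] * (b - a))
    deaths <- which(abs(time - b) < 1e-12 & status == 1)
    if (length(deaths) && any(risk)) {
      dL <- sum(E[deaths]) / sum(E[risk])
      log_prod <- log_prod + log1p(-dL)
    }
    hit <- which(abs(t_eval - b) < 1e-9)
    if (length(hit)) out[hit] <- -(log_prod + lam2)
    a <- b
  }
  out  # cumulative excess hazard at t_eval
}

# Random small cohort for Kaplan-Meier equality checks (times kept above
# one day; ties induced by rounding).
random_km_cohort <- function(n) {
  mk_cohort(time = round(stats::rexp(n, 0.4), 1) + 0.05,
            status = stats::rbinom(n, 1, 0.6))
}

# Cached synthetic life-table system (built once per test run).
synthetic_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_life_tables()
    cache
  }
})
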