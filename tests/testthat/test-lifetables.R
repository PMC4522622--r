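base_one_stratum <- function(q, age = 60) {
  life_table(data.frame(age = age, year = 2001, qx = q,
                        ethnicity_group = "White",
                        deprivation_group = "less_deprived"))
}

test_that("interpolation is the identity at the base year and scales hazards elsewhere", {
  base <- base_one_stratum(0.010)
  h <- function(q) -log(1 - q)
  nat <- life_table(data.frame(age = 60, year = c(2001, 2012),
                               qx = c(0.02, -expm1(-0.8 * h(0.02)))))
  it <- interpolate_life_tables(base, nat, years = c(2001, 2012))
  d <- as.data.frame(it)
  expect_equal(d$qx[d$year == 2001], 0.010)  # exact identity
  # national hazard ratio 0.8 applied on the hazard scale, q recomputed
  expect_equal(d$qx[d$year == 2012], -expm1(-0.8 * h(0.010)), tolerance = 1e-12)
})

test_that("equal national hazards in all years reproduce the base table everywhere", {
  base <- life_table(data.frame(age = rep(50:70, 2), year = 2001,
                                ethnicity_group = rep(c("Asian", "Black"), each = 21),
                                deprivation_group = "less_deprived",
                                qx = rep(seq(0.004, 0.02, length.out = 21), 2)))
  nat <- life_table(expand.grid(age = 50:70, year = 1989:2012, qx = 0.015))
  it <- interpolate_life_tables(base, nat, years = 1989:2012)
  d <- as.data.frame(it)
  b <- as.data.frame(base)
  for (y in c(1989, 1995, 2007, 2012)) {
    sub <- d[d$year == y, ]
    merged <- merge(sub, b, by = c("age", "ethnicity_group", "deprivation_group"))
    expect_equal(merged$qx.x, merged$qx.y, tolerance = 1e-12)
  }
})

test_that("interpolation errors are raised for missing years and zero base hazards", {
  base <- base_one_stratum(0.01)
  nat <- life_table(data.frame(age = 60, year = c(2001, 2005), qx = c(0.02, 0.02)))
  expect_error(interpolate_life_tables(base, nat, years = 2001:2006), "missing year")
  nat0 <- life_table(data.frame(age = 60, year = c(2001, 2005), qx = c(0, 0.02)))
  expect_error(interpolate_life_tables(base, nat0, years = c(2001, 2005)),
               "zero national")
})

test_that("larger national hazards give uniformly smaller expected survival", {
  base <- base_one_stratum(0.02, age = 50:80)
  # national hazards equal in the base year; `hi` grows 1.5-fold afterwards
  mk_nat <- function(f) {
    g <- expand.grid(age = 50:80, year = 2001:2012)
    g$qx <- -expm1(-ifelse(g$year == 2001, 0.02, f * 0.02))
    life_table(g)
  }
  lo <- interpolate_life_tables(base, mk_nat(1.0), years = 2001:2012)
  hi <- interpolate_life_tables(base, mk_nat(1.5), years = 2001:2012)
  p <- list(age_at_diagnosis = 60, diagnosis_year = 2002,
            ethnicity_group = "White", deprivation_group = "less_deprived")
  t <- c(1, 3, 7)
  expect_true(all(expected_survival(p, t, hi) < expected_survival(p, t, lo)))
})

test_that("expected survival matches closed forms", {
  p <- list(age_at_diagnosis = 60, diagnosis_year = 2000,
            ethnicity_group = NA, deprivation_group = NA)
  expect_equal(expected_survival(p, c(0, 1, 5, 10), flat_life_table(0)),
               rep(1, 4))
  expect_equal(expected_survival(p, 5, flat_life_table(0.1)), exp(-0.5),
               tolerance = 1e-12)
  # hazard 0.1 in the first year since diagnosis, 0.2 in the second
  lt <- fn_life_table(function(age, year) ifelse(year <= 2000, 0.1, 0.2))
  expect_equal(expected_survival(p, 2, lt), exp(-0.3), tolerance = 1e-12)
  expect_equal(expected_survival(p, 2, lt),
               oracle_expected_survival(c(0.1, 0.2), 2), tolerance = 1e-8)
})

test_that("expected survival agrees with a daily-step product oracle on random paths", {
  set.seed(7)
  lt <- fn_life_table(function(age, year) {
    3e-5 * exp(0.09 * age) * (1 + 0.2 * sin(year / 3))
  })
  for (i in 1:100) {
    p <- list(age_at_diagnosis = sample(50:70, 1),
              diagnosis_year = sample(1990:2011, 1),
              ethnicity_group = NA, deprivation_group = NA)
    t <- stats::runif(1, 0, 20)
    lam <- hazard_paths(as.data.frame(p), lt, ceiling(t) + 1)[1, ]
    expect_equal(expected_survival(p, t, lt),
                 oracle_expected_survival(lam, t), tolerance = 1e-8)
  }
})

test_that("ages beyond the table use the terminal band; missing strata are errors", {
  lt <- flat_life_table(0.1, ages = 0:99)
  p <- list(age_at_diagnosis = 95, diagnosis_year = 2000,
            ethnicity_group = NA, deprivation_group = NA)
  expect_equal(expected_survival(p, 10, lt), exp(-1), tolerance = 1e-12)
  lt_s <- flat_life_table(0.1, stratified = TRUE)
  p2 <- list(age_at_diagnosis = 60, diagnosis_year = 2000,
             ethnicity_group = "Martian", deprivation_group = "less_deprived")
  expect_error(expected_survival(p2, 5, lt_s), "stratum")
})

test_that("life expectancy under a constant hazard matches its closed form", {
  lam <- 0.2
  lt <- flat_life_table(lam, ages = 0:109)
  # sum over annual intervals: (1/lam) * (1 - exp(-lam * K)) with K years to max_age
  e <- life_expectancy(60, 2000, "all", lt, max_age = 110)
  expect_equal(e, (1 - exp(-lam * 50)) / lam, tolerance = 1e-10)
})

test_that("life tables reject invalid probabilities and gaps", {
  expect_error(life_table(data.frame(age = 60, year = 2001, qx = 1.2)), "qx")
  expect_error(life_table(data.frame(age = c(60, 62), year = 2001,
                                     qx = c(0.1, 0.1))), "contiguous")
  expect_error(life_table(data.frame(age = c(60, 60, 61), year = c(2001, 2002, 2001),
                                     qx = 0.1)), "missing")
})

test_that("life tables round-trip through CSV", {
  lt <- synthetic_tables()$base
  f <- tempfile(fileext = ".csv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(lt2$qx, lt$qx, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(lt2$strata, lt$strata)
})
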