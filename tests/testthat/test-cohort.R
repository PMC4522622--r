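test_that("ethnicity resolution follows the count / recency / alphanumeric hierarchy", {
  obs <- function(codes, dates) data.frame(code = codes, record_date = as.Date(dates))
  expect_equal(resolve_ethnicity(obs(c("A", "A", "B"),
                                     c("2001-01-01", "2003-01-01", "2002-01-01"))), "A")
  expect_equal(resolve_ethnicity(obs("A", "2001-01-01")), "A")
  expect_equal(resolve_ethnicity(obs(c("A", "B"), c("2001-01-01", "2003-01-01"))), "B")
  expect_equal(resolve_ethnicity(obs(c("A", "B"), c("2001-01-01", "2001-01-01"))), "A")
  expect_equal(resolve_ethnicity(obs(c("b", "A"), c("2001-01-01", "2001-01-01"))), "A")
  expect_error(resolve_ethnicity(data.frame(code = character(),
                                            record_date = as.Date(character()))),
               "no ethnicity")
  expect_error(resolve_ethnicity(obs(c("A", ""), c("2001-01-01", "2002-01-01"))),
               "non-empty")
})

test_that("ethnicity resolution is invariant to the order of observations", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    o <- data.frame(code = sample(LETTERS[1:3], k, replace = TRUE),
                    record_date = as.Date("2000-01-01") + sample(0:2000, k))
    ref <- resolve_ethnicity(o)
    perm <- o[sample(k), ]
    expect_identical(resolve_ethnicity(perm), ref)
  }
})

test_that("ethnicity grouping sends mixed minority heritage to the minority group", {
  expect_equal(group_ethnicity("White British"), "White")
  expect_equal(group_ethnicity("Mixed White and Black Caribbean"), "Black")
  expect_equal(group_ethnicity("Mixed White and Asian"), "Asian")
  expect_equal(group_ethnicity("Any other ethnic group"), "White")
  expect_equal(group_ethnicity("Any other Mixed background"), "White")
  expect_equal(group_ethnicity(c("Indian", "Black African")), c("Asian", "Black"))
  expect_error(group_ethnicity("Martian"), "Martian")
})

test_that("extent of disease derivation checks metastases, then regional spread, then confinement", {
  expect_equal(classify_extent(FALSE, FALSE, TRUE), "distant")
  expect_equal(classify_extent(FALSE, TRUE, FALSE), "regional")
  expect_equal(classify_extent(TRUE, FALSE, FALSE), "localised")
  # missing information propagates: cannot rule out a worse category
  expect_true(is.na(classify_extent(TRUE, FALSE, NA)))
  expect_true(is.na(classify_extent(NA, NA, FALSE)))
  expect_equal(classify_extent(c(TRUE, NA), c(FALSE, TRUE), c(FALSE, FALSE)),
               c("localised", "regional"))
})

test_that("deprivation quintiles collapse to two groups, totally and surjectively", {
  expect_equal(group_deprivation(1:5),
               c("less_deprived", "less_deprived", "middle_more_deprived",
                 "middle_more_deprived", "middle_more_deprived"))
  expect_true(is.na(group_deprivation(NA)))
  expect_error(group_deprivation(6), "quintile")
  expect_setequal(unique(group_deprivation(1:5)),
                  c("less_deprived", "middle_more_deprived"))
})

test_that("cohort selection keeps invasive non-recurrent primaries aged 50-70 in window", {
  rec <- function(age, dx, behaviour = "invasive", recur = FALSE, exit = "2012-01-01") {
    data.frame(diagnosis_date = dx, exit_date = exit, age_at_diagnosis = age,
               behaviour = behaviour, recurrence_flag = recur,
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec(55, "1995-06-01"),               # included
    rec(49, "1995-06-01"),               # age boundary: excluded
    rec(50, "1995-06-01"),               # boundary: included
    rec(70, "2010-06-01"),               # boundary: included
    rec(71, "2010-06-01"),               # excluded
    rec(60, "1995-06-01", recur = TRUE), # recurrence
    rec(60, "1995-06-01", behaviour = "in_situ"),
    rec(60, "1989-03-31"),               # day before window opens
    rec(60, "2011-04-01"),               # after window closes
    rec(60, "not-a-date"),               # malformed
    rec(60, "1995-06-01", exit = "1994-01-01")  # exit precedes diagnosis
  )
  sel <- select_cohort(records, study_window())
  expect_s3_class(sel, "cohort_selection")
  expect_equal(nrow(sel$included) + nrow(sel$excluded), nrow(records))
  expect_equal(nrow(sel$included), 3)
  expect_equal(unname(sel$log[c("age_outside_50_70", "recurrence", "not_invasive",
                                "outside_diagnosis_window", "malformed_date",
                                "exit_before_diagnosis")]),
               c(2L, 1L, 1L, 2L, 1L, 1L))
})

test_that("selection partitions any simulated cohort", {
  lt <- synthetic_tables()$interpolated
  sim <- simulate_cohort(simulation_config(n_patients = 500, seed = 3), lt)
  sel <- select_cohort(sim$cohort)
  expect_equal(nrow(sel$included) + nrow(sel$excluded), 500)
  expect_true(all(sel$included$age_at_diagnosis >= 50 &
                    sel$included$age_at_diagnosis <= 70))
  expect_false(any(sel$included$recurrence_flag))
})
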