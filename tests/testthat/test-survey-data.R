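test_that("survey tables round-trip through CSV field-for-field", {
  ev <- toy_events(c("E1", "E2", "E3"), c(1, 3, 5))
  ev$age_guess[2] <- 25L
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(ev, path, "contact")
  back <- read_survey_table(path, "contact")
  expect_equal(as.data.frame(back), as.data.frame(ev))

  pp <- toy_participants()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(pp, path2, "participant")
  expect_equal(as.data.frame(read_survey_table(path2, "participant")),
               as.data.frame(pp))
})

test_that("readers enforce schema and row-level invariants", {
  ev <- toy_events(c("E1", "E2", "E3"), c(1, 0, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ev, path, na = "")
  expect_error(read_survey_table(path, "contact"), "group_size.*2")

  ev_ok <- toy_events("E1", 2)
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ev_ok[setdiff(names(ev_ok), "setting")], path3, na = "")
  expect_error(read_survey_table(path3, "contact"), "missing column.*setting")

  bad_level <- toy_events("E1", 2)
  bad_level$setting <- "park"
  expect_error(validate_survey_table(bad_level, "contact"), "setting")
})

test_that("triangle responses must reference known contact events", {
  ev <- toy_events(c("E1", "E2"), c(1, 1))
  resp <- toy_responses("E1", "E9")
  expect_error(check_triangle_references(resp, ev),
               "Referential-integrity")
  expect_silent(check_triangle_references(toy_responses("E1", "E2"), ev))
})

test_that("participant age grouping matches the instrument bands", {
  expect_equal(derive_participant_age_group(14), "2-15")
  expect_equal(derive_participant_age_group(76), "76+")
  expect_equal(derive_participant_age_group(NA), "unknown")
  expect_error(derive_participant_age_group(1), "age_years < 2")
  # partition: every valid age maps to exactly one non-unknown level
  ages <- 2:100
  groups <- derive_participant_age_group(ages)
  expect_true(all(groups %in% setdiff(survey_levels("age_group"),
                                      "unknown")))
  expect_equal(derive_participant_age_group(c(15, 16, 25, 26, 75)),
               c("2-15", "16-25", "16-25", "26-35", "66-75"))
})

test_that("contact age category prefers the reported category over the guess", {
  expect_equal(derive_contact_age_category("20-39", 58L), "20-39")
  expect_equal(derive_contact_age_category(NA, 12L), "5-19")
  expect_equal(derive_contact_age_category(NA, NA), "unknown")
  expect_equal(derive_contact_age_category(NA, c(4L, 5L, 19L, 20L, 64L, 65L)),
               c("0-4", "5-19", "5-19", "20-39", "40-64", "65+"))
  expect_error(derive_contact_age_category(NA, -3L), "Negative age_guess")
})

test_that("occupation classing covers the documented cases", {
  expect_equal(derive_occupation_class(c("retired", "unemployed", "student",
                                         "employed", NA, "astronaut")),
               c("other", "other", "student", "employed", "unknown",
                 "unknown"))
})

test_that("total reported contacts sums group sizes, counting repeats once", {
  expect_equal(total_reported_contacts(toy_events(c("a", "b", "c"),
                                                  c(1, 3, 5))), 9L)
  ev <- toy_events(c("a", "b", "c"), c(1, 1, 4))
  ev$repeat_flag[2] <- TRUE
  expect_equal(total_reported_contacts(ev), 5L)
  expect_equal(total_reported_contacts(toy_events(character(0),
                                                  integer(0))), 0L)
  # order invariance; equals plain sum without repeat flags
  for (seed in 1:5) {
    set.seed(seed)
    sizes <- sample(1:20, 8, replace = TRUE)
    ev <- toy_events(paste0("e", 1:8), sizes)
    perm <- sample(8)
    expect_equal(total_reported_contacts(ev[perm, ]), sum(sizes))
  }
})

test_that("weekly contact minutes multiply the configured midpoints", {
  expect_equal(weekly_contact_minutes("1-3/wk", "10-59 min"), 69)
  expect_equal(weekly_contact_minutes("4+/wk", "<10 min"), 25)
  expect_equal(weekly_contact_minutes("<1/wk", "60+ min"), 45)
  expect_error(weekly_contact_minutes("sometimes", "60+ min"), "Unknown")
  custom <- midpoint_config(frequency = c("<1/wk" = 0.25, "1-3/wk" = 2,
                                          "4+/wk" = 7))
  expect_equal(weekly_contact_minutes("<1/wk", "<10 min", custom), 1.25)
})

test_that("certainty dichotomisation is monotone in cutoff leniency", {
  expect_true(dichotomize_certainty("probably yes", "probably-yes"))
  expect_false(dichotomize_certainty("probably yes", "yes-only"))
  expect_false(dichotomize_certainty("no", "probably-no"))
  lvls <- survey_levels("certainty")
  yes_only <- dichotomize_certainty(lvls, "yes-only")
  prob_yes <- dichotomize_certainty(lvls, "probably-yes")
  prob_no <- dichotomize_certainty(lvls, "probably-no")
  expect_true(all(yes_only <= prob_yes))
  expect_true(all(prob_yes <= prob_no))
  expect_error(dichotomize_certainty("maybe"), "Unknown certainty")
})

test_that("log10 density transforms and rejects non-positive input", {
  expect_equal(log10_density(100), 2)
  expect_equal(log10_density(1), 0)
  expect_error(log10_density(0), "Non-positive")
})
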