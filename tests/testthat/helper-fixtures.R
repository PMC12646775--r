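# Shared fixtures: small hand-built survey tables and simulation
# configurations used across the test files.

toy_participants <- function() {
  tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    household_id = c("H1", "H1", "H1"),
    visit = c(2L, 3L, 2L),
    age_years = c(30L, 30L, 70L),
    sex = c("male", "male", "female"),
    occupation_raw = c("employed", "employed", "retired")
  )
}

toy_households <- function() {
  tibble::tibble(
    household_id = "H1", location_id = "L1",
    household_size = 3L, density_at_first_visit = 450
  )
}

toy_events <- function(ids, sizes, participant = "P1", visit = 2L,
                       setting = "social", repeat_flag = FALSE) {
  n <- length(ids)
  tibble::tibble(
    event_id = ids, participant_id = participant, visit = visit,
    group_size = as.integer(sizes),
    contact_age_category = "20-39", age_guess = NA_integer_,
    setting = rep_len(setting, n), touch = "no", frequency = "4+/wk",
    duration = "60+ min", repeat_flag = rep_len(repeat_flag, n)
  )
}

toy_responses <- function(primaries, secondaries, certainty = "yes",
                          participant = "P1", visit = 2L) {
  tibble::tibble(
    participant_id = participant, visit = visit,
    primary_event_id = primaries, secondary_event_id = secondaries,
    certainty = rep_len(certainty, length(primaries))
  )
}

# Small synthetic survey for integration-style tests.
small_config <- function(...) {
  synth_config(n_locations = 4, households_per_location = 6, visits = 2:3,
               ...)
}

# The parameter-recovery benchmark: about 800 participants over two
# analysed visits (~1600 participant-visits) yielding on the order of
# 20,000 potential triangles, with small event groups so diaries carry
# many events.
recovery_config <- function(...) {
  synth_config(n_locations = 20, households_per_location = 16,
               visits = 2:3, group_size_mu = 0.5, ...)
}

# A truth list with every coefficient zero except those supplied, built on
# the default truth structure.
zeroed_truth <- function(base, ..., sigma = NULL) {
  over <- list(...)
  base$beta[] <- 0
  for (nm in names(over)) base$beta[[nm]] <- over[[nm]]
  base$visit[] <- 0
  if (!is.null(sigma)) base$sigma[] <- sigma
  base
}
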