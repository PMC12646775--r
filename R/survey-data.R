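#' @importFrom rlang abort warn .data
#' @importFrom stats median quantile rnorm runif rbinom rpois sd var setNames
#' @importFrom utils head
NULL

# Column schemas for the four survey tables. `required` columns must be
# present; readers coerce types and validators enforce row-level invariants.
et_schemas <- list(
  participant = list(
    required = c("participant_id", "household_id", "visit", "age_years",
                 "sex", "occupation_raw"),
    types = c(participant_id = "c", household_id = "c", visit = "i",
              age_years = "i", sex = "c", occupation_raw = "c")
  ),
  household = list(
    required = c("household_id", "location_id", "household_size",
                 "density_at_first_visit"),
    types = c(household_id = "c", location_id = "c", household_size = "i",
              density_at_first_visit = "d")
  ),
  contact = list(
    required = c("event_id", "participant_id", "visit", "group_size",
                 "contact_age_category", "age_guess", "setting", "touch",
                 "frequency", "duration", "repeat_flag"),
    types = c(event_id = "c", participant_id = "c", visit = "i",
              group_size = "i", contact_age_category = "c", age_guess = "i",
              setting = "c", touch = "c", frequency = "c", duration = "c",
              repeat_flag = "l")
  ),
  triangle = list(
    required = c("participant_id", "visit", "primary_event_id",
                 "secondary_event_id", "certainty"),
    types = c(participant_id = "c", visit = "i", primary_event_id = "c",
              secondary_event_id = "c", certainty = "c")
  )
)

et_check_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% names(et_schemas)) {
    abort("`kind` must be one of \"participant\", \"household\", \"contact\", \"triangle\".")
  }
  kind
}

#' Read a survey table from CSV
#'
#' Reads one of the four survey tables (participant, household, contact or
#' triangle responses) from a comma-separated file with a header row, coerces
#' columns to their documented types and validates every row-level invariant
#' (positive group sizes, recognised category levels, ages of at least 2
#' years, and so on). Empty strings are treated as missing.
#'
#' @param path Path to a CSV file.
#' @param kind One of `"participant"`, `"household"`, `"contact"`,
#'   `"triangle"`.
#' @return A validated tibble with the documented columns.
#' @seealso [write_survey_table()], [validate_survey_table()]
#' @export
read_survey_table <- function(path, kind) {
  et_check_kind(kind)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  schema <- et_schemas[[kind]]
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(schema$required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema error in ", kind, " table: missing column(s) ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x <- x[schema$required]
  for (col in names(schema$types)) {
    x[[col]] <- switch(schema$types[[col]],
      c = as.character(x[[col]]),
      i = et_parse_int(x[[col]], col),
      d = et_parse_dbl(x[[col]], col),
      l = et_parse_lgl(x[[col]], col)
    )
  }
  validate_survey_table(x, kind)
}

et_parse_int <- function(v, col) {
  out <- suppressWarnings(as.integer(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    abort(paste0("Column '", col, "' is not integer at row(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  out
}

et_parse_dbl <- function(v, col) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    abort(paste0("Column '", col, "' is not numeric at row(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  out
}

et_parse_lgl <- function(v, col) {
  if (is.logical(v)) return(v)
  low <- tolower(as.character(v))
  out <- ifelse(low %in% c("true", "t", "1", "yes"), TRUE,
         ifelse(low %in% c("false", "f", "0", "no"), FALSE, NA))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    abort(paste0("Column '", col, "' is not logical at row(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  out
}

#' Write a survey table to CSV
#'
#' Inverse of [read_survey_table()]: writes the documented columns as
#' comma-separated UTF-8 with a header row, encoding missing values as empty
#' strings, so that a read/write round trip reproduces the table
#' field-for-field.
#'
#' @param x A survey table (tibble or data frame).
#' @param path Output file path.
#' @param kind One of `"participant"`, `"household"`, `"contact"`,
#'   `"triangle"`.
#' @return `x`, invisibly.
#' @export
write_survey_table <- function(x, path, kind) {
  et_check_kind(kind)
  x <- validate_survey_table(x, kind)
  readr::write_csv(x[et_schemas[[kind]]$required], path, na = "")
  invisible(x)
}

et_bad_rows <- function(cond) which(!is.na(cond) & cond)

#' Validate a survey table against its row-level invariants
#'
#' Checks the invariants of the given table kind: positive group sizes and
#' household sizes, positive population density, participant ages of at
#' least 2 years, categorical fields restricted to their documented levels,
#' analysed visits in 2--5, and distinct primary/secondary events in
#' triangle responses. Violations are reported with their row numbers.
#'
#' @inheritParams write_survey_table
#' @return The validated tibble (invisibly usable in a pipe).
#' @export
validate_survey_table <- function(x, kind) {
  et_check_kind(kind)
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(et_schemas[[kind]]$required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema error in ", kind, " table: missing column(s) ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " at row(s) ",
                                      paste(head(rows, 10), collapse = ", "),
                                      if (length(rows) > 10) ", ..." else ""))
    }
  }
  check_levels <- function(col, levels) {
    note(et_bad_rows(!x[[col]] %in% levels & !is.na(x[[col]])),
         paste0("'", col, "' outside {", paste(levels, collapse = ", "), "}"))
  }
  if (kind == "participant") {
    note(et_bad_rows(x$age_years < 2), "age_years < 2")
    check_levels("sex", et_levels$sex)
    note(et_bad_rows(!x$visit %in% et_levels$visit), "visit outside 2-5")
    note(et_bad_rows(is.na(x$participant_id)), "missing participant_id")
    dup <- duplicated(x[c("participant_id", "visit")])
    note(which(dup), "duplicated (participant_id, visit)")
  } else if (kind == "household") {
    note(et_bad_rows(x$household_size < 1), "household_size < 1")
    note(et_bad_rows(x$density_at_first_visit <= 0),
         "density_at_first_visit <= 0")
    note(which(duplicated(x$household_id)), "duplicated household_id")
  } else if (kind == "contact") {
    note(et_bad_rows(x$group_size < 1), "group_size < 1")
    note(et_bad_rows(x$age_guess < 0), "negative age_guess")
    check_levels("contact_age_category", et_levels$contact_age)
    check_levels("setting", et_levels$setting)
    check_levels("touch", et_levels$touch)
    check_levels("frequency", et_levels$frequency)
    check_levels("duration", et_levels$duration)
    note(et_bad_rows(is.na(x$event_id)), "missing event_id")
    note(which(duplicated(x$event_id)), "duplicated event_id")
  } else if (kind == "triangle") {
    check_levels("certainty", et_levels$certainty)
    note(et_bad_rows(x$primary_event_id == x$secondary_event_id),
         "primary_event_id equals secondary_event_id")
  }
  if (length(problems) > 0) {
    abort(paste0("Validation error in ", kind, " table:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  x
}

#' Check that triangle responses reference known contact events
#'
#' Verifies referential integrity between a triangle-response table and a
#' contact table: both events of each response must exist and belong to the
#' same participant-visit as the response.
#'
#' @param triangles A triangle-response table.
#' @param contacts A contact-event table.
#' @return `triangles`, invisibly, if all references resolve.
#' @export
check_triangle_references <- function(triangles, contacts) {
  key <- paste(contacts$event_id, contacts$participant_id, contacts$visit)
  bad_primary <- which(!paste(triangles$primary_event_id,
                              triangles$participant_id,
                              triangles$visit) %in% key)
  bad_secondary <- which(!paste(triangles$secondary_event_id,
                                triangles$participant_id,
                                triangles$visit) %in% key)
  bad <- sort(unique(c(bad_primary, bad_secondary)))
  if (length(bad) > 0) {
    abort(paste0("Referential-integrity error: triangle row(s) ",
                 paste(head(bad, 10), collapse = ", "),
                 " reference contact events not found for that",
                 " participant-visit."))
  }
  invisible(triangles)
}

#' Assign participants to analysis age groups
#'
#' Children aged 2--15 form one group, adults aged 16--75 fall into 10-year
#' bands, and ages 76 and over are grouped together. Missing ages map to
#' `"unknown"`.
#'
#' @param age_years Integer vector of ages in years (`NA` allowed); ages
#'   below 2 are a domain error.
#' @return Character vector of age-group levels (see
#'   `survey_levels("age_group")`).
#' @export
#' @examples
#' derive_participant_age_group(c(14, 16, 76, NA))
derive_participant_age_group <- function(age_years) {
  age_years <- as.numeric(age_years)
  bad <- which(!is.na(age_years) & age_years < 2)
  if (length(bad) > 0) {
    abort(paste0("age_years < 2 at position(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  breaks <- c(2, 16, 26, 36, 46, 56, 66, 76, Inf)
  labels <- c("2-15", "16-25", "26-35", "36-45", "46-55", "56-65", "66-75",
              "76+")
  out <- as.character(cut(age_years, breaks = breaks, labels = labels,
                          right = FALSE))
  out[is.na(age_years)] <- "unknown"
  out
}

#' Resolve the age category of a contact
#'
#' The reported age category is used when present; otherwise an exact age
#' guess, when available, is binned into the five contact age bands (0--4,
#' 5--19, 20--39, 40--64, 65+). With neither response the category is
#' `"unknown"`.
#'
#' @param category Reported category (levels of
#'   `survey_levels("contact_age")`) or `NA`.
#' @param age_guess Optional integer age guess (`NA` allowed); negative
#'   guesses are a domain error.
#' @return Character vector of contact age categories.
#' @export
#' @examples
#' derive_contact_age_category(c("20-39", NA, NA), c(58L, 12L, NA))
derive_contact_age_category <- function(category, age_guess) {
  n <- max(length(category), length(age_guess))
  category <- rep_len(as.character(category), n)
  age_guess <- rep_len(as.numeric(age_guess), n)
  bad <- which(!is.na(age_guess) & age_guess < 0)
  if (length(bad) > 0) {
    abort(paste0("Negative age_guess at position(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  binned <- as.character(cut(age_guess, breaks = c(0, 5, 20, 40, 65, Inf),
                             labels = c("0-4", "5-19", "20-39", "40-64",
                                        "65+"),
                             right = FALSE))
  out <- ifelse(!is.na(category) & category != "unknown", category, binned)
  out[is.na(out)] <- "unknown"
  out
}

#' Classify free-text occupation into analysis classes
#'
#' Occupation status is analysed as employed, student or other, where
#' "other" covers children not in school, the unemployed and the retired.
#' Unrecognised or missing responses map to `"unknown"`.
#'
#' @param occupation_raw Character vector of raw occupation responses.
#' @return Character vector over
#'   `c("employed", "student", "other", "unknown")`.
#' @export
derive_occupation_class <- function(occupation_raw) {
  low <- tolower(trimws(as.character(occupation_raw)))
  out <- rep("unknown", length(low))
  out[low %in% c("employed", "worker", "farmer", "self-employed")] <- "employed"
  out[low %in% c("student", "pupil")] <- "student"
  out[low %in% c("other", "retired", "unemployed", "homemaker",
                 "child not in school", "preschool")] <- "other"
  out
}

#' Total reported contacts for one participant-visit
#'
#' The total number of people a participant reports having met is the sum of
#' the group sizes of their contact events. Events flagged as repeats
#' re-list individuals already counted in another event and therefore
#' contribute nothing to the total.
#'
#' @param events Contact-event tibble for a single participant-visit (may be
#'   empty).
#' @return A single non-negative integer.
#' @export
#' @examples
#' ev <- tibble::tibble(group_size = c(1L, 1L, 4L),
#'                      repeat_flag = c(FALSE, TRUE, FALSE))
#' total_reported_contacts(ev)  # 5
total_reported_contacts <- function(events) {
  if (nrow(events) == 0) return(0L)
  if (all(c("participant_id", "visit") %in% names(events)) &&
      length(unique(paste(events$participant_id, events$visit))) > 1) {
    abort("`events` must belong to a single participant-visit.")
  }
  keep <- !isTRUE_vec(events$repeat_flag)
  as.integer(sum(events$group_size[keep]))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Default intimacy midpoints
#'
#' Weekly time spent with a contact is computed as the product of the
#' midpoints of the reported frequency and duration categories. The closed
#' bins use their arithmetic midpoints; the open bins are closed at a
#' plausible cap: under once per week counts as 0.5 meetings/week, four or
#' more as 5/week, under 10 minutes as 5 minutes and an hour or more as 90
#' minutes.
#'
#' @param frequency Named numeric vector of meetings per week, one per
#'   frequency level.
#' @param duration Named numeric vector of minutes, one per duration level.
#' @return A `midpoint_config` list with `frequency` and `duration` entries.
#' @export
midpoint_config <- function(frequency = c("<1/wk" = 0.5, "1-3/wk" = 2,
                                          "4+/wk" = 5),
                            duration = c("<10 min" = 5, "10-59 min" = 34.5,
                                         "60+ min" = 90)) {
  stopifnot(setequal(names(frequency), et_levels$frequency),
            setequal(names(duration), et_levels$duration),
            all(frequency > 0), all(duration > 0))
  structure(list(frequency = frequency, duration = duration),
            class = "midpoint_config")
}

#' Weekly contact minutes (intimacy)
#'
#' Converts the categorical frequency and duration responses into an
#' intimacy measure: minutes per week spent with the contact, as frequency
#' midpoint (times/week) times duration midpoint (minutes).
#'
#' @param frequency Character vector of frequency levels.
#' @param duration Character vector of duration levels.
#' @param midpoints A [midpoint_config()].
#' @return Numeric vector of minutes per week.
#' @export
#' @examples
#' weekly_contact_minutes("1-3/wk", "10-59 min")  # 69
weekly_contact_minutes <- function(frequency, duration,
                                   midpoints = midpoint_config()) {
  bad_f <- which(!frequency %in% et_levels$frequency)
  bad_d <- which(!duration %in% et_levels$duration)
  if (length(bad_f) > 0 || length(bad_d) > 0) {
    abort("Unknown frequency or duration level; levels must be known to compute intimacy.")
  }
  unname(midpoints$frequency[frequency] * midpoints$duration[duration])
}

#' Dichotomise a triangle certainty response
#'
#' The four-level certainty response ("yes", "probably yes", "probably no",
#' "no") is reduced to a connected/not-connected indicator. The main
#' analysis counts "yes" and "probably yes" as affirmative
#' (`cutoff = "probably-yes"`); the stricter `"yes-only"` and more lenient
#' `"probably-no"` cutoffs implement the sensitivity analyses.
#'
#' @param certainty Character vector of certainty levels.
#' @param cutoff `"probably-yes"` (default), `"yes-only"` or
#'   `"probably-no"`.
#' @return Logical vector: `TRUE` if the response is at or above the cutoff.
#' @export
#' @examples
#' dichotomize_certainty("probably yes", "yes-only")     # FALSE
#' dichotomize_certainty("probably yes", "probably-yes") # TRUE
dichotomize_certainty <- function(certainty,
                                  cutoff = c("probably-yes", "yes-only",
                                             "probably-no")) {
  cutoff <- match.arg(cutoff)
  bad <- which(!certainty %in% et_levels$certainty & !is.na(certainty))
  if (length(bad) > 0) {
    abort(paste0("Unknown certainty level at position(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  affirmative <- switch(cutoff,
    "yes-only"     = "yes",
    "probably-yes" = c("yes", "probably yes"),
    "probably-no"  = c("yes", "probably yes", "probably no")
  )
  certainty %in% affirmative
}

#' Base-10 log population density
#'
#' Population density enters the regression models on the log10 scale so
#' that effects are reported per 10-fold increase in density. Density is
#' fixed at its value at the first analysed visit and attached at the
#' household level.
#'
#' @param density Numeric vector of people per square kilometre (> 0).
#' @return `log10(density)`.
#' @export
log10_density <- function(density) {
  bad <- which(!is.na(density) & density <= 0)
  if (length(bad) > 0) {
    abort(paste0("Non-positive density at position(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  log10(density)
}
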