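# Descriptive reporting: stratified characteristic tables, daily-contact
# summaries and contact decompositions, plus pooling helpers for per-visit
# triangle summaries.

#' Band a group size
#'
#' Standard reporting bands for event group sizes: 1, 2--5, 6--10, 11--20,
#' 21+.
#'
#' @param group_size Integer vector of group sizes (>= 1).
#' @return Character vector of bands.
#' @export
group_size_band <- function(group_size) {
  as.character(cut(group_size, breaks = c(1, 2, 6, 11, 21, Inf),
                   labels = et_levels$group_band, right = FALSE))
}

#' Percentages for a count table
#'
#' Adds column percentages (in percent, 0--100) to a `level`/`n` count
#' table; within each grouping the percentages sum to 100 up to rounding.
#'
#' @param counts Tibble with a count column `n` (grouping columns are
#'   respected).
#' @return The table with a `pct` column.
#' @export
count_percentages <- function(counts) {
  dplyr::mutate(counts, pct = 100 * .data$n / sum(.data$n))
}

#' Characteristics of reported contacts by participant age group
#'
#' Tabulates total reported contacts (each event weighted by its group
#' size; repeat-flagged events excluded) by group-size band, contact age
#' category, setting, touch, frequency and duration, stratified by
#' participant age group, with column percentages. The `"total"` stratum
#' pools all participants.
#'
#' @param contacts Contact-event tibble.
#' @param participants Participant tibble.
#' @return A tidy tibble with `characteristic`, `level`, `age_group`, `n`,
#'   `pct`.
#' @export
contact_characteristics_table <- function(contacts, participants) {
  ev <- contacts[!isTRUE_vec(contacts$repeat_flag), ]
  ev <- ev |>
    dplyr::left_join(
      dplyr::select(participants, "participant_id", "visit", "age_years"),
      by = c("participant_id", "visit")
    ) |>
    dplyr::mutate(
      age_group = derive_participant_age_group(.data$age_years),
      group_band = group_size_band(.data$group_size),
      contact_age = derive_contact_age_category(.data$contact_age_category,
                                                .data$age_guess),
      touch = dplyr::coalesce(.data$touch, "unknown"),
      frequency = dplyr::coalesce(.data$frequency, "unknown"),
      duration = dplyr::coalesce(.data$duration, "unknown")
    )
  characteristics <- c(group_band = "group_band",
                       contact_age = "contact_age", setting = "setting",
                       touch = "touch", frequency = "frequency",
                       duration = "duration")
  one_stratum <- function(ev_s, label) {
    purrr::map_dfr(names(characteristics), function(ch) {
      ev_s |>
        dplyr::count(level = .data[[characteristics[[ch]]]],
                     wt = .data$group_size) |>
        count_percentages() |>
        dplyr::mutate(characteristic = ch, age_group = label,
                      .before = 1)
    })
  }
  dplyr::bind_rows(
    one_stratum(ev, "total"),
    purrr::map_dfr(sort(unique(ev$age_group)),
                   function(g) one_stratum(ev[ev$age_group == g, ], g))
  )
}

#' Summary of daily reported contacts by participant strata
#'
#' Median, interquartile range and mean of the per-visit total (or
#' extra-household) contact counts, stratified by age group, sex,
#' occupation, household size and population density band.
#'
#' @inheritParams build_count_design
#' @return A tibble with `stratifier`, `stratum`, `n`, `median`, `q25`,
#'   `q75`, `mean`.
#' @export
daily_contact_summary <- function(participants, households, diaries,
                                  outcome = c("all", "extra-household")) {
  design <- suppressMessages(
    build_count_design(participants, households, diaries, outcome)
  )
  design <- design |>
    dplyr::mutate(
      density_band = as.character(cut(.data$density,
                                      breaks = c(0, 100, 500, 5000, Inf),
                                      labels = c("<=100", "101-500",
                                                 "501-5000", "5000+"))),
      household_size_band = as.character(cut(.data$household_size,
                                             breaks = c(1, 3, 5, Inf),
                                             labels = c("1-2", "3-4", "5+"),
                                             right = FALSE))
    )
  strat <- c("age_group", "sex", "occupation", "household_size_band",
             "density_band")
  purrr::map_dfr(strat, function(sv) {
    design |>
      dplyr::group_by(stratum = .data[[sv]]) |>
      dplyr::summarise(n = dplyr::n(), median = median(.data$y),
                       q25 = quantile(.data$y, 0.25, names = FALSE),
                       q75 = quantile(.data$y, 0.75, names = FALSE),
                       mean = mean(.data$y), .groups = "drop") |>
      dplyr::mutate(stratifier = sv, .before = 1)
  })
}

#' Decomposition of total contacts by contact type
#'
#' Splits each participant stratum's total reported contacts into
#' percentage shares by contact setting, group-size band and weekly
#' contact minutes (intimacy) band. Shares sum to 100 within each stratum
#' and characteristic up to rounding.
#'
#' @param contacts Contact-event tibble.
#' @param participants Participant tibble.
#' @param households Household tibble.
#' @param by Participant stratifier: `"age_group"` (default) or
#'   `"density_band"`.
#' @param midpoints A [midpoint_config()] for the intimacy bands.
#' @return A tidy tibble with `stratum`, `characteristic`, `level`, `n`,
#'   `pct`.
#' @export
contact_decomposition <- function(contacts, participants, households,
                                  by = c("age_group", "density_band"),
                                  midpoints = midpoint_config()) {
  by <- match.arg(by)
  ev <- contacts[!isTRUE_vec(contacts$repeat_flag), ]
  pp <- participants |>
    dplyr::left_join(households, by = "household_id") |>
    dplyr::mutate(
      age_group = derive_participant_age_group(.data$age_years),
      density_band = as.character(cut(.data$density_at_first_visit,
                                      breaks = c(0, 100, 500, 5000, Inf),
                                      labels = c("<=100", "101-500",
                                                 "501-5000", "5000+")))
    )
  ev <- ev |>
    dplyr::left_join(dplyr::select(pp, "participant_id", "visit",
                                   "age_group", "density_band"),
                     by = c("participant_id", "visit")) |>
    dplyr::mutate(
      group_band = group_size_band(.data$group_size),
      minutes = ifelse(is.na(.data$frequency) | is.na(.data$duration),
                       NA_real_,
                       weekly_contact_minutes(
                         dplyr::coalesce(.data$frequency, "4+/wk"),
                         dplyr::coalesce(.data$duration, "60+ min"),
                         midpoints)),
      minutes_band = as.character(cut(.data$minutes,
                                      breaks = c(0, 30, 120, Inf),
                                      labels = c("<30 min/wk",
                                                 "30-119 min/wk",
                                                 "120+ min/wk")))
    )
  characteristics <- c("setting", "group_band", "minutes_band")
  purrr::map_dfr(characteristics, function(ch) {
    ev |>
      dplyr::filter(!is.na(.data[[ch]]), !is.na(.data[[by]])) |>
      dplyr::group_by(stratum = .data[[by]]) |>
      dplyr::count(level = .data[[ch]], wt = .data$group_size) |>
      count_percentages() |>
      dplyr::ungroup() |>
      dplyr::mutate(characteristic = ch, .before = 2)
  })
}

#' Per-visit potential-triangle summary
#'
#' Counts potential triangles and the percentage connected at each visit.
#'
#' @param triangles Potential-triangle tibble with `visit` and `y`.
#' @return A tibble with `visit`, `n_triangles`, `pct_connected`.
#' @export
triangle_visit_summary <- function(triangles) {
  triangles |>
    dplyr::group_by(.data$visit) |>
    dplyr::summarise(n_triangles = dplyr::n(),
                     pct_connected = 100 * mean(.data$y), .groups = "drop")
}

#' Pool a per-visit triangle summary
#'
#' Pools per-visit potential-triangle counts and connectedness
#' percentages: the pooled count is the sum, and the pooled percentage the
#' count-weighted mean of the per-visit percentages.
#'
#' @param visit_summary A tibble as returned by
#'   [triangle_visit_summary()] (columns `n_triangles`,
#'   `pct_connected`).
#' @return A one-row tibble with `n_triangles` and `pct_connected`.
#' @export
pool_visit_summary <- function(visit_summary) {
  tibble::tibble(
    n_triangles = sum(visit_summary$n_triangles),
    pct_connected = sum(visit_summary$pct_connected *
                          visit_summary$n_triangles) /
      sum(visit_summary$n_triangles)
  )
}

#' Full descriptive report
#'
#' Bundles the stratified contact-characteristics table, the daily-contact
#' summaries (all and extra-household), the contact decomposition and,
#' when triangle data are supplied, the per-visit and pooled triangle
#' summaries. Deterministic: the same inputs give the same report.
#'
#' @param participants,households,contacts Survey tables.
#' @param triangles Optional potential-triangle tibble (with `y`).
#' @return A named list of tibbles.
#' @export
descriptive_report <- function(participants, households, contacts,
                               triangles = NULL) {
  out <- list(
    contact_characteristics = contact_characteristics_table(contacts,
                                                            participants),
    daily_contacts_all = daily_contact_summary(participants, households,
                                               contacts, "all"),
    daily_contacts_extra = daily_contact_summary(participants, households,
                                                 contacts,
                                                 "extra-household"),
    decomposition_age = contact_decomposition(contacts, participants,
                                              households, "age_group")
  )
  if (!is.null(triangles)) {
    out$triangles_by_visit <- triangle_visit_summary(triangles)
    out$triangles_pooled <- pool_visit_summary(out$triangles_by_visit)
  }
  out
}

#' Boxplot-style summary of daily contacts by stratum
#'
#' @param summary A tibble from [daily_contact_summary()].
#' @param stratifier Which stratifier to display (default `"age_group"`).
#' @return A ggplot object.
#' @export
plot_daily_contacts <- function(summary, stratifier = "age_group") {
  df <- summary[summary$stratifier == stratifier, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), colour = "orange") +
    ggplot2::labs(x = stratifier, y = "daily reported contacts") +
    ggplot2::theme_minimal()
}

#' Plot stratified connection probabilities
#'
#' @param strat A tibble from [stratified_probability()].
#' @return A ggplot object.
#' @export
plot_stratified_probability <- function(strat) {
  ggplot2::ggplot(strat, ggplot2::aes(x = .data$stratum, y = .data$p_hat)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL,
                  y = "per-underlying-triangle connection probability") +
    ggplot2::theme_minimal()
}
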