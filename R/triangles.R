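#' Number of underlying person-level triangles
#'
#' A potential contact triangle pairs two contact events. When either event
#' is a group, the pair stands for every combination of one member of each
#' group with the participant, so it represents
#' `g_primary * g_secondary` underlying individual triangles (100 for two
#' groups of 10).
#'
#' @param g_primary,g_secondary Reported group sizes (integers >= 1).
#' @return Integer vector of underlying-triangle counts.
#' @export
#' @examples
#' underlying_triangle_count(10, 10)  # 100
underlying_triangle_count <- function(g_primary, g_secondary) {
  if (any(g_primary < 1, na.rm = TRUE) || any(g_secondary < 1, na.rm = TRUE)) {
    abort("Group sizes must be >= 1.")
  }
  as.integer(g_primary) * as.integer(g_secondary)
}

#' Select the two randomly chosen primary contacts
#'
#' Picks two contact events uniformly at random without replacement from a
#' participant-visit diary, emulating the instrument's selection of the two
#' "randomly selected primary contacts". When observed triangle responses
#' are available their primaries are used instead; this operation exists
#' for fully synthetic enumeration.
#'
#' @param events Contact-event tibble for one participant-visit.
#' @param seed Integer seed making the selection reproducible.
#' @return Character vector of two event ids; `character(0)` (with a
#'   warning) when fewer than two events exist.
#' @export
select_random_primaries <- function(events, seed = 1) {
  ids <- events$event_id[!isTRUE_vec(events$repeat_flag)]
  if (length(ids) < 2) {
    warn("Fewer than two contact events; no primaries selected.")
    return(character(0))
  }
  et_stream_seed(seed, 4L)
  sample(ids, 2)
}

#' Enumerate potential contact triangles
#'
#' Builds one potential triangle per triangle response: the pair of a
#' randomly selected primary contact event and a secondary contact event,
#' with the underlying-triangle count `m` (product of the two group sizes)
#' and the observed connectedness `y` from dichotomising the certainty
#' response at the chosen cutoff. The pair of the two primaries, which the
#' instrument can elicit from either side, is collapsed to a single
#' triangle keyed on the lower event id. Repeat-flagged events re-list
#' already-counted individuals and are excluded. Participant-, household-
#' and contact-level covariates are joined on.
#'
#' @param diaries Contact-event tibble.
#' @param responses Triangle-response tibble.
#' @param participants Participant tibble.
#' @param households Household tibble.
#' @param cutoff Certainty cutoff passed to [dichotomize_certainty()].
#' @return A potential-triangle tibble with columns `participant_id`,
#'   `visit`, `primary_event_id`, `secondary_event_id`, `m`, `y`, the
#'   `primary_*`/`secondary_*` event attributes and participant covariates.
#' @export
enumerate_potential_triangles <- function(diaries, responses, participants,
                                          households,
                                          cutoff = c("probably-yes",
                                                     "yes-only",
                                                     "probably-no")) {
  cutoff <- match.arg(cutoff)
  check_triangle_references(responses, diaries)
  ev <- diaries[!isTRUE_vec(diaries$repeat_flag), ]
  responses <- responses[responses$primary_event_id %in% ev$event_id &
                           responses$secondary_event_id %in% ev$event_id, ]

  # Collapse duplicated elicitations of the same unordered pair (notably
  # primary-primary) onto the lexicographically ordered key; a pair counts
  # as connected if any of its elicitations is affirmative at the cutoff.
  responses <- responses |>
    dplyr::mutate(
      y = dichotomize_certainty(.data$certainty, cutoff),
      .lo = pmin(.data$primary_event_id, .data$secondary_event_id),
      .hi = pmax(.data$primary_event_id, .data$secondary_event_id)
    )
  dup <- duplicated(responses[c("participant_id", "visit", ".lo", ".hi")])
  if (any(dup)) {
    responses <- responses |>
      dplyr::group_by(.data$participant_id, .data$visit, .data$.lo,
                      .data$.hi) |>
      dplyr::summarise(
        primary_event_id = .data$.lo[1],
        secondary_event_id = .data$.hi[1],
        certainty = .data$certainty[1],
        y = any(.data$y),
        .groups = "drop"
      )
  }
  responses <- dplyr::select(responses, -dplyr::any_of(c(".lo", ".hi")))

  tri <- et_join_pair_attributes(responses, ev) |>
    dplyr::mutate(m = underlying_triangle_count(.data$primary_group_size,
                                                .data$secondary_group_size))
  pp <- participants |>
    dplyr::left_join(households, by = "household_id") |>
    dplyr::mutate(age_group = derive_participant_age_group(.data$age_years),
                  occupation = derive_occupation_class(.data$occupation_raw),
                  density = .data$density_at_first_visit)
  tri |>
    dplyr::left_join(dplyr::select(pp, "participant_id", "visit",
                                   "age_group", "sex", "occupation",
                                   "household_size", "density",
                                   "location_id", "household_id"),
                     by = c("participant_id", "visit")) |>
    dplyr::select("participant_id", "visit", "primary_event_id",
                  "secondary_event_id", "m", "y", "certainty",
                  dplyr::starts_with("primary_"),
                  dplyr::starts_with("secondary_"),
                  "age_group", "sex", "occupation", "household_size",
                  "density", "location_id", "household_id") |>
    dplyr::arrange(.data$participant_id, .data$visit,
                   .data$primary_event_id, .data$secondary_event_id)
}

#' Trim potential triangles with extreme underlying-triangle counts
#'
#' Removes observations in the top share of the underlying-triangle count
#' distribution (default: top 0.5%), which would otherwise exert undue
#' influence on the any-of-m likelihood. The threshold is the empirical
#' quantile of `m` (order-statistic definition with linear interpolation,
#' R's default type 7), computed on the pooled table or per visit; rows
#' strictly above the threshold are removed, so ties at the threshold are
#' retained and trimming is idempotent.
#'
#' @param triangles Potential-triangle tibble with column `m`.
#' @param quantile Retention quantile in (0, 1]; default 0.995.
#' @param per_visit Compute the threshold within each visit instead of
#'   pooled (default pooled).
#' @return A list with `retained` and `trimmed` tibbles.
#' @export
trim_by_underlying_count <- function(triangles, quantile = 0.995,
                                     per_visit = FALSE) {
  if (nrow(triangles) == 0) abort("Cannot trim an empty triangle table.")
  stopifnot(quantile > 0, quantile <= 1)
  if (per_visit) {
    triangles <- triangles |>
      dplyr::group_by(.data$visit) |>
      dplyr::mutate(.thr = stats::quantile(.data$m, quantile, type = 7)) |>
      dplyr::ungroup()
  } else {
    triangles$.thr <- stats::quantile(triangles$m, quantile, type = 7)
  }
  keep <- triangles$m <= triangles$.thr
  triangles$.thr <- NULL
  list(retained = triangles[keep, , drop = FALSE],
       trimmed = triangles[!keep, , drop = FALSE])
}
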