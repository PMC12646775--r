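# First-order analysis: hierarchical overdispersed-Poisson regression of
# daily reported contacts. Overdispersion is modelled with an
# observation-level normal random effect on the log mean
# (lognormal-Poisson), alongside location, household and participant
# random effects and a visit fixed effect.

#' Build the contact-count regression design
#'
#' Aggregates contact diaries to one observation per participant-visit and
#' attaches the analysis covariates: participant age group, sex, occupation
#' class, (log) household size, log10 population density fixed at the first
#' analysed visit, and visit. The outcome is either the total number of
#' reported contacts or the extra-household total (events in any setting
#' other than the home; transport/shopping count as extra-household).
#' Repeat-flagged events never add to either total. Rows with unknown age
#' group, sex or occupation, or missing density, are excluded
#' (complete-case) and the exclusion count is reported.
#'
#' @param participants Participant tibble (one row per participant-visit).
#' @param households Household tibble.
#' @param diaries Contact-event tibble.
#' @param outcome `"all"` or `"extra-household"`.
#' @return A tibble with `participant_id`, `visit`, `y` and covariate
#'   columns (`age_group`, `sex`, `occupation`, `household_size`,
#'   `density`, `location_id`, `household_id`).
#' @export
build_count_design <- function(participants, households, diaries,
                               outcome = c("all", "extra-household")) {
  outcome <- match.arg(outcome)
  ev <- diaries[!isTRUE_vec(diaries$repeat_flag), ]
  if (outcome == "extra-household") {
    ev <- ev[!is.na(ev$setting) & ev$setting != "home", ]
  }
  totals <- ev |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::summarise(y = sum(.data$group_size), .groups = "drop")
  design <- participants |>
    dplyr::left_join(households, by = "household_id") |>
    dplyr::left_join(totals, by = c("participant_id", "visit")) |>
    dplyr::mutate(
      y = as.integer(dplyr::coalesce(.data$y, 0L)),
      age_group = derive_participant_age_group(.data$age_years),
      occupation = derive_occupation_class(.data$occupation_raw),
      density = .data$density_at_first_visit
    )
  complete <- design$age_group != "unknown" & design$sex != "unknown" &
    design$occupation != "unknown" & !is.na(design$density) &
    !is.na(design$household_size)
  dropped <- sum(!complete)
  if (dropped > 0) {
    rlang::inform(paste0("Excluded ", dropped,
                         " participant-visit(s) with incomplete covariates."))
  }
  design <- design[complete, ]
  if (nrow(design) == 0) abort("Empty count design after complete-case exclusion.")
  dplyr::select(design, "participant_id", "visit", "y", "age_group", "sex",
                "occupation", "household_size", "density", "location_id",
                "household_id")
}

et_count_design_matrix <- function(design, covariates) {
  X <- et_design_participant(design)
  all_cov <- c("age_group", "sex", "occupation", "household_size",
               "density")
  drop_map <- list(
    age_group = paste0("age_", et_age_levels_nonref),
    sex = "sex_female",
    occupation = c("occ_student", "occ_other"),
    household_size = "log_hh_size",
    density = "log10_density"
  )
  drop <- unlist(drop_map[setdiff(all_cov, covariates)])
  X[, setdiff(colnames(X), drop), drop = FALSE]
}

#' Pointwise log-likelihood of the contact-count model
#'
#' Evaluates the Poisson log-probability of each observation at mean
#' `exp(x'beta + gamma_visit + u_loc + u_hh + u_part + e_obs)`. Exposed so
#' the likelihood can be checked against independent Poisson evaluations.
#'
#' @param params List with `beta` (named vector over the design columns,
#'   visit effects included as `visit_*`) and optional named random-effect
#'   vectors `u_loc`, `u_hh`, `u_part` and per-row `e_obs`.
#' @param observations A design tibble from [build_count_design()].
#' @param covariates Covariate blocks included (default all).
#' @return Numeric vector of pointwise log-likelihoods.
#' @export
count_log_likelihood <- function(params, observations,
                                 covariates = c("age_group", "sex",
                                                "occupation",
                                                "household_size",
                                                "density")) {
  X <- et_count_design_matrix(observations, covariates)
  beta <- params$beta[colnames(X)]
  if (any(is.na(beta))) abort("`params$beta` must name every design column.")
  eta <- as.vector(X %*% beta)
  re <- function(u, ids) if (is.null(u)) 0 else unname(u[ids])
  eta <- eta + re(params$u_loc, observations$location_id) +
    re(params$u_hh, observations$household_id) +
    re(params$u_part, observations$participant_id)
  if (!is.null(params$e_obs)) eta <- eta + params$e_obs
  if (any(!is.finite(eta))) abort("Non-finite linear predictor.")
  observations$y * eta - exp(eta) - lgamma(observations$y + 1)
}

#' Fit the hierarchical contact-count model
#'
#' Fits the overdispersed-Poisson regression by MCMC with random effects at
#' the location, household, participant and observation levels and visit
#' fixed effects. Priors are weakly informative: Normal(0, 5) on the
#' intercept, Normal(0, 2.5) on other fixed effects, half-Normal(0, 1) on
#' all random-effect SDs.
#'
#' @param design A tibble from [build_count_design()].
#' @param config An [mcmc_config()].
#' @param covariates Covariate blocks to adjust for; the default is the
#'   fully adjusted model (age group, sex, household size, occupation,
#'   log10 density). Pass a single block for an unadjusted analysis.
#' @param store_loglik Keep the pointwise log-likelihood draws (needed for
#'   WAIC; disable to save memory in simulation studies).
#' @return An `egotriad_fit` with posterior draws, pointwise
#'   log-likelihoods, WAIC and convergence diagnostics.
#' @export
fit_count_model <- function(design, config = mcmc_config(),
                            covariates = c("age_group", "sex", "occupation",
                                           "household_size", "density"),
                            store_loglik = TRUE) {
  X <- et_count_design_matrix(design, covariates)
  et_fit_hierarchical(X, design$y, rep(1, nrow(X)), family = 0L,
                      loc_id = design$location_id,
                      hh_id = design$household_id,
                      part_id = design$participant_id,
                      config = config, model_label = "count",
                      store_loglik = store_loglik)
}

#' Relative contact rates from a fitted count model
#'
#' Exponentiates the posterior draws of the requested fixed-effect
#' coefficients and summarises them by the posterior mean and central 95%
#' credible interval. The reference level of each factor has relative rate
#' exactly 1.
#'
#' @param fit An `egotriad_fit` from [fit_count_model()].
#' @param term Optional term name(s); default all fixed effects.
#' @return A tibble with `term`, `rr`, `conf.low`, `conf.high`.
#' @export
relative_rates <- function(fit, term = NULL) {
  td <- tidy.egotriad_fit(fit, exponentiate = TRUE)
  td <- td[td$class == "fixed", ]
  if (!is.null(term)) {
    missing_terms <- setdiff(term, td$term)
    if (length(missing_terms) > 0) {
      abort(paste0("Unknown term(s): ",
                   paste(missing_terms, collapse = ", ")))
    }
    td <- td[td$term %in% term, ]
  }
  dplyr::select(dplyr::rename(td, rr = "estimate"),
                "term", "rr", "conf.low", "conf.high")
}
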