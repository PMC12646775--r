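#' Configuration for the synthetic survey generator
#'
#' Builds the configuration object consumed by [generate_population()],
#' [generate_contact_diaries()], [generate_triangle_responses()] and
#' [simulate_survey()]. The defaults emulate the structure of a
#' transect-sampled longitudinal contact survey: 40 communities sampled
#' along a population-density gradient with a target of 20 households per
#' community, all resident members aged 2+ enrolled, and four analysed
#' visits. Contact totals are generated from the same hierarchical
#' lognormal-Poisson model the count fitter assumes, and triangle
#' connectedness from the same hierarchical any-of-m logistic model the
#' triangle fitter assumes, so every generating coefficient is a recoverable
#' ground truth.
#'
#' @param n_locations Number of communities along the transect.
#' @param households_per_location Households enrolled per community.
#' @param visits Analysed visits, a subset of `2:5`.
#' @param density_range Range (people per km^2) spanned by the transect.
#' @param density_gradient `+1` for density increasing with location index,
#'   `-1` for decreasing.
#' @param household_density_jitter_sd SD (log10 units) of household-level
#'   density noise around the community density.
#' @param mean_household_size,max_household_size Household size is
#'   `1 + Poisson(mean_household_size - 1)` truncated at the maximum; every
#'   member aged 2+ is enrolled.
#' @param missing_prob Probability that age, sex or occupation is missing /
#'   unknown (exercises complete-case exclusion downstream).
#' @param group_size_mu,group_size_size Mean and dispersion of the negative
#'   binomial that (after zero-truncation) generates event group sizes;
#'   `group_size_mu = 0` degenerates to all-singleton events.
#' @param p_repeat Probability that a participant-visit diary appends one
#'   repeat-flagged event (a re-listing that does not add to the total).
#' @param p_category_missing Probability a contact's age category is not
#'   reported.
#' @param p_age_guess Probability an exact age guess is given when the
#'   category is missing (visits 3+ only, as in the instrument).
#' @param p_multiple_age Probability a group event spans multiple contact
#'   age bands.
#' @param setting_probs Named list of setting probability vectors by
#'   occupation class.
#' @param touch_probs Named vector: probability a contact involves touch,
#'   by setting.
#' @param frequency_probs,duration_probs,contact_age_probs Marginal
#'   probabilities for the respective categorical responses.
#' @param count_truth List with `beta` (named fixed effects on the log
#'   scale), `visit` (named visit effects, reference visit 2) and `sigma`
#'   (named SDs `loc`, `hh`, `part`, `obs`) for the contact-count model.
#' @param triangle_truth As `count_truth` (SDs `loc`, `hh`, `part`; no
#'   observation level) plus `spec`, the generating specification, one of
#'   `"participant_only"`, `"individual_contact"`, `"shared_contact"`:
#'   coefficients outside the generating specification are ignored.
#' @param certainty_soften Probability that a latent connected /
#'   not-connected report is softened to "probably yes" / "probably no".
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_locations = 40,
                         households_per_location = 20,
                         visits = 2:5,
                         density_range = c(100, 20000),
                         density_gradient = 1,
                         household_density_jitter_sd = 0.05,
                         mean_household_size = 2.5,
                         max_household_size = 8,
                         missing_prob = 0.005,
                         group_size_mu = 2.7,
                         group_size_size = 0.35,
                         p_repeat = 0.02,
                         p_category_missing = 0.05,
                         p_age_guess = 0.7,
                         p_multiple_age = 0.7,
                         setting_probs = NULL,
                         touch_probs = c(home = 0.50, work = 0.08,
                                         school = 0.40, social = 0.20,
                                         other = 0.10),
                         frequency_probs = c("<1/wk" = 0.17, "1-3/wk" = 0.11,
                                             "4+/wk" = 0.72),
                         duration_probs = c("<10 min" = 0.34,
                                            "10-59 min" = 0.15,
                                            "60+ min" = 0.51),
                         contact_age_probs = c("0-4" = 0.03, "5-19" = 0.14,
                                               "20-39" = 0.27,
                                               "40-64" = 0.42, "65+" = 0.09,
                                               "unknown" = 0.05),
                         count_truth = NULL,
                         triangle_truth = NULL,
                         certainty_soften = 0.10) {
  if (is.null(setting_probs)) {
    setting_probs <- list(
      employed = c(home = 0.25, work = 0.45, school = 0.00, social = 0.20,
                   other = 0.10),
      student  = c(home = 0.25, work = 0.00, school = 0.50, social = 0.15,
                   other = 0.10),
      other    = c(home = 0.40, work = 0.05, school = 0.02, social = 0.33,
                   other = 0.20),
      unknown  = c(home = 0.40, work = 0.20, school = 0.05, social = 0.20,
                   other = 0.15)
    )
  }
  if (is.null(count_truth)) count_truth <- default_count_truth()
  if (is.null(triangle_truth)) triangle_truth <- default_triangle_truth()
  cfg <- list(
    n_locations = as.integer(n_locations),
    households_per_location = as.integer(households_per_location),
    visits = sort(as.integer(visits)),
    density_range = density_range,
    density_gradient = density_gradient,
    household_density_jitter_sd = household_density_jitter_sd,
    mean_household_size = mean_household_size,
    max_household_size = as.integer(max_household_size),
    missing_prob = missing_prob,
    group_size_mu = group_size_mu,
    group_size_size = group_size_size,
    p_repeat = p_repeat,
    p_category_missing = p_category_missing,
    p_age_guess = p_age_guess,
    p_multiple_age = p_multiple_age,
    setting_probs = setting_probs,
    touch_probs = touch_probs,
    frequency_probs = frequency_probs,
    duration_probs = duration_probs,
    contact_age_probs = contact_age_probs,
    count_truth = count_truth,
    triangle_truth = triangle_truth,
    certainty_soften = certainty_soften
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  ok <- function(cond, msg) if (!isTRUE(cond)) abort(paste0("Invalid synthetic configuration: ", msg))
  ok(cfg$n_locations >= 1, "n_locations must be >= 1.")
  ok(cfg$households_per_location >= 1, "households_per_location must be >= 1.")
  ok(length(cfg$visits) >= 1 && all(cfg$visits %in% 2:5),
     "visits must be a non-empty subset of 2:5.")
  ok(all(cfg$density_range > 0) && length(cfg$density_range) == 2,
     "density_range must be two positive numbers.")
  ok(all(cfg$count_truth$sigma >= 0) && all(cfg$triangle_truth$sigma >= 0),
     "random-effect SDs must be >= 0.")
  probs <- c(cfg$missing_prob, cfg$p_repeat, cfg$p_category_missing,
             cfg$p_age_guess, cfg$p_multiple_age, cfg$certainty_soften,
             unlist(cfg$setting_probs), cfg$touch_probs,
             cfg$frequency_probs, cfg$duration_probs, cfg$contact_age_probs)
  ok(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1].")
  ok(cfg$triangle_truth$spec %in% c("participant_only", "individual_contact",
                                    "shared_contact"),
     "triangle_truth$spec must name one of the three specifications.")
  ok(cfg$group_size_mu >= 0 && cfg$group_size_size > 0,
     "group-size parameters must be non-negative (size > 0).")
  invisible(cfg)
}

#' Default generating truth for the contact-count model
#'
#' Fixed effects on the log scale. The age pattern (flat through midlife,
#' declining in the oldest groups), the density effect per 10-fold increase,
#' and the overall scale (about a dozen daily contacts at the reference
#' covariates) are set to values typical of contact surveys in dense Asian
#' settings.
#'
#' @return A list with `beta`, `visit` and `sigma`.
#' @export
default_count_truth <- function() {
  list(
    beta = c(intercept = log(12),
             "age_2-15" = log(1.06), "age_16-25" = log(0.84),
             "age_26-35" = log(0.98), "age_46-55" = log(0.97),
             "age_56-65" = log(0.86), "age_66-75" = log(0.76),
             "age_76+" = log(0.60),
             sex_female = -0.02, occ_student = -0.15, occ_other = -0.30,
             log_hh_size = 0.15, log10_density = log(1.10)),
    visit = c("3" = 0.05, "4" = -0.05, "5" = 0.10),
    sigma = c(loc = 0.15, hh = 0.25, part = 0.30, obs = 0.35)
  )
}

#' Default generating truth for the triangle-connection model
#'
#' Fixed effects on the log-odds scale for the per-underlying-triangle
#' connection probability. Defaults encode a U-shaped age pattern (highest
#' clustering in children and the oldest adults), lower clustering at high
#' population density, strongly reduced odds for group contacts, and a
#' large positive effect of the two contacts sharing a setting.
#'
#' @return A list with `beta`, `visit`, `sigma` and `spec`.
#' @export
default_triangle_truth <- function() {
  list(
    beta = c(intercept = stats::qlogis(0.15),
             "age_2-15" = log(1.38), "age_16-25" = log(1.25),
             "age_26-35" = log(1.10), "age_46-55" = log(1.10),
             "age_56-65" = log(1.35), "age_66-75" = log(1.80),
             "age_76+" = log(2.67),
             sex_female = log(1.20), occ_student = log(1.30),
             occ_other = log(1.30), log_hh_size = 0.15,
             log10_density = log(0.57),
             n_home = log(0.85), n_work = log(0.30), n_school = log(0.23),
             n_other_setting = log(0.60),
             n_freq_lt1 = log(0.60), n_freq_1_3 = log(0.80),
             n_dur_lt10 = log(0.55), n_dur_10_59 = log(0.75),
             n_touch = log(1.50),
             group_contact = log(0.26), log_m = log(0.70),
             same_setting = log(7.37), same_frequency = log(1.30),
             same_duration = log(1.30), both_touch = log(1.40)),
    visit = c("3" = 0, "4" = 0.05, "5" = 0.20),
    sigma = c(loc = 0.25, hh = 0.25, part = 0.35),
    spec = "shared_contact"
  )
}

# Independent seed streams so each table can be regenerated on its own.
et_stream_seed <- function(seed, stream) {
  set.seed((as.integer(seed) %% 1000003L) * 2048L + as.integer(stream))
}

# Assemble the full coefficient vector (fixed effects + visit effects) in
# the order of the design columns; errors on any unnamed term.
et_truth_beta <- function(truth, design_cols) {
  full <- truth$beta
  for (v in names(truth$visit)) full[paste0("visit_", v)] <- truth$visit[[v]]
  missing_terms <- setdiff(design_cols, names(full))
  if (length(missing_terms) > 0) {
    abort(paste0("Generating truth lacks coefficients for: ",
                 paste(missing_terms, collapse = ", ")))
  }
  full[design_cols]
}

#' Generate a synthetic study population
#'
#' Creates the location, household and participant tables together with the
#' realised ground truth (fixed effects and location-, household- and
#' participant-level random effects for both models). Density follows a
#' monotone gradient along the transect; ages span 2--90 with occupation
#' conditional on age (students concentrated at school ages, employment at
#' working ages); every household member aged 2+ is enrolled at every
#' configured visit.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the output is fully determined by
#'   `(config, seed)`.
#' @return A list of class `synth_population` with elements `locations`,
#'   `households`, `participants` and `truth`.
#' @export
generate_population <- function(config = synth_config(), seed = 1) {
  validate_synth_config(config)
  et_stream_seed(seed, 1L)
  nl <- config$n_locations
  lr <- log10(config$density_range)
  base <- if (nl == 1) mean(lr) else seq(lr[1], lr[2], length.out = nl)
  if (config$density_gradient < 0) base <- rev(base)
  locations <- tibble::tibble(
    location_id = sprintf("L%03d", seq_len(nl)),
    population_density = 10^base
  )

  nh <- nl * config$households_per_location
  hh_loc <- rep(locations$location_id, each = config$households_per_location)
  hh_density <- rep(locations$population_density,
                    each = config$households_per_location) *
    10^rnorm(nh, 0, config$household_density_jitter_sd)
  hh_size <- pmin(1L + rpois(nh, max(config$mean_household_size - 1, 0)),
                  config$max_household_size)
  households <- tibble::tibble(
    household_id = sprintf("H%05d", seq_len(nh)),
    location_id = hh_loc,
    household_size = as.integer(hh_size),
    density_at_first_visit = hh_density
  )

  np <- sum(hh_size)
  p_hh <- rep(households$household_id, times = hh_size)
  ages <- et_sample_ages(np)
  ages[runif(np) < config$missing_prob] <- NA_integer_
  sex <- sample(c("male", "female"), np, replace = TRUE)
  sex[runif(np) < config$missing_prob] <- "unknown"
  occ_raw <- et_sample_occupation(ages)
  occ_raw[runif(np) < config$missing_prob] <- NA_character_
  base_participants <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(np)),
    household_id = p_hh,
    age_years = ages, sex = sex, occupation_raw = occ_raw
  )
  participants <- tidyr::crossing(base_participants,
                                  visit = config$visits) |>
    dplyr::select("participant_id", "household_id", "visit", "age_years",
                  "sex", "occupation_raw") |>
    dplyr::arrange(.data$participant_id, .data$visit)

  draw_re <- function(ids, sd) setNames(rnorm(length(ids), 0, sd), ids)
  truth <- list(
    count = c(config$count_truth, list(
      u_loc = draw_re(locations$location_id, config$count_truth$sigma["loc"]),
      u_hh = draw_re(households$household_id, config$count_truth$sigma["hh"]),
      u_part = draw_re(base_participants$participant_id,
                       config$count_truth$sigma["part"])
    )),
    triangle = c(config$triangle_truth, list(
      u_loc = draw_re(locations$location_id,
                      config$triangle_truth$sigma["loc"]),
      u_hh = draw_re(households$household_id,
                     config$triangle_truth$sigma["hh"]),
      u_part = draw_re(base_participants$participant_id,
                       config$triangle_truth$sigma["part"])
    ))
  )
  structure(list(locations = locations, households = households,
                 participants = participants, truth = truth),
            class = "synth_population")
}

et_sample_ages <- function(n) {
  ages <- 2:90
  w <- dplyr::case_when(
    ages <= 15 ~ 0.8, ages <= 25 ~ 1.0, ages <= 55 ~ 1.3,
    ages <= 75 ~ 1.0, TRUE ~ 0.4
  )
  sample(ages, n, replace = TRUE, prob = w)
}

et_sample_occupation <- function(ages) {
  n <- length(ages)
  u <- runif(n)
  out <- rep("unemployed", n)
  a <- ifelse(is.na(ages), 40L, ages)
  out[a < 5] <- "child not in school"
  is_school <- a >= 5 & a <= 22
  out[is_school] <- ifelse(u[is_school] < 0.8, "student",
                           ifelse(a[is_school] >= 16, "employed",
                                  "child not in school"))
  is_work <- a >= 23 & a <= 65
  out[is_work] <- ifelse(u[is_work] < 0.7, "employed",
                         ifelse(u[is_work] < 0.85, "unemployed",
                                "homemaker"))
  out[a > 65] <- "retired"
  out
}

# Participant-visit covariate frame joined with household attributes and
# derived classes; the common input to the linear predictors.
et_pv_frame <- function(population) {
  population$participants |>
    dplyr::left_join(population$households, by = "household_id") |>
    dplyr::mutate(
      age_group = derive_participant_age_group(.data$age_years),
      occupation = derive_occupation_class(.data$occupation_raw),
      density = .data$density_at_first_visit
    )
}

#' Generate synthetic contact diaries
#'
#' For every participant-visit, a total contact count is drawn from the
#' hierarchical lognormal-Poisson model (fixed effects, visit effect,
#' location/household/participant random effects and an observation-level
#' normal deviate on the log mean). The total is then partitioned into
#' contact events whose group sizes follow a zero-truncated negative
#' binomial, and event attributes (setting, touch, frequency, duration,
#' contact age) are drawn conditional on the participant's occupation
#' class. A small fraction of diaries append a repeat-flagged event.
#'
#' @param population A `synth_population` from [generate_population()].
#' @inheritParams generate_population
#' @return A contact-event tibble passing
#'   `validate_survey_table(kind = "contact")`.
#' @export
generate_contact_diaries <- function(population, config = synth_config(),
                                     seed = 1) {
  et_stream_seed(seed, 2L)
  pv <- et_pv_frame(population)
  X <- et_design_participant(pv, visits = config$visits)
  tr <- population$truth$count
  beta <- et_truth_beta(tr, colnames(X))
  eta <- as.vector(X %*% beta) +
    tr$u_loc[pv$location_id] + tr$u_hh[pv$household_id] +
    tr$u_part[pv$participant_id] +
    rnorm(nrow(pv), 0, tr$sigma["obs"])
  totals <- rpois(nrow(pv), exp(pmin(eta, 20)))

  sizes <- vector("list", nrow(pv))
  for (i in seq_len(nrow(pv))) {
    sizes[[i]] <- et_partition_total(totals[i], config)
  }
  n_ev <- lengths(sizes)
  idx <- rep(seq_len(nrow(pv)), n_ev)
  ev <- tibble::tibble(
    participant_id = pv$participant_id[idx],
    visit = pv$visit[idx],
    group_size = as.integer(unlist(sizes)),
    occupation = pv$occupation[idx],
    repeat_flag = FALSE
  )
  # repeat-flagged re-listings: same person appearing in a second entry
  rep_pv <- which(n_ev >= 1 & runif(nrow(pv)) < config$p_repeat)
  if (length(rep_pv) > 0) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      participant_id = pv$participant_id[rep_pv],
      visit = pv$visit[rep_pv],
      group_size = 1L,
      occupation = pv$occupation[rep_pv],
      repeat_flag = TRUE
    ))
  }
  ne <- nrow(ev)
  if (ne == 0) {
    return(tibble::tibble(event_id = character(0),
                          participant_id = character(0),
                          visit = integer(0), group_size = integer(0),
                          contact_age_category = character(0),
                          age_guess = integer(0), setting = character(0),
                          touch = character(0), frequency = character(0),
                          duration = character(0), repeat_flag = logical(0)))
  }
  setting <- character(ne)
  for (occ in names(config$setting_probs)) {
    sel <- ev$occupation == occ
    if (any(sel)) {
      setting[sel] <- sample(names(config$setting_probs[[occ]]), sum(sel),
                             replace = TRUE,
                             prob = config$setting_probs[[occ]])
    }
  }
  touch <- ifelse(runif(ne) < config$touch_probs[setting], "yes", "no")
  frequency <- sample(names(config$frequency_probs), ne, replace = TRUE,
                      prob = config$frequency_probs)
  duration <- sample(names(config$duration_probs), ne, replace = TRUE,
                     prob = config$duration_probs)
  cat_lvls <- names(config$contact_age_probs)
  contact_age <- sample(cat_lvls, ne, replace = TRUE,
                        prob = config$contact_age_probs)
  is_group <- ev$group_size > 1
  contact_age[is_group & runif(ne) < config$p_multiple_age] <- "multiple"
  miss <- runif(ne) < config$p_category_missing
  contact_age[miss] <- NA_character_
  age_guess <- rep(NA_integer_, ne)
  guess <- miss & ev$visit >= 3 & runif(ne) < config$p_age_guess
  age_guess[guess] <- sample(2:85, sum(guess), replace = TRUE)

  ev |>
    dplyr::mutate(contact_age_category = contact_age, age_guess = age_guess,
                  setting = setting, touch = touch, frequency = frequency,
                  duration = duration) |>
    dplyr::arrange(.data$participant_id, .data$visit, .data$repeat_flag) |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::mutate(event_id = sprintf("%s_v%d_e%02d", .data$participant_id,
                                     .data$visit, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("event_id", "participant_id", "visit", "group_size",
                  "contact_age_category", "age_guess", "setting", "touch",
                  "frequency", "duration", "repeat_flag")
}

# Split a total of `total` contacts into event group sizes drawn from a
# zero-truncated negative binomial; the last event is shrunk so that the
# sizes sum exactly to the total.
et_partition_total <- function(total, config) {
  if (total <= 0) return(integer(0))
  if (config$group_size_mu <= 0) return(rep(1L, total))
  out <- integer(0)
  remaining <- total
  while (remaining > 0) {
    k <- max(8L, ceiling(remaining / (1 + config$group_size_mu)))
    draws <- et_rztnb(k, config$group_size_mu, config$group_size_size)
    cum <- cumsum(draws)
    if (cum[length(cum)] < remaining) {
      out <- c(out, draws)
      remaining <- remaining - cum[length(cum)]
    } else {
      cut <- which(cum >= remaining)[1]
      if (cut > 1) {
        draws[cut] <- remaining - cum[cut - 1]
        out <- c(out, draws[seq_len(cut)])
      } else {
        out <- c(out, remaining)
      }
      remaining <- 0
    }
  }
  as.integer(out)
}

# Zero-truncated negative binomial via inverse CDF on a uniform restricted
# to (P(X = 0), 1); deterministic given the RNG state.
et_rztnb <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  u <- p0 + runif(n) * (1 - p0)
  pmax(1L, stats::qnbinom(u, size = size, mu = mu))
}

#' Generate synthetic triangle responses
#'
#' For each participant-visit with at least two (non-repeat) contact
#' events, two primary events are selected uniformly at random and paired
#' with every other event; the primary-primary pair appears once. For a
#' pair with group sizes \eqn{g_1, g_2}, each of the \eqn{m = g_1 g_2}
#' underlying person-level triangles is connected independently with
#' probability \eqn{p} from the hierarchical logistic truth, so the latent
#' "any connected" indicator is Bernoulli with probability
#' \eqn{1 - (1-p)^m}. The indicator is then mapped to the four-level
#' certainty scale, softening to the neighbouring "probably" category with
#' the configured probability.
#'
#' @param diaries Contact-event tibble from [generate_contact_diaries()].
#' @param population The `synth_population` holding the generating truth.
#' @inheritParams generate_population
#' @return A triangle-response tibble; the per-pair true connection
#'   probabilities are attached as `attr(, "pair_truth")`.
#' @export
generate_triangle_responses <- function(diaries,
                                        population,
                                        config = synth_config(),
                                        seed = 1) {
  et_stream_seed(seed, 3L)
  ev <- diaries[!diaries$repeat_flag, ]
  pairs <- ev |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      prim <- sample(g$event_id, 2)
      sec1 <- setdiff(g$event_id, prim[1])
      sec2 <- setdiff(g$event_id, prim)
      tibble::tibble(participant_id = key$participant_id,
                     visit = key$visit,
                     primary_event_id = c(rep(prim[1], length(sec1)),
                                          rep(prim[2], length(sec2))),
                     secondary_event_id = c(sec1, sec2))
    }) |>
    dplyr::bind_rows()
  if (nrow(pairs) == 0) {
    return(tibble::tibble(participant_id = character(0), visit = integer(0),
                          primary_event_id = character(0),
                          secondary_event_id = character(0),
                          certainty = character(0)))
  }
  tri <- et_join_pair_attributes(pairs, ev)
  pv <- et_pv_frame(population)
  tri <- tri |>
    dplyr::left_join(dplyr::select(pv, "participant_id", "visit",
                                   "age_group", "sex", "occupation",
                                   "household_size", "density",
                                   "location_id", "household_id"),
                     by = c("participant_id", "visit"))
  tr <- population$truth$triangle
  terms <- triangle_spec_terms(tr$spec)
  Xp <- et_design_participant(tri, visits = config$visits)
  X <- Xp
  if (tr$spec %in% c("individual_contact", "shared_contact")) {
    X <- cbind(X, et_design_contact(tri))
  }
  if (tr$spec == "shared_contact") {
    X <- cbind(X, et_design_shared(tri))
  }
  keep <- c(terms, paste0("visit_", setdiff(config$visits, 2L)))
  X <- X[, intersect(colnames(X), keep), drop = FALSE]
  beta <- et_truth_beta(tr, colnames(X))
  eta <- as.vector(X %*% beta) +
    tr$u_loc[tri$location_id] + tr$u_hh[tri$household_id] +
    tr$u_part[tri$participant_id]
  p <- stats::plogis(eta)
  prob_any <- -expm1(tri$m * log1p(-p))
  connected <- runif(nrow(tri)) < prob_any
  soften <- runif(nrow(tri)) < config$certainty_soften
  certainty <- ifelse(connected,
                      ifelse(soften, "probably yes", "yes"),
                      ifelse(soften, "probably no", "no"))
  out <- tibble::tibble(
    participant_id = tri$participant_id, visit = tri$visit,
    primary_event_id = tri$primary_event_id,
    secondary_event_id = tri$secondary_event_id,
    certainty = certainty
  )
  attr(out, "pair_truth") <- tibble::tibble(
    participant_id = tri$participant_id, visit = tri$visit,
    primary_event_id = tri$primary_event_id,
    secondary_event_id = tri$secondary_event_id,
    m = tri$m, p_true = p, prob_connected = prob_any,
    connected = connected
  )
  out
}

# Attach primary_*/secondary_* event attributes and m to a pair table.
et_join_pair_attributes <- function(pairs, events) {
  attrs <- events |>
    dplyr::select("event_id", "group_size", "setting", "touch",
                  "frequency", "duration")
  pairs |>
    dplyr::left_join(dplyr::rename_with(attrs, ~ paste0("primary_", .x)),
                     by = c(primary_event_id = "primary_event_id")) |>
    dplyr::left_join(dplyr::rename_with(attrs, ~ paste0("secondary_", .x)),
                     by = c(secondary_event_id = "secondary_event_id")) |>
    dplyr::mutate(m = as.numeric(.data$primary_group_size) *
                    as.numeric(.data$secondary_group_size))
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper running [generate_population()],
#' [generate_contact_diaries()] and [generate_triangle_responses()] under
#' one seed.
#'
#' @inheritParams generate_population
#' @return A list with `locations`, `households`, `participants`,
#'   `contacts`, `triangles` and `truth`.
#' @export
#' @examples
#' sim <- simulate_survey(synth_config(n_locations = 2,
#'                                     households_per_location = 3,
#'                                     visits = 2:3), seed = 1)
#' nrow(sim$households)  # 6
simulate_survey <- function(config = synth_config(), seed = 1) {
  population <- generate_population(config, seed)
  contacts <- generate_contact_diaries(population, config, seed)
  triangles <- generate_triangle_responses(contacts, population, config,
                                           seed)
  list(locations = population$locations,
       households = population$households,
       participants = population$participants,
       contacts = contacts, triangles = triangles,
       truth = population$truth)
}
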