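# Fixed-effect design encodings. Both the synthetic generator and the model
# fitters build linear predictors through these helpers, so coefficient
# names used as simulation truth line up exactly with fitted terms.
#
# Reference levels: age 36-45, male, employed, visit 2, social setting,
# frequency 4+/wk, duration 60+ min. Population density enters as
# log10(density) - 3, i.e. centered at 1000 people per square kilometre, a
# fixed constant so the covariate does not depend on the sample analysed.

DENSITY_CENTER_LOG10 <- 3

et_age_levels_nonref <- c("2-15", "16-25", "26-35", "46-55", "56-65",
                          "66-75", "76+")

# df must carry: age_group, sex, occupation, household_size, density, visit
et_design_participant <- function(df, visits = NULL) {
  if (is.null(visits)) visits <- sort(unique(df$visit))
  visits_nonref <- setdiff(visits, 2L)
  n <- nrow(df)
  cols <- list(intercept = rep(1, n))
  for (a in et_age_levels_nonref) {
    cols[[paste0("age_", a)]] <- as.numeric(df$age_group == a)
  }
  cols$sex_female <- as.numeric(df$sex == "female")
  cols$occ_student <- as.numeric(df$occupation == "student")
  cols$occ_other <- as.numeric(df$occupation == "other")
  cols$log_hh_size <- log(df$household_size)
  cols$log10_density <- log10(df$density) - DENSITY_CENTER_LOG10
  for (v in visits_nonref) {
    cols[[paste0("visit_", v)]] <- as.numeric(df$visit == v)
  }
  do.call(cbind, cols)
}

# Symmetric per-contact encoding for a triangle table: each categorical
# contact attribute contributes the count (0, 1 or 2) of the pair's contacts
# at that level, so the coefficient is an effect per contact and the design
# does not depend on which event was the primary.
et_design_contact <- function(tri) {
  cnt <- function(attr, level) {
    as.numeric(tri[[paste0("primary_", attr)]] == level) +
      as.numeric(tri[[paste0("secondary_", attr)]] == level)
  }
  cbind(
    n_home          = cnt("setting", "home"),
    n_work          = cnt("setting", "work"),
    n_school        = cnt("setting", "school"),
    n_other_setting = cnt("setting", "other"),
    n_freq_lt1      = cnt("frequency", "<1/wk"),
    n_freq_1_3      = cnt("frequency", "1-3/wk"),
    n_dur_lt10      = cnt("duration", "<10 min"),
    n_dur_10_59     = cnt("duration", "10-59 min"),
    n_touch         = cnt("touch", "yes"),
    group_contact   = as.numeric(tri$primary_group_size > 1 |
                                   tri$secondary_group_size > 1),
    log_m           = log(tri$m)
  )
}

et_design_shared <- function(tri) {
  cbind(
    same_setting   = as.numeric(tri$primary_setting == tri$secondary_setting),
    same_frequency = as.numeric(tri$primary_frequency ==
                                  tri$secondary_frequency),
    same_duration  = as.numeric(tri$primary_duration ==
                                  tri$secondary_duration),
    both_touch     = as.numeric(tri$primary_touch == "yes" &
                                  tri$secondary_touch == "yes")
  )
}

#' Covariate sets of the three nested triangle-model specifications
#'
#' The three specifications are strictly nested. `participant_only` uses
#' characteristics of the participant and their household (age group, sex,
#' occupation, log household size, log10 population density) plus visit.
#' `individual_contact` adds the attributes of the two contact events
#' (setting, frequency, duration, touch, a group-contact indicator and the
#' log number of underlying triangles). `shared_contact` further adds
#' indicators for shared attributes of the pair (same setting, same
#' frequency, same duration, both involve touch).
#'
#' @param spec One of `"participant_only"`, `"individual_contact"`,
#'   `"shared_contact"`.
#' @return Character vector of design-column names for the specification
#'   (visit columns depend on the data and are appended at design time).
#' @export
triangle_spec_terms <- function(spec = c("participant_only",
                                         "individual_contact",
                                         "shared_contact")) {
  spec <- match.arg(spec)
  participant <- c("intercept", paste0("age_", et_age_levels_nonref),
                   "sex_female", "occ_student", "occ_other", "log_hh_size",
                   "log10_density")
  contact <- c("n_home", "n_work", "n_school", "n_other_setting",
               "n_freq_lt1", "n_freq_1_3", "n_dur_lt10", "n_dur_10_59",
               "n_touch", "group_contact", "log_m")
  shared <- c("same_setting", "same_frequency", "same_duration",
              "both_touch")
  switch(spec,
    participant_only   = participant,
    individual_contact = c(participant, contact),
    shared_contact     = c(participant, contact, shared)
  )
}
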