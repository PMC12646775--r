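# Canonical factor levels for the survey instruments. Kept in one place so
# readers, validators, the synthetic generator and the model design builders
# never disagree about spellings.

et_levels <- list(
  sex          = c("male", "female", "unknown"),
  occupation   = c("employed", "student", "other", "unknown"),
  age_group    = c("2-15", "16-25", "26-35", "36-45", "46-55", "56-65",
                   "66-75", "76+", "unknown"),
  contact_age  = c("0-4", "5-19", "20-39", "40-64", "65+", "multiple",
                   "unknown"),
  setting      = c("home", "work", "school", "social", "other"),
  touch        = c("yes", "no", "unknown"),
  frequency    = c("<1/wk", "1-3/wk", "4+/wk"),
  duration     = c("<10 min", "10-59 min", "60+ min"),
  certainty    = c("yes", "probably yes", "probably no", "no"),
  group_band   = c("1", "2-5", "6-10", "11-20", "21+"),
  visit        = 2:5
)

#' Canonical category levels used throughout the package
#'
#' Returns the factor levels recognised for a survey field: contact settings,
#' touch, frequency and duration categories, participant age groups, contact
#' age categories, occupation classes, certainty responses, group-size bands
#' and analysed visit numbers.
#'
#' @param field One of `"sex"`, `"occupation"`, `"age_group"`,
#'   `"contact_age"`, `"setting"`, `"touch"`, `"frequency"`, `"duration"`,
#'   `"certainty"`, `"group_band"`, `"visit"`.
#' @return A character (or integer, for `"visit"`) vector of levels.
#' @export
#' @examples
#' survey_levels("setting")
survey_levels <- function(field) {
  if (!field %in% names(et_levels)) {
    rlang::abort(paste0("Unknown field '", field, "'."))
  }
  et_levels[[field]]
}
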