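#' Published summary counts from a southern-China contact survey
#'
#' Small summary tables transcribed from the published descriptive results
#' of a large longitudinal contact survey in Guangdong province (visits
#' 2--5): counts of individual versus group contact events, total reported
#' contacts by touch and frequency category, and per-visit potential
#' contact triangle counts with the percentage connected. They serve as
#' worked examples for the reporting helpers (e.g. [count_percentages()]
#' and [pool_visit_summary()]).
#'
#' @param which `"events"`, `"contacts"` or `"triangles"`.
#' @return A tibble.
#' @export
#' @examples
#' study_summary_counts("events") |> count_percentages()
study_summary_counts <- function(which = c("events", "contacts",
                                           "triangles")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("study_", sub("s$", "", which),
                                     "_counts.csv"),
                   package = "egotriad", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}
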