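# Second-order analysis: hierarchical logistic regression for contact
# triangle connectedness. A potential triangle whose events have group
# sizes g1, g2 stands for m = g1 * g2 underlying person-level triangles,
# each connected independently with probability p, so the observation
# likelihood is P(any connected) = 1 - (1 - p)^m for an affirmative report
# and (1 - p)^m otherwise.

#' Per-underlying-triangle connection probability
#'
#' Numerically stable inverse logit of the linear predictor, defined for
#' |eta| up to several hundred without overflow.
#'
#' @param eta Finite numeric vector of linear predictors.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' connection_probability(0)   # 0.5
connection_probability <- function(eta) {
  if (any(!is.finite(eta))) abort("Non-finite linear predictor.")
  stats::plogis(eta)
}

#' Any-of-m observation log-likelihood
#'
#' Log-probability of the observed connectedness of a potential triangle
#' representing `m` underlying triangles, each independently connected
#' with probability `p`: `log(1 - (1 - p)^m)` for a connected report and
#' `m * log(1 - p)` otherwise. Computed through `log1p`/`expm1` so it is
#' finite and accurate for small `p`, large `m`, and `p` within 1e-12 of
#' the boundaries (`p` is clamped to `[1e-12, 1 - 1e-12]`).
#'
#' @param p Connection probabilities in (0, 1).
#' @param m Underlying-triangle counts (integers >= 1).
#' @param y Logical observed connectedness.
#' @return Numeric vector of log-probabilities.
#' @export
#' @examples
#' triangle_observation_loglik(0.5, 2, TRUE)  # log(0.75)
triangle_observation_loglik <- function(p, m, y) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in (0, 1).")
  if (any(m < 1)) abort("`m` must be >= 1.")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n <- max(length(p), length(m), length(y))
  p <- rep_len(p, n); m <- rep_len(m, n); y <- rep_len(y, n)
  log_none <- m * log1p(-p)              # log (1-p)^m
  ifelse(y, log(-expm1(log_none)), log_none)
}

#' Build a triangle-model design
#'
#' Encodes a (trimmed) potential-triangle table for one of the three
#' nested specifications (see [triangle_spec_terms()]). Contact-level
#' categorical attributes enter symmetrically as the count (0--2) of the
#' pair's contacts at each non-reference level, plus a pair-level
#' group-contact indicator and `log(m)`; the shared-contact specification
#' adds same-setting/frequency/duration and both-touch indicators. Rows
#' with incomplete covariates are dropped (complete-case).
#'
#' @param triangles Potential-triangle tibble from
#'   [enumerate_potential_triangles()] (after trimming).
#' @param spec `"participant_only"`, `"individual_contact"` or
#'   `"shared_contact"`.
#' @return A tibble holding the design columns together with `y`, `m` and
#'   the grouping ids; the design column names are recorded in
#'   `attr(, "terms")`.
#' @export
build_triangle_design <- function(triangles,
                                  spec = c("participant_only",
                                           "individual_contact",
                                           "shared_contact")) {
  spec <- match.arg(spec)
  needed <- c("age_group", "sex", "occupation")
  complete <- !is.na(triangles$y) & !is.na(triangles$density) &
    !is.na(triangles$household_size) &
    Reduce(`&`, lapply(needed, function(cn) triangles[[cn]] != "unknown"))
  if (spec != "participant_only") {
    attr_cols <- c(t(outer(c("primary_", "secondary_"),
                           c("setting", "touch", "frequency", "duration"),
                           paste0)))
    complete <- complete &
      Reduce(`&`, lapply(attr_cols, function(cn) {
        !is.na(triangles[[cn]]) & triangles[[cn]] != "unknown"
      }))
  }
  dropped <- sum(!complete)
  if (dropped > 0) {
    rlang::inform(paste0("Excluded ", dropped,
                         " triangle(s) with incomplete covariates."))
  }
  tri <- triangles[complete, ]
  if (nrow(tri) == 0) abort("Empty triangle design after complete-case exclusion.")
  X <- et_design_participant(tri)
  if (spec %in% c("individual_contact", "shared_contact")) {
    X <- cbind(X, et_design_contact(tri))
  }
  if (spec == "shared_contact") X <- cbind(X, et_design_shared(tri))
  out <- dplyr::bind_cols(
    tibble::as_tibble(X),
    tibble::tibble(y = tri$y, m = tri$m,
                   location_id = tri$location_id,
                   household_id = tri$household_id,
                   participant_id = tri$participant_id)
  )
  attr(out, "terms") <- colnames(X)
  attr(out, "spec") <- spec
  out
}

#' Fit the hierarchical triangle-connection model
#'
#' Fits the any-of-m logistic regression by MCMC with random effects at
#' the location, household and participant levels and visit fixed effects.
#' Priors match the count model: Normal(0, 5) intercept, Normal(0, 2.5)
#' fixed effects, half-Normal(0, 1) random-effect SDs.
#'
#' @param design A design tibble from [build_triangle_design()].
#' @param config An [mcmc_config()].
#' @param store_loglik Keep the pointwise log-likelihood draws (needed for
#'   WAIC; disable to save memory in simulation studies).
#' @return An `egotriad_fit`.
#' @export
fit_triangle_model <- function(design, config = mcmc_config(),
                               store_loglik = TRUE) {
  terms <- attr(design, "terms")
  X <- as.matrix(design[terms])
  et_fit_hierarchical(X, as.numeric(design$y), design$m, family = 1L,
                      loc_id = design$location_id,
                      hh_id = design$household_id,
                      part_id = design$participant_id,
                      config = config, model_label = "triangle",
                      spec = attr(design, "spec"),
                      store_loglik = store_loglik)
}

#' Odds ratios from a fitted triangle model
#'
#' Exponentiates the posterior draws of the requested coefficients and
#' summarises them by the posterior mean and central 95% credible
#' interval.
#'
#' @param fit An `egotriad_fit` from [fit_triangle_model()].
#' @param term Optional term name(s); default all fixed effects.
#' @return A tibble with `term`, `or`, `conf.low`, `conf.high`.
#' @export
odds_ratios <- function(fit, term = NULL) {
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
  dplyr::select(dplyr::rename(td, or = "estimate"),
                "term", "or", "conf.low", "conf.high")
}

#' Stratified per-underlying-triangle connection probabilities
#'
#' For each level of a stratifying variable, fits a one-parameter
#' non-hierarchical logistic model with the any-of-m likelihood (an
#' intercept-only model within the stratum, incorporating group size
#' through `m`) and returns the maximum-likelihood per-underlying-triangle
#' connection probability. With all `m = 1` and `k` of `n` connected this
#' is exactly `k/n`.
#'
#' @param triangles Potential-triangle tibble with columns `y`, `m` and
#'   the stratum variable.
#' @param stratum_variable Name of the stratifying column.
#' @return A tibble with `stratum`, `n`, `p_hat`.
#' @export
stratified_probability <- function(triangles, stratum_variable) {
  if (!stratum_variable %in% names(triangles)) {
    abort(paste0("Column '", stratum_variable, "' not found."))
  }
  strata <- triangles[[stratum_variable]]
  keep <- !is.na(strata) & !is.na(triangles$y)
  if (sum(!keep) > 0) {
    warn(paste0("Excluded ", sum(!keep),
                " row(s) with missing stratum or outcome."))
  }
  tri <- triangles[keep, ]
  strata <- strata[keep]
  purrr::map_dfr(sort(unique(strata)), function(s) {
    sub <- tri[strata == s, ]
    if (all(sub$y)) {
      p_hat <- 1
    } else if (!any(sub$y)) {
      p_hat <- 0
    } else {
      opt <- stats::optimize(function(theta) {
        sum(triangle_observation_loglik(stats::plogis(theta), sub$m, sub$y))
      }, interval = c(-15, 15), maximum = TRUE, tol = 1e-9)
      p_hat <- stats::plogis(opt$maximum)
    }
    tibble::tibble(stratum = as.character(s), n = nrow(sub), p_hat = p_hat)
  })
}
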