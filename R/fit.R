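#' MCMC sampler configuration
#'
#' Defaults follow the analysis protocol: four chains of 2000 iterations
#' with the first 1000 discarded as warm-up. [mcmc_config_test()] is a
#' reduced preset (2 chains of 600, 300 warm-up) for small synthetic
#' problems.
#'
#' @param chains Number of chains (>= 1; >= 2 needed for R-hat).
#' @param iterations Total iterations per chain.
#' @param warmup Warm-up iterations discarded from each chain
#'   (`warmup < iterations`); all proposal adaptation happens here.
#' @param seed Integer seed; chains use derived, fixed sub-seeds so a
#'   repeated fit is draw-for-draw identical.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iterations = 2000, warmup = 1000,
                        seed = 1) {
  stopifnot(chains >= 1, warmup >= 1, warmup < iterations)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_test <- function(seed = 1) {
  mcmc_config(chains = 2, iterations = 600, warmup = 300, seed = seed)
}

# Shared fitting engine. X: design matrix with named columns ("intercept"
# first); y: outcome; m: underlying-triangle counts (ignored by the count
# family); level ids: character vectors mapping rows to location /
# household / participant units.
et_fit_hierarchical <- function(X, y, m, family, loc_id, hh_id, part_id,
                                config, model_label, spec = NULL,
                                store_loglik = TRUE) {
  n <- nrow(X)
  if (n == 0) abort("Empty design: no observations to fit.")
  if (any(!is.finite(X))) abort("Non-finite values in the design matrix.")
  prior_sd <- ifelse(colnames(X) == "intercept", 5, 2.5)

  # crude fixed-effect initialisation from an unpenalised GLM fit
  init <- tryCatch({
    fam <- if (family == 0) stats::poisson() else stats::binomial()
    fit0 <- suppressWarnings(stats::glm.fit(X, y, family = fam,
                                            control = list(maxit = 25)))
    b <- fit0$coefficients
    b[!is.finite(b)] <- 0
    pmin(pmax(b, -10), 10)
  }, error = function(e) rep(0, ncol(X)))

  as_index <- function(ids) as.integer(factor(ids))
  loc <- as_index(loc_id)
  hh <- as_index(hh_id)
  part <- as_index(part_id)

  base_seed <- (as.integer(config$seed) %% 1000003L) * 2048L
  chains <- lapply(seq_len(config$chains), function(ch) {
    et_run_chain(X, as.numeric(y), as.numeric(m), family, loc, hh, part,
                 init, prior_sd, 1.0, config$iterations, config$warmup,
                 base_seed + 100L + ch, store_loglik)
  })
  sig_names <- c("sigma_loc", "sigma_hh", "sigma_part",
                 if (family == 0) "sigma_obs")
  par_names <- c(colnames(X), sig_names)
  draws <- lapply(chains, function(cc) {
    d <- cc$draws[, seq_along(par_names), drop = FALSE]
    colnames(d) <- par_names
    d
  })
  ll <- if (store_loglik) do.call(rbind, lapply(chains, `[[`, "loglik"))
  fit <- structure(list(
    draws = draws, par_names = par_names, family = family, spec = spec,
    model = model_label, n_obs = n, config = config,
    accept_joint = vapply(chains, `[[`, numeric(1), "accept_joint"),
    loglik = ll
  ), class = "egotriad_fit")
  fit$waic <- if (store_loglik) waic(ll)
  fit$diagnostics <- et_fit_diagnostics(fit)
  fit
}

# One row per parameter: posterior mean/sd, 95% interval, R-hat, ESS.
et_fit_diagnostics <- function(fit) {
  purrr::map_dfr(fit$par_names, function(p) {
    mat <- sapply(fit$draws, function(d) d[, p])
    pooled <- as.vector(mat)
    rh <- if (length(fit$draws) >= 2) gelman_rubin(mat) else NA_real_
    es <- effective_sample_size(mat)
    tibble::tibble(
      term = p, estimate = mean(pooled), std.error = sd(pooled),
      conf.low = quantile(pooled, 0.025, names = FALSE),
      conf.high = quantile(pooled, 0.975, names = FALSE),
      rhat = as.numeric(rh), ess_bulk = es$bulk, ess_tail = es$tail,
      ess_pass = es$pass
    )
  })
}

#' Abort when a fit shows convergence problems
#'
#' Errors with a per-parameter R-hat report when any R-hat exceeds the
#' threshold or any effective sample size falls below the minimum.
#'
#' @param fit An `egotriad_fit`.
#' @param rhat_max Largest acceptable R-hat (default 1.05).
#' @param min_ess Smallest acceptable bulk/tail ESS (default 200).
#' @return `fit`, invisibly, when diagnostics pass.
#' @export
check_convergence <- function(fit, rhat_max = 1.05, min_ess = 200) {
  d <- fit$diagnostics
  bad <- d[!is.na(d$rhat) & (d$rhat > rhat_max |
                               pmin(d$ess_bulk, d$ess_tail) < min_ess), ]
  if (nrow(bad) > 0) {
    abort(paste0(
      "Convergence failure (R-hat > ", rhat_max, " or ESS < ", min_ess,
      "):\n", paste0(sprintf("  %s: rhat=%.3f ess_bulk=%.0f ess_tail=%.0f",
                             bad$term, bad$rhat, bad$ess_bulk,
                             bad$ess_tail), collapse = "\n")))
  }
  invisible(fit)
}

#' @export
print.egotriad_fit <- function(x, ...) {
  cat("Hierarchical", if (x$family == 0) "lognormal-Poisson count"
      else "any-of-m logistic triangle", "model\n")
  if (!is.null(x$spec)) cat("Specification:", x$spec, "\n")
  cat(sprintf("%d observations; %d chains x %d iterations (%d warmup)\n",
              x$n_obs, x$config$chains, x$config$iterations,
              x$config$warmup))
  if (!is.null(x$waic)) {
    cat(sprintf("WAIC %.1f (lppd %.1f, p_waic %.1f)\n", x$waic$waic,
                x$waic$lppd, x$waic$p_waic))
  }
  print(x$diagnostics, n = 8)
  invisible(x)
}

#' Tidy posterior summaries of a fitted model
#'
#' One row per parameter with the posterior mean (the point estimate used
#' throughout), standard deviation, central 95% credible interval, and
#' convergence diagnostics. With `exponentiate = TRUE` the fixed effects
#' are reported as rate/odds ratios (scale parameters are left
#' untransformed and flagged in `class`).
#'
#' @param x An `egotriad_fit`.
#' @param exponentiate Report `exp()` of fixed-effect draws.
#' @param conf.level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess_bulk`, `ess_tail`, `class`.
#' @export
tidy.egotriad_fit <- function(x, exponentiate = FALSE, conf.level = 0.95,
                              ...) {
  alpha <- (1 - conf.level) / 2
  purrr::map_dfr(x$par_names, function(p) {
    pooled <- unlist(lapply(x$draws, function(d) d[, p]))
    is_sigma <- grepl("^sigma_", p)
    if (exponentiate && !is_sigma) pooled <- exp(pooled)
    d <- x$diagnostics[x$diagnostics$term == p, ]
    tibble::tibble(
      term = p, estimate = mean(pooled), std.error = sd(pooled),
      conf.low = quantile(pooled, alpha, names = FALSE),
      conf.high = quantile(pooled, 1 - alpha, names = FALSE),
      rhat = d$rhat, ess_bulk = d$ess_bulk, ess_tail = d$ess_tail,
      class = if (is_sigma) "scale" else "fixed"
    )
  })
}

#' One-line model summary
#'
#' @param x An `egotriad_fit`.
#' @param ... Unused.
#' @return A one-row tibble with observation count, WAIC components,
#'   worst-case diagnostics and the MCMC configuration.
#' @export
glance.egotriad_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    waic = if (!is.null(x$waic)) x$waic$waic else NA_real_,
    lppd = if (!is.null(x$waic)) x$waic$lppd else NA_real_,
    p_waic = if (!is.null(x$waic)) x$waic$p_waic else NA_real_,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = min(x$diagnostics$ess_bulk, na.rm = TRUE),
    min_ess_tail = min(x$diagnostics$ess_tail, na.rm = TRUE),
    chains = x$config$chains, iterations = x$config$iterations,
    warmup = x$config$warmup
  )
}

#' Coefficient plot for a fitted model
#'
#' Plots posterior means and 95% credible intervals of the fixed effects
#' on the rate-/odds-ratio scale, with a reference line at 1.
#'
#' @param object An `egotriad_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egotriad_fit <- function(object, ...) {
  td <- tidy.egotriad_fit(object, exponentiate = TRUE)
  td <- td[td$class == "fixed" & td$term != "intercept", ]
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (object$family == 0) "relative rate"
                  else "odds ratio", y = NULL) +
    ggplot2::theme_minimal()
}
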