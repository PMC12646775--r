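# MCMC diagnostics: rank-normalised split R-hat and bulk/tail effective
# sample sizes (the modern forms of the Gelman-Rubin statistic and ESS),
# plus WAIC from pointwise posterior log-likelihoods.

# Split each chain (column) in half; drops the last draw of odd chains.
et_split_chains <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq(n - half + 1, n), , drop = FALSE])
}

# Rank-normalise pooled draws (fractional offset 3/8), preserving shape.
et_rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

# Classic split-R-hat on an iterations x chains matrix.
et_rhat_basic <- function(x) {
  n <- nrow(x)
  if (n < 2 || ncol(x) < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Gelman-Rubin convergence diagnostic (rank-normalised split R-hat)
#'
#' Computes the rank-normalised split potential scale reduction factor: the
#' maximum of the split R-hat of the rank-normalised draws and of the
#' rank-normalised folded draws (absolute deviations from the median).
#' Chains that are all constant have no between/within variance to compare;
#' by convention the statistic is reported as 1 with a `constant`
#' attribute set.
#'
#' @param draws A numeric matrix of posterior draws for one parameter,
#'   iterations in rows and chains in columns (at least 2 chains and 2
#'   iterations).
#' @return A single R-hat value (attribute `constant` flags degenerate
#'   input).
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) abort("R-hat needs at least two chains.")
  if (nrow(draws) < 4) abort("R-hat needs at least four draws per chain.")
  if (max(draws) - min(draws) < .Machine$double.eps * 100) {
    return(structure(1, constant = TRUE))
  }
  sp <- et_split_chains(draws)
  bulk <- et_rhat_basic(et_rank_normalize(sp))
  folded <- et_rhat_basic(et_rank_normalize(abs(sp - median(sp))))
  structure(max(bulk, folded, na.rm = TRUE), constant = FALSE)
}

# Biased autocovariance by FFT.
et_acov <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  mfft <- stats::nextn(2 * n)
  f <- stats::fft(c(xc, rep(0, mfft - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (mfft * n)
}

# ESS of an iterations x chains matrix via Geyer's initial monotone
# positive sequence (combined-chain autocorrelations).
et_ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  acov <- apply(x, 2, et_acov)
  mean_acov <- rowMeans(acov)
  w <- mean(apply(x, 2, var))
  b <- if (m > 1) n * var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * w + b / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho <- 1 - (w - mean_acov) / var_plus
  # paired sums, truncated at first negative pair, forced monotone
  max_t <- 2 * ((n - 1) %/% 2)
  p <- rho[seq(1, max_t, by = 2)] + rho[seq(2, max_t, by = 2)]
  k <- which(p < 0)[1]
  if (!is.na(k)) p <- p[seq_len(max(k - 1, 1))]
  p <- cummin(pmax(p, 0))
  tau <- max(-1 + 2 * sum(p), 1 / (n * m))
  min(n * m / tau, n * m)
}

#' Bulk and tail effective sample sizes
#'
#' Bulk ESS is computed on the rank-normalised split chains; tail ESS is
#' the smaller of the ESS of the 5% and 95% quantile exceedance
#' indicators. Both are compared against the adequacy threshold of 200
#' used for reporting model coefficients. Chains with no variation carry
#' essentially one independent draw each; they are reported as ESS equal
#' to the number of chains, flagged via the `constant` attribute.
#'
#' @inheritParams gelman_rubin
#' @param threshold Minimum acceptable ESS (default 200).
#' @return A list with `bulk`, `tail`, `pass` (both above the threshold)
#'   and `constant`.
#' @export
effective_sample_size <- function(draws, threshold = 200) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4) abort("ESS needs at least four draws per chain.")
  if (max(draws) - min(draws) < .Machine$double.eps * 100) {
    return(list(bulk = ncol(draws), tail = ncol(draws), pass = FALSE,
                constant = TRUE))
  }
  sp <- et_split_chains(draws)
  bulk <- et_ess_basic(et_rank_normalize(sp))
  q <- quantile(sp, c(0.05, 0.95), names = FALSE)
  tail_ess <- min(et_ess_basic((sp <= q[1]) * 1),
                  et_ess_basic((sp <= q[2]) * 1), na.rm = TRUE)
  list(bulk = bulk, tail = tail_ess,
       pass = is.finite(bulk) && is.finite(tail_ess) &&
         bulk >= threshold && tail_ess >= threshold,
       constant = FALSE)
}

et_log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Watanabe-Akaike information criterion
#'
#' Computes WAIC from a pointwise log-likelihood matrix (posterior draws in
#' rows, observations in columns): the log pointwise predictive density
#' `lppd = sum_i log mean_s exp(ll[s, i])` (evaluated with log-sum-exp
#' stabilisation), the effective parameter count
#' `p_waic = sum_i var_s(ll[s, i])`, and `waic = -2 (lppd - p_waic)`.
#'
#' @param loglik Numeric matrix of pointwise log-likelihoods
#'   (draws x observations) with at least 2 draws; all entries finite.
#' @return A list with `lppd`, `p_waic` and `waic`.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) abort("WAIC needs at least two posterior draws.")
  if (!all(is.finite(loglik))) {
    abort("Non-finite entries in the pointwise log-likelihood matrix.")
  }
  s <- nrow(loglik)
  lppd <- sum(apply(loglik, 2, et_log_sum_exp) - log(s))
  p_waic <- sum(apply(loglik, 2, var))
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

#' Compare fitted models by WAIC
#'
#' Ranks fits by ascending WAIC and reports differences from the best
#' model. All fits must be computed on the same set of observations; ties
#' are broken by model name for a stable ordering.
#'
#' @param fits A named list of `egotriad_fit` objects (or of lists with
#'   `waic` and `n_obs` elements).
#' @return A tibble with columns `model`, `waic`, `lppd`, `p_waic`,
#'   `delta_waic`.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) > 1) {
    abort("Models were fitted to different numbers of observations; WAIC values are not comparable.")
  }
  out <- tibble::tibble(
    model = names(fits),
    waic = unname(vapply(fits, function(f) f$waic$waic, numeric(1))),
    lppd = unname(vapply(fits, function(f) f$waic$lppd, numeric(1))),
    p_waic = unname(vapply(fits, function(f) f$waic$p_waic, numeric(1)))
  )
  out <- out[order(out$waic, out$model), ]
  out$delta_waic <- out$waic - out$waic[1]
  out
}
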