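test_that("the count design splits all and extra-household outcomes", {
  pp <- toy_participants()[1, ]
  hh <- toy_households()
  ev <- toy_events(c("E1", "E2"), c(3, 5))
  ev$setting <- c("home", "work")
  d_all <- build_count_design(pp, hh, ev, "all")
  d_ex <- build_count_design(pp, hh, ev, "extra-household")
  expect_equal(d_all$y, 8L)
  expect_equal(d_ex$y, 5L)
  # repeat-flagged events add nothing
  ev2 <- ev
  ev2$repeat_flag[2] <- TRUE
  expect_equal(build_count_design(pp, hh, ev2, "all")$y, 3L)
  # participant-visits without diary rows count zero
  pp2 <- toy_participants()[c(1, 3), ]
  d2 <- build_count_design(pp2, hh, ev, "all")
  expect_equal(d2$y[d2$participant_id == "P2"], 0L)
})

test_that("incomplete covariates are excluded with a message", {
  pp <- toy_participants()[c(1, 3), ]
  pp$occupation_raw[2] <- NA
  ev <- toy_events("E1", 2)
  expect_message(
    d <- build_count_design(pp, toy_households(), ev, "all"),
    "Excluded 1"
  )
  expect_equal(nrow(d), 1)
  expect_equal(d$participant_id, "P1")
})

test_that("unadjusted designs carry one covariate block plus visit", {
  s <- simulate_survey(small_config(), seed = 30)
  des <- suppressMessages(build_count_design(s$participants, s$households,
                                             s$contacts, "all"))
  X <- egotriad:::et_count_design_matrix(des, "age_group")
  expect_setequal(colnames(X),
                  c("intercept", paste0("age_", c("2-15", "16-25", "26-35",
                                                  "46-55", "56-65", "66-75",
                                                  "76+")), "visit_3"))
})

test_that("pointwise log-likelihood matches independent Poisson evaluation", {
  s <- simulate_survey(small_config(), seed = 31)
  des <- suppressMessages(build_count_design(s$participants, s$households,
                                             s$contacts, "all"))
  X <- egotriad:::et_count_design_matrix(
    des, c("age_group", "sex", "occupation", "household_size", "density"))
  set.seed(99)
  for (rep in 1:100) {
    beta <- stats::setNames(rnorm(ncol(X), 0, 0.3), colnames(X))
    params <- list(
      beta = beta,
      u_loc = stats::setNames(rnorm(4, 0, 0.2),
                              unique(des$location_id)),
      u_part = stats::setNames(
        rnorm(length(unique(des$participant_id)), 0, 0.2),
        unique(des$participant_id)),
      e_obs = rnorm(nrow(des), 0, 0.1)
    )
    ll <- count_log_likelihood(params, des)
    eta <- as.vector(X %*% beta) + params$u_loc[des$location_id] +
      params$u_part[des$participant_id] + params$e_obs
    oracle <- stats::dpois(des$y, exp(eta), log = TRUE)
    expect_equal(ll, unname(oracle), tolerance = 1e-10)
  }
  # closed-form spot checks
  obs1 <- des[1, ]
  obs1$y <- 0L
  p0 <- list(beta = stats::setNames(rep(0, ncol(X)), colnames(X)))
  expect_equal(count_log_likelihood(p0, obs1), -1)
  obs2 <- obs1
  obs2$y <- 2L
  p2 <- p0
  p2$beta["intercept"] <- log(2)
  expect_equal(count_log_likelihood(p2, obs2), 2 * log(2) - 2 - log(2))
})

test_that("an intercept-only fit recovers the lognormal-Poisson mean", {
  cfg <- synth_config(
    n_locations = 4, households_per_location = 20, visits = 2,
    missing_prob = 0, p_repeat = 0,
    count_truth = zeroed_truth(default_count_truth(), intercept = log(8),
                               sigma = 0)
  )
  cfg$count_truth$sigma["obs"] <- 0.5
  s <- simulate_survey(cfg, seed = 32)
  des <- build_count_design(s$participants, s$households, s$contacts, "all")
  fit <- fit_count_model(des, mcmc_config(chains = 2, iterations = 700,
                                          warmup = 300, seed = 2),
                         covariates = character(0), store_loglik = FALSE)
  draws <- do.call(rbind, fit$draws)
  fitted_mean <- mean(exp(draws[, "intercept"] +
                            draws[, "sigma_obs"]^2 / 2))
  expect_lt(abs(fitted_mean / mean(des$y) - 1), 0.1)
})

test_that("count fits are reproducible and report relative rates", {
  s <- simulate_survey(small_config(), seed = 33)
  des <- suppressMessages(build_count_design(s$participants, s$households,
                                             s$contacts, "all"))
  cfg <- mcmc_config(chains = 2, iterations = 150, warmup = 80, seed = 4)
  f1 <- fit_count_model(des, cfg, store_loglik = FALSE)
  f2 <- fit_count_model(des, cfg, store_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)
  f1$draws <- lapply(f1$draws, function(d) {
    d[, "sex_female"] <- log(2)
    d
  })
  rr <- relative_rates(f1, "sex_female")
  expect_equal(rr$rr, 2)
  expect_equal(rr$conf.low, 2)
  expect_error(relative_rates(f1, "not_a_term"), "Unknown term")
})
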