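test_that("connection probability is a stable inverse logit", {
  expect_equal(connection_probability(0), 0.5)
  expect_lte(connection_probability(40), 1)
  expect_gt(connection_probability(40), 1 - 1e-15)
  expect_false(is.nan(connection_probability(700)))
  eta <- seq(-30, 30, by = 0.5)
  expect_equal(connection_probability(-eta), 1 - connection_probability(eta),
               tolerance = 1e-12)
  expect_error(connection_probability(Inf), "Non-finite")
})

test_that("any-of-m log-likelihood matches closed forms and an MC oracle", {
  expect_equal(triangle_observation_loglik(0.5, 1, TRUE), log(0.5))
  expect_equal(triangle_observation_loglik(0.5, 2, TRUE), log(0.75))
  expect_equal(triangle_observation_loglik(0.3, 4, FALSE), 4 * log(0.7))
  # Monte-Carlo oracle: any of 4 Bernoulli(0.3)
  set.seed(42)
  draws <- matrix(rbinom(4e5, 1, 0.3), ncol = 4)
  frac <- mean(rowSums(draws) > 0)
  closed <- exp(triangle_observation_loglik(0.3, 4, TRUE))
  se <- sqrt(closed * (1 - closed) / nrow(draws))
  expect_lt(abs(frac - closed), 3 * se)
  expect_equal(closed, 1 - 0.7^4, tolerance = 1e-12)
})

test_that("connected and not-connected probabilities sum to one", {
  for (p in c(1e-6, 0.01, 0.3, 0.5, 0.9, 1 - 1e-6)) {
    for (m in c(1, 2, 10, 100, 1e4)) {
      tot <- exp(triangle_observation_loglik(p, m, TRUE)) +
        exp(triangle_observation_loglik(p, m, FALSE))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("the m = 1 likelihood reduces exactly to Bernoulli", {
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(triangle_observation_loglik(p, 1, TRUE), log(p),
               tolerance = 1e-12)
  expect_equal(triangle_observation_loglik(p, 1, FALSE), log(1 - p),
               tolerance = 1e-12)
})

test_that("connection log-probability is monotone in p and m and stays finite", {
  p_grid <- c(0.01, 0.1, 0.4, 0.8)
  ll_p <- triangle_observation_loglik(p_grid, 5, TRUE)
  expect_true(all(diff(ll_p) > 0))
  m_grid <- c(1, 2, 5, 50, 1000)
  ll_m <- triangle_observation_loglik(0.05, m_grid, TRUE)
  expect_true(all(diff(ll_m) > 0))
  expect_true(is.finite(triangle_observation_loglik(1 - 1e-12, 1e4, FALSE)))
  expect_true(is.finite(triangle_observation_loglik(1e-12, 1e4, TRUE)))
  expect_error(triangle_observation_loglik(1.2, 1, TRUE), "0, 1")
})

test_that("designs for the three specifications are strictly nested", {
  s <- simulate_survey(small_config(), seed = 21)
  tri <- enumerate_potential_triangles(s$contacts, s$triangles,
                                       s$participants, s$households)
  d_p <- suppressMessages(build_triangle_design(tri, "participant_only"))
  d_i <- suppressMessages(build_triangle_design(tri, "individual_contact"))
  d_s <- suppressMessages(build_triangle_design(tri, "shared_contact"))
  expect_true(all(attr(d_p, "terms") %in% attr(d_i, "terms")))
  expect_true(all(attr(d_i, "terms") %in% attr(d_s, "terms")))
  expect_false("n_work" %in% attr(d_p, "terms"))
  expect_true("same_setting" %in% attr(d_s, "terms"))
  # two same-setting contacts flag the shared indicator
  same <- d_s$same_setting[tri_complete <- seq_len(nrow(d_s))]
  expect_true(all(same %in% c(0, 1)))
  # singleton pair: no group indicator, m covariate log(1) = 0
  ones <- d_s$group_contact == 0
  expect_true(all(d_s$log_m[ones] == 0))
})

test_that("stratified probabilities invert the any-of-m likelihood", {
  tri1 <- tibble::tibble(y = c(rep(TRUE, 30), rep(FALSE, 70)), m = 1,
                         stratum = "a")
  out1 <- stratified_probability(tri1, "stratum")
  expect_equal(out1$p_hat, 0.3, tolerance = 1e-6)
  # all m = 2: p_hat = 1 - sqrt(1 - k/n)
  tri2 <- tibble::tibble(y = c(rep(TRUE, 40), rep(FALSE, 60)), m = 2,
                         stratum = "b")
  out2 <- stratified_probability(tri2, "stratum")
  expect_equal(out2$p_hat, 1 - sqrt(1 - 0.4), tolerance = 1e-6)
  # generated orderings are preserved
  set.seed(31)
  mk <- function(p, lab) {
    m <- sample(1:3, 400, replace = TRUE)
    tibble::tibble(y = runif(400) < -expm1(m * log1p(-p)), m = m,
                   stratum = lab)
  }
  tri3 <- dplyr::bind_rows(mk(0.10, "low"), mk(0.20, "high"))
  out3 <- stratified_probability(tri3, "stratum")
  expect_gt(out3$p_hat[out3$stratum == "high"],
            out3$p_hat[out3$stratum == "low"])
  expect_warning(
    stratified_probability(
      tibble::tibble(y = c(TRUE, NA), m = 1, stratum = "a"), "stratum"),
    "Excluded")
})

test_that("odds ratios summarise exponentiated draws with trivial cases exact", {
  s <- simulate_survey(small_config(), seed = 22)
  tri <- enumerate_potential_triangles(s$contacts, s$triangles,
                                       s$participants, s$households)
  des <- suppressMessages(build_triangle_design(tri, "participant_only"))
  fit <- fit_triangle_model(des, mcmc_config(chains = 2, iterations = 200,
                                             warmup = 100, seed = 5),
                            store_loglik = FALSE)
  # forced draws: zero coefficient -> OR exactly 1; log 0.5 -> OR 0.5
  fit$draws <- lapply(fit$draws, function(d) {
    d[, "sex_female"] <- 0
    d[, "occ_student"] <- log(0.5)
    d
  })
  or <- odds_ratios(fit, c("sex_female", "occ_student"))
  expect_equal(or$or[or$term == "sex_female"], 1)
  expect_equal(or$conf.low[or$term == "sex_female"], 1)
  expect_equal(or$or[or$term == "occ_student"], 0.5)
  expect_error(odds_ratios(fit, "nope"), "Unknown term")
})

test_that("triangle fits are reproducible under a fixed seed", {
  s <- simulate_survey(small_config(), seed = 23)
  tri <- enumerate_potential_triangles(s$contacts, s$triangles,
                                       s$participants, s$households)
  des <- suppressMessages(build_triangle_design(tri, "participant_only"))
  cfg <- mcmc_config(chains = 2, iterations = 150, warmup = 80, seed = 9)
  f1 <- fit_triangle_model(des, cfg, store_loglik = FALSE)
  f2 <- fit_triangle_model(des, cfg, store_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)
})
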