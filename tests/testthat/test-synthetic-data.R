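test_that("generation is deterministic given the seed, per generator", {
  cfg <- synth_config(n_locations = 2, households_per_location = 3,
                      visits = 2:3)
  s1 <- simulate_survey(cfg, seed = 1)
  s2 <- simulate_survey(cfg, seed = 1)
  expect_identical(s1$households, s2$households)
  expect_identical(s1$contacts, s2$contacts)
  expect_identical(s1$triangles, s2$triangles)
  expect_equal(nrow(s1$locations), 2)
  expect_equal(nrow(s1$households), 6)
  # each table can be regenerated independently of the others
  pop <- generate_population(cfg, seed = 1)
  diaries <- generate_contact_diaries(pop, cfg, seed = 1)
  expect_identical(diaries, s1$contacts)
  expect_identical(generate_triangle_responses(diaries, pop, cfg, seed = 1),
                   s1$triangles)
  s3 <- simulate_survey(cfg, seed = 2)
  expect_false(identical(s1$contacts, s3$contacts))
})

test_that("zero random-effect SDs give exactly zero realised effects", {
  cfg <- small_config(
    count_truth = zeroed_truth(default_count_truth(), intercept = log(5),
                               sigma = 0),
    triangle_truth = zeroed_truth(default_triangle_truth(),
                                  intercept = 0, sigma = 0)
  )
  pop <- generate_population(cfg, seed = 3)
  expect_true(all(pop$truth$count$u_loc == 0))
  expect_true(all(pop$truth$count$u_part == 0))
  expect_true(all(pop$truth$triangle$u_hh == 0))
})

test_that("density follows the configured transect gradient", {
  pop <- generate_population(synth_config(n_locations = 15,
                                          households_per_location = 2),
                             seed = 4)
  expect_equal(cor(seq_len(15), pop$locations$population_density,
                   method = "spearman"), 1)
  pop_dec <- generate_population(synth_config(n_locations = 15,
                                              households_per_location = 2,
                                              density_gradient = -1),
                                 seed = 4)
  expect_equal(cor(seq_len(15), pop_dec$locations$population_density,
                   method = "spearman"), -1)
})

test_that("generated totals match lognormal-Poisson moments", {
  # intercept-only, no random effects: mean 10 Poisson totals
  cfg <- synth_config(
    n_locations = 10, households_per_location = 25, visits = 2:3,
    missing_prob = 0, p_repeat = 0,
    count_truth = zeroed_truth(default_count_truth(),
                               intercept = log(10), sigma = 0)
  )
  pop <- generate_population(cfg, seed = 11)
  diaries <- generate_contact_diaries(pop, cfg, seed = 11)
  totals <- dplyr::count(diaries, .data$participant_id, .data$visit,
                         wt = .data$group_size)$n
  n <- length(totals)
  expect_gt(n, 1000)
  expect_lt(abs(mean(totals) - 10), 3 * sqrt(10 / n))
  # Poisson dispersion: variance/mean near 1
  expect_lt(abs(var(totals) / mean(totals) - 1), 0.15)

  # observation-level SD 1 inflates the mean by the lognormal factor
  cfg2 <- synth_config(
    n_locations = 10, households_per_location = 25, visits = 2:3,
    missing_prob = 0, p_repeat = 0,
    count_truth = zeroed_truth(default_count_truth(), intercept = log(5),
                               sigma = 0)
  )
  cfg2$count_truth$sigma["obs"] <- 1
  pop2 <- generate_population(cfg2, seed = 12)
  d2 <- generate_contact_diaries(pop2, cfg2, seed = 12)
  # join onto the full participant-visit frame so empty diaries count zero
  totals2 <- dplyr::coalesce(dplyr::left_join(
    pop2$participants[c("participant_id", "visit")],
    dplyr::count(d2, .data$participant_id, .data$visit,
                 wt = .data$group_size),
    by = c("participant_id", "visit"))$n, 0L)
  mu <- exp(log(5) + 0.5)
  mc_sd <- sqrt(mu + mu^2 * (exp(1) - 1))
  expect_lt(abs(mean(totals2) - mu), 3 * mc_sd / sqrt(length(totals2)))
  expect_gt(var(totals2), mean(totals2))
})

test_that("degenerate group-size distribution yields singleton events", {
  cfg <- small_config(group_size_mu = 0)
  s <- simulate_survey(cfg, seed = 5)
  expect_true(all(s$contacts$group_size == 1))
})

test_that("latent connection frequency matches 1 - (1-p)^m", {
  # identity on the generator's own record of pair-level truth
  s <- simulate_survey(small_config(), seed = 6)
  pt <- attr(s$triangles, "pair_truth")
  expect_equal(pt$prob_connected, -expm1(pt$m * log1p(-pt$p_true)),
               tolerance = 1e-12)

  # frequency check against the closed form on a grid of (p, m)
  for (case in list(c(p = 0.1, g = 1), c(p = 0.5, g = 1),
                    c(p = 0.9, g = 1), c(p = 0.3, g = 2))) {
    p <- case[["p"]]; g <- case[["g"]]  # m = g^2 per pair
    cfg <- small_config(
      certainty_soften = 0,
      triangle_truth = zeroed_truth(default_triangle_truth(),
                                    intercept = stats::qlogis(p),
                                    sigma = 0)
    )
    cfg$triangle_truth$spec <- "participant_only"
    pop <- generate_population(synth_config(n_locations = 1,
                                            households_per_location = 40,
                                            visits = 2,
                                            count_truth = cfg$count_truth,
                                            triangle_truth = cfg$triangle_truth),
                               seed = 7)
    pop$truth$triangle$u_loc[] <- 0
    pop$truth$triangle$u_hh[] <- 0
    pop$truth$triangle$u_part[] <- 0
    ids <- unique(pop$participants$participant_id)
    diaries <- dplyr::bind_rows(lapply(ids, function(pid) {
      toy_events(sprintf("%s_e%02d", pid, 1:12), rep(g, 12),
                 participant = pid, visit = 2L)
    }))
    resp <- generate_triangle_responses(diaries, pop, cfg, seed = 8)
    y <- dichotomize_certainty(resp$certainty)
    expected <- 1 - (1 - p)^(g * g)
    se <- sqrt(expected * (1 - expected) / length(y))
    expect_lt(abs(mean(y) - expected), 3 * se + 1e-9)
  }
})

test_that("forcing the connection probability hits the boundaries", {
  cfg_hi <- small_config(
    certainty_soften = 0,
    triangle_truth = zeroed_truth(default_triangle_truth(), intercept = 40,
                                  sigma = 0)
  )
  s_hi <- simulate_survey(cfg_hi, seed = 9)
  expect_true(all(dichotomize_certainty(s_hi$triangles$certainty)))
  cfg_lo <- small_config(
    certainty_soften = 0,
    triangle_truth = zeroed_truth(default_triangle_truth(),
                                  intercept = -40, sigma = 0)
  )
  s_lo <- simulate_survey(cfg_lo, seed = 9)
  expect_false(any(dichotomize_certainty(s_lo$triangles$certainty)))
})

test_that("generated tables pass survey validation with zero errors", {
  s <- simulate_survey(small_config(), seed = 10)
  expect_silent(validate_survey_table(s$participants, "participant"))
  expect_silent(validate_survey_table(s$households, "household"))
  expect_silent(validate_survey_table(s$contacts, "contact"))
  expect_silent(validate_survey_table(s$triangles, "triangle"))
  expect_silent(check_triangle_references(s$triangles, s$contacts))
})
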