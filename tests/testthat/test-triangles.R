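test_that("underlying triangle counts multiply group sizes", {
  expect_identical(underlying_triangle_count(10, 10), 100L)
  expect_identical(underlying_triangle_count(1, 1), 1L)
  expect_identical(underlying_triangle_count(3, 4), 12L)
  # symmetry
  for (a in 1:5) for (b in 1:5) {
    expect_identical(underlying_triangle_count(a, b),
                     underlying_triangle_count(b, a))
  }
  expect_error(underlying_triangle_count(0, 3), ">= 1")
})

test_that("primary selection is seeded, uniform and degenerate-safe", {
  ev <- toy_events(paste0("E", 1:5), rep(1, 5))
  expect_identical(select_random_primaries(ev, seed = 3),
                   select_random_primaries(ev, seed = 3))
  expect_length(select_random_primaries(ev, seed = 3), 2)
  two <- toy_events(c("A", "B"), c(1, 1))
  expect_setequal(select_random_primaries(two, seed = 1), c("A", "B"))
  one <- toy_events("A", 1)
  expect_warning(out <- select_random_primaries(one, seed = 1),
                 "Fewer than two")
  expect_length(out, 0)
})

test_that("enumeration yields 2(E-2)+1 triangles with the pair deduplicated", {
  ev <- toy_events(LETTERS[1:5], c(1, 2, 1, 3, 1))
  resp <- toy_responses(
    primaries = c("A", "A", "A", "A", "B", "B", "B", "B"),
    secondaries = c("C", "D", "E", "B", "C", "D", "E", "A")
  )
  tri <- enumerate_potential_triangles(ev, resp, toy_participants(),
                                       toy_households())
  expect_equal(nrow(tri), 7)  # A-B elicited twice, collapsed once
  expect_equal(sum(tri$primary_event_id == "A" &
                     tri$secondary_event_id == "B"), 1)
  # m from the group sizes: A(1) x D(3) = 3
  expect_equal(tri$m[tri$primary_event_id == "A" &
                       tri$secondary_event_id == "D"], 3L)
  # brute-force oracle: unordered pairs {primary, other}
  pairs <- unique(t(apply(
    rbind(cbind("A", setdiff(LETTERS[1:5], "A")),
          cbind("B", setdiff(LETTERS[1:5], "B"))), 1, sort)))
  expect_equal(nrow(tri), nrow(pairs))
})

test_that("enumeration count matches the closed form for E = 2..6 events", {
  for (E in 2:6) {
    ids <- paste0("e", seq_len(E))
    ev <- toy_events(ids, rep(1, E))
    prim <- ids[1:2]
    resp <- toy_responses(
      primaries = c(rep(prim[1], E - 1), rep(prim[2], E - 2)),
      secondaries = c(setdiff(ids, prim[1]), setdiff(ids, prim))
    )
    tri <- enumerate_potential_triangles(ev, resp, toy_participants(),
                                         toy_households())
    expect_equal(nrow(tri), 2 * (E - 2) + 1)
  }
})

test_that("certainty cutoffs drive observed connectedness", {
  ev <- toy_events(c("A", "B"), c(1, 1))
  resp <- toy_responses("A", "B", certainty = "probably yes")
  y_main <- enumerate_potential_triangles(ev, resp, toy_participants(),
                                          toy_households(),
                                          cutoff = "probably-yes")$y
  y_strict <- enumerate_potential_triangles(ev, resp, toy_participants(),
                                            toy_households(),
                                            cutoff = "yes-only")$y
  expect_true(y_main)
  expect_false(y_strict)
})

test_that("repeat-flagged events are excluded from enumeration", {
  ev <- toy_events(c("A", "B", "C"), c(1, 1, 1))
  ev$repeat_flag[3] <- TRUE
  resp <- toy_responses(c("A", "A"), c("B", "C"))
  tri <- enumerate_potential_triangles(ev, resp, toy_participants(),
                                       toy_households())
  expect_equal(nrow(tri), 1)
  expect_equal(tri$secondary_event_id, "B")
})

test_that("trimming removes exactly the rows above the 99.5th percentile", {
  tab <- tibble::tibble(m = c(rep(1, 995), rep(1e4, 5)),
                        visit = rep(2:3, 500))
  out <- trim_by_underlying_count(tab)
  expect_equal(nrow(out$trimmed), 5)
  expect_true(all(out$trimmed$m == 1e4))
  expect_true(all(out$retained$m == 1))
  # brute-force threshold: sorted order statistic with interpolation
  thr <- stats::quantile(tab$m, 0.995, type = 7)
  expect_equal(nrow(out$retained), sum(tab$m <= thr))
})

test_that("trimming retains ties and is idempotent", {
  tab <- tibble::tibble(m = rep(4, 100), visit = 2L)
  out <- trim_by_underlying_count(tab)
  expect_equal(nrow(out$trimmed), 0)
  mixed <- tibble::tibble(m = c(rep(1, 400), rep(50, 3)), visit = 2L)
  once <- trim_by_underlying_count(mixed)
  twice <- trim_by_underlying_count(once$retained)
  expect_equal(nrow(twice$trimmed), 0)
  expect_equal(twice$retained$m, once$retained$m)
  expect_error(trim_by_underlying_count(mixed[0, ]), "empty")
  # per-visit thresholds
  pv <- tibble::tibble(m = c(rep(1, 300), 100, rep(9, 300), 900),
                       visit = rep(c(2L, 3L), each = 301))
  out_pv <- trim_by_underlying_count(pv, per_visit = TRUE)
  expect_equal(sort(out_pv$trimmed$m), c(100, 900))
})

test_that("the triangle pipeline is deterministic for identical inputs", {
  s <- simulate_survey(small_config(), seed = 20)
  t1 <- enumerate_potential_triangles(s$contacts, s$triangles,
                                      s$participants, s$households)
  t2 <- enumerate_potential_triangles(s$contacts, s$triangles,
                                      s$participants, s$households)
  expect_identical(t1, t2)
  expect_true(all(t1$m == t1$primary_group_size * t1$secondary_group_size))
})
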