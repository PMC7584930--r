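test_that("best survivor prefers censored over event at tied maximum time", {
  d <- survival_dataset(c(3, 5, 5, 1), c(1, 1, 0, 1),
                        c(rep("experimental", 3), "control"))
  expect_equal(best_survivor_index(d, "experimental"), 3)
  single <- survival_dataset(c(1, 2), c(1, 1), c("experimental", "control"))
  expect_equal(best_survivor_index(single, "control"), 2)
  expect_error(best_survivor_index(
    survival_dataset(1, 1, "control"), "experimental"), "empty")
})

test_that("worst survivor is the earliest event, not the earliest time", {
  d <- survival_dataset(c(1, 2, 9), c(0, 1, 1),
                        c("experimental", "experimental", "control"))
  expect_equal(worst_survivor_index(d, "experimental"), 2)
  cens <- survival_dataset(c(1, 2), c(0, 1), c("experimental", "control"))
  expect_error(worst_survivor_index(cens, "experimental"), "no events")
})

test_that("extreme-survivor selection matches exhaustive scans on seeded arms", {
  set.seed(401)
  for (rep in 1:5) {
    n <- 1000
    time <- round(stats::rexp(n), 2)  # rounding forces ties
    event <- stats::rbinom(n, 1, 0.7)
    arm <- sample(c("experimental", "control"), n, replace = TRUE)
    d <- survival_dataset(time, event, arm)
    for (a in c("experimental", "control")) {
      idx <- which(arm == a)
      tmax <- max(time[idx])
      cand <- idx[time[idx] == tmax]
      want <- if (any(event[cand] == 0)) min(cand[event[cand] == 0])
              else min(cand)
      expect_identical(best_survivor_index(d, a), want)
      ev <- idx[event[idx] == 1]
      expect_identical(worst_survivor_index(d, a),
                       min(ev[time[ev] == min(time[ev])]))
    }
  }
})

test_that("sign follows initial significance and identical arms go negative", {
  d <- survival_dataset(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                        rep(c("experimental", "control"), each = 3))
  res <- sifi_all_variants(d)
  for (r in res) {
    expect_lt(r$value, 0)
    expect_equal(r$p_initial, 1)
    expect_equal(tail(r$p_trajectory, 1) < r$alpha, !r$exhausted)
  }
  expect_length(unique(vapply(res, function(r) r$p_initial, 0)), 1)
})

test_that("trajectory crosses exactly at the final move, on either side", {
  for (seed in c(21, 22, 23, 24)) {
    d <- simulate_trial(n = 150 + (seed %% 2) * 50, beta = -0.6 + 0.2 * (seed %% 3),
                        seed = seed)
    for (variant in c("flip_best", "flip_worst", "clone_best", "clone_worst")) {
      r <- compute_sifi(d, variant = variant)
      k <- abs(r$value)
      expect_length(r$p_trajectory, k)
      expect_false(r$exhausted)
      if (r$value > 0) {
        expect_true(r$p_initial < r$alpha)
        if (k > 1) expect_true(all(r$p_trajectory[1:(k - 1)] < r$alpha))
        expect_gte(r$p_trajectory[k], r$alpha)
      } else {
        expect_true(r$p_initial >= r$alpha)
        if (k > 1) expect_true(all(r$p_trajectory[1:(k - 1)] >= r$alpha))
        expect_lt(r$p_trajectory[k], r$alpha)
      }
    }
  }
})

test_that("flip conserves subject count, clone grows it by |value|", {
  d <- make_significant(31)
  for (variant in c("flip_best", "flip_worst")) {
    r <- compute_sifi(d, variant = variant)
    expect_equal(r$n_final, r$n_initial)
  }
  for (variant in c("clone_best", "clone_worst")) {
    r <- compute_sifi(d, variant = variant)
    expect_equal(r$n_final, r$n_initial + abs(r$value))
  }
})

test_that("identical input yields identical results (no hidden randomness)", {
  d <- make_significant(55)
  a <- compute_sifi(d, variant = "clone_best")
  b <- compute_sifi(d, variant = "clone_best")
  expect_identical(a, b)
})

test_that("flip SIFI equals the from-scratch prefix oracle", {
  # exponential arms, hazard ratio 3, no censoring, n = 60 per arm
  d <- make_significant(77, n_per_arm = 60, hr = 3)
  r <- compute_sifi(d, variant = "flip_best")
  expect_identical(r$value, prefix_oracle_flip(d, "flip_best"))
  r2 <- compute_sifi(d, variant = "flip_worst")
  expect_identical(r2$value, prefix_oracle_flip(d, "flip_worst"))
})

test_that("all four p_initial agree and variants run independently", {
  d <- make_significant(91, cens = 0.3)
  res <- sifi_all_variants(d)
  p0 <- vapply(res, function(r) r$p_initial, 0)
  expect_equal(unname(diff(range(p0))), 0)
  expect_named(res, c("flip_best", "flip_worst", "clone_best", "clone_worst"))
})

test_that("literal flip_worst direction strengthens a positive result", {
  # moving the experimental arm's earliest event to control improves the
  # experimental curve, so significance is typically never lost: the run
  # must terminate via the exhaustion flag rather than a crossing
  d <- make_significant(13, n_per_arm = 40, hr = 3)
  r <- compute_sifi(d, variant = "flip_worst", literal_directions = TRUE,
                    max_iterations = 25)
  expect_true(r$exhausted)
  expect_true(all(r$p_trajectory < 0.05))
})

test_that("exhaustion is flagged when the iteration cap stops the search", {
  d <- make_significant(14, n_per_arm = 80, hr = 4)
  r <- compute_sifi(d, max_iterations = 1)
  expect_true(r$exhausted)
  expect_equal(abs(r$value), 1)
})
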