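test_that("Poisson-binomial density is a proper distribution", {
  withr::local_seed(101)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    probs <- runif(n)
    f <- pb_density(probs)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
    expect_equal(length(f), n + 1)
  }
})

test_that("Poisson-binomial tail matches 2^n brute-force enumeration", {
  withr::local_seed(202)
  for (rep in 1:12) {
    n <- sample(1:12, 1)
    probs <- runif(n)
    x <- sample(0:n, 1)
    expect_equal(pb_upper_tail(probs, x), bf_pb_upper(probs, x),
                 tolerance = 1e-12)
  }
  # plus the fixture profiles themselves
  for (k in fixture_k_profiles()) {
    probs <- k / 4
    for (x in c(0, length(k) %/% 2, length(k))) {
      expect_equal(pb_upper_tail(probs, x), bf_pb_upper(probs, x),
                   tolerance = 1e-12)
    }
  }
})

test_that("equal probabilities reduce the Poisson-binomial to the binomial", {
  for (x in 0:12) {
    expect_equal(pb_upper_tail(rep(0.25, 12), x),
                 binom_upper_tail(x, 12, 0.25), tolerance = 1e-12)
  }
  expect_equal(pb_upper_tail(1, 1), 1)  # forced success
  expect_equal(pb_upper_tail(numeric(0), 0), 1)
})

test_that("Poisson-binomial rejects invalid domains", {
  expect_error(pb_density(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(pb_upper_tail(c(0.5, 0.5), 3), "0 <= x")
  expect_error(pb_upper_tail(c(0.5, 0.5), -1), "0 <= x")
})

test_that("the free-selection null validates its k-profile", {
  null <- free_selection_null(c(4, 2, 1), m = 4)
  expect_s3_class(null, "free_selection_null")
  expect_equal(null$inclusion_probs, c(1, 0.5, 0.25))
  expect_error(free_selection_null(c(0, 1)), "1 <= k <= m")
  expect_error(free_selection_null(c(5, 1), m = 4), "1 <= k <= m")
  expect_error(free_selection_null(c(1, 1), m = 1), "m must be")
})

test_that("exact free-selection tails reproduce the compartment results", {
  prof <- fixture_k_profiles()
  # Maria-Magdalena: prints as 0.094
  mm <- free_selection_test(free_selection_null(prof[["Maria-Magdalena"]]), 7)
  expect_equal(mm$p_value, 0.09362793, tolerance = 1e-7)
  expect_equal(format_p(mm$p_value), "0.094")
  # Manda: every trial must include the target, so the tail is the product
  # of the inclusion probabilities
  manda <- free_selection_test(free_selection_null(prof[["Manda"]]), 12)
  expect_equal(manda$p_value, prod(prof[["Manda"]] / 4), tolerance = 1e-12)
  expect_equal(manda$p_value, 8.583069e-6, tolerance = 1e-6)
  # Naong: seven singleton removals and one pair
  naong <- free_selection_test(free_selection_null(prof[["Naong"]]), 7)
  expect_equal(naong$p_value, 7.019043e-4, tolerance = 1e-6)
})

test_that("a unit k-profile collapses the free test to the exact binomial", {
  null <- free_selection_null(rep(1, 9), m = 4)
  for (x in 0:9) {
    expect_equal(free_selection_test(null, x)$p_value,
                 binom_upper_tail(x, 9, 0.25), tolerance = 1e-12)
  }
})

test_that("Monte Carlo selection p-values sit within 3 SE of the exact tail", {
  prof <- fixture_k_profiles()
  observed <- list(`Maria-Magdalena` = 7, Manda = 12, Naong = 7)
  for (s in names(observed)) {
    null <- free_selection_null(prof[[s]])
    exact <- free_selection_test(null, observed[[s]])$p_value
    mc <- free_selection_test(null, observed[[s]], method = "monte_carlo",
                              n_sims = 50000, seed = 11)
    # the replicate hit count is Binomial(n_sims, exact); demand it inside
    # the central 99.7% band (equivalent to +/- 3 SE for moderate tails and
    # correctly skewed for the very small ones)
    hits <- round(mc$p_value * 50000)
    expect_gte(hits, qbinom(0.0015, 50000, exact))
    expect_lte(hits, qbinom(0.9985, 50000, exact))
    expect_equal(mc$method, "monte_carlo")
    expect_equal(mc$n_sims, 50000L)
    expect_equal(mc$seed, 11L)
  }
})

test_that("Monte Carlo draws are reproducible given the seed", {
  null <- free_selection_null(c(2, 1, 3, 1, 1))
  a <- free_selection_test(null, 3, method = "monte_carlo", n_sims = 2000,
                           seed = 99)
  b <- free_selection_test(null, 3, method = "monte_carlo", n_sims = 2000,
                           seed = 99)
  expect_identical(tidy(a), tidy(b))
  expect_error(free_selection_test(null, 3, method = "monte_carlo"),
               "seed")
})

test_that("simulated inclusion frequencies track k/m and the count mean", {
  prof <- fixture_k_profiles()
  null <- free_selection_null(prof[["Maria-Magdalena"]])
  counts <- simulate_retrieval_counts(null, 50000, seed = 5)
  mu <- sum(null$inclusion_probs)            # 4.5 for this profile
  expect_equal(mu, 4.5)
  sd_mean <- sqrt(sum(null$inclusion_probs * (1 - null$inclusion_probs)) / 50000)
  expect_lt(abs(mean(counts) - mu), 3 * sd_mean)
  # a trial with k = m is always included
  inc <- simulate_free_selection(free_selection_null(c(4, 1)), 500, seed = 6)
  expect_true(all(inc[, 1]))
  # empty profile
  expect_equal(ncol(simulate_free_selection(
    free_selection_null(integer(0)), 5, seed = 1)), 0)
})

test_that("joint behaviour test reduces to Binomial(n, 1/m) exactly", {
  prof <- fixture_k_profiles()
  mm <- joint_behavior_test(free_selection_null(prof[["Maria-Magdalena"]]), 12)
  expect_equal(mm$p_value, 0.25^12, tolerance = 1e-12)
  naong <- joint_behavior_test(free_selection_null(prof[["Naong"]]), 7)
  expect_equal(naong$p_value, binom_upper_tail(7, 8, 0.25), tolerance = 1e-12)
  expect_equal(naong$p_value, 3.814697e-4, tolerance = 1e-6)
  # the per-trial probability is 1/m regardless of the k-profile
  skew <- joint_behavior_test(free_selection_null(c(4, 3, 2, 1)), 2)
  expect_equal(skew$p_value, binom_upper_tail(2, 4, 0.25), tolerance = 1e-12)
  # zero observed: whole support
  expect_equal(joint_behavior_test(
    free_selection_null(c(1, 1)), 0)$p_value, 1)
})

test_that("joint Monte Carlo agrees with its exact branch for both policies", {
  null <- free_selection_null(c(3, 3, 2, 2, 1, 1, 2, 1, 1, 2, 1, 1))
  for (policy in c("always_offer", "offer_or_refuse")) {
    for (obs in c(4, 6)) {
      exact <- joint_behavior_test(null, obs, offer_policy = policy)$p_value
      mc <- joint_behavior_test(null, obs, method = "monte_carlo",
                                offer_policy = policy, n_sims = 50000,
                                seed = 21)$p_value
      se <- sqrt(exact * (1 - exact) / 50000)
      expect_lt(abs(mc - exact), 3 * se + 1e-12)
    }
  }
})

test_that("offer-or-refuse policy has per-trial probability 1/(k+1)", {
  null <- free_selection_null(c(1, 2, 4))
  res <- joint_behavior_test(null, 3, offer_policy = "offer_or_refuse")
  expect_equal(res$p_value, (1 / 2) * (1 / 3) * (1 / 5), tolerance = 1e-12)
})

test_that("the add-one estimator never reports an exact zero", {
  null <- free_selection_null(rep(1, 12))
  mc <- free_selection_test(null, 12, method = "monte_carlo", n_sims = 2000,
                            seed = 3, estimator = "add_one")
  expect_gt(mc$p_value, 0)
})

test_that("observed counts outside the profile are rejected", {
  null <- free_selection_null(c(1, 1, 1))
  expect_error(free_selection_test(null, 4), "between 0")
  expect_error(joint_behavior_test(null, 4), "between 0")
})
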