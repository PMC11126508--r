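test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_children = 300, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # end states of the public path simulator are reproducible too
  q <- default_band_intensities()[[1]]$q
  set.seed(4); s1 <- replicate(20, simulate_ctmc_path(q, 0, 5, 2))
  set.seed(4); s2 <- replicate(20, simulate_ctmc_path(q, 0, 5, 2))
  expect_identical(s1, s2)
})

test_that("degenerate configurations behave exactly", {
  # zero attrition: every child keeps all waves
  pan <- simulate_cohort(clean_config(100, seed = 2))
  expect_true(all(table(pan$child_id) == 6))

  # all-healthy baseline with zero intensities stays healthy
  zero_q <- intensity_matrix(rep(0, 6))
  cfg <- clean_config(50, seed = 3,
                      bands = list(list(age_from = 3, age_to = 17,
                                        q = zero_q)),
                      baseline = c(0, 1, 0, 0))
  pan0 <- simulate_cohort(cfg)
  expect_true(all(pan0$state == 2))

  # absorbing path: zero generator keeps the starting state
  expect_equal(simulate_ctmc_path(zero_q, 0, 10, 3), 3L)
})

test_that("holding times are exponential: single-exit escape probability", {
  q <- intensity_matrix(c(0, 0, 0.03, 0, 0, 0))  # healthy -> overweight only
  set.seed(8)
  ends <- replicate(10000, simulate_ctmc_path(q, 0, 2, 2))
  p_true <- 1 - exp(-0.06)
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(mean(ends != 2) - p_true), 3 * mc_se)
})

test_that("empirical wave-to-wave transitions match expm of the generator", {
  pan <- simulate_cohort(clean_config(20000, seed = 6))
  q <- default_band_intensities()[[1]]$q
  P <- transition_probability_matrix(q, 2)  # ages 3 -> 5
  w1 <- pan[round(pan$age) == 3, ]
  w2 <- pan[round(pan$age) == 5, ]
  s1 <- w1$state[match(w2$child_id, w1$child_id)]
  # 12 simultaneous 3-SE checks: allow a single boundary excursion, but
  # nothing beyond 4 SEs
  z <- c()
  for (r in 2:4) {  # states with enough occupants at baseline
    n_r <- sum(s1 == r)
    for (s in 1:4) {
      phat <- mean(w2$state[s1 == r] == s)
      se <- sqrt(max(P[r, s] * (1 - P[r, s]), 1e-6) / n_r)
      z <- c(z, abs(phat - P[r, s]) / se)
    }
  }
  expect_lte(sum(z > 3), 1)
  expect_true(all(z < 4))
})

test_that("design weights undo oversampling in expectation", {
  # inverse-probability definition
  expect_equal(assign_design_weights(c("a", "b", "a")), rep(1, 3))
  w <- assign_design_weights(rep(c("over", "base"), each = 2),
                             c(over = 2))
  expect_equal(w[1] / w[3], 0.5)  # twice the sampling rate, half the weight
  expect_error(assign_design_weights("a", c(a = -1)), "positive")

  # Horvitz-Thompson recovery over 200 replications
  set.seed(15)
  pi_pop <- 0.3; f <- 2
  pi_samp <- pi_pop * f / (pi_pop * f + (1 - pi_pop))
  est <- replicate(200, {
    g <- rbinom(500, 1, pi_samp)
    w <- assign_design_weights(ifelse(g == 1, "d", "n"), c(d = f))
    sum(w * g) / sum(w)
  })
  expect_lt(abs(mean(est) - pi_pop), 3 * sd(est) / sqrt(200))
})

test_that("weighted prevalence is oversampling-invariant; unweighted is not", {
  cfg <- sim_config(n_children = 8000, wave_ages = c(3, 5),
                    age_jitter_sd = 0,
                    band_intensities = default_band_intensities()[1],
                    attrition_rate = 0, missing_covariate_rate = 0,
                    n_strata = 3, n_clusters = 24, seed = 44)
  pan <- simulate_cohort(cfg)
  first <- pan[!duplicated(pan$child_id), ]
  p_w <- sum(first$weight * first$disadvantaged) / sum(first$weight)
  p_u <- mean(first$disadvantaged)
  pi_pop <- 0.30
  pi_samp <- pi_pop * 2 / (pi_pop * 2 + (1 - pi_pop))
  se <- sqrt(pi_samp * (1 - pi_samp) / nrow(first))
  expect_lt(abs(p_w - pi_pop), 4 * se)     # weighted recovers the population
  expect_gt(abs(p_u - pi_pop), 10 * se)    # unweighted sits at the sample rate
  expect_lt(abs(p_u - pi_samp), 4 * se)
})

test_that("attrition is monotone and masked covariates hit the configured rate", {
  cfg <- sim_config(n_children = 3000, seed = 17, age_jitter_sd = 0,
                    attrition_rate = 0.2, missing_covariate_rate = 0.15,
                    oversample = numeric(),
                    covariate_effects = list(sex = rep(0, 6),
                                             disadvantaged = rep(0, 6)))
  pan <- simulate_cohort(cfg)
  # once gone, gone: observed waves per child are an initial segment
  waves <- c(3, 5, 7, 11, 14, 17)
  for (id in unique(pan$child_id)[1:200]) {
    a <- round(pan$age[pan$child_id == id])
    expect_equal(a, waves[seq_along(a)])
  }
  first <- pan[!duplicated(pan$child_id), ]
  miss <- mean(is.na(first$sex))
  expect_lt(abs(miss - 0.15), 3 * sqrt(0.15 * 0.85 / nrow(first)))
})

test_that("bands must cover the wave span", {
  expect_error(sim_config(wave_ages = c(3, 18)), "cover")
  expect_error(sim_config(band_intensities = list(
    list(age_from = 3, age_to = 5, q = intensity_matrix(rep(0.1, 6))),
    list(age_from = 6, age_to = 17, q = intensity_matrix(rep(0.1, 6))))),
    "contiguous")
})
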