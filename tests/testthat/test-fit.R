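test_that("panel MLE matches the closed form in a two-state reduction", {
  # only healthy -> overweight allowed, equal 1-year intervals:
  # qhat = -log(weighted stay fraction)
  s <- matrix(FALSE, 4, 4,
              dimnames = list(names(weight_states()), names(weight_states())))
  s[2, 3] <- TRUE
  class(s) <- c("transition_structure", class(s))

  set.seed(12)
  n <- 400
  w <- runif(n, 0.5, 2)
  stay <- runif(n) < 0.9
  p <- data.frame(child_id = rep(1:n, each = 2), age = rep(c(6, 7), n),
                  state = c(rbind(rep(2, n), ifelse(stay, 2, 3))),
                  weight = rep(w, each = 2))
  f <- fit_msm(p, structure = s, control = list(reltol = 1e-12))
  expect_true(f$converged)
  p_stay <- sum(w[stay]) / sum(w)
  expect_equal(exp(unname(f$log_q)), -log(p_stay), tolerance = 1e-4)
})

test_that("constant weights are a no-op for point estimates", {
  pan <- simulate_cohort(clean_config(600, seed = 31, wave_ages = c(3, 5),
                                      bands = default_band_intensities()[1],
                                      n_strata = 2, n_clusters = 8))
  f_on <- fit_msm(pan, weights = "on", control = list(reltol = 1e-10))
  pan2 <- pan; pan2$weight <- NULL
  f_off <- fit_msm(pan2, control = list(reltol = 1e-10))
  expect_equal(f_on$log_q, f_off$log_q, tolerance = 1e-6)
})

test_that("an all-zero covariate changes no estimate", {
  pan <- simulate_cohort(clean_config(600, seed = 9, wave_ages = c(3, 5),
                                      bands = default_band_intensities()[1],
                                      n_strata = 2, n_clusters = 8))
  pan$zero <- 0
  ctl <- list(reltol = 1e-12)
  f1 <- fit_msm(pan, control = ctl)
  f2 <- fit_msm(pan, covariates = "zero", control = ctl)
  expect_equal(f1$log_q, f2$log_q, tolerance = 1e-8)
})

test_that("simulated intensities are recovered and scale with covariates", {
  cfg <- sim_config(n_children = 4000, wave_ages = c(3, 5),
                    age_jitter_sd = 0,
                    band_intensities = default_band_intensities()[1],
                    covariate_probs = list(sex = 0.5),
                    covariate_effects = list(sex = c(0, 0, log(1.5), 0, 0, 0)),
                    oversample = numeric(), attrition_rate = 0,
                    missing_covariate_rate = 0,
                    n_strata = 3, n_clusters = 24, seed = 77)
  pan <- simulate_cohort(cfg)
  f <- fit_msm(pan, covariates = "sex")
  expect_true(f$converged)

  hr <- hazard_ratios(f)
  hr23 <- hr$hr[hr$transition == "healthy-overweight"]
  expect_gt(hr23, 1)                       # sign consistency with beta > 0
  expect_equal(hr$hr, exp(hr$log_hr))
  rw <- jackknife_replicates(panel_design(pan))
  reps <- msm_replicate_fits(f, pan, rw)
  se <- replicate_variance(f$beta[3, 1], reps$par[, 9], reps$meta)
  expect_lt(abs(f$beta[3, 1] - log(1.5)), 3 * se)

  # common intensities near truth (generous band for a single replicate)
  truth <- intensity_rates(default_band_intensities()[[1]]$q)
  for (j in c(3, 4, 5, 6)) {
    sej <- replicate_variance(f$log_q[j], reps$par[, j], reps$meta)
    expect_lt(abs(f$log_q[j] - log(truth[j])), 3 * sej)
  }
})

test_that("annual probabilities obey Chapman-Kolmogorov and gating", {
  pan <- simulate_cohort(clean_config(800, seed = 13, wave_ages = c(3, 5),
                                      bands = default_band_intensities()[1],
                                      n_strata = 2, n_clusters = 8))
  f <- fit_msm(pan)
  p1 <- annual_probabilities(f)
  p2 <- transition_probability_matrix(fitted_intensities(f), 2)
  expect_equal(unclass(p1 %*% p1), unclass(p2), ignore_attr = TRUE,
               tolerance = 1e-10)

  f_bad <- f; f_bad$converged <- FALSE
  expect_error(annual_probabilities(f_bad), "converge")
  expect_error(hazard_ratios(f_bad), "converge")
})

test_that("covariate levels with no observed transitions are named in a warning", {
  p <- data.frame(child_id = rep(1:20, each = 2), age = rep(c(3, 5), 20),
                  state = c(rbind(rep(2, 20), c(rep(3, 5), rep(2, 15)))),
                  weight = 1,
                  eth = rep(c("white", "other"), c(10, 30)))
  # all five movers are in the "white" group; "other" has no transitions
  p$state[p$eth == "other"] <- 2
  expect_warning(fit_msm(p, covariates = "eth", control = list(maxit = 5)),
                 "other")
})

test_that("merge_levels recodes explicitly and only on request", {
  p <- data.frame(child_id = c(1, 1), age = c(3, 5), state = c(2, 2),
                  weight = 1, eth = c(3, 2))
  p2 <- merge_levels(p, "eth", c(`3` = 2))
  expect_equal(p2$eth, c(2, 2))
  expect_equal(merge_levels(p, "eth", c(`9` = 1))$eth, p$eth)
})
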