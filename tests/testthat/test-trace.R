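identity_schedule <- function(a0 = 3, a1 = 18) {
  matrix_schedule(list(list(age_from = a0, age_to = a1, P = diag(4))))
}

test_that("identity matrices leave the occupancy at baseline", {
  b <- c(0.1, 0.6, 0.2, 0.1)
  tr <- markov_trace(b, identity_schedule(), 3, 18)
  expect_equal(nrow(tr), 16)
  for (k in seq_len(nrow(tr))) {
    expect_equal(as.numeric(tr[k, ]), b)
  }
})

test_that("two cycles of a simple matrix reproduce hand arithmetic", {
  P <- diag(4)
  P[2, 2] <- 0.9; P[2, 3] <- 0.1
  P[3, 3] <- 0.95; P[3, 2] <- 0.05
  sch <- matrix_schedule(list(list(age_from = 3, age_to = 18, P = P)))
  tr <- markov_trace(c(0, 1, 0, 0), sch, 3, 5)
  # healthy after 2 cycles: 0.9^2 + 0.1 * 0.05 (return flow)
  expect_equal(tr[3, "healthy"], 0.9^2 + 0.1 * 0.05, tolerance = 1e-12)
  expect_equal(tr[3, "overweight"], 0.9 * 0.1 + 0.1 * 0.95,
               tolerance = 1e-12)
})

test_that("traces conserve mass and compose associatively", {
  sch <- mcs_schedule()
  tr <- suppressMessages(markov_trace(c(0.05, 0.7, 0.15, 0.1), sch, 3, 18))
  expect_equal(rowSums(unclass(tr)), rep(1, 16), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_true(all(tr >= 0 & tr <= 1))

  # yearly multiplication equals per-band matrix powers composed once
  b <- c(0, 1, 0, 0)
  step <- b
  for (e in sch$entries) {
    step <- step %*% (diag(4) %*% .pow(e$P, e$age_to - e$age_from))
  }
  tr2 <- suppressMessages(markov_trace(b, sch, 3, 17))
  expect_equal(as.numeric(tr2[nrow(tr2), ]), as.numeric(step),
               tolerance = 1e-10)
})

test_that("a state with zero inflow never gains occupancy", {
  P <- diag(4)
  P[1, 1] <- 0.8; P[1, 2] <- 0.2   # underweight only drains
  sch <- matrix_schedule(list(list(age_from = 3, age_to = 18, P = P)))
  tr <- markov_trace(c(0.3, 0.5, 0.1, 0.1), sch, 3, 12)
  expect_true(all(diff(tr[, 1]) <= 1e-12))
})

test_that("the schedule extension beyond the last band is announced", {
  expect_message(markov_trace(c(0, 1, 0, 0), mcs_schedule(), 3, 18),
                 "extended")
  expect_silent(markov_trace(c(0, 1, 0, 0), mcs_schedule(), 3, 17))
  short <- matrix_schedule(list(list(age_from = 5, age_to = 7, P = diag(4))))
  expect_error(markov_trace(c(0, 1, 0, 0), short, 3, 10), "not covered")
})

test_that("weighted cohort expansion replicates children by normalised weight", {
  pan <- data.frame(child_id = 1:4, state = c(2, 2, 3, 4), weight = 1)
  ex <- expand_validation_cohort(pan, 100)
  expect_equal(ex$counts, rep(100, 4))      # equal weights: 100 each

  pan2 <- data.frame(child_id = 1:2, state = c(2, 3), weight = c(1, 3))
  ex2 <- expand_validation_cohort(pan2, 100)
  expect_equal(ex2$counts, c(50, 150))

  # a cohort constructed with the published baseline mix reproduces it
  n_per <- c(78, 7270, 1590, 1063)
  pan3 <- data.frame(child_id = seq_len(sum(n_per)),
                     state = rep(1:4, n_per), weight = 1)
  ex3 <- expand_validation_cohort(pan3, 100)
  # the printed percentages sum to 100.01, so agreement is to print precision
  expect_lt(max(abs(100 * ex3$baseline - c(0.78, 72.70, 15.90, 10.63))),
            0.01)
})

test_that("predicted-to-observed ratios are 1 under agreement, NA at zero", {
  sch <- mcs_schedule()
  tr <- suppressMessages(markov_trace(c(0, 1, 0, 0), sch, 3, 17))
  obs <- unclass(tr)[match(c(3, 5, 7, 11), as.numeric(rownames(tr))), ]
  rownames(obs) <- c(3, 5, 7, 11)
  po <- predicted_vs_observed(tr, obs)
  # ratios are 1 wherever defined; undefined only where nothing was observed
  expect_equal(po$ratio[!is.na(po$ratio)],
               rep(1, sum(!is.na(po$ratio))), tolerance = 1e-12)
  expect_true(all(po$observed[is.na(po$ratio)] == 0))
  expect_gt(sum(!is.na(po$ratio)), 10)

  obs0 <- obs; obs0[1, 1] <- 0; obs0[1, ] <- obs0[1, ] / sum(obs0[1, ])
  po0 <- predicted_vs_observed(tr, obs0)
  expect_true(is.na(po0$ratio[po0$age == 3 & po0$state == "underweight"]))
  expect_false(any(is.infinite(po0$ratio), na.rm = TRUE))
})

test_that("misspecified time-homogeneous schedules drift at later waves", {
  # observed prevalence follows the age-varying published matrices; a
  # schedule freezing the first band's matrix must drift with age
  sch <- mcs_schedule()
  tr_true <- suppressMessages(markov_trace(c(0, 1, 0, 0), sch, 3, 17))
  waves <- c(3, 5, 7, 11, 14, 17)
  obs <- unclass(tr_true)[match(waves, as.numeric(rownames(tr_true))), ]
  rownames(obs) <- waves

  hom <- matrix_schedule(list(list(age_from = 3, age_to = 17,
                                   P = sch$entries[[1]]$P)))
  tr_hom <- markov_trace(c(0, 1, 0, 0), hom, 3, 17)
  po <- predicted_vs_observed(tr_hom, obs)
  dev <- abs(po$ratio - 1)
  early <- mean(dev[po$age == 5], na.rm = TRUE)
  late <- mean(dev[po$age == 17], na.rm = TRUE)
  expect_gt(late, early)

  cmp <- compare_scenarios(list(true_model = tr_true, frozen = tr_hom), obs)
  expect_equal(cmp$model[1], "true_model")
  expect_lt(cmp$mae[1], cmp$mae[2])

  # identical traces tie
  cmp2 <- compare_scenarios(list(a = tr_hom, b = tr_hom), obs)
  expect_equal(cmp2$mae[1], cmp2$mae[2])
})

test_that("trace CSV export is faithful", {
  tr <- markov_trace(c(0, 1, 0, 0), identity_schedule(), 3, 6)
  path <- file.path(tempdir(), "trace.csv")
  write_trace(tr, path)
  df <- read.csv(path)
  expect_equal(names(df),
               c("age", "p_underweight", "p_healthy", "p_overweight",
                 "p_obesity"))
  expect_equal(df$p_healthy, rep(1, 4))
  unlink(path)
})
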