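test_that("smallest legal design: two clusters, delete-one doubling", {
  d <- survey_design(1:6, stratum = 1, cluster = rep(c(1, 2), each = 3),
                     weight = c(1, 2, 3, 1, 1, 2))
  rw <- jackknife_replicates(d)
  expect_equal(ncol(rw$weights), 2)
  # replicate 1 deletes cluster 1: its children zeroed, cluster 2 doubled
  expect_equal(rw$weights[, 1], c(0, 0, 0, 2, 2, 4), ignore_attr = TRUE)
  expect_equal(rw$weights[, 2], c(2, 4, 6, 0, 0, 0), ignore_attr = TRUE)
})

test_that("a 9-stratum, 398-cluster design yields 398 total-preserving replicates", {
  # balanced design: equal children per cluster, weights constant within
  # stratum, so the n_h/(n_h-1) rescaling preserves stratum totals exactly
  cluster_stratum <- rep(1:9, length.out = 398)
  psu <- rep(1:398, each = 5)
  strat <- cluster_stratum[psu]
  w_strat <- seq(0.4, 2, length.out = 9)
  d <- survey_design(seq_along(psu), stratum = strat, cluster = psu,
                     weight = w_strat[strat])
  rw <- jackknife_replicates(d)
  expect_equal(ncol(rw$weights), 398)
  expect_equal(nrow(rw$meta), 398)
  base_tot <- tapply(d$weight, d$stratum, sum)
  for (r in seq(1, 398, by = 23)) {
    rep_tot <- tapply(rw$weights[, r], d$stratum, sum)
    expect_equal(rep_tot, base_tot, tolerance = 1e-12)
  }
  # construction is deterministic
  expect_identical(rw$weights, jackknife_replicates(d)$weights)
})

test_that("singleton-cluster strata are refused by name", {
  expect_error(survey_design(1:4, stratum = c(1, 1, 2, 2),
                             cluster = c(1, 2, 3, 3), weight = 1),
               "2")
})

test_that("replicate variance matches the textbook JKn formula end-to-end", {
  set.seed(33)
  n <- 40
  cl <- rep(1:8, each = 5)
  w <- runif(n, 0.5, 2)
  y <- rnorm(n, 5, 2)
  d <- survey_design(1:n, stratum = 1, cluster = cl, weight = w)
  rw <- jackknife_replicates(d)
  wmean <- function(wt) sum(wt * y) / sum(wt)
  full <- wmean(w)
  reps <- apply(rw$weights, 2, wmean)
  se <- replicate_variance(full, reps, rw$meta)

  # independent textbook computation: delete each cluster, rescale by
  # n_h/(n_h-1), and apply v = ((n_h-1)/n_h) sum_j (theta_(j) - theta)^2
  theta_j <- vapply(1:8, function(j) {
    keep <- cl != j
    sum(w[keep] * y[keep] * 8 / 7) / sum(w[keep] * 8 / 7)
  }, numeric(1))
  v <- (7 / 8) * sum((theta_j - full)^2)
  expect_equal(se, sqrt(v), tolerance = 1e-12)

  # all replicates equal to the full estimate: se = 0 is legal
  expect_equal(replicate_variance(full, rep(full, 8), rw$meta), 0)
})

test_that("JKn with one child per cluster reduces to the classic jackknife", {
  set.seed(34)
  n <- 30
  y <- rnorm(n)
  d <- survey_design(1:n, stratum = 1, cluster = 1:n, weight = 1)
  rw <- jackknife_replicates(d)
  reps <- apply(rw$weights, 2, function(wt) sum(wt * y) / sum(wt))
  se <- replicate_variance(mean(y), reps, rw$meta)
  loo <- vapply(1:n, function(i) mean(y[-i]), numeric(1))
  se_classic <- sqrt(((n - 1) / n) * sum((loo - mean(loo))^2))
  expect_equal(se, se_classic, tolerance = 1e-12)
})

test_that("failed replicates are dropped up to 5% then refused", {
  meta <- data.frame(replicate = 1:40, stratum = 1, cluster = 1:40, n_h = 40)
  reps <- rnorm(40, 1, 0.1)
  se_ok <- replicate_variance(1, reps, meta)
  reps_na <- reps; reps_na[1] <- NA
  expect_gt(replicate_variance(1, reps_na, meta), 0)  # 2.5% failed: tolerated
  reps_bad <- reps; reps_bad[1:3] <- NA               # 7.5% failed
  expect_error(replicate_variance(1, reps_bad, meta), "refusing")
})

test_that("interval construction follows the declared scales", {
  ie <- interval_estimate(0.5, 0, "identity")
  expect_equal(c(ie$ci_low, ie$ci_high), c(0.5, 0.5))  # degenerate

  ie <- interval_estimate(1.5, 0.1, "log")
  expect_equal(ie$ci_low, 1.5 * exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(ie$ci_high, 1.5 * exp(qnorm(0.975) * 0.1), tolerance = 1e-12)

  ie <- interval_estimate(0.001, 0.5, "probability")
  expect_equal(ie$ci_low, 0)                            # clipped
  expect_lte(ie$ci_high, 1)
})

test_that("JKn intervals for a weighted mean attain nominal coverage", {
  set.seed(55)
  n <- 100; n_cl <- 25
  cover <- replicate(500, {
    cl <- rep(seq_len(n_cl), each = n / n_cl)
    w <- runif(n, 0.5, 2)
    y <- rnorm(n, 10, 3)
    d <- survey_design(seq_len(n), 1, cl, w)
    rw <- jackknife_replicates(d)
    full <- sum(w * y) / sum(w)
    reps <- apply(rw$weights, 2, function(wt) sum(wt * y) / sum(wt))
    se <- replicate_variance(full, reps, rw$meta)
    ie <- interval_estimate(full, se, "identity")
    ie$ci_low <= 10 && 10 <= ie$ci_high
  })
  expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / 500))
})

test_that("replicate weights survive a CSV round trip", {
  d <- survey_design(1:6, stratum = 1, cluster = rep(c(1, 2), each = 3),
                     weight = c(1, 2, 3, 1, 1, 2))
  rw <- jackknife_replicates(d)
  path <- file.path(tempdir(), "rw.csv")
  write_replicate_weights(rw, path)
  rt <- read_replicate_weights(path)
  expect_equal(unname(rt$weights), unname(rw$weights))
  expect_equal(rt$meta$n_h, rw$meta$n_h)
  unlink(c(path, paste0(path, ".meta.json")))
})
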