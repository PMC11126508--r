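#' Default age-band generating intensities
#'
#' Per-year transition intensities for five age bands (3-5, 5-7, 7-11,
#' 11-14, 14-17), used as the synthetic cohort generator's ground truth.
#' They are rounded matrix logarithms of the published annual transition
#' matrices (see [mcs_annual_probabilities()]), so the generator reproduces
#' the empirical age gradient: young children move between healthy weight
#' and overweight far more readily than older children, and resolution of
#' excess weight declines even more steeply with age.
#'
#' @return List of bands, each `list(age_from, age_to, q)` with `q` an
#'   [intensity_matrix()].
#' @export
default_band_intensities <- function() {
  mk <- function(a0, a1, r) list(age_from = a0, age_to = a1,
                                 q = intensity_matrix(r))
  list(
    mk(3, 5,   c(0.325, 0.0030, 0.040, 0.233, 0.122, 0.185)),
    mk(5, 7,   c(0.326, 0.0050, 0.032, 0.207, 0.121, 0.108)),
    mk(7, 11,  c(0.070, 0.0015, 0.015, 0.027, 0.055, 0.018)),
    mk(11, 14, c(0.101, 0.0023, 0.019, 0.082, 0.057, 0.042)),
    mk(14, 17, c(0.085, 0.0024, 0.020, 0.086, 0.078, 0.043))
  )
}

#' Synthetic cohort configuration
#'
#' Assembles (and validates) the configuration of the synthetic cohort
#' generator. Defaults emulate the structure of a large UK birth-cohort
#' panel: 10,000 children sampled through 398 clusters nested in 9 strata
#' with a 2x oversampled disadvantaged subgroup, measured at waves with mean
#' ages 3, 5, 7, 11, 14, 17 years (child-specific measurement ages jittered
#' around the wave mean), weight-state paths following a continuous-time
#' Markov chain with band-specific intensities and log-linear covariate
#' effects, monotone inter-wave attrition, and occasional missing covariate
#' values.
#'
#' @param n_children Number of sampled children.
#' @param wave_ages Mean measurement ages per wave (years, increasing).
#' @param age_jitter_sd SD (years) of child-specific measurement-age jitter
#'   around the wave mean; 0 gives nominal ages.
#' @param band_intensities List of bands as [default_band_intensities()];
#'   bands must partition the wave-age span.
#' @param baseline Baseline state distribution at the first wave (length 4,
#'   sums to 1 after normalisation). Default: the weighted baseline of the
#'   published validation cohort (0.78, 72.70, 15.90, 10.63 percent).
#' @param covariate_probs Named list of Bernoulli superpopulation
#'   prevalences for binary covariates.
#' @param covariate_effects Named list: per covariate, six log-hazard-ratios
#'   ordered as [allowed_transitions()]. The generator and the estimator
#'   share the proportional-intensities definition `q_rs(x) = q_rs
#'   exp(beta_rs' x)`, so parameter recovery is meaningful.
#' @param oversample Named length-1 numeric: sampling-rate factor for the
#'   subgroup with value 1 of the named binary covariate (1 = equal
#'   probability sampling).
#' @param attrition_rate Per-wave probability of (monotone) dropout after
#'   the first wave.
#' @param missing_covariate_rate Per-child, per-covariate probability of a
#'   masked (missing) covariate value.
#' @param n_strata,n_clusters Survey design dimensions (each stratum keeps
#'   at least two clusters).
#' @param include_bmi If `TRUE`, also emit a BMI and z-score per record,
#'   back-transformed through the bundled synthetic LMS reference.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_children = 10000,
                       wave_ages = c(3, 5, 7, 11, 14, 17),
                       age_jitter_sd = 0.15,
                       band_intensities = default_band_intensities(),
                       baseline = c(0.0078, 0.7270, 0.1590, 0.1063),
                       covariate_probs = list(sex = 0.5,
                                              disadvantaged = 0.30),
                       covariate_effects = list(
                         sex = rep(0, 6),
                         disadvantaged = c(0, 0, log(1.5), 0, log(1.3), 0)),
                       oversample = c(disadvantaged = 2),
                       attrition_rate = 0.07,
                       missing_covariate_rate = 0.05,
                       n_strata = 9, n_clusters = 398,
                       include_bmi = FALSE,
                       seed = 1L) {
  stopifnot(n_children >= 2, all(diff(wave_ages) > 0),
            attrition_rate >= 0, attrition_rate <= 1,
            missing_covariate_rate >= 0, missing_covariate_rate <= 1,
            n_strata >= 1, n_clusters >= 2 * n_strata,
            age_jitter_sd >= 0)
  baseline <- baseline / sum(baseline)
  stopifnot(length(baseline) == 4, all(baseline >= 0))
  # bands must cover [min wave age, max wave age] contiguously
  a0 <- vapply(band_intensities, `[[`, numeric(1), "age_from")
  a1 <- vapply(band_intensities, `[[`, numeric(1), "age_to")
  o <- order(a0)
  band_intensities <- band_intensities[o]; a0 <- a0[o]; a1 <- a1[o]
  if (a0[1] > min(wave_ages) || a1[length(a1)] < max(wave_ages) ||
      any(abs(a1[-length(a1)] - a0[-1]) > 1e-9)) {
    stop("band_intensities must contiguously cover the wave-age span",
         call. = FALSE)
  }
  stopifnot(all(names(covariate_effects) %in% names(covariate_probs)))
  if (length(oversample)) {
    stopifnot(length(oversample) == 1, oversample > 0,
              names(oversample) %in% names(covariate_probs))
  }
  structure(list(n_children = n_children, wave_ages = wave_ages,
                 age_jitter_sd = age_jitter_sd,
                 band_intensities = band_intensities, baseline = baseline,
                 covariate_probs = covariate_probs,
                 covariate_effects = covariate_effects,
                 oversample = oversample,
                 attrition_rate = attrition_rate,
                 missing_covariate_rate = missing_covariate_rate,
                 n_strata = n_strata, n_clusters = n_clusters,
                 include_bmi = include_bmi, seed = as.integer(seed)),
            class = "sim_config")
}

#' Exact simulation of a continuous-time Markov path
#'
#' Simulates the chain forward from `t0` to `t1` by drawing exponential
#' holding times with rate `-q[s,s]` and jump destinations with probability
#' `q[s,r] / -q[s,s]`; only structurally allowed (adjacent-state) jumps can
#' occur. Uses R's global random number stream; seed with [set.seed()].
#'
#' @param q An [intensity_matrix()].
#' @param t0,t1 Interval endpoints in years, `t1 > t0`.
#' @param state0 State at `t0` (code 1--4).
#' @return The state code at `t1`.
#' @export
simulate_ctmc_path <- function(q, t0, t1, state0) {
  q <- validate_intensity_matrix(q, tol = 1e-7)
  stopifnot(t1 > t0, state0 %in% 1:4)
  .sim_path(unclass(q), t0, t1, as.integer(state0))
}

# unvalidated inner stepper shared by the public path simulator and the
# cohort generator
.sim_path <- function(q, t0, t1, s) {
  t <- t0
  repeat {
    rate <- -q[s, s]
    if (rate <= 0) return(s)
    t <- t + stats::rexp(1, rate)
    if (t >= t1) return(s)
    p <- q[s, ]; p[s] <- 0
    s <- sample.int(4L, 1L, prob = p)
  }
}

# State at each of `times` for one child whose generator switches at band
# boundaries; `qs` is a list of 4x4 matrices aligned with bands (a0, a1).
.sim_piecewise_states <- function(qs, a0, a1, times, state0) {
  out <- integer(length(times))
  s <- as.integer(state0)
  out[1] <- s
  t <- times[1]
  for (i in seq_along(times)[-1]) {
    target <- times[i]
    while (t < target - 1e-12) {
      b <- max(1L, min(length(qs), findInterval(t + 1e-9, a0)))
      seg_end <- min(target, if (b < length(qs)) a1[b] else target)
      s <- .sim_path(qs[[b]], t, seg_end, s)
      t <- seg_end
    }
    out[i] <- s
  }
  out
}

#' Attach inverse-probability design weights for subgroup oversampling
#'
#' Given each child's subgroup membership and the per-subgroup sampling-rate
#' factors, computes design weights proportional to the inverse inclusion
#' probability (normalised to mean one). A subgroup sampled at twice the
#' base rate receives half the weight; Horvitz-Thompson weighted subgroup
#' proportions then match the superpopulation in expectation.
#'
#' @param subgroup Vector of subgroup labels, one per child.
#' @param oversample_factor Named positive numeric: sampling-rate factor per
#'   subgroup label; labels not named have factor 1.
#' @return Numeric weights, mean one.
#' @export
assign_design_weights <- function(subgroup, oversample_factor = numeric()) {
  if (length(oversample_factor) &&
      (any(!is.finite(oversample_factor)) || any(oversample_factor <= 0))) {
    stop("oversample factors must be positive", call. = FALSE)
  }
  f <- rep(1, length(subgroup))
  hit <- as.character(subgroup) %in% names(oversample_factor)
  f[hit] <- oversample_factor[as.character(subgroup)[hit]]
  w <- 1 / f
  w / mean(w)
}

#' Simulate a synthetic survey cohort with known ground truth
#'
#' Generates a long-format panel dataset according to a [sim_config()]:
#' children are sampled with subgroup oversampling (design weights
#' attached), allocated to clusters nested in strata, given a baseline state
#' and binary covariates, and moved through the age bands by exact
#' continuous-time Markov simulation with child-specific intensities
#' `q_rs exp(beta_rs' x)`. States are recorded at (jittered) wave ages;
#' waves are then dropped by monotone attrition and covariate values masked
#' at the configured rate. Children left with fewer than two observations
#' are removed (their count is recorded).
#'
#' All randomness flows from `cfg$seed`: identical configurations give
#' byte-identical datasets.
#'
#' @param cfg A [sim_config()].
#' @return A [as_panel_data()] data frame with columns `child_id`, `age`,
#'   `state`, `weight`, `stratum`, `psu` and one column per covariate
#'   (plus `bmi`, `zscore` if `include_bmi`), carrying attributes
#'   `ground_truth` (band intensities and effects) and `n_dropped_single`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_children
  covs <- names(cfg$covariate_probs)

  # -- sample covariates with oversampling of the designated subgroup
  X <- matrix(0L, n, length(covs), dimnames = list(NULL, covs))
  over_cov <- if (length(cfg$oversample)) names(cfg$oversample) else NULL
  for (cc in covs) {
    p <- cfg$covariate_probs[[cc]]
    if (identical(cc, over_cov)) {
      f <- unname(cfg$oversample)
      p <- p * f / (p * f + (1 - p))  # sample-composition prevalence
    }
    X[, cc] <- stats::rbinom(n, 1L, p)
  }
  weight <- if (is.null(over_cov)) rep(1, n) else {
    assign_design_weights(ifelse(X[, over_cov] == 1L, "over", "base"),
                          c(over = unname(cfg$oversample)))
  }

  # -- survey design: clusters nested in strata, children in clusters
  cluster_stratum <- rep(seq_len(cfg$n_strata), length.out = cfg$n_clusters)
  psu <- sample.int(cfg$n_clusters, n, replace = TRUE)
  stratum <- cluster_stratum[psu]

  # -- measurement ages
  W <- length(cfg$wave_ages)
  ages <- matrix(rep(cfg$wave_ages, each = n), n, W)
  if (cfg$age_jitter_sd > 0) {
    jit <- matrix(stats::rnorm(n * W, 0, cfg$age_jitter_sd), n, W)
    bad <- which(apply(ages + jit, 1, function(r) any(diff(r) <= 0.1)))
    while (length(bad)) {  # redraw jitter until measurement ages increase
      jit[bad, ] <- stats::rnorm(length(bad) * W, 0, cfg$age_jitter_sd)
      bad <- bad[apply((ages + jit)[bad, , drop = FALSE], 1,
                       function(r) any(diff(r) <= 0.1))]
    }
    ages <- ages + jit
    # clamp into the band span so piecewise simulation stays defined
    a_min <- cfg$band_intensities[[1]]$age_from
    a_max <- cfg$band_intensities[[length(cfg$band_intensities)]]$age_to
    ages <- pmin(pmax(ages, a_min), a_max)
  }

  # -- per-child piecewise intensities and state paths
  a0 <- vapply(cfg$band_intensities, `[[`, numeric(1), "age_from")
  a1 <- vapply(cfg$band_intensities, `[[`, numeric(1), "age_to")
  base_rates <- lapply(cfg$band_intensities,
                       function(b) intensity_rates(b$q))
  beta <- vapply(covs, function(cc) {
    e <- cfg$covariate_effects[[cc]]
    if (is.null(e)) rep(0, 6) else e
  }, numeric(6))
  state0 <- sample.int(4L, n, replace = TRUE, prob = cfg$baseline)
  states <- matrix(0L, n, W)
  # binary covariates give few distinct profiles; build each profile's band
  # generators once
  profile_key <- apply(X, 1, paste, collapse = "")
  qs_by_profile <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- profile_key[i]
    qi <- qs_by_profile[[key]]
    if (is.null(qi)) {
      mult <- exp(as.numeric(beta %*% X[i, ]))
      qi <- lapply(base_rates,
                   function(r) unclass(intensity_matrix(r * mult)))
      qs_by_profile[[key]] <- qi
    }
    states[i, ] <- .sim_piecewise_states(qi, a0, a1, ages[i, ], state0[i])
  }

  # -- monotone attrition: once gone, gone
  present <- matrix(TRUE, n, W)
  if (cfg$attrition_rate > 0) {
    for (w in 2:W) {
      present[, w] <- present[, w - 1] &
        (stats::runif(n) > cfg$attrition_rate)
    }
  }

  # -- covariate masking (per child, per covariate)
  Xout <- X
  if (cfg$missing_covariate_rate > 0) {
    mask <- matrix(stats::runif(n * length(covs)) <
                     cfg$missing_covariate_rate, n, length(covs))
    Xout[mask] <- NA_integer_
  }

  keep_wave <- which(t(present))  # row-major over (child, wave)
  child <- rep(seq_len(n), each = W)[keep_wave]
  wave <- rep(seq_len(W), times = n)[keep_wave]
  df <- data.frame(child_id = child,
                   age = ages[cbind(child, wave)],
                   state = states[cbind(child, wave)],
                   weight = weight[child],
                   stratum = stratum[child],
                   psu = psu[child])
  for (cc in covs) df[[cc]] <- Xout[child, cc]

  if (cfg$include_bmi) {
    ref <- synthetic_growth_reference()
    cuts <- stats::qnorm(c(0.02, 0.85, 0.95))
    lo <- c(-4, cuts)[df$state]
    hi <- c(cuts, 4)[df$state]
    u <- stats::runif(nrow(df))
    z <- stats::qnorm(stats::pnorm(lo) + u * (stats::pnorm(hi) -
                                                stats::pnorm(lo)))
    sex_chr <- ifelse(is.na(df$sex) | df$sex == 1L, "M", "F")
    df$zscore <- z
    df$bmi <- lms_inverse(z, pmin(df$age * 12, 216), sex_chr, ref)
  }

  nobs <- table(df$child_id)
  singles <- names(nobs)[nobs < 2]
  dropped <- length(singles)
  if (dropped) df <- df[!df$child_id %in% as.integer(singles), , drop = FALSE]

  out <- as_panel_data(df)
  attr(out, "ground_truth") <- list(band_intensities = cfg$band_intensities,
                                    covariate_effects = cfg$covariate_effects,
                                    baseline = cfg$baseline)
  attr(out, "n_dropped_single") <- dropped
  attr(out, "config") <- cfg
  out
}
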