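# Independent oracles and small fixture builders shared across tests.

# Truncated power-series matrix exponential: sum_k (M)^k / k!.
# Independent of the package's expm route.
series_expm <- function(M, nterm = 120) {
  S <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(nterm)) {
    term <- term %*% M / k
    S <- S + term
  }
  S
}

# Hand-rolled weighted panel log-likelihood: explicit product of
# series-expm entries, child by child. Used only on tiny panels.
manual_loglik <- function(log_q, beta, panel, covariates = character()) {
  at <- allowed_transitions()
  ll <- 0
  for (id in unique(panel$child_id)) {
    sub <- panel[panel$child_id == id, ]
    sub <- sub[order(sub$age), ]
    x <- if (length(covariates)) as.numeric(sub[1, covariates]) else numeric(0)
    rates <- exp(log_q + if (length(x)) as.numeric(beta %*% x) else 0)
    q <- matrix(0, 4, 4)
    q[cbind(at$from, at$to)] <- rates
    diag(q) <- -rowSums(q)
    for (j in seq_len(nrow(sub) - 1)) {
      P <- series_expm(q * (sub$age[j + 1] - sub$age[j]))
      ll <- ll + sub$weight[1] * log(P[sub$state[j], sub$state[j + 1]])
    }
  }
  ll
}

# Integer matrix power by repeated multiplication.
.pow <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

# Random valid intensity matrix (six allowed rates).
random_q <- function(max_rate = 1) {
  intensity_matrix(stats::runif(6, 0, max_rate))
}

# Tiny two-knot-per-sex LMS table with age-constant parameters;
# L/M/S give the (male, female) values.
toy_lms <- function(L = c(1, 1), M = c(16, 18), S = c(0.1, 0.12),
                    ages = c(24, 216)) {
  growth_reference(data.frame(
    sex = rep(c("M", "F"), each = length(ages)),
    age_months = rep(ages, 2),
    L = rep(L, each = length(ages)),
    M = rep(M, each = length(ages)),
    S = rep(S, each = length(ages))))
}

# Simulation configuration used by estimation tests: single covariate-free
# process, no attrition or missingness, nominal wave ages.
clean_config <- function(n, seed, wave_ages = c(3, 5, 7, 11, 14, 17),
                         bands = default_band_intensities(),
                         n_strata = 3, n_clusters = 24, ...) {
  sim_config(n_children = n, wave_ages = wave_ages, age_jitter_sd = 0,
             band_intensities = bands,
             covariate_effects = list(sex = rep(0, 6),
                                      disadvantaged = rep(0, 6)),
             oversample = numeric(), attrition_rate = 0,
             missing_covariate_rate = 0, n_strata = n_strata,
             n_clusters = n_clusters, seed = seed, ...)
}
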