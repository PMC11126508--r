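#' Fit a survey-weighted multistate model to panel data
#'
#' Maximises the design-weighted interval-censored likelihood
#' (see [weighted_loglik()]) over the six baseline log-intensities and, if
#' covariates are supplied, a log-hazard-ratio per covariate coefficient per
#' allowed transition. Optimisation is quasi-Newton (BFGS) on the
#' unconstrained log scale, started from [crude_initial_intensities()], with
#' a derivative-free Nelder-Mead fallback if BFGS does not converge.
#'
#' Non-convergence is never silent: the returned object carries a
#' `converged` flag which downstream functions ([annual_probabilities()],
#' [hazard_ratios()]) refuse to ignore. When a covariate level has no
#' observed transitions in the data, a warning names the level; such levels
#' typically need merging (see [merge_levels()]) before the fit can converge.
#'
#' @param panel A [as_panel_data()] data frame (each child must have at least
#'   two observations; covariate columns must be complete).
#' @param structure A [transition_structure()].
#' @param covariates Character vector of covariate column names. All listed
#'   covariates enter one mutually adjusted fit; fit one at a time for
#'   univariable hazard ratios.
#' @param weights `"on"` (default) uses the panel's design weights; `"off"`
#'   sets all weights to one.
#' @param init Optional starting values: an `intensity_matrix` or a length-six
#'   rate vector (plus optionally an attached `beta` attribute). Defaults to
#'   crude rates.
#' @param band_label Optional label recording which age band / dataset the
#'   fit covers.
#' @param control List: `maxit` (default 500), `reltol` (relative
#'   log-likelihood change, default 1e-6), `floor` (crude-rate floor,
#'   1e-6).
#' @return An object of class `msm_fit` with elements `log_q` (named),
#'   `beta` (6 x k matrix), `loglik`, `converged`, `n_children`,
#'   `n_intervals`, `n_transitions` (observed state changes), `band_label`.
#' @export
fit_msm <- function(panel, structure = transition_structure(),
                    covariates = character(),
                    weights = c("on", "off"),
                    init = NULL, band_label = NA_character_,
                    control = list()) {
  weights <- match.arg(weights)
  panel <- as_panel_data(panel)
  if (weights == "off") panel$weight <- 1
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-6, floor = 1e-6),
                            control)
  ctx <- .panel_context(panel, covariates)
  at <- allowed_transitions(structure)
  m <- nrow(at)
  k <- ncol(ctx$gX)

  .warn_sparse_levels(panel, covariates, ctx)

  if (is.null(init)) init <- crude_initial_intensities(panel, structure,
                                                       floor = ctrl$floor)
  log_q0 <- if (inherits(init, "intensity_matrix")) {
    log(pmax(intensity_rates(init, structure), ctrl$floor))
  } else log(pmax(as.numeric(init), ctrl$floor))
  beta0 <- attr(init, "beta")
  if (is.null(beta0)) beta0 <- matrix(0, m, k)
  theta0 <- c(log_q0, as.numeric(beta0))

  negll <- function(theta) {
    lq <- theta[seq_len(m)]
    bb <- if (k) matrix(theta[-seq_len(m)], m, k) else NULL
    ll <- .loglik_from_context(lq, bb, ctx, structure)
    if (!is.finite(ll)) 1e12 else -ll
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = ctrl$maxit,
                                     reltol = ctrl$reltol))
  if (opt$convergence != 0 || !is.finite(opt$value) || opt$value >= 1e12) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 10L * ctrl$maxit,
                                        reltol = ctrl$reltol))
    if (opt2$value <= opt$value) opt <- opt2
  }

  log_q <- stats::setNames(opt$par[seq_len(m)], at$label)
  beta <- matrix(opt$par[-seq_len(m)], m, k,
                 dimnames = list(at$label, ctx$coef_names))
  structure(list(
    log_q = log_q,
    beta = beta,
    loglik = -opt$value,
    converged = opt$convergence == 0 && is.finite(opt$value) &&
      opt$value < 1e12,
    n_children = ctx$n_children,
    n_intervals = length(ctx$from),
    n_transitions = sum(ctx$from != ctx$to),
    band_label = band_label,
    covariates = covariates,
    coef_names = ctx$coef_names,
    structure = structure,
    context = ctx,
    optim = opt[c("convergence", "counts")]
  ), class = "msm_fit")
}

# Warn (by name) when a covariate level shows no observed state changes:
# the corresponding hazard ratio is not estimable and the fit may not
# converge.
.warn_sparse_levels <- function(panel, covariates, ctx) {
  if (!length(covariates) || !length(ctx$from)) return(invisible())
  changed <- ctx$from != ctx$to
  # covariate value at interval start
  n <- nrow(panel)
  i0 <- which(panel$child_id[-1] == panel$child_id[-n])
  for (cc in covariates) {
    vals <- panel[[cc]][i0]
    for (lev in unique(vals)) {
      if (!any(changed & vals == lev)) {
        warning("covariate ", cc, " level \"", lev,
                "\" has no observed transitions; estimates for it will not ",
                "converge - consider merge_levels()", call. = FALSE)
      }
    }
  }
  invisible()
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Survey-weighted multistate model fit",
      if (!is.na(x$band_label)) paste0("(", x$band_label, ")"), "\n")
  cat("  children:", x$n_children, " intervals:", x$n_intervals,
      " observed state changes:", x$n_transitions, "\n")
  cat("  log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  cat("  intensities (per year):\n")
  print(round(exp(x$log_q), 5))
  if (length(x$coef_names)) {
    cat("  log-hazard-ratios:\n")
    print(round(x$beta, 4))
  }
  invisible(x)
}

#' Fitted intensity matrix, optionally at a covariate profile
#'
#' @param fit An [fit_msm()] result.
#' @param covariate_profile Named numeric vector over the fit's coefficient
#'   names (`fit$coef_names`); missing entries default to 0 (the reference
#'   profile).
#' @return An [intensity_matrix()].
#' @export
fitted_intensities <- function(fit, covariate_profile = NULL) {
  x <- stats::setNames(numeric(length(fit$coef_names)), fit$coef_names)
  if (!is.null(covariate_profile)) {
    unknown <- setdiff(names(covariate_profile), fit$coef_names)
    if (length(unknown)) {
      stop("unknown coefficient(s) in profile: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    x[names(covariate_profile)] <- covariate_profile
  }
  lin <- if (length(x)) as.numeric(fit$beta %*% x) else 0
  intensity_matrix(exp(fit$log_q + lin), fit$structure)
}

#' Annual transition probability matrix from a fitted model
#'
#' The matrix exponential of the fitted (profile-specific) intensity matrix
#' at one year, i.e. the annual-cycle transition matrix used by Markov
#' traces. Refuses to operate on a fit that did not converge.
#'
#' @inheritParams fitted_intensities
#' @return 4x4 row-stochastic matrix.
#' @export
annual_probabilities <- function(fit, covariate_profile = NULL) {
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to report probabilities",
         call. = FALSE)
  }
  transition_probability_matrix(fitted_intensities(fit, covariate_profile),
                                1, fit$structure)
}

#' Hazard ratios from a fitted model
#'
#' One row per allowed transition per covariate coefficient, with
#' `hr = exp(beta)`. Reference levels of factor covariates carry a hazard
#' ratio of 1 by construction (they are the baseline and are not listed).
#'
#' @param fit A converged [fit_msm()] with covariates.
#' @return Data frame with columns `transition`, `covariate`, `hr`,
#'   `log_hr`.
#' @export
hazard_ratios <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to report hazard ratios",
         call. = FALSE)
  }
  if (!length(fit$coef_names)) {
    stop("fit has no covariates", call. = FALSE)
  }
  out <- expand.grid(transition = rownames(fit$beta),
                     covariate = colnames(fit$beta),
                     stringsAsFactors = FALSE)
  out$log_hr <- as.numeric(fit$beta)
  out$hr <- exp(out$log_hr)
  out[c("transition", "covariate", "hr", "log_hr")]
}

#' Merge sparse covariate levels
#'
#' Recode levels of a coded covariate column, e.g. to merge levels with no
#' observed transitions. Merging is always explicit user configuration; the
#' package never merges automatically.
#'
#' @param panel A panel data frame.
#' @param column Covariate column name.
#' @param mapping Named vector: `names(mapping)` are existing level values
#'   (as character), values are the replacement levels.
#' @return The panel with the column recoded.
#' @export
merge_levels <- function(panel, column, mapping) {
  if (!column %in% names(panel)) {
    stop("no column ", column, " in panel", call. = FALSE)
  }
  v <- as.character(panel[[column]])
  hit <- v %in% names(mapping)
  v[hit] <- as.character(mapping[v[hit]])
  panel[[column]] <- if (is.numeric(panel[[column]])) as.numeric(v) else v
  panel
}
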