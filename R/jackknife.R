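#' Survey design metadata for a cohort
#'
#' One row per child: stratum, primary sampling unit (cluster) and base
#' design weight. Used to build delete-one-cluster (JKn) replicate weights.
#'
#' @param child_id,stratum,cluster,weight Equal-length vectors; weights
#'   positive; every stratum must contain at least two clusters.
#' @return Data frame of class `survey_design`.
#' @export
survey_design <- function(child_id, stratum, cluster, weight = 1) {
  n <- length(child_id)
  df <- data.frame(child_id = child_id,
                   stratum = rep_len(stratum, n),
                   cluster = rep_len(cluster, n),
                   weight = rep_len(weight, n))
  if (anyDuplicated(df$child_id)) {
    stop("child_id must be unique in a survey design", call. = FALSE)
  }
  if (any(!is.finite(df$weight)) || any(df$weight <= 0)) {
    stop("design weights must be positive", call. = FALSE)
  }
  nest <- unique(df[c("stratum", "cluster")])
  if (anyDuplicated(nest$cluster)) {
    stop("each cluster must belong to exactly one stratum", call. = FALSE)
  }
  n_h <- table(nest$stratum)
  if (any(n_h < 2)) {
    stop("stratum ", paste(names(n_h)[n_h < 2], collapse = ", "),
         " has a single cluster; JKn needs at least two clusters per stratum",
         call. = FALSE)
  }
  class(df) <- c("survey_design", class(df))
  df
}

#' Extract the survey design from a panel dataset
#'
#' @param panel Panel data with `child_id`, `stratum`, `psu`, `weight`.
#' @return A [survey_design()], one row per child.
#' @export
panel_design <- function(panel) {
  first <- !duplicated(panel$child_id)
  survey_design(panel$child_id[first], panel$stratum[first],
                panel$psu[first], panel$weight[first])
}

#' Delete-one-cluster (JKn) jackknife replicate weights
#'
#' Builds one replicate per cluster: in replicate (h, j), children of
#' cluster j in stratum h get weight zero, children of the other clusters in
#' stratum h get their base weight scaled by `n_h / (n_h - 1)` (n_h clusters
#' in the stratum), and children outside stratum h keep their base weight.
#' Column sums within each stratum therefore equal the stratum's base weight
#' total exactly. Construction is deterministic.
#'
#' @param design A [survey_design()].
#' @return Object of class `replicate_weights`: list with `base` (named
#'   weights), `weights` (children x replicates matrix) and `meta` (data
#'   frame: `replicate`, `stratum`, `cluster`, `n_h`).
#' @export
jackknife_replicates <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  nest <- unique(design[c("stratum", "cluster")])
  nest <- nest[order(nest$stratum, nest$cluster), ]
  n_h <- table(nest$stratum)
  R <- nrow(nest)
  n <- nrow(design)
  W <- matrix(design$weight, n, R)
  for (r in seq_len(R)) {
    h <- nest$stratum[r]
    nh <- as.numeric(n_h[as.character(h)])
    in_stratum <- design$stratum == h
    W[in_stratum, r] <- design$weight[in_stratum] * nh / (nh - 1)
    W[in_stratum & design$cluster == nest$cluster[r], r] <- 0
  }
  rownames(W) <- as.character(design$child_id)
  structure(list(base = stats::setNames(design$weight,
                                        as.character(design$child_id)),
                 weights = W,
                 meta = data.frame(replicate = seq_len(R),
                                   stratum = nest$stratum,
                                   cluster = nest$cluster,
                                   n_h = as.numeric(n_h[as.character(
                                     nest$stratum)]))),
            class = "replicate_weights")
}

#' @export
print.replicate_weights <- function(x, ...) {
  cat("JKn replicate weights:", ncol(x$weights), "replicates (",
      length(unique(x$meta$stratum)), "strata,",
      nrow(x$meta), "clusters ) for", nrow(x$weights), "children\n")
  invisible(x)
}

#' Write / read replicate weights as CSV plus a JSON sidecar
#'
#' @param rw A [jackknife_replicates()] result.
#' @param path CSV path (`child_id`, `base`, then one column per replicate);
#'   the metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly (write); a `replicate_weights` (read).
#' @export
write_replicate_weights <- function(rw, path) {
  df <- data.frame(child_id = rownames(rw$weights), base = rw$base,
                   rw$weights, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("rep", seq_len(ncol(rw$weights)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(rw$meta, paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_replicate_weights
#' @export
read_replicate_weights <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  W <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(W) <- as.character(df$child_id)
  structure(list(base = stats::setNames(df$base, as.character(df$child_id)),
                 weights = W, meta = meta),
            class = "replicate_weights")
}

#' JKn replicate variance and standard error
#'
#' Valliant-Dever stratified jackknife variance: with `theta_hat` the
#' full-sample estimate and `theta_(hj)` the estimate under replicate (h, j),
#' `v = sum_h ((n_h - 1) / n_h) * sum_{j in h} (theta_(hj) - theta_hat)^2`.
#' Non-finite replicate estimates (non-converged replicate fits) are dropped
#' and the affected stratum sums rescaled, provided no more than
#' `max_failures` of replicates failed; otherwise an error is raised.
#'
#' @param full Full-sample estimate (scalar).
#' @param reps Numeric vector of per-replicate estimates, aligned with
#'   `meta`.
#' @param meta Replicate metadata from [jackknife_replicates()].
#' @param max_failures Maximum tolerated fraction of non-finite replicate
#'   estimates (default 0.05).
#' @return The jackknife standard error (scalar).
#' @export
replicate_variance <- function(full, reps, meta, max_failures = 0.05) {
  stopifnot(length(reps) == nrow(meta), is.finite(full))
  ok <- is.finite(reps)
  if (mean(!ok) > max_failures) {
    stop(sum(!ok), " of ", length(reps),
         " replicate estimates failed (> ", 100 * max_failures,
         "%); refusing to report variance", call. = FALSE)
  }
  v <- 0
  for (h in unique(meta$stratum)) {
    in_h <- meta$stratum == h & ok
    nh <- meta$n_h[match(h, meta$stratum)]
    n_used <- sum(in_h)
    if (n_used == 0) next
    contrib <- ((nh - 1) / nh) * sum((reps[in_h] - full)^2)
    v <- v + contrib * sum(meta$stratum == h) / n_used  # rescale for drops
  }
  sqrt(v)
}

#' Normal-theory interval on a chosen scale
#'
#' Builds a symmetric 95% (or other level) interval around the point
#' estimate: on the log scale for intensities and hazard ratios (`se` is the
#' SE of the log estimate), or on the identity scale with clipping to
#' `[0, 1]` for probabilities.
#'
#' @param point Point estimate on its natural scale.
#' @param se Standard error (on the log scale when `scale = "log"`).
#' @param scale `"identity"`, `"log"` or `"probability"`.
#' @param level Confidence level (default 0.95).
#' @return List with `point`, `se`, `ci_low`, `ci_high`, `scale`.
#' @export
interval_estimate <- function(point, se,
                              scale = c("identity", "log", "probability"),
                              level = 0.95) {
  scale <- match.arg(scale)
  stopifnot(se >= 0)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "log") {
    lo <- point * exp(-zc * se)
    hi <- point * exp(zc * se)
  } else {
    lo <- point - zc * se
    hi <- point + zc * se
    if (scale == "probability") {
      lo <- min(max(lo, 0), 1)
      hi <- min(max(hi, 0), 1)
    }
  }
  list(point = point, se = se, ci_low = lo, ci_high = hi, scale = scale)
}

#' Refit a multistate model under each replicate weight
#'
#' Re-estimates the model once per JKn replicate, replacing each child's
#' design weight by the replicate weight and warm-starting the optimiser
#' from the full-sample estimates (the optimum moves little, so warm starts
#' change nothing but the run time). Children whose replicate weight is zero
#' drop out of that replicate's likelihood.
#'
#' @param fit A converged [fit_msm()].
#' @param panel The panel the fit was estimated on.
#' @param rw [jackknife_replicates()] for the panel's design.
#' @param workers Number of parallel workers (forked; results are identical
#'   for any worker count).
#' @param control Passed to [fit_msm()].
#' @return Object of class `msm_replicates`: list with `par` (replicates x
#'   parameters matrix of `c(log_q, beta)`), `converged` (logical vector),
#'   `meta`, and the originating `fit`.
#' @export
msm_replicate_fits <- function(fit, panel, rw, workers = 1L,
                               control = list()) {
  stopifnot(inherits(fit, "msm_fit"), inherits(rw, "replicate_weights"))
  if (!isTRUE(fit$converged)) {
    stop("full-sample fit did not converge", call. = FALSE)
  }
  panel <- as_panel_data(panel)
  ids <- as.character(panel$child_id)
  if (!all(ids %in% rownames(rw$weights))) {
    stop("replicate weights do not cover every child in the panel",
         call. = FALSE)
  }
  init <- intensity_matrix(exp(fit$log_q), fit$structure)
  attr(init, "beta") <- fit$beta
  one <- function(r) {
    p <- panel
    p$weight <- rw$weights[ids, r]
    p <- p[p$weight > 0, , drop = FALSE]
    nobs <- table(p$child_id)
    p <- p[!p$child_id %in% names(nobs)[nobs < 2], , drop = FALSE]
    f <- suppressWarnings(try(
      fit_msm(p, fit$structure, fit$covariates, weights = "on",
              init = init, control = control), silent = TRUE))
    if (inherits(f, "try-error") || !f$converged) {
      return(rep(NA_real_, length(fit$log_q) + length(fit$beta)))
    }
    c(f$log_q, as.numeric(f$beta))
  }
  R <- ncol(rw$weights)
  res <- if (workers > 1L) {
    parallel::mclapply(seq_len(R), one, mc.cores = workers)
  } else {
    lapply(seq_len(R), one)
  }
  par <- do.call(rbind, res)
  colnames(par) <- c(names(fit$log_q),
                     if (length(fit$beta)) {
                       paste(rep(rownames(fit$beta), ncol(fit$beta)),
                             rep(colnames(fit$beta),
                                 each = nrow(fit$beta)), sep = ":")
                     })
  structure(list(par = par, converged = stats::complete.cases(par),
                 meta = rw$meta, fit = fit),
            class = "msm_replicates")
}

#' @export
print.msm_replicates <- function(x, ...) {
  cat("Replicate refits:", nrow(x$par), "replicates,",
      sum(!x$converged), "non-converged\n")
  invisible(x)
}

#' Replicate-based intervals for intensities, probabilities and hazard ratios
#'
#' Turns replicate re-estimates into 95% confidence intervals. Intensities
#' and hazard ratios use the jackknife SE of the log estimate with a
#' symmetric log-scale interval. Annual transition probabilities are
#' recomputed through the full matrix-exponential pipeline for every
#' replicate (replication propagates through all transformations; no delta
#' method), then given identity-scale intervals clipped to `[0, 1]`.
#'
#' @param reps A [msm_replicate_fits()] result.
#' @param covariate_profile Passed to [annual_probabilities()].
#' @param level Confidence level.
#' @return List of data frames: `intensities` (transition, estimate, se,
#'   ci_low, ci_high), `annual_probabilities` (from, to, estimate, se,
#'   ci_low, ci_high), and `hazard_ratios` (transition, covariate, hr,
#'   ci_low, ci_high) when the fit has covariates.
#' @export
msm_intervals <- function(reps, covariate_profile = NULL, level = 0.95) {
  fit <- reps$fit
  meta <- reps$meta
  m <- length(fit$log_q)
  at <- allowed_transitions(fit$structure)

  # intensities: log scale
  ints <- lapply(seq_len(m), function(j) {
    se <- replicate_variance(fit$log_q[j], reps$par[, j], meta)
    ie <- interval_estimate(exp(fit$log_q[j]), se, "log", level)
    data.frame(transition = at$label[j], estimate = ie$point, se = se,
               ci_low = ie$ci_low, ci_high = ie$ci_high)
  })

  # annual probabilities: recompute P(1) per replicate
  p_full <- annual_probabilities(fit, covariate_profile)
  rep_p <- apply(reps$par, 1, function(th) {
    if (anyNA(th)) return(rep(NA_real_, 16))
    f2 <- fit
    f2$log_q[] <- th[seq_len(m)]
    f2$beta[] <- th[-seq_len(m)]
    as.numeric(annual_probabilities(f2, covariate_profile))
  })  # 16 x R
  st <- names(weight_states())
  probs <- lapply(seq_len(16), function(e) {
    se <- replicate_variance(as.numeric(p_full)[e], rep_p[e, ], meta)
    ie <- interval_estimate(as.numeric(p_full)[e], se, "probability", level)
    data.frame(from = st[(e - 1) %% 4 + 1], to = st[(e - 1) %/% 4 + 1],
               estimate = ie$point, se = se,
               ci_low = ie$ci_low, ci_high = ie$ci_high)
  })

  out <- list(intensities = do.call(rbind, ints),
              annual_probabilities = do.call(rbind, probs))

  if (length(fit$beta)) {
    k <- ncol(fit$beta)
    hrs <- lapply(seq_len(m * k), function(j) {
      b <- as.numeric(fit$beta)[j]
      se <- replicate_variance(b, reps$par[, m + j], meta)
      ie <- interval_estimate(exp(b), se, "log", level)
      data.frame(transition = at$label[(j - 1) %% m + 1],
                 covariate = colnames(fit$beta)[(j - 1) %/% m + 1],
                 hr = ie$point, se_log = se,
                 ci_low = ie$ci_low, ci_high = ie$ci_high)
    })
    out$hazard_ratios <- do.call(rbind, hrs)
  }
  out
}
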