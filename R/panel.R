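#' Validate a long-format panel dataset
#'
#' A panel dataset holds interval-censored observations of weight state: one
#' row per child per measurement occasion, with the child's exact age in
#' decimal years, the observed state code, the design weight, and survey
#' design identifiers. Rows are sorted by child then age; every retained
#' child has at least two observations (a single observation carries no
#' transition information).
#'
#' @param df Data frame with columns `child_id`, `age` (years), `state`
#'   (codes 1--4), and optionally `weight` (default 1), `stratum`, `psu`, and
#'   covariate columns.
#' @param require_two Drop-check: error if any child has fewer than two rows
#'   (default `TRUE`).
#' @return The validated, sorted data frame with class `panel_data`.
#' @export
as_panel_data <- function(df, require_two = TRUE) {
  needed <- c("child_id", "age", "state")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("panel data missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$weight)) df$weight <- 1
  if (any(!is.finite(df$weight)) || any(df$weight <= 0)) {
    stop("design weights must be positive", call. = FALSE)
  }
  if (any(!df$state %in% 1:4)) {
    stop("state codes must be integers 1-4", call. = FALSE)
  }
  df <- df[order(df$child_id, df$age), , drop = FALSE]
  rownames(df) <- NULL
  same <- df$child_id[-1] == df$child_id[-nrow(df)]
  if (any(same & diff(df$age) <= 0)) {
    stop("ages must be strictly increasing within child", call. = FALSE)
  }
  if (require_two) {
    nobs <- table(df$child_id)
    if (any(nobs < 2)) {
      stop(sum(nobs < 2), " child(ren) have fewer than two observations; ",
           "drop them or set require_two = FALSE", call. = FALSE)
    }
  }
  class(df) <- unique(c("panel_data", class(df)))
  df
}

# Covariate design matrix: numeric columns pass through, factors/characters
# expand to treatment-coded dummies (reference level carries zero).
.covariate_matrix <- function(panel, covariates) {
  if (!length(covariates)) {
    return(matrix(0, nrow(panel), 0))
  }
  missing_cols <- setdiff(covariates, names(panel))
  if (length(missing_cols)) {
    stop("covariate column(s) not in panel: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sub <- as.data.frame(panel)[covariates]
  if (anyNA(sub)) {
    stop("covariate columns contain missing values; apply complete-case ",
         "exclusion first (see apply_exclusions)", call. = FALSE)
  }
  for (cc in covariates) {
    if (is.character(sub[[cc]])) sub[[cc]] <- factor(sub[[cc]])
  }
  mm <- stats::model.matrix(~ ., data = sub)
  mm[, -1, drop = FALSE]
}

# Interval representation of a panel: one row per consecutive observation
# pair within child, grouped by unique (elapsed time, covariate profile) so
# the likelihood evaluates one matrix exponential per group.
.panel_context <- function(panel, covariates = character()) {
  panel <- as_panel_data(panel)
  X <- .covariate_matrix(panel, covariates)
  n <- nrow(panel)
  same <- panel$child_id[-1] == panel$child_id[-n]
  i0 <- which(same)        # interval start rows
  i1 <- i0 + 1L
  dt <- panel$age[i1] - panel$age[i0]
  Xi <- X[i0, , drop = FALSE]  # covariates fixed at interval start
  key <- do.call(paste, c(list(signif(dt, 12)),
                          lapply(seq_len(ncol(Xi)),
                                 function(j) signif(Xi[, j], 12)),
                          sep = "|"))
  ukey <- unique(key)
  grp <- match(key, ukey)
  first <- match(ukey, key)
  list(from = as.integer(panel$state[i0]),
       to = as.integer(panel$state[i1]),
       dt = dt,
       w = panel$weight[i0],
       grp = as.integer(grp),
       gdt = dt[first],
       gX = Xi[first, , drop = FALSE],
       child = panel$child_id[i0],
       n_children = length(unique(panel$child_id)),
       coef_names = colnames(X))
}

#' Survey-weighted interval-censored log-likelihood
#'
#' Evaluates the design-weighted log-likelihood of a four-state
#' continuous-time Markov model on panel data: each child contributes the sum
#' over consecutive observation pairs of `log P(s_j -> s_{j+1}; dt_j)`, the
#' log transition probability from the matrix exponential of the child's
#' intensity matrix, and the whole contribution is multiplied by the child's
#' design weight (pseudo-likelihood weighting). Covariates act log-linearly
#' on each allowed intensity: `q_rs(x) = q_rs * exp(beta_rs' x)`.
#'
#' Returns `-Inf` (never an error) when an observed transition has zero
#' probability under the structure at the supplied parameters.
#'
#' @param log_q Length-six vector of baseline log-intensities, ordered as
#'   [allowed_transitions()].
#' @param beta Optional 6 x k matrix of log-hazard-ratios (k covariate
#'   columns), or `NULL` for no covariate effects.
#' @param panel A [as_panel_data()] data frame.
#' @param structure A [transition_structure()].
#' @param covariates Character vector of covariate column names (must match
#'   the columns `beta` was coded against).
#' @return The weighted log-likelihood (scalar).
#' @export
weighted_loglik <- function(log_q, beta = NULL, panel,
                            structure = transition_structure(),
                            covariates = character()) {
  ctx <- .panel_context(panel, covariates)
  .loglik_from_context(log_q, beta, ctx, structure)
}

.loglik_from_context <- function(log_q, beta, ctx, structure) {
  at <- allowed_transitions(structure)
  k <- ncol(ctx$gX)
  if (is.null(beta)) beta <- matrix(0, nrow(at), k)
  beta <- matrix(beta, nrow = nrow(at), ncol = k)
  .panel_loglik(as.numeric(log_q), beta,
                as.integer(at$from), as.integer(at$to),
                ctx$from, ctx$to, ctx$w, ctx$grp,
                ctx$gdt, ctx$gX, 4L)
}

#' Crude initial transition intensities
#'
#' Moment-style starting values for the optimizer: for each allowed
#' transition r -> s, the weighted count of observed r -> s interval moves
#' divided by the weighted person-time of intervals starting in r. Allowed
#' transitions with no observed moves are floored at a small positive rate so
#' the optimizer starts in the interior of the parameter space.
#'
#' @inheritParams weighted_loglik
#' @param floor Minimum rate for zero-count transitions (per year).
#' @return An [intensity_matrix()].
#' @export
crude_initial_intensities <- function(panel,
                                      structure = transition_structure(),
                                      floor = 1e-6) {
  ctx <- .panel_context(panel)
  if (!length(ctx$from)) stop("panel has no intervals", call. = FALSE)
  at <- allowed_transitions(structure)
  rates <- numeric(nrow(at))
  for (j in seq_len(nrow(at))) {
    moves <- sum(ctx$w * (ctx$from == at$from[j] & ctx$to == at$to[j]))
    persontime <- sum(ctx$w * ctx$dt * (ctx$from == at$from[j]))
    rates[j] <- if (persontime > 0) moves / persontime else 0
  }
  rates[rates < floor] <- floor
  intensity_matrix(rates, structure)
}
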