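#' Schedule of annual transition matrices by age band
#'
#' A matrix schedule pairs contiguous, non-overlapping age bands with the
#' annual (one-year-cycle) transition matrix that applies inside each band.
#' Markov traces look up the band containing the current age at every cycle.
#'
#' @param entries List of `list(age_from, age_to, P)` with `P` a 4x4
#'   row-stochastic matrix.
#' @return Object of class `matrix_schedule`.
#' @export
matrix_schedule <- function(entries) {
  a0 <- vapply(entries, `[[`, numeric(1), "age_from")
  a1 <- vapply(entries, `[[`, numeric(1), "age_to")
  o <- order(a0)
  entries <- entries[o]; a0 <- a0[o]; a1 <- a1[o]
  if (any(a1 <= a0)) stop("bands must have age_to > age_from", call. = FALSE)
  if (length(a0) > 1 && any(abs(a1[-length(a1)] - a0[-1]) > 1e-9)) {
    stop("schedule bands must be contiguous and non-overlapping",
         call. = FALSE)
  }
  for (e in entries) {
    P <- e$P
    if (!is.matrix(P) || !all(dim(P) == c(4, 4)) ||
        any(P < -1e-8) || any(abs(rowSums(P) - 1) > 1e-8)) {
      stop("each matrix must be 4x4 row-stochastic (tolerance 1e-8)",
           call. = FALSE)
    }
  }
  structure(list(entries = entries, age_from = a0[1],
                 age_to = a1[length(a1)]),
            class = "matrix_schedule")
}

#' @export
print.matrix_schedule <- function(x, ...) {
  cat("Matrix schedule:", length(x$entries), "band(s) covering ages",
      x$age_from, "-", x$age_to, "\n")
  invisible(x)
}

#' Build a matrix schedule from band-wise model fits
#'
#' @param fits List of converged [fit_msm()] objects, one per band.
#' @param bands List of `c(age_from, age_to)` pairs aligned with `fits`.
#' @param covariate_profile Passed to [annual_probabilities()].
#' @return A [matrix_schedule()].
#' @export
schedule_from_fits <- function(fits, bands, covariate_profile = NULL) {
  stopifnot(length(fits) == length(bands))
  matrix_schedule(lapply(seq_along(fits), function(i) {
    list(age_from = bands[[i]][1], age_to = bands[[i]][2],
         P = annual_probabilities(fits[[i]], covariate_profile))
  }))
}

.schedule_matrix_at <- function(schedule, age) {
  a0 <- vapply(schedule$entries, `[[`, numeric(1), "age_from")
  a1 <- vapply(schedule$entries, `[[`, numeric(1), "age_to")
  i <- which(age >= a0 - 1e-9 & age < a1 - 1e-9)
  if (!length(i)) {
    if (age >= a1[length(a1)] - 1e-9) return(length(a1))  # extend last band
    stop("age ", age, " not covered by the schedule", call. = FALSE)
  }
  i[1]
}

#' Markov cohort trace
#'
#' Projects a cohort's state-occupancy distribution forward in annual
#' cycles: `occupancy[k+1] = occupancy[k] %*% P(band containing age_k)`.
#' If the horizon extends beyond the last band, the final band's matrix is
#' carried forward (a message notes the extension).
#'
#' @param baseline Length-4 occupancy at `start_age`, summing to 1.
#' @param schedule A [matrix_schedule()].
#' @param start_age,end_age Trace horizon in years; one cycle per year.
#' @return Object of class `markov_trace`: `(cycles + 1) x 4` occupancy
#'   matrix with ages as row names.
#' @export
#' @examples
#' tr <- markov_trace(c(0, 1, 0, 0), mcs_schedule(), 3, 18)
#' tr[nrow(tr), ]
markov_trace <- function(baseline, schedule, start_age, end_age) {
  stopifnot(inherits(schedule, "matrix_schedule"),
            length(baseline) == 4, all(baseline >= 0), end_age > start_age)
  if (abs(sum(baseline) - 1) > 1e-8) {
    stop("baseline occupancy must sum to 1", call. = FALSE)
  }
  baseline <- baseline / sum(baseline)
  cycles <- as.integer(round(end_age - start_age))
  occ <- matrix(0, cycles + 1L, 4,
                dimnames = list(start_age + 0:cycles,
                                names(weight_states())))
  occ[1, ] <- baseline
  extended <- FALSE
  for (k in seq_len(cycles)) {
    age <- start_age + k - 1L
    if (age >= schedule$age_to - 1e-9) extended <- TRUE
    P <- schedule$entries[[.schedule_matrix_at(schedule, age)]]$P
    occ[k + 1L, ] <- occ[k, ] %*% P
  }
  if (extended) {
    message("schedule extended: final band's matrix applied beyond age ",
            schedule$age_to)
  }
  class(occ) <- c("markov_trace", class(occ))
  occ
}

#' @export
print.markov_trace <- function(x, ...) {
  cat("Markov trace:", nrow(x) - 1, "annual cycles\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
plot.markov_trace <- function(x, ...) {
  ages <- as.numeric(rownames(x))
  graphics::matplot(ages, unclass(x), type = "l", lty = 1, lwd = 2,
                    col = c("#999999", "#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "Age (years)", ylab = "State occupancy",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x), lty = 1, lwd = 2,
                   col = c("#999999", "#1b9e77", "#d95f02", "#7570b3"),
                   bty = "n")
  invisible(x)
}

#' Weighted expansion of a validation cohort
#'
#' Replicates each child in proportion to its normalised survey weight:
#' child i appears `round(factor * w_i / mean(w))` times (round half away
#' from zero), so the expanded cohort's state distribution is the weighted
#' distribution of the input.
#'
#' @param panel Panel rows at the baseline wave (one row per child), with
#'   `state` and `weight`.
#' @param factor Expansion factor (default 100).
#' @return List: `counts` (replicates per child), `n_expanded`, and
#'   `baseline` (length-4 state distribution of the expanded cohort).
#' @export
expand_validation_cohort <- function(panel, factor = 100) {
  stopifnot(factor >= 1, all(panel$weight > 0))
  x <- factor * panel$weight / mean(panel$weight)
  counts <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  tab <- vapply(1:4, function(s) sum(counts[panel$state == s]), numeric(1))
  list(counts = counts, n_expanded = sum(counts),
       baseline = stats::setNames(tab / sum(tab), names(weight_states())))
}

#' Observed weighted prevalence by wave
#'
#' @param panel A panel dataset.
#' @param wave_ages Nominal wave ages; each observation is assigned to the
#'   nearest wave age.
#' @return Matrix (waves x 4) of weighted state prevalences, rows summing
#'   to 1, with wave ages as row names.
#' @export
observed_prevalence <- function(panel, wave_ages) {
  wave <- vapply(panel$age, function(a) which.min(abs(wave_ages - a)),
                 integer(1))
  out <- matrix(0, length(wave_ages), 4,
                dimnames = list(wave_ages, names(weight_states())))
  for (i in seq_along(wave_ages)) {
    sel <- wave == i
    if (!any(sel)) next
    w <- panel$weight[sel]
    out[i, ] <- vapply(1:4, function(s) sum(w[panel$state[sel] == s]),
                       numeric(1)) / sum(w)
  }
  out
}

#' Predicted-to-observed prevalence ratios
#'
#' Compares a Markov trace against observed weighted prevalence at each wave
#' age: `ratio = predicted occupancy / observed prevalence`. Perfect
#' agreement gives ratios of 1. States with zero observed prevalence get
#' `NA` (undefined), never infinity.
#'
#' @param trace A [markov_trace()].
#' @param observed Waves x 4 matrix from [observed_prevalence()] with wave
#'   ages as row names.
#' @return Data frame: `age`, `state`, `predicted`, `observed`, `ratio`.
#' @export
predicted_vs_observed <- function(trace, observed) {
  trace_ages <- as.numeric(rownames(trace))
  obs_ages <- as.numeric(rownames(observed))
  if (any(is.na(match(round(obs_ages), round(trace_ages))))) {
    stop("trace does not cover every observed wave age", call. = FALSE)
  }
  rows <- lapply(seq_along(obs_ages), function(i) {
    k <- match(round(obs_ages[i]), round(trace_ages))
    pred <- as.numeric(trace[k, ])
    obs <- as.numeric(observed[i, ])
    data.frame(age = obs_ages[i], state = names(weight_states()),
               predicted = pred, observed = obs,
               ratio = ifelse(obs > 0, pred / obs, NA_real_))
  })
  do.call(rbind, rows)
}

#' Compare model fit of competing trace schedules
#'
#' Scores each model's trace against observed prevalence by mean absolute
#' prevalence error across states and waves, and reports the ordering
#' (smallest error = best fit).
#'
#' @param traces Named list of [markov_trace()] objects sharing a horizon.
#' @param observed Waves x 4 observed prevalence matrix (ages as row
#'   names).
#' @return Data frame with `model`, `mae`, `rank`, ordered best first.
#' @export
compare_scenarios <- function(traces, observed) {
  stopifnot(is.list(traces), length(names(traces)) == length(traces))
  mae <- vapply(traces, function(tr) {
    po <- predicted_vs_observed(tr, observed)
    mean(abs(po$predicted - po$observed))
  }, numeric(1))
  out <- data.frame(model = names(traces), mae = mae)
  out <- out[order(out$mae), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a trace to CSV
#'
#' @param trace A [markov_trace()].
#' @param path Output CSV path (columns: age, p_underweight, p_healthy,
#'   p_overweight, p_obesity).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(age = as.numeric(rownames(trace)), unclass(trace))
  names(df)[-1] <- paste0("p_", names(weight_states()))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
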