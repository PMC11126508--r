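#' Weight-status state space
#'
#' The model's four ordinal states. State codes are integers 1 to 4 and
#' adjacent states differ by one; only adjacent states communicate directly
#' (see [transition_structure()]).
#'
#' @return Named integer vector mapping state labels to codes 1--4.
#' @export
#' @examples
#' weight_states()
weight_states <- function() {
  c(underweight = 1L, healthy = 2L, overweight = 3L, obesity = 4L)
}

#' Allowed transition structure of the four-state model
#'
#' Returns the adjacency of clinically plausible instantaneous transitions:
#' movement is only possible between adjacent weight states, giving exactly
#' six allowed transitions (1-2, 2-1, 2-3, 3-2, 3-4, 4-3). A child observed
#' to move, say, from healthy weight to obesity over an interval must have
#' passed through overweight; the direct intensity is structurally zero.
#'
#' @return An object of class `transition_structure`: a 4x4 logical matrix
#'   with `TRUE` where a direct transition is allowed.
#' @export
#' @examples
#' s <- transition_structure()
#' sum(s)               # six allowed transitions
#' s["healthy", "obesity"]  # FALSE: must pass through overweight
transition_structure <- function() {
  st <- names(weight_states())
  allowed <- matrix(FALSE, 4, 4, dimnames = list(st, st))
  for (r in 1:3) {
    allowed[r, r + 1L] <- TRUE
    allowed[r + 1L, r] <- TRUE
  }
  class(allowed) <- c("transition_structure", class(allowed))
  allowed
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", sum(x), "allowed transitions\n")
  print(unclass(x))
  invisible(x)
}

#' Allowed transitions as an index table
#'
#' @param structure A [transition_structure()].
#' @return Data frame with columns `from`, `to` (state codes) and `label`,
#'   one row per allowed transition, in row-major order.
#' @export
allowed_transitions <- function(structure = transition_structure()) {
  idx <- which(t(unclass(structure)) != 0)  # row-major order
  to <- (idx - 1L) %% 4L + 1L
  from <- (idx - 1L) %/% 4L + 1L
  st <- names(weight_states())
  data.frame(from = from, to = to,
             label = paste0(st[from], "-", st[to]),
             stringsAsFactors = FALSE)
}

#' Build an intensity matrix from per-transition rates
#'
#' Assembles the 4x4 generator of the continuous-time chain from the six
#' allowed per-year transition rates. Off-diagonal entries outside the allowed
#' structure are zero; the diagonal makes each row sum to zero.
#'
#' @param rates Numeric vector of length six, non-negative, ordered as
#'   [allowed_transitions()] (1-2, 2-1, 2-3, 3-2, 3-4, 4-3).
#' @param structure A [transition_structure()].
#' @return An `intensity_matrix`: 4x4 numeric matrix, rows summing to zero.
#' @export
#' @examples
#' q <- intensity_matrix(c(0.33, 0.003, 0.034, 0.23, 0.12, 0.18))
#' rowSums(q)
intensity_matrix <- function(rates, structure = transition_structure()) {
  at <- allowed_transitions(structure)
  if (length(rates) != nrow(at)) {
    stop("need ", nrow(at), " rates, one per allowed transition", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("transition rates must be finite and non-negative", call. = FALSE)
  }
  st <- names(weight_states())
  q <- matrix(0, 4, 4, dimnames = list(st, st))
  q[cbind(at$from, at$to)] <- rates
  diag(q) <- -rowSums(q)
  class(q) <- c("intensity_matrix", class(q))
  q
}

#' Validate a generator matrix against the transition structure
#'
#' @param q 4x4 numeric matrix.
#' @param structure A [transition_structure()].
#' @param tol Numerical tolerance for row sums and structural zeros.
#' @return `q`, invisibly, with class `intensity_matrix`; errors otherwise.
#' @export
validate_intensity_matrix <- function(q, structure = transition_structure(),
                                      tol = 1e-8) {
  q <- unclass(q)
  if (!is.matrix(q) || !all(dim(q) == c(4, 4)) || any(!is.finite(q))) {
    stop("intensity matrix must be a finite 4x4 matrix", call. = FALSE)
  }
  off <- q; diag(off) <- 0
  if (any(off < -tol)) {
    stop("off-diagonal intensities must be non-negative", call. = FALSE)
  }
  if (any(abs(off[!unclass(structure)]) > tol)) {
    stop("nonzero intensity on a structurally forbidden transition",
         call. = FALSE)
  }
  if (any(abs(rowSums(q)) > tol)) {
    stop("intensity matrix rows must sum to zero", call. = FALSE)
  }
  class(q) <- c("intensity_matrix", class(q))
  invisible(q)
}

#' Rates of an intensity matrix in allowed-transition order
#'
#' @param q An `intensity_matrix`.
#' @param structure A [transition_structure()].
#' @return Named numeric vector of the six allowed rates.
#' @export
intensity_rates <- function(q, structure = transition_structure()) {
  at <- allowed_transitions(structure)
  stats::setNames(unclass(q)[cbind(at$from, at$to)], at$label)
}

#' Transition probability matrix over an elapsed time
#'
#' Computes `P(t) = expm(Q t)`, the matrix of probabilities of occupying each
#' state after `t` years given the current state, under a time-homogeneous
#' generator `Q`.
#'
#' @param q A valid intensity matrix (see [validate_intensity_matrix()]).
#' @param t Elapsed time in years, non-negative.
#' @param structure A [transition_structure()] used for validation.
#' @return 4x4 row-stochastic matrix.
#' @export
#' @examples
#' q <- intensity_matrix(c(0.33, 0.003, 0.034, 0.23, 0.12, 0.18))
#' p <- transition_probability_matrix(q, 1)
#' rowSums(p)
transition_probability_matrix <- function(q, t,
                                          structure = transition_structure()) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single non-negative number", call. = FALSE)
  }
  q <- validate_intensity_matrix(q, structure)
  p <- .expm_dense(unclass(q) * t)
  # expm of a generator is row-stochastic up to round-off; clamp tiny noise
  p[p < 0 & p > -1e-12] <- 0
  dimnames(p) <- dimnames(q)
  p
}
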