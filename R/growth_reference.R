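#' Construct a growth reference from an LMS table
#'
#' An LMS growth reference gives, per sex and age, the Box-Cox power `L`, the
#' median `M` (kg/m^2 for BMI references) and the coefficient of variation
#' `S`. BMI measurements are mapped to z-scores with [lms_zscore()] by linear
#' interpolation of L, M and S at the child's exact age.
#'
#' @param df Data frame with columns `sex` ("M"/"F"), `age_months`, `L`, `M`,
#'   `S`.
#' @return An object of class `growth_reference`.
#' @export
growth_reference <- function(df) {
  needed <- c("sex", "age_months", "L", "M", "S")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("growth reference is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[needed]
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("M", "F"))) {
    stop("sex must be coded \"M\" or \"F\"", call. = FALSE)
  }
  if (!all(c("M", "F") %in% df$sex)) {
    stop("growth reference must cover both sexes", call. = FALSE)
  }
  bad <- which(!is.finite(df$M) | df$M <= 0 | !is.finite(df$S) | df$S <= 0 |
                 !is.finite(df$L) | !is.finite(df$age_months))
  if (length(bad)) {
    stop("invalid L/M/S values in growth reference at row(s) ",
         paste(bad, collapse = ", "), " (M and S must be positive)",
         call. = FALSE)
  }
  df <- df[order(df$sex, df$age_months), , drop = FALSE]
  for (s in c("M", "F")) {
    a <- df$age_months[df$sex == s]
    if (any(diff(a) <= 0)) {
      stop("ages must be strictly increasing within sex ", s, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(list(table = df), class = "growth_reference")
}

#' @export
print.growth_reference <- function(x, ...) {
  rng <- range(x$table$age_months)
  cat("Growth reference (LMS):", nrow(x$table), "rows, ages",
      rng[1], "-", rng[2], "months\n")
  invisible(x)
}

#' Read an LMS growth-reference table from CSV
#'
#' @param path CSV file with header `sex,age_months,L,M,S` and sex coded
#'   "M"/"F".
#' @return A validated [growth_reference()].
#' @export
read_growth_reference <- function(path) {
  growth_reference(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled synthetic LMS reference
#'
#' Loads the small synthetic BMI LMS table shipped with the package (monthly
#' knots, ages 24-216 months, both sexes). It mimics the shape of a childhood
#' BMI reference (post-infancy dip, adiposity rebound, adolescent rise) but is
#' generated from smooth parametric curves, not from measured data, and must
#' not be used for real children.
#'
#' @return A [growth_reference()].
#' @export
synthetic_growth_reference <- function() {
  read_growth_reference(system.file("extdata", "synthetic_lms_reference.csv",
                                    package = "weightmsm", mustWork = TRUE))
}

.interp_lms <- function(ref, sex, age_months) {
  tab <- ref$table[ref$table$sex == sex, , drop = FALSE]
  rng <- range(tab$age_months)
  out_of_range <- age_months < rng[1] | age_months > rng[2]
  if (any(out_of_range)) {
    stop("age(s) outside growth reference range [", rng[1], ", ", rng[2],
         "] months for sex ", sex, call. = FALSE)
  }
  list(L = stats::approx(tab$age_months, tab$L, age_months)$y,
       M = stats::approx(tab$age_months, tab$M, age_months)$y,
       S = stats::approx(tab$age_months, tab$S, age_months)$y)
}

#' BMI z-score via the LMS transform
#'
#' Maps BMI to an age- and sex-adjusted standard-deviation score using the
#' Cole LMS method: `z = ((bmi/M)^L - 1) / (L * S)` when `L != 0`, and
#' `z = log(bmi/M) / S` when `L = 0`, with L, M and S linearly interpolated at
#' the child's age within the reference table for their sex.
#'
#' @param bmi Positive BMI values (kg/m^2).
#' @param age_months Ages at measurement in months, within the reference
#'   range.
#' @param sex Character vector, "M" or "F", recycled against `bmi`.
#' @param ref A [growth_reference()].
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' ref <- synthetic_growth_reference()
#' lms_zscore(16.2, 60, "F", ref)
lms_zscore <- function(bmi, age_months, sex, ref) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and positive", call. = FALSE)
  }
  n <- max(length(bmi), length(age_months), length(sex))
  bmi <- rep_len(bmi, n); age_months <- rep_len(age_months, n)
  sex <- rep_len(as.character(sex), n)
  z <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    lms <- .interp_lms(ref, s, age_months[i])
    ratio <- bmi[i] / lms$M
    z[i] <- ifelse(abs(lms$L) < 1e-12,
                   log(ratio) / lms$S,
                   (ratio^lms$L - 1) / (lms$L * lms$S))
  }
  z
}

#' Invert the LMS transform (z-score to BMI)
#'
#' @inheritParams lms_zscore
#' @param z Z-scores.
#' @return BMI values (kg/m^2).
#' @export
lms_inverse <- function(z, age_months, sex, ref) {
  n <- max(length(z), length(age_months), length(sex))
  z <- rep_len(z, n); age_months <- rep_len(age_months, n)
  sex <- rep_len(as.character(sex), n)
  bmi <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    lms <- .interp_lms(ref, s, age_months[i])
    bmi[i] <- ifelse(abs(lms$L) < 1e-12,
                     lms$M * exp(lms$S * z[i]),
                     lms$M * (1 + lms$L * lms$S * z[i])^(1 / lms$L))
  }
  bmi
}

#' Flag biologically implausible z-scores
#'
#' @param z Z-scores.
#' @param threshold Absolute z-score above which a record is flagged
#'   (default 5, a common biological-plausibility rule).
#' @return Logical vector: `TRUE` where the record should be excluded.
#' @export
flag_implausible <- function(z, threshold = 5) {
  !is.finite(z) | abs(z) > threshold
}

#' Classify z-scores under UK90 population-monitoring centile cut-offs
#'
#' Converts each z-score to a centile through the standard normal
#' distribution and applies the population-monitoring boundaries: centile
#' <= 2nd underweight; < 85th healthy weight; < 95th overweight; >= 95th
#' obesity. Boundary z-values are computed from the normal quantile function,
#' never hard-coded decimals.
#'
#' @param z Finite z-scores.
#' @return Integer state codes 1--4 (see [weight_states()]).
#' @export
#' @examples
#' classify_uk90(c(-2.5, 0, 1.2, 2))
classify_uk90 <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  cuts <- stats::qnorm(c(0.02, 0.85, 0.95))
  # <= 2nd centile | (2nd, 85th) | [85th, 95th) | >= 95th
  out <- ifelse(z <= cuts[1], 1L,
                ifelse(z < cuts[2], 2L,
                       ifelse(z < cuts[3], 3L, 4L)))
  as.integer(out)
}

#' Classify z-scores under WHO cut-offs
#'
#' Applies the WHO classification, which is age-dependent: for children aged
#' 60 months or younger, overweight is z in (2, 3] and obesity z > 3; from 61
#' months, overweight is z in (1, 2] and obesity z > 2. Underweight is z < -2
#' at all ages.
#'
#' @param z Finite z-scores.
#' @param age_months Ages in months (recycled).
#' @return Integer state codes 1--4.
#' @export
#' @examples
#' classify_who(2.5, 48)  # overweight under the under-5 rule
#' classify_who(2.5, 72)  # obesity from 61 months
classify_who <- function(z, age_months) {
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  if (any(!is.finite(age_months)) || any(age_months < 0)) {
    stop("age_months must be finite and non-negative", call. = FALSE)
  }
  n <- max(length(z), length(age_months))
  z <- rep_len(z, n); age_months <- rep_len(age_months, n)
  young <- age_months <= 60
  ow_cut <- ifelse(young, 2, 1)
  ob_cut <- ifelse(young, 3, 2)
  out <- ifelse(z < -2, 1L,
                ifelse(z <= ow_cut, 2L,
                       ifelse(z <= ob_cut, 3L, 4L)))
  as.integer(out)
}
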