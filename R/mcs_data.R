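#' Published annual transition probabilities by age band
#'
#' Survey-weighted point estimates (with replicate-weight 95% CIs) of annual
#' transition probabilities between the four childhood weight states, for the
#' five adjacent-wave age bands of the UK Millennium Cohort Study (ages 3-5,
#' 5-7, 7-11, 11-14, 14-17). These printed estimates are shipped as package
#' data so that cohort traces and worked examples can be run without access
#' to the restricted microdata.
#'
#' @return Data frame with columns `age_from`, `age_to`, `n`, `from`, `to`,
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' head(mcs_annual_probabilities())
mcs_annual_probabilities <- function() {
  utils::read.csv(system.file("extdata", "mcs_annual_probabilities.csv",
                              package = "weightmsm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published annual matrices as a matrix schedule
#'
#' Assembles the [mcs_annual_probabilities()] point estimates into a
#' [matrix_schedule()] of per-band annual transition matrices, ready for
#' [markov_trace()].
#'
#' @return A `matrix_schedule` covering ages 3 to 17.
#' @export
mcs_schedule <- function() {
  tab <- mcs_annual_probabilities()
  st <- names(weight_states())
  bands <- unique(tab[c("age_from", "age_to")])
  entries <- lapply(seq_len(nrow(bands)), function(i) {
    sub <- tab[tab$age_from == bands$age_from[i], ]
    p <- matrix(0, 4, 4, dimnames = list(st, st))
    p[cbind(match(sub$from, st), match(sub$to, st))] <- sub$estimate
    list(age_from = bands$age_from[i], age_to = bands$age_to[i], P = p)
  })
  matrix_schedule(entries)
}
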