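# Generates inst/extdata/synthetic_lms_reference.csv: a synthetic BMI LMS
# table with the qualitative shape of a childhood BMI reference (post-infancy
# dip, adiposity rebound, adolescent rise). Parametric curves, not real data.
age <- 24:216  # months
curve_M <- function(a, shift) {
  15.5 + shift + 1.0 * exp(-(a - 24) / 24) + 5.5 / (1 + exp(-(a - 140) / 35))
}
mk <- function(sex, shift, s0, s1) {
  data.frame(sex = sex, age_months = age,
             L = round(-1.7 + 0.002 * age, 4),
             M = round(curve_M(age, shift), 4),
             S = round(s0 + s1 * age, 5))
}
tab <- rbind(mk("M", 0.00, 0.074, 0.00028),
             mk("F", 0.12, 0.078, 0.00031))
write.csv(tab, file.path("inst", "extdata", "synthetic_lms_reference.csv"),
          row.names = FALSE, quote = FALSE)
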