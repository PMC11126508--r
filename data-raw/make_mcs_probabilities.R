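# Writes inst/extdata/mcs_annual_probabilities.csv: published survey-weighted
# annual transition probability point estimates (with 95% CIs) between the
# four childhood weight states for each adjacent-wave age band of the UK
# Millennium Cohort Study, as printed in the source analysis.
st <- c("underweight", "healthy", "overweight", "obesity")
band <- function(age_from, age_to, n, est, lo, hi) {
  data.frame(age_from = age_from, age_to = age_to, n = n,
             from = rep(st, each = 4), to = rep(st, 4),
             estimate = est, ci_low = lo, ci_high = hi)
}
rows <- rbind(
  band(3, 5, 10399,
    c(0.7228,0.2719,0.0051,0.0002, 0.0024,0.9624,0.0332,0.0020,
      0.0003,0.1928,0.7132,0.0937, 0.0000,0.0178,0.1419,0.8403),
    c(0.4704,0.1283,0.0018,0.0000, 0.0010,0.9496,0.0261,0.0010,
      0.0001,0.1534,0.6343,0.0675, 0.0000,0.0101,0.1079,0.7873),
    c(0.8699,0.5155,0.0133,0.0008, 0.0052,0.9719,0.0414,0.0038,
      0.0008,0.2381,0.7790,0.1268, 0.0001,0.0309,0.1817,0.8820)),
  band(5, 7, 10729,
    c(0.7224,0.2733,0.0041,0.0002, 0.0039,0.9677,0.0267,0.0017,
      0.0004,0.1736,0.7281,0.0979, 0.0000,0.0097,0.0874,0.9029),
    c(0.3939,0.1057,0.0012,0.0000, 0.0018,0.9566,0.0212,0.0009,
      0.0001,0.1392,0.6545,0.0714, 0.0000,0.0051,0.0616,0.8608),
    c(0.8931,0.5929,0.0124,0.0008, 0.0073,0.9761,0.0331,0.0030,
      0.0010,0.2133,0.7893,0.1312, 0.0001,0.0177,0.1214,0.9333)),
  band(7, 11, 9685,
    c(0.9326,0.0669,0.0005,0.0000, 0.0014,0.9836,0.0146,0.0004,
      0.0000,0.0253,0.9223,0.0524, 0.0000,0.0002,0.0168,0.9830),
    c(0.8339,0.0263,0.0002,0.0000, 0.0006,0.9785,0.0119,0.0002,
      0.0000,0.0155,0.8911,0.0401, 0.0000,0.0001,0.0097,0.9707),
    c(0.9735,0.1645,0.0016,0.0000, 0.0030,0.9873,0.0178,0.0007,
      0.0001,0.0408,0.9444,0.0680, 0.0000,0.0006,0.0287,0.9902)),
  band(11, 14, 8593,
    c(0.9042,0.0949,0.0009,0.0000, 0.0022,0.9798,0.0175,0.0005,
      0.0002,0.0758,0.8716,0.0524, 0.0000,0.0016,0.0382,0.9602),
    c(0.7654,0.0369,0.0003,0.0000, 0.0009,0.9710,0.0133,0.0002,
      0.0000,0.0550,0.8185,0.0349, 0.0000,0.0008,0.0258,0.9411),
    c(0.9628,0.2316,0.0029,0.0001, 0.0051,0.9856,0.0229,0.0010,
      0.0003,0.1034,0.9101,0.0778, 0.0000,0.0033,0.0556,0.9734)),
  band(14, 17, 7085,
    c(0.9186,0.0806,0.0008,0.0000, 0.0023,0.9787,0.0183,0.0007,
      0.0001,0.0787,0.8507,0.0705, 0.0000,0.0017,0.0391,0.9592),
    c(0.8185,0.0350,0.0002,0.0000, 0.0006,0.9654,0.0132,0.0003,
      0.0000,0.0551,0.7702,0.0406, 0.0000,0.0007,0.0245,0.9349),
    c(0.9648,0.1789,0.0025,0.0001, 0.0079,0.9859,0.0249,0.0018,
      0.0005,0.1101,0.9043,0.1192, 0.0000,0.0041,0.0610,0.9748)))
stopifnot(all(abs(tapply(rows$estimate,
  interaction(rows$age_from, rows$from), sum) - 1) < 1e-12))
write.csv(rows, file.path("inst", "extdata", "mcs_annual_probabilities.csv"),
          row.names = FALSE, quote = FALSE)
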