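# Shared test utilities.

# Interval of true values consistent with a number printed to `dp` decimal
# places (half-ULP rounding band).
printed_interval <- function(value, dp) {
  h <- 0.5 * 10^(-dp)
  c(lo = value - h, hi = value + h)
}

# Tolerance for comparing a ratio of two printed values against its printed
# result: the spread induced by rounding of the inputs plus half an ULP of
# the printed result. Entries flagged approximate (the source marks them
# "~", errors > 50%) get a flat 15% relative band instead.
ratio_check <- function(num, num_dp, den, den_dp, printed, printed_dp,
                        approx = FALSE) {
  computed <- num / den
  if (approx) {
    return(list(computed = computed,
                ok = abs(computed - printed) <= 0.15 * printed))
  }
  ni <- printed_interval(num, num_dp)
  di <- printed_interval(den, den_dp)
  lo <- ni[["lo"]] / di[["hi"]]
  hi <- ni[["hi"]] / di[["lo"]]
  h <- 0.5 * 10^(-printed_dp)
  list(computed = computed,
       ok = printed >= lo - h && printed <= hi + h)
}

# Canonical strongly cooperative truth used across fitting tests
# (wild-type-with-m7Guo-like, phosphate as the variable substrate).
wt_like_truth <- function() is_params(Km1 = 0.015, Vmax1 = 10.8,
                                      a = 266.67, b = 0.7593)

# log-uniform random draw
rlogunif <- function(n, lo = 1e-3, hi = 1e3) {
  exp(stats::runif(n, log(lo), log(hi)))
}
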