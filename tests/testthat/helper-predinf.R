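# shared small fixtures, built once per test run
.predinf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.predinf_cache[[key]])) .predinf_cache[[key]] <- force(expr)
  .predinf_cache[[key]]
}

small_cohort <- function() {
  cached("coh40", simulate_cohort(40, seed = 101))
}

small_analysis_data <- function() {
  cached("ad40", prepare_analysis_data(small_cohort()))
}

# circular mean oracle for wrap checks
circular_mean <- function(x) {
  rad <- x * pi / 180
  wrap_position(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}
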