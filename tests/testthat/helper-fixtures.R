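# Shared fixtures and small generators used across test files.

fx <- flex_ru2_parameters()

# Random positive rate sets on a log-uniform scale
random_rates <- function(n, seed) {
  set.seed(seed)
  replicate(n, {
    v <- 10^runif(4, -4, 0)
    elementary_rates(v[1], v[2], v[3], v[4])
  }, simplify = FALSE)
}

# Noiseless bi-exponential trace from known parameters
biexp_trace <- function(p, duration = 600, rate = 1, force = 20, conc = 5) {
  tt <- seq(1 / rate, duration, by = 1 / rate)
  threading_trace(tt, biexp_extension(p, tt), force, conc)
}
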