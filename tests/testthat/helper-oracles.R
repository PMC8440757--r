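# Independent oracles used across the suite.

# Exhaustive enumeration of P(device ON within N pulses) for a k-element
# serial device with per-pulse SET probability p: sums the probability of
# every Bernoulli outcome sequence containing >= k successes. Independent
# of any distribution function in the package or in stats.
enumerate_on_probability <- function(k, p, N) {
  if (N == 0) return(0)
  total <- 0
  for (code in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(code))[1:N]
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# Tiny toy dataset helpers
toy_spec <- function(...) synthetic_pattern_spec(...)

# Two orthogonal half-field patterns for the 2-neuron WTA checks
orthogonal_patterns <- function(n_pixels = 100, intensity = 220) {
  a <- numeric(n_pixels); b <- numeric(n_pixels)
  a[1:(n_pixels / 2)] <- intensity
  b[(n_pixels / 2 + 1):n_pixels] <- intensity
  list(a = a, b = b)
}
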