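# Shared fixtures: the published rate-constant set and random admissible
# draws for property-style tests.

ref_k <- function() rate_constants(reference_rate_constants()$estimate)

# Strictly positive random rate constants on the scale of the system
# (1e-4 .. 5e-3 min^-1).
random_k <- function(seed) {
  withr::local_seed(seed)
  stats::runif(12, min = 1e-4, max = 5e-3)
}

# Nonnegative random draws, with some entries zeroed to exercise bounds.
random_k_with_zeros <- function(seed) {
  withr::local_seed(seed)
  k <- stats::runif(12, min = 0, max = 5e-3)
  k[stats::runif(12) < 0.2] <- 0
  k
}

default_times <- function() seq(0, 360, by = 40)

pure_A <- function() c(1, rep(0, 8))
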