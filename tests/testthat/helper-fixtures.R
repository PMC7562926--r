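# shared fixture builders (all generated in code, no stored data)

# small stack of random nonnegative patterns (not mode-based), unit-sum rows
random_stack <- function(np, side, seed = 1) {
  g <- grid_spec(side)
  p <- with_seed_test(seed, matrix(stats::runif(np * side^2), np, side^2))
  p <- p / rowSums(p)
  lanternimg:::new_pattern_stack(p, g, "unit_sum", "simulated", seed = seed)
}

# identity measurement stack: pattern p is an impulse at pixel p
identity_stack <- function(side) {
  g <- grid_spec(side)
  lanternimg:::new_pattern_stack(diag(side^2), g, "unit_sum", "simulated")
}

manual_measurements <- function(y, epsilon, noise_sigma = 0) {
  lanternimg:::new_measurement_set(y, noise_sigma, epsilon)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
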