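# shared fixtures built in code

# quadrature oracle for the orientation-averaged stick signal
quad_astrosticks <- function(b, d) {
  vapply(b, function(bb) {
    integrate(function(t) exp(-bb * 1e-3 * d * t^2), 0, 1,
              rel.tol = 1e-12)$value
  }, numeric(1))
}

# small, fast phantom dataset used across tests
small_phantom_dataset <- function(grid = c(12, 12, 2), snr = 50, seed = 11,
                                  classes = tissue_classes()) {
  spec <- phantom_spec(grid = grid, classes = classes, snr = snr, seed = seed)
  ds <- simulate_signals(make_phantom(spec), kidney_full_protocol(), spec)
  ds
}

# cohort in which the measurements of 5 of the 9 b-values are replaced by
# noise-floor magnitudes (Rayleigh over a noisy b0): no signal information
planted_cohort <- function(n_subjects, seed, grid = c(16, 16, 2), snr = 50,
                           noise_combos = c(2, 4, 6, 8, 9)) {
  spec <- phantom_spec(grid = grid, snr = snr)
  coh <- make_cohort(spec, n_subjects, seed)
  lapply(seq_along(coh), function(i) {
    x <- coh[[i]]$dw_directions
    set.seed(seed * 1000 + i)
    sg <- 1 / snr
    for (j in noise_combos) for (k in 1:3) {
      col <- (j - 1L) * 3L + k
      x[, col] <- pmax(
        sqrt(rnorm(nrow(x), 0, sg)^2 + rnorm(nrow(x), 0, sg)^2) /
          sqrt((1 + rnorm(nrow(x), 0, sg))^2 + rnorm(nrow(x), 0, sg)^2),
        1e-6)
    }
    x
  })
}

mean_scores_by_b <- function(scores, n_directions = 3) {
  nb <- length(scores) / n_directions
  vapply(seq_len(nb), function(j)
    mean(scores[((j - 1) * n_directions + 1):(j * n_directions)]), numeric(1))
}
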