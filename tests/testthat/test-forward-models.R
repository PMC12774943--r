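sch <- kidney_full_protocol()

test_that("all compartment and composite signals equal 1 at b = 0", {
  expect_equal(signal_sphere_gpd(7, 2, b = 0, delta = 4.8, Delta = 27), 1)
  expect_equal(signal_astrosticks(0, 50), 1)
  expect_equal(signal_ball(0, 2), 1)
  p <- tissue_params(0.3, 0.5, R = 7)
  b0sch <- acq_scheme(b = 0, delta = 4.8, Delta = 27)
  expect_equal(model_signal("verdict", p, b0sch), 1)
  expect_equal(model_signal("ivim", list(f = 0.2, D = 1.5, Dstar = 30),
                            b0sch), 1)
  expect_equal(model_signal("adc", list(adc = 1.7), b0sch), 1)
})

test_that("a vanishing sphere does not attenuate", {
  s <- signal_sphere_gpd(1e-3, 2, b = sch$b, delta = sch$delta,
                         Delta = sch$Delta)
  expect_true(all(abs(s - 1) < 1e-6))
})

test_that("astrosticks closed form matches numerical quadrature to 1e-6", {
  for (d in c(2, 50)) {
    s <- signal_astrosticks(sch$b, d)
    q <- quad_astrosticks(sch$b, d)
    expect_true(all(abs(s - q) <= 1e-6))
  }
  # small-argument regime crosses into the series branch smoothly
  bs <- c(1e-6, 1e-3, 0.1, 1)
  expect_true(all(abs(signal_astrosticks(bs, 2) -
                        quad_astrosticks(bs, 2)) <= 1e-6))
})

test_that("ball attenuation follows the exponential identities", {
  expect_equal(signal_ball(1000, 2), exp(-2))
  expect_equal(signal_ball(2000, 2), signal_ball(1000, 2)^2)
  expect_error(signal_ball(1000, -1), "positive")
})

test_that("model signals stay in (0, 1] over the parameter ranges", {
  set.seed(1)
  for (i in 1:25) {
    f_ic <- runif(1); f_ees <- runif(1, 0, 1 - f_ic); R <- runif(1, 0, 15)
    s <- model_signal("verdict", tissue_params(f_ic, f_ees, R), sch)
    expect_true(all(s > 0 & s <= 1))
  }
})

test_that("sphere attenuation is monotone in b, d and R over the protocol", {
  combo <- sch[7, ]  # b = 2000
  # non-increasing in b at fixed timing
  bgrid <- seq(0, 3000, by = 250)
  sb <- signal_sphere_gpd(7, 2, bgrid, combo$delta, combo$Delta)
  expect_true(all(diff(sb) <= 1e-12))
  # non-increasing in d while the diffusion length stays below the radius
  # (restricted diffusion is non-monotone in d globally: once spins sample
  # the whole sphere, further increasing d narrows the phase distribution
  # and the signal recovers)
  sd_ <- vapply(c(0.25, 0.5, 1, 2), function(d)
    signal_sphere_gpd(15, d, combo$b, combo$delta, combo$Delta), numeric(1))
  expect_true(all(diff(sd_) <= 1e-12))
  # increasing R never increases the signal (clamp range, all combos)
  for (j in seq_len(nrow(sch))) {
    sR <- vapply(seq(0.5, 15, by = 0.5), function(R)
      signal_sphere_gpd(R, 2, sch$b[j], sch$delta[j], sch$Delta[j]),
      numeric(1))
    expect_true(all(diff(sR) <= 1e-10))
  }
})

test_that("the GPD series is converged at the default root count", {
  c20 <- model_constants(n_gpd_roots = 20)
  c60 <- model_constants(n_gpd_roots = 60)
  for (R in c(1, 5, 10, 15)) {
    s20 <- signal_sphere_gpd(R, 2, sch$b, sch$delta, sch$Delta, c20)
    s60 <- signal_sphere_gpd(R, 2, sch$b, sch$delta, sch$Delta, c60)
    expect_true(all(abs(s20 - s60) < 1e-8))
  }
})

test_that("the VERDICT mixture is affine in the fractions at fixed R", {
  R <- 7
  s00 <- model_signal("verdict", tissue_params(0, 0, R), sch)     # pure stick
  s10 <- model_signal("verdict", tissue_params(1, 0, R), sch)     # pure sphere
  s01 <- model_signal("verdict", tissue_params(0, 1, R), sch)     # pure ball
  for (w in list(c(0.3, 0.5), c(0.1, 0.2), c(0.6, 0.4))) {
    s <- model_signal("verdict", tissue_params(w[1], w[2], R), sch)
    expect_equal(s, (1 - w[1] - w[2]) * s00 + w[1] * s10 + w[2] * s01,
                 tolerance = 1e-12)
  }
})

test_that("degenerate mixtures reduce to their single compartments", {
  expect_equal(model_signal("verdict", tissue_params(0, 1, R = 7), sch),
               signal_ball(sch$b, 2))
  expect_equal(model_signal("ivim", list(f = 0, D = 1.5, Dstar = 30), sch),
               model_signal("adc", list(adc = 1.5), sch))
  # composite equals the audited sum of its three compartments
  p <- tissue_params(0.3, 0.5, R = 7)
  manual <- p$f_vasc * signal_astrosticks(sch$b, 50) +
    p$f_ic * vapply(seq_len(9), function(j)
      signal_sphere_gpd(7, 2, sch$b[j], sch$delta[j], sch$Delta[j]),
      numeric(1)) +
    p$f_ees * signal_ball(sch$b, 2)
  expect_equal(model_signal("verdict", p, sch), manual, tolerance = 1e-12)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(tissue_params(-0.1, 0.5, 7), "fractions")
  expect_error(tissue_params(0.6, 0.6, 7), "exceed")
  expect_error(tissue_params(0.3, 0.5, 20), "radius")
  expect_error(signal_sphere_gpd(-1, 2, 100, 4.8, 27), "non-negative")
  expect_error(signal_astrosticks(100, -2), "positive")
})
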