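sch <- kidney_full_protocol()

test_that("noiseless single-model signals are recovered essentially exactly", {
  y_adc <- model_signal("adc", list(adc = 1.7), sch)
  f <- fit_nlls("adc", y_adc, sch)
  expect_lt(abs(coef(f)[["adc"]] - 1.7), 1e-6)
  expect_lt(f$mse, 1e-12)

  y_iv <- model_signal("ivim", list(f = 0.2, D = 1.5, Dstar = 30), sch)
  fi <- fit_nlls("ivim", y_iv, sch)
  expect_lt(abs(coef(fi)[["f"]] - 0.2), 1e-3)
  expect_lt(abs(coef(fi)[["D"]] - 1.5), 1e-3)

  y_v <- model_signal("verdict", tissue_params(0.3, 0.5, R = 7), sch)
  fv <- fit_nlls("verdict", y_v, sch)
  expect_lt(abs(coef(fv)[["f_ic"]] - 0.3), 1e-3)
  expect_lt(abs(coef(fv)[["f_ees"]] - 0.5), 1e-3)
  expect_lt(abs(coef(fv)[["R"]] - 7), 1e-2)
})

test_that("noiseless VERDICT recovery holds across a grid of interior truths", {
  for (f_ic in c(0.15, 0.35, 0.55)) {
    for (R in c(4, 8, 12)) {
      f_ees <- 0.8 - f_ic
      y <- model_signal("verdict", tissue_params(f_ic, f_ees, R), sch)
      f <- fit_nlls("verdict", y, sch)
      expect_lt(abs(coef(f)[["f_ic"]] - f_ic), 1e-2)
      expect_lt(abs(coef(f)[["f_ees"]] - f_ees), 1e-2)
    }
  }
})

test_that("the fit is deterministic and respects its bounds", {
  set.seed(5)
  y <- pmax(model_signal("verdict", tissue_params(0.4, 0.4, R = 9), sch) +
              rnorm(9, 0, 0.03), 1e-3)
  f1 <- fit_nlls("verdict", y, sch)
  f2 <- fit_nlls("verdict", y, sch)
  expect_identical(coef(f1), coef(f2))
  cf <- coef(f1)
  expect_true(cf[["f_ic"]] >= 0 && cf[["f_ic"]] <= 1)
  expect_true(cf[["f_ees"]] >= 0 && cf[["f_ees"]] <= 1)
  expect_true(cf[["R"]] >= 0 && cf[["R"]] <= 15)
  expect_equal(sum(cf[c("f_ic", "f_ees", "f_vasc")]), 1, tolerance = 1e-9)
})

test_that("fit_nlls validates its inputs", {
  expect_error(fit_nlls("adc", c(1, 0.5), sch), "combos")
  expect_error(fit_nlls("adc", c(rep(0.5, 8), NA), sch), "finite")
  expect_error(fit_nlls("adc", c(rep(0.5, 8), -0.1), sch), "finite")
})

test_that("model_mse computes residual identities", {
  y <- model_signal("adc", list(adc = 2), sch)
  f <- fit_nlls("adc", y, sch)
  expect_equal(model_mse(f, y), 0, tolerance = 1e-12)
  # constant prediction: MSE equals the mean squared deviation about it
  const <- rep(0.5, 9)
  expect_equal(model_mse(const, y), mean((y - 0.5)^2))
  expect_error(model_mse(const, y[1:5]), "mismatch")
})

test_that("IVIM never fits worse than its nested ADC model", {
  set.seed(42)
  for (i in 1:10) {
    truth <- tissue_params(runif(1, 0.1, 0.5), runif(1, 0.2, 0.5),
                           runif(1, 3, 12))
    y <- pmax(model_signal("verdict", truth, sch) + rnorm(9, 0, 0.02), 1e-3)
    m_ivim <- fit_nlls("ivim", y, sch)$mse
    m_adc <- fit_nlls("adc", y, sch)$mse
    expect_lte(m_ivim, m_adc + 1e-10)
  }
})

test_that("Rician-noise recovery error stays within the frozen bound", {
  # recovery simulation: 60 repeats at SNR = 20 on a mid-range tumour-like
  # voxel; the median |f_ic error| bound was frozen from this simulation
  truth <- tissue_params(0.3, 0.5, R = 7)
  mu <- model_signal("verdict", truth, sch)
  set.seed(99)
  sg <- 1 / 20
  errs <- replicate(60, {
    b0 <- sqrt((1 + rnorm(9, 0, sg))^2 + rnorm(9, 0, sg)^2)
    dw <- vapply(seq_len(9), function(j) {
      mean(sqrt((mu[j] + rnorm(3, 0, sg))^2 + rnorm(3, 0, sg)^2))
    }, numeric(1))
    y <- pmax(dw / b0, 1e-4)
    abs(coef(fit_nlls("verdict", y, sch))[["f_ic"]] - truth$f_ic)
  })
  expect_lt(median(errs), 0.06)
})
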