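sch <- kidney_full_protocol()

test_that("class means land where configured and SD = 0 is exact", {
  cls <- tissue_classes()[1:3, ]
  cls$f_ic_sd <- 0; cls$f_ees_sd <- 0; cls$r_sd <- 0
  spec <- phantom_spec(grid = c(9, 6, 1), classes = cls, seed = 4)
  ph <- make_phantom(spec)
  for (k in seq_len(nrow(cls))) {
    sel <- ph$class_mask == k
    expect_true(all(ph$maps$maps$f_ic[sel] == cls$f_ic_mean[k]))
    expect_true(all(ph$maps$maps$f_ees[sel] == cls$f_ees_mean[k]))
    expect_true(all(ph$maps$maps$R[sel] == cls$r_mean[k]))
  }
})

test_that("the default class table encodes the reported tissue contrasts", {
  cls <- tissue_classes()
  rownames(cls) <- cls$name
  expect_equal(cls["normal_kidney", "f_ic_mean"], 0.12)
  expect_equal(cls["oncocytoma", "f_ic_mean"], 0.17)
  # cancer classes average near the reported cancer-vs-normal contrast
  cancer <- cls[cls$name %in% c("ccRCC", "pRCC", "chRCC", "uRCC"), ]
  wts <- c(5, 2, 4, 1)  # study tumour-type counts
  expect_equal(sum(cancer$f_ic_mean * wts) / sum(wts), 0.32,
               tolerance = 0.02)
  # vascular/non-vascular split of the derived vascular fraction
  fv <- 1 - cls$f_ic_mean - cls$f_ees_mean
  expect_equal(mean(fv[which(cls$vascular)]), 0.29, tolerance = 0.01)
  expect_equal(mean(fv[which(!cls$vascular)]), 0.13, tolerance = 0.01)
})

test_that("phantom generation is reproducible and classes are disjoint", {
  spec <- phantom_spec(grid = c(14, 8, 2), seed = 9)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$maps$maps, b$maps$maps)
  expect_true(all(table(a$class_mask[a$class_mask > 0]) > 0))
  # truths respect the model bounds
  expect_true(all(a$maps$maps$f_ic[a$class_mask > 0] >= 0))
  tot <- a$maps$maps$f_ic + a$maps$maps$f_ees
  expect_true(all(tot[a$class_mask > 0] <= 1))
})

test_that("noise-free simulation reproduces the forward model exactly", {
  spec <- phantom_spec(grid = c(8, 8, 1), snr = Inf, seed = 3)
  ph <- make_phantom(spec)
  ds <- simulate_signals(ph, sch, spec)
  truth <- attr(ds, "truth")
  lay <- verdictmri:::.volume_layout(sch)
  for (i in c(1, 10, 40)) {
    expected <- model_signal("verdict",
      tissue_params(truth[i, "f_ic"], truth[i, "f_ees"], truth[i, "R"]), sch)
    expect_equal(unname(ds$volumes[i, lay$dw_idx]), expected,
                 tolerance = 1e-10)
  }
  expect_true(all(ds$volumes[, lay$b0_idx] == 1))
  # the direction-resolved table equals the averaged one without noise
  expect_equal(unname(ds$dw_directions[, seq(1, 27, by = 3)]),
               unname(ds$volumes[, lay$dw_idx]), tolerance = 1e-10)
})

test_that("matched-b0 division cancels the T2 channel", {
  base <- phantom_spec(grid = c(8, 8, 1), snr = 40, seed = 6)
  with_t2 <- phantom_spec(grid = c(8, 8, 1), snr = 40, seed = 6,
                          t2 = c(80, 70, 60, 65, 75, 60, 200))
  ds0 <- simulate_signals(make_phantom(base), sch, base)
  ds1 <- simulate_signals(make_phantom(with_t2), sch, with_t2)
  # not bit-identical (noise is applied to different raw magnitudes), but
  # the normalised signal distribution is unchanged up to noise: compare
  # the noiseless part by switching noise off
  base_inf <- phantom_spec(grid = c(8, 8, 1), snr = Inf, seed = 6)
  t2_inf <- phantom_spec(grid = c(8, 8, 1), snr = Inf, seed = 6,
                         t2 = c(80, 70, 60, 65, 75, 60, 200))
  d0 <- simulate_signals(make_phantom(base_inf), sch, base_inf)
  d1 <- simulate_signals(make_phantom(t2_inf), sch, t2_inf)
  expect_equal(d0$volumes, d1$volumes, tolerance = 1e-12)
  expect_equal(dim(ds0$volumes), dim(ds1$volumes))
})

test_that("b0 magnitudes follow the closed-form Rice mean", {
  # direct check of the noise generator against the analytic Rice mean
  set.seed(123)
  for (snr in c(2, 10, 50)) {
    sg <- 1 / snr
    x <- sqrt((1 + rnorm(4e4, 0, sg))^2 + rnorm(4e4, 0, sg)^2)
    expect_equal(mean(x), rice_mean(1, sg),
                 tolerance = 4 * sg / sqrt(4e4) / rice_mean(1, sg))
  }
  # Rayleigh limit at zero signal
  expect_equal(rice_mean(0, 0.1), 0.1 * sqrt(pi / 2), tolerance = 1e-10)
})

test_that("the Rician generator has the right distributional limits", {
  set.seed(77)
  sgn <- function(n, nu, sg) sqrt((nu + rnorm(n, 0, sg))^2 + rnorm(n, 0, sg)^2)
  # high SNR: skewness of the magnitude tends to 0 (Gaussian limit)
  hi <- sgn(3e4, 1, 1 / 100)
  skew <- mean((hi - mean(hi))^3) / sd(hi)^3
  expect_lt(abs(skew), 0.1)
  # zero SNR: mean/sigma of the magnitude matches the Rayleigh value
  lo <- sgn(3e4, 0, 1)
  expect_equal(mean(lo), sqrt(pi / 2), tolerance = 0.02)
})

test_that("cohorts are reproducible, independent and sized as requested", {
  spec <- phantom_spec(grid = c(8, 8, 1), seed = 1)
  coh <- make_cohort(spec, n_subjects = 3, seed = 10)
  expect_length(coh, 3)
  coh2 <- make_cohort(spec, n_subjects = 3, seed = 10)
  expect_identical(coh[[2]]$volumes, coh2[[2]]$volumes)
  expect_false(identical(coh[[1]]$volumes, coh[[2]]$volumes))
  # a single-subject cohort equals the derived-seed subject pipeline
  one <- make_cohort(spec, n_subjects = 1, seed = 10)
  direct <- verdictmri:::.simulate_subject(spec, 11L)
  expect_identical(one[[1]]$volumes, direct$volumes)
})

test_that("noiseless phantom closes the loop through the classical fit", {
  # master regression: generator -> forward model -> NLLS recovers truth
  spec <- phantom_spec(grid = c(7, 4, 1), snr = Inf, seed = 13)
  ds <- simulate_signals(make_phantom(spec), sch, spec)
  truth <- attr(ds, "truth")
  lay <- verdictmri:::.volume_layout(sch)
  set.seed(2)
  idx <- sample(nrow(truth), 8)
  for (i in idx) {
    cf <- coef(fit_nlls("verdict", ds$volumes[i, lay$dw_idx], sch))
    interior <- truth[i, "f_ic"] > 0.02 && truth[i, "f_ic"] < 0.98 &&
      truth[i, "R"] > 1 && truth[i, "R"] < 14
    if (interior) {
      expect_lt(abs(cf[["f_ic"]] - truth[i, "f_ic"]), 1e-2)
      expect_lt(abs(cf[["f_ees"]] - truth[i, "f_ees"]), 1e-2)
    }
  }
})
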