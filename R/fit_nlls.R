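# Conventional bound-constrained least-squares fitting of the VERDICT, IVIM
# and ADC models. Serves as the reference ("classical") fit and as the oracle
# the self-supervised engine is compared against.

# parameter mapping shared with the network fit: clamp fractions to [0,1],
# renormalise proportionally when their sum exceeds 1, clamp R to [0,15].
.map_verdict_params <- function(f_ic, f_ees, R) {
  f_ic <- pmin(pmax(f_ic, 0), 1)
  f_ees <- pmin(pmax(f_ees, 0), 1)
  s <- f_ic + f_ees
  over <- s > 1
  f_ic[over] <- f_ic[over] / s[over]
  f_ees[over] <- f_ees[over] / s[over]
  list(f_ic = f_ic, f_ees = f_ees,
       f_vasc = pmax(0, 1 - f_ic - f_ees),
       R = pmin(pmax(R, 0), 15))
}

# compartment basis signals over a scheme (VERDICT is affine in the fractions
# at fixed R, so fits and network gradients reuse these three vectors)
.verdict_basis <- function(scheme, R, d_ic = 2, d_ees = 2, d_vasc = 50,
                           constants = model_constants()) {
  list(stick = signal_astrosticks(scheme$b, d_vasc),
       sphere = .sphere_gpd_matrix(R, d_ic, scheme$b, scheme$delta,
                                   scheme$Delta, constants$n_gpd_roots),
       ball = signal_ball(scheme$b, d_ees))
}

.verdict_pred <- function(theta, scheme, constants = model_constants()) {
  p <- .map_verdict_params(theta[1], theta[2], theta[3])
  bas <- .verdict_basis(scheme, p$R, constants = constants)
  p$f_vasc * bas$stick + p$f_ic * drop(bas$sphere) + p$f_ees * bas$ball
}

#' Control settings for the classical fit
#'
#' @param n_grid points per free parameter in the deterministic multi-start
#'   grid (VERDICT: `n_grid^3` candidate starts on the fraction simplex x R).
#' @param n_refine number of best grid starts polished with
#'   Levenberg-Marquardt; the lowest-loss polished start wins, ties broken by
#'   lowest start index.
#' @param maxiter LM iteration cap per start.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(n_grid = 5L, n_refine = 3L, maxiter = 100L) {
  stopifnot(n_grid >= 2L, n_refine >= 1L)
  structure(list(n_grid = as.integer(n_grid), n_refine = as.integer(n_refine),
                 maxiter = as.integer(maxiter)), class = "fit_control")
}

# deterministic VERDICT start grid: (f_ic, f_ees) on the simplex x R interior
.verdict_grid <- function(n) {
  fr <- seq(0.05, 0.9, length.out = n)
  Rg <- seq(1.5, 13.5, length.out = n)
  g <- expand.grid(f_ic = fr, f_ees = fr, R = Rg)
  g[g$f_ic + g$f_ees <= 0.95, , drop = FALSE]
}

#' Classical bound-constrained least-squares model fit
#'
#' Fits the VERDICT, IVIM or ADC model to a normalised per-combo signal
#' vector by deterministic multi-start bound-constrained least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}). The start grid is fixed, so
#' the fit is fully deterministic given the data and control settings.
#'
#' Bounds: VERDICT fractions in \[0, 1\] on the simplex, R in \[0, 15\] um;
#' ADC in (0, 4\] um^2/ms; IVIM f in \[0, 1\], D in (0, 4\],
#' D* in \[4, 100\] um^2/ms.
#'
#' @param model `"verdict"`, `"ivim"` or `"adc"`.
#' @param signals normalised signal vector, one value per combo.
#' @param scheme an [acq_scheme()] with `nrow(scheme) == length(signals)`.
#' @param control a [fit_control()].
#' @param constants a [model_constants()].
#' @return An object of class `verdict_fit` with elements `model`, `method`,
#'   `coefficients`, `fitted`, `mse`, `n_starts`, `scheme`, `data`.
#' @seealso [verdict_fit()], [model_mse()]
#' @export
#' @examples
#' sch <- kidney_full_protocol()
#' y <- model_signal("verdict", tissue_params(0.3, 0.5, R = 7), sch)
#' fit_nlls("verdict", y, sch)
fit_nlls <- function(model = c("verdict", "ivim", "adc"), signals, scheme,
                     control = fit_control(), constants = model_constants()) {
  model <- match.arg(model)
  stopifnot(inherits(scheme, "acq_scheme"))
  if (length(signals) != nrow(scheme))
    stop("signals length (", length(signals), ") must equal the number of combos (",
         nrow(scheme), ")")
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("signals must be finite and positive")
  b <- scheme$b

  fit <- switch(model,
    adc = {
      # log-linear start (exact in the noiseless case), LM polish in bounds
      adc0 <- max(1e-4, min(4, -coef(lm(log(signals) ~ 0 + I(b * 1e-3)))[[1]]))
      r <- minpack.lm::nls.lm(
        par = adc0, lower = 1e-6, upper = 4,
        fn = function(p) signal_ball(b, p) - signals,
        control = minpack.lm::nls.lm.control(maxiter = control$maxiter))
      list(coef = c(adc = unname(r$par)),
           pred = signal_ball(b, r$par), n_starts = 1L)
    },
    ivim = {
      starts <- expand.grid(f = c(0.05, 0.2, 0.4), D = c(1, 2, 3),
                            Dstar = c(8, 20, 60))
      resfn <- function(p) p[1] * signal_ball(b, p[3]) +
        (1 - p[1]) * signal_ball(b, p[2]) - signals
      best <- NULL
      for (i in seq_len(nrow(starts))) {
        r <- minpack.lm::nls.lm(
          par = as.numeric(starts[i, ]), lower = c(0, 1e-6, 4),
          upper = c(1, 4, 100), fn = resfn,
          control = minpack.lm::nls.lm.control(maxiter = control$maxiter))
        if (is.null(best) || r$deviance < best$deviance - 1e-15) best <- r
      }
      p <- best$par
      list(coef = c(f = p[1], D = p[2], Dstar = p[3]),
           pred = p[1] * signal_ball(b, p[3]) + (1 - p[1]) * signal_ball(b, p[2]),
           n_starts = nrow(starts))
    },
    verdict = {
      grid <- .verdict_grid(control$n_grid)
      # vectorised loss over the whole grid: basis depends on R only
      Rvals <- unique(grid$R)
      loss <- numeric(nrow(grid))
      for (Rv in Rvals) {
        idx <- which(grid$R == Rv)
        bas <- .verdict_basis(scheme, Rv, constants = constants)
        sph <- drop(bas$sphere)
        for (i in idx) {
          fic <- grid$f_ic[i]; fees <- grid$f_ees[i]
          pred <- (1 - fic - fees) * bas$stick + fic * sph + fees * bas$ball
          loss[i] <- mean((pred - signals)^2)
        }
      }
      ord <- order(loss)                       # stable: ties keep grid order
      resfn <- function(p) .verdict_pred(p, scheme, constants) - signals
      best <- NULL
      for (i in ord[seq_len(min(control$n_refine, length(ord)))]) {
        r <- minpack.lm::nls.lm(
          par = as.numeric(grid[i, ]), lower = c(0, 0, 0), upper = c(1, 1, 15),
          fn = resfn,
          control = minpack.lm::nls.lm.control(maxiter = control$maxiter))
        if (is.null(best) || r$deviance < best$deviance - 1e-15) best <- r
      }
      p <- .map_verdict_params(best$par[1], best$par[2], best$par[3])
      list(coef = c(f_ic = p$f_ic, f_ees = p$f_ees, f_vasc = p$f_vasc, R = p$R),
           pred = .verdict_pred(best$par, scheme, constants),
           n_starts = nrow(grid))
    }
  )

  structure(list(model = model, method = "nlls",
                 coefficients = fit$coef, fitted = fit$pred,
                 mse = mean((fit$pred - signals)^2),
                 n_starts = fit$n_starts, scheme = scheme, data = signals),
            class = "verdict_fit")
}

#' Mean squared error between a fit's prediction and observed signals
#'
#' @param fit a `verdict_fit` object (or anything with a `fitted` element).
#' @param signals observed normalised signals, same length as the prediction.
#' @return Mean of squared residuals over combos.
#' @export
model_mse <- function(fit, signals) {
  pred <- if (is.list(fit)) fit$fitted else fit
  if (length(pred) != length(signals)) stop("prediction/signal length mismatch")
  mean((pred - signals)^2)
}
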