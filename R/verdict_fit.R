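#' Fit a diffusion model to renal DWI data
#'
#' The single entry point for model fitting. For a per-ROI signal vector it
#' dispatches to the classical multi-start least-squares fit ([fit_nlls()]);
#' for a whole [voxel_dataset()] it dispatches to the self-supervised
#' network fit ([fit_selfsupervised()], VERDICT only) or to voxelwise
#' classical fits. Returns a classed model object with `print`, `summary`,
#' `coef`, `predict`, `residuals`, `plot` and `simulate` methods.
#'
#' @param x normalised per-combo signal vector, or a [voxel_dataset()].
#' @param scheme an [acq_scheme()]; defaults to the dataset's own scheme.
#' @param model `"verdict"`, `"ivim"` or `"adc"`.
#' @param method `"nlls"` (classical) or `"selfsupervised"` (dataset input,
#'   VERDICT only). Defaults to `"nlls"` for vectors and `"selfsupervised"`
#'   for datasets.
#' @param control a [fit_control()] or [train_config()] matching `method`.
#' @param constants a [model_constants()].
#' @return An object of class `verdict_fit` (additionally `verdict_selfsup`
#'   for the network fit, `verdict_voxelwise` for voxelwise classical fits).
#' @export
#' @examples
#' sch <- kidney_full_protocol()
#' y <- model_signal("verdict", tissue_params(0.3, 0.5, R = 7), sch)
#' fit <- verdict_fit(y, sch)
#' coef(fit)
verdict_fit <- function(x, scheme = NULL,
                        model = c("verdict", "ivim", "adc"),
                        method = NULL, control = NULL,
                        constants = model_constants()) {
  model <- match.arg(model)
  if (inherits(x, "voxel_dataset")) {
    if (is.null(scheme)) scheme <- x$scheme
    if (is.null(method)) method <- "selfsupervised"
    if (method == "selfsupervised") {
      if (model != "verdict")
        stop("the self-supervised fit implements the VERDICT model only")
      if (is.null(control)) control <- train_config()
      return(fit_selfsupervised(x, scheme, control, constants))
    }
    if (is.null(control)) control <- fit_control()
    lay <- .volume_layout(scheme)
    sig <- x$volumes[, lay$dw_idx, drop = FALSE]
    fits <- lapply(seq_len(nrow(sig)), function(i)
      fit_nlls(model, sig[i, ], scheme, control, constants))
    coefs <- do.call(rbind, lapply(fits, coef))
    out <- structure(list(model = model, method = "nlls_voxelwise",
                          coefficients = coefs,
                          fitted = do.call(rbind, lapply(fits, fitted)),
                          mse = vapply(fits, function(f) f$mse, numeric(1)),
                          scheme = scheme, data = sig),
                     class = c("verdict_voxelwise", "verdict_fit"))
    return(out)
  }
  if (is.null(scheme)) stop("a scheme is required for signal-vector input")
  if (is.null(method)) method <- "nlls"
  if (method != "nlls") stop("signal-vector input supports method = 'nlls'")
  if (is.null(control)) control <- fit_control()
  fit_nlls(model, x, scheme, control, constants)
}

#' @export
print.verdict_fit <- function(x, digits = 4, ...) {
  cat(toupper(x$model), " fit (", x$method, ")\n", sep = "")
  if (is.matrix(x$coefficients)) {
    cat(nrow(x$coefficients), "voxels; parameter means:\n")
    print(round(colMeans(x$coefficients), digits))
  } else {
    print(round(x$coefficients, digits))
  }
  cat("MSE:", format(mean(x$mse), digits = digits), "\n")
  invisible(x)
}

#' @export
coef.verdict_fit <- function(object, ...) object$coefficients

#' @export
fitted.verdict_fit <- function(object, ...) object$fitted

#' @export
residuals.verdict_fit <- function(object, ...) {
  if (is.matrix(object$fitted)) {
    lay <- .volume_layout(object$scheme)
    obs <- if (ncol(object$data) == ncol(object$fitted)) object$data
           else object$data[, lay$dw_idx, drop = FALSE]
    obs - object$fitted
  } else {
    object$data - object$fitted
  }
}

#' Predict normalised signals from a fitted model
#'
#' @param object a `verdict_fit`.
#' @param scheme scheme to predict on; default: the fitted scheme.
#' @param ... unused.
#' @return Per-combo signal vector (or voxels x combos matrix).
#' @export
predict.verdict_fit <- function(object, scheme = object$scheme, ...) {
  cf <- object$coefficients
  one <- function(p) {
    switch(object$model,
      verdict = model_signal("verdict",
        tissue_params(p[["f_ic"]], p[["f_ees"]], p[["R"]]), scheme),
      ivim = model_signal("ivim",
        list(f = p[["f"]], D = p[["D"]], Dstar = p[["Dstar"]]), scheme),
      adc = model_signal("adc", list(adc = p[["adc"]]), scheme))
  }
  if (is.matrix(cf)) t(apply(cf, 1, one)) else one(cf)
}

#' @export
summary.verdict_fit <- function(object, ...) {
  cf <- object$coefficients
  tab <- if (is.matrix(cf)) {
    data.frame(parameter = colnames(cf), mean = colMeans(cf),
               sd = apply(cf, 2, sd), row.names = NULL)
  } else {
    data.frame(parameter = names(cf), estimate = unname(cf))
  }
  out <- list(model = object$model, method = object$method, table = tab,
              mse = mean(object$mse),
              n_voxels = if (is.matrix(cf)) nrow(cf) else 1L,
              converged = object$converged, best_epoch = object$best_epoch)
  class(out) <- "summary.verdict_fit"
  out
}

#' @export
print.summary.verdict_fit <- function(x, digits = 4, ...) {
  cat(toupper(x$model), " fit (", x$method, "), ", x$n_voxels, " voxel(s)\n",
      sep = "")
  print(x$table, digits = digits, row.names = FALSE)
  cat("mean MSE:", format(x$mse, digits = digits), "\n")
  if (!is.null(x$converged))
    cat(if (isTRUE(x$converged)) "early stopping at epoch" else
        "epoch cap reached; best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Plot a fitted signal curve or parameter map
#'
#' For a per-ROI fit, plots the observed normalised signals against b with
#' the model prediction overlaid. For a self-supervised (map) fit, shows one
#' axial slice of a parameter map.
#'
#' @param x a `verdict_fit`.
#' @param parameter map name to display (map fits only).
#' @param slice axial slice index (map fits only).
#' @param ... passed to the underlying plotting function.
#' @export
plot.verdict_fit <- function(x, parameter = "f_ic", slice = 1L, ...) {
  if (!is.null(x$maps)) {
    m <- x$maps$maps[[parameter]]
    if (is.null(m)) stop("no map named '", parameter, "'")
    graphics::image(m[, , slice], main = paste(parameter, "slice", slice),
                    useRaster = TRUE, ...)
    return(invisible(x))
  }
  b <- x$scheme$b
  graphics::plot(b, x$data, xlab = "b (s/mm^2)",
                 ylab = "normalised signal", ylim = c(0, 1.05), ...)
  ord <- order(b)
  graphics::lines(b[ord], x$fitted[ord], col = "red3")
  graphics::legend("topright", legend = c("data", toupper(x$model)),
                   pch = c(1, NA), lty = c(NA, 1), col = c("black", "red3"))
  invisible(x)
}

#' Simulate noisy signal replicates from a fitted model
#'
#' Draws Rician-noise replicates of the fitted signal at a given b0 SNR
#' (noise applied per combo, then renormalised by a noisy b0, mirroring the
#' acquisition chain).
#'
#' @param object a `verdict_fit` (per-ROI).
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param snr b0 signal-to-noise ratio.
#' @param ... unused.
#' @return A combos x nsim matrix of simulated normalised signals.
#' @export
simulate.verdict_fit <- function(object, nsim = 1, seed = NULL, snr = 50,
                                 ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.matrix(object$fitted)) colMeans(object$fitted) else
    object$fitted
  sigma <- 1 / snr
  replicate(nsim, {
    b0 <- sqrt((1 + rnorm(length(mu), 0, sigma))^2 +
                 rnorm(length(mu), 0, sigma)^2)
    dw <- sqrt((mu + rnorm(length(mu), 0, sigma))^2 +
                 rnorm(length(mu), 0, sigma)^2)
    dw / b0
  })
}
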