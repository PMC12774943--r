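#' Monte-Carlo random-walk oracle for the GPD sphere signal
#'
#' Simulates reflecting Brownian walkers inside an impermeable sphere and
#' accrues spin phase under the two PGSE gradient lobes; the attenuation is
#' the magnitude of the mean complex phasor. This is an independent
#' validation oracle for [signal_sphere_gpd()]; it is far slower and is not
#' part of any fitting path.
#'
#' @param R sphere radius, um.
#' @param d diffusivity, um^2/ms.
#' @param combo list or one-row data frame with `b` (s/mm^2), `delta`, `Delta`
#'   (ms).
#' @param n_walkers number of walkers (>= 1e4).
#' @param seed RNG seed (integer); the walk is reproducible under a fixed seed.
#' @param n_steps time steps over the interval \[0, Delta + delta\]; the
#'   default chooses the step so the RMS per-axis displacement stays below
#'   R/10 (bounded to 800-6000 steps).
#' @return List with `estimate`, `se` (standard error), `step_um` (RMS
#'   per-axis step) and `coarse_step` (`TRUE` with a warning recorded when the
#'   step exceeds R/10, which biases the reflection).
#' @export
#' @examples
#' \donttest{
#' mc_sphere_oracle(7, 2, list(b = 2000, delta = 16.8, Delta = 37.5),
#'                  n_walkers = 2e4, seed = 1)
#' }
mc_sphere_oracle <- function(R, d, combo, n_walkers = 1e5, seed = 1,
                             n_steps = NULL) {
  stopifnot(n_walkers >= 1e4, R > 0, d >= 0)
  b <- combo$b; delta <- combo$delta; Delta <- combo$Delta
  stopifnot(delta < Delta, b >= 0)
  if (is.null(n_steps)) {
    dt_max <- (R / 10)^2 / (2 * max(d, 1e-12))
    n_steps <- min(6000L, max(800L, ceiling((Delta + delta) / dt_max)))
  }
  gamma_g <- sqrt(.gamma2g2(b, delta, Delta))   # rad / (um ms)
  set.seed(as.integer(seed))
  res <- .mc_sphere_walk(R, d, delta, Delta, gamma_g,
                         as.integer(n_walkers), as.integer(n_steps))
  res$coarse_step <- res$step_um > R / 10
  if (res$coarse_step) {
    warning("MC step (", signif(res$step_um, 3), " um) is coarse relative to R; ",
            "increase n_steps")
  }
  res
}
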