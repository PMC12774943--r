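# Synthetic renal phantom and cohort generator. Tissue contrasts follow the
# reported group-level parameter estimates (normal parenchyma f_ic ~ 0.12,
# cancerous tumours ~ 0.32 on average, oncocytoma ~ 0.17; vascular tumours
# f_vasc ~ 0.29 vs 0.13 in non-vascular). Cell radii are plausible defaults
# inside the [0, 15] um model range; no per-class radii are reported, so they
# are synthetic choices, not measured values.

#' Default tissue class table
#'
#' One row per tissue class with means and SDs for f_ic, f_ees and R (um) and
#' a vascular flag (`NA` where the vascular/non-vascular tumour grouping does
#' not apply). f_vasc is derived per voxel as 1 - f_ic - f_ees; class means
#' were chosen so the vascular classes centre near f_vasc = 0.29 and the
#' non-vascular near 0.13.
#'
#' @return Data frame of class specs usable in [phantom_spec()].
#' @export
tissue_classes <- function() {
  data.frame(
    name     = c("normal_kidney", "ccRCC", "pRCC", "chRCC", "oncocytoma",
                 "uRCC", "cyst"),
    f_ic_mean  = c(0.12, 0.26, 0.55, 0.21, 0.17, 0.59, 0.02),
    f_ic_sd    = c(0.03, 0.05, 0.05, 0.05, 0.04, 0.05, 0.01),
    f_ees_mean = c(0.68, 0.45, 0.32, 0.50, 0.54, 0.28, 0.93),
    f_ees_sd   = c(0.05, 0.05, 0.04, 0.05, 0.05, 0.04, 0.02),
    r_mean     = c(5, 7, 9, 7, 6, 10, 3),
    r_sd       = c(0.5, 0.7, 0.8, 0.7, 0.6, 0.8, 0.5),
    vascular   = c(NA, TRUE, FALSE, TRUE, TRUE, FALSE, NA)
  )
}

#' Phantom specification
#'
#' Describes a rectangular digital phantom: grid shape, which tissue classes
#' occupy it (disjoint slabs along the first axis), the Rician noise level as
#' b0 SNR, an optional per-class T2 for the matched-b0 channel, and the seed.
#'
#' @param grid integer grid dimensions (default 32 x 32 x 4: desk scale, yet
#'   about a thousand voxels per class for recovery statistics).
#' @param classes tissue class table as from [tissue_classes()]; subsets are
#'   fine.
#' @param snr b0 signal-to-noise ratio; `Inf` disables noise.
#' @param t2 optional numeric vector of per-class T2 values (ms), recycled
#'   over classes; `NULL` disables the T2 channel (normalised signals are
#'   unaffected either way, because matched-b0 division cancels TE decay).
#' @param seed RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32, 32, 4), classes = tissue_classes(),
                         snr = 50, t2 = NULL, seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 1L), snr > 0, nrow(classes) >= 1L)
  if (any(classes$f_ic_mean < 0 | classes$f_ic_mean > 1) ||
      any(classes$f_ees_mean < 0 | classes$f_ees_mean > 1) ||
      any(classes$f_ic_mean + classes$f_ees_mean > 1) ||
      any(classes$r_mean < 0 | classes$r_mean > 15))
    stop("class means must lie inside the model parameter bounds")
  if (any(classes$f_ic_sd < 0 | classes$f_ees_sd < 0 | classes$r_sd < 0))
    stop("class SDs must be >= 0")
  structure(list(grid = as.integer(grid), classes = classes, snr = snr,
                 t2 = t2, seed = as.integer(seed)), class = "phantom_spec")
}

# truncated-normal draw by resampling out-of-range values
.rtrunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a ground-truth phantom
#'
#' Assigns each tissue class a disjoint slab of the grid and draws voxelwise
#' ground-truth parameters from truncated normals within the model bounds
#' (fraction pairs violating f_ic + f_ees <= 1 are redrawn).
#'
#' @param spec a [phantom_spec()].
#' @return List of class `phantom`: `maps` (ground-truth [param_maps()]),
#'   `class_mask` (integer array, 0 outside), `classes`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid
  cls <- spec$classes
  nc <- nrow(cls)
  if (g[1] < nc) stop("grid too small for ", nc, " disjoint class slabs")
  # slab boundaries along the first axis; disjoint by construction
  edges <- floor(seq(0, g[1], length.out = nc + 1L))
  class_mask <- array(0L, g)
  f_ic <- array(NA_real_, g); f_ees <- array(NA_real_, g)
  R <- array(NA_real_, g)
  for (k in seq_len(nc)) {
    rows <- (edges[k] + 1L):edges[k + 1L]
    sel <- array(FALSE, g); sel[rows, , ] <- TRUE
    n <- sum(sel)
    repeat {
      fi <- .rtrunc(n, cls$f_ic_mean[k], cls$f_ic_sd[k], 0, 1)
      fe <- .rtrunc(n, cls$f_ees_mean[k], cls$f_ees_sd[k], 0, 1)
      bad <- fi + fe > 1
      if (!any(bad)) break
      # redraw violating pairs jointly
      keep_i <- fi[!bad]; keep_e <- fe[!bad]
      n_bad <- sum(bad)
      fi2 <- .rtrunc(n_bad, cls$f_ic_mean[k], cls$f_ic_sd[k], 0, 1)
      fe2 <- .rtrunc(n_bad, cls$f_ees_mean[k], cls$f_ees_sd[k], 0, 1)
      fi <- c(keep_i, fi2); fe <- c(keep_e, fe2)
      if (!any(fi + fe > 1)) break
    }
    class_mask[sel] <- k
    f_ic[sel] <- fi; f_ees[sel] <- fe
    R[sel] <- .rtrunc(n, cls$r_mean[k], cls$r_sd[k], 0, 15)
  }
  inside <- class_mask > 0L
  maps <- param_maps(list(f_ic = f_ic, f_ees = f_ees,
                          f_vasc = array(pmax(0, 1 - f_ic - f_ees), g),
                          R = R),
                     mask = inside)
  structure(list(maps = maps, class_mask = class_mask, classes = cls,
                 spec = spec), class = "phantom")
}

#' Simulate DWI signals from a phantom
#'
#' Forward-simulates the acquisition for every in-mask voxel: noiseless
#' per-direction signals from the VERDICT forward model (identical across
#' the three orthogonal directions, the compartments being isotropic after
#' spherical averaging), independent Rician noise on every direction image
#' and every matched b0, spherical averaging, then division by the matched
#' noisy b0. Noise is applied before averaging and before normalisation,
#' matching the acquisition order. When the T2 channel is enabled, both the
#' b0 and the DW images of a combo are scaled by exp(-TE/T2), which cancels
#' in the normalised output.
#'
#' @param phantom a [make_phantom()] result.
#' @param scheme an [acq_scheme()].
#' @param spec the [phantom_spec()] (noise/T2/seed settings; defaults to the
#'   phantom's own spec).
#' @return A [voxel_dataset()] with the direction-resolved normalised DW
#'   table in `$dw_directions` and the ground-truth parameter matrix as
#'   attribute `truth`.
#' @export
simulate_signals <- function(phantom, scheme = kidney_full_protocol(),
                             spec = phantom$spec) {
  stopifnot(inherits(phantom, "phantom"), inherits(scheme, "acq_scheme"))
  inside <- phantom$class_mask > 0L
  coords <- which(inside, arr.ind = TRUE)
  f_ic <- phantom$maps$maps$f_ic[inside]
  f_ees <- phantom$maps$maps$f_ees[inside]
  f_vasc <- pmax(0, 1 - f_ic - f_ees)
  Rv <- phantom$maps$maps$R[inside]
  nv <- length(f_ic)
  nc <- nrow(scheme)
  nd <- attr(scheme, "n_directions")

  stick <- signal_astrosticks(scheme$b, 50)
  ball <- signal_ball(scheme$b, 2)
  sph <- .sphere_gpd_matrix(Rv, 2, scheme$b, scheme$delta, scheme$Delta, 40L)
  S <- f_vasc %o% stick + f_ic * sph + f_ees %o% ball   # nv x nc, noiseless

  # per-combo amplitude: T2 decay of the matched-b0 channel (cancels later)
  amp <- matrix(1, nv, nc)
  if (!is.null(spec$t2)) {
    t2_by_class <- rep_len(spec$t2, nrow(phantom$classes))
    t2v <- t2_by_class[phantom$class_mask[inside]]
    amp <- exp(-outer(1 / t2v, scheme$TE))
  }

  sigma <- if (is.finite(spec$snr)) 1 / spec$snr else 0
  rice <- function(x) {
    if (sigma == 0) return(x)
    sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
  }
  set.seed(spec$seed + 1L)   # offset from the phantom draw stream

  dw_dirs <- matrix(NA_real_, nv, nc * nd)
  dw_avg <- matrix(NA_real_, nv, nc)
  b0_noisy <- matrix(NA_real_, nv, nc)
  for (j in seq_len(nc)) {
    b0_noisy[, j] <- rice(amp[, j])
    dirs <- matrix(NA_real_, nv, nd)
    for (k in seq_len(nd)) {
      dirs[, k] <- rice(amp[, j] * S[, j])
      dw_dirs[, (j - 1L) * nd + k] <- dirs[, k] / b0_noisy[, j]
    }
    dw_avg[, j] <- rowMeans(dirs) / b0_noisy[, j]
  }

  lay <- .volume_layout(scheme)
  vols <- matrix(1, nv, lay$n_volumes)
  vols[, lay$dw_idx] <- dw_avg
  ds <- voxel_dataset(vols, scheme, coords = coords, dim = spec$grid,
                      dw_directions = dw_dirs)
  attr(ds, "truth") <- cbind(f_ic = f_ic, f_ees = f_ees, f_vasc = f_vasc,
                             R = Rv)
  attr(ds, "class_id") <- phantom$class_mask[inside]
  ds
}

# one cohort subject: jitter the class means, build phantom, simulate
.simulate_subject <- function(spec, subject_seed, jitter_frac = 0.02,
                              jitter_r = 0.5) {
  set.seed(subject_seed)
  cls <- spec$classes
  cls$f_ic_mean <- pmin(pmax(cls$f_ic_mean +
                               rnorm(nrow(cls), 0, jitter_frac), 0.01), 0.95)
  cls$f_ees_mean <- pmin(pmax(cls$f_ees_mean +
                                rnorm(nrow(cls), 0, jitter_frac), 0.01), 0.95)
  over <- cls$f_ic_mean + cls$f_ees_mean > 0.99
  sc <- ifelse(over, 0.99 / (cls$f_ic_mean + cls$f_ees_mean), 1)
  cls$f_ic_mean <- cls$f_ic_mean * sc
  cls$f_ees_mean <- cls$f_ees_mean * sc
  cls$r_mean <- pmin(pmax(cls$r_mean + rnorm(nrow(cls), 0, jitter_r), 1), 14)
  sub_spec <- phantom_spec(grid = spec$grid, classes = cls, snr = spec$snr,
                           t2 = spec$t2, seed = subject_seed)
  simulate_signals(make_phantom(sub_spec), kidney_full_protocol(), sub_spec)
}

#' Simulate a cohort of subjects
#'
#' Independent phantoms with subject-level jitter on the class means
#' (SD 0.02 on fractions, 0.5 um on radii), each pushed through
#' [simulate_signals()]. Subject s uses the derived seed `seed + s`, so the
#' cohort is reproducible and subjects are mutually independent.
#'
#' @param spec a [phantom_spec()] (its own seed is ignored in favour of the
#'   derived per-subject seeds).
#' @param n_subjects number of subjects (default 14, the study scale).
#' @param seed base seed.
#' @return List of [voxel_dataset()]s, one per subject.
#' @export
make_cohort <- function(spec = phantom_spec(), n_subjects = 14L, seed = 1L) {
  stopifnot(n_subjects >= 1L)
  lapply(seq_len(n_subjects), function(s) .simulate_subject(spec, seed + s))
}

#' Closed-form mean of the Rice distribution
#'
#' Mean of `sqrt((nu + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`;
#' reduces to the Rayleigh mean `sigma * sqrt(pi/2)` at `nu = 0`. Used as an
#' independent oracle for the noise generator.
#'
#' @param nu noiseless magnitude.
#' @param sigma Gaussian noise SD per channel.
#' @return The expected magnitude.
#' @export
rice_mean <- function(nu, sigma) {
  t <- nu^2 / (2 * sigma^2)
  # sigma*sqrt(pi/2) * exp(-t/2) * ((1+t) I0(t/2) + t I1(t/2)),
  # with exponentially scaled Bessel functions to avoid overflow at high SNR
  sigma * sqrt(pi / 2) *
    ((1 + t) * besselI(t / 2, 0, expon.scaled = TRUE) +
       t * besselI(t / 2, 1, expon.scaled = TRUE))
}
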