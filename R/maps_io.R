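#' Named parameter-map volumes
#'
#' A container for co-registered 3-D parameter volumes (f_ic, f_ees, f_vasc,
#' R, ADC, ...) sharing one grid and mask. Masked-out voxels carry `NA` so
#' downstream viewers render holes correctly.
#'
#' @param maps named list of 3-D arrays of identical dimensions.
#' @param mask logical array of the same dimensions (`NULL` means all-in).
#' @param pixdim voxel size, mm; defaults to the acquisition's
#'   1.25 x 1.25 x 5 mm.
#' @return An object of class `param_maps`.
#' @export
param_maps <- function(maps, mask = NULL, pixdim = c(1.25, 1.25, 5)) {
  stopifnot(is.list(maps), length(maps) > 0, !is.null(names(maps)))
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d))
    stop("all maps must share the same dimensions")
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask dimensions must match the maps")
  maps <- lapply(maps, function(m) { m[!mask] <- NA_real_; m })
  structure(list(maps = maps, mask = mask, pixdim = pixdim),
            class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  cat("param_maps: ", paste(names(x$maps), collapse = ", "), "\n",
      "grid ", paste(dim(x$maps[[1]]), collapse = " x "),
      ", ", sum(x$mask), " voxels in mask\n", sep = "")
  invisible(x)
}

#' Write parameter maps to NIfTI
#'
#' Emits one NIfTI-1 file per map (`<name>.nii.gz`) with the voxel geometry
#' recorded in the header.
#'
#' @param maps a [param_maps()].
#' @param dir output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "param_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(maps$maps), function(nm) {
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(maps$maps[[nm]])
    RNifti::pixdim(img) <- maps$pixdim
    RNifti::writeNifti(img, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a 4-D DWI volume against a scheme
#'
#' Reads a 4-D diffusion-weighted NIfTI whose volumes follow the interleaved
#' (matched b0, spherically-averaged DW) ordering of the scheme, applies
#' matched-b0 normalisation (each DW volume divided by its combo's b0), and
#' returns the masked voxels as a [voxel_dataset()]. Reading an
#' already-normalised dataset (all b0 volumes equal to 1) changes nothing.
#' Voxels whose b0 is zero or non-finite cannot be normalised; they are
#' dropped with a warning giving the count.
#'
#' @param path NIfTI file of dimensions X x Y x Z x n_volumes.
#' @param scheme an [acq_scheme()] (4th dimension must equal its volume
#'   count).
#' @param mask optional NIfTI path or logical array selecting voxels;
#'   default: all voxels.
#' @return A [voxel_dataset()] with grid coordinates attached.
#' @export
read_dwi <- function(path, scheme, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  lay <- .volume_layout(scheme)
  if (length(dim(arr)) != 4L || dim(arr)[4] != lay$n_volumes)
    stop("4th dimension is ", if (length(dim(arr)) == 4L) dim(arr)[4] else
         "absent", "; scheme expects ", lay$n_volumes, " volumes")
  d3 <- dim(arr)[1:3]
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask)) > 0
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!identical(dim(mask), d3)) stop("mask geometry does not match the DWI")
  coords <- which(mask, arr.ind = TRUE)
  flat <- matrix(arr, prod(d3), lay$n_volumes)
  vox <- flat[mask, , drop = FALSE]
  # matched-b0 normalisation
  b0 <- vox[, lay$b0_idx, drop = FALSE]
  bad <- rowSums(!is.finite(b0) | b0 <= 0) > 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with zero/invalid b0 excluded")
    vox <- vox[!bad, , drop = FALSE]
    coords <- coords[!bad, , drop = FALSE]
    b0 <- b0[!bad, , drop = FALSE]
  }
  if (nrow(vox) == 0L) stop("no usable voxels after b0 screening")
  combo_of_dw <- seq_len(nrow(scheme))
  for (j in seq_along(lay$dw_idx)) {
    vox[, lay$dw_idx[j]] <- vox[, lay$dw_idx[j]] / b0[, combo_of_dw[j]]
  }
  vox[, lay$b0_idx] <- 1
  voxel_dataset(vox, scheme, coords = coords, dim = d3)
}

#' Write a voxel dataset back to a 4-D NIfTI volume
#'
#' Inverse of [read_dwi()] for synthetic data: scatters the normalised
#' volumes onto their grid (out-of-mask voxels zero) and writes one 4-D file.
#'
#' @param dataset a [voxel_dataset()] with coordinates and grid dimensions.
#' @param path output path.
#' @param pixdim voxel size, mm.
#' @return `path`, invisibly.
#' @export
write_dwi <- function(dataset, path, pixdim = c(1.25, 1.25, 5)) {
  stopifnot(inherits(dataset, "voxel_dataset"),
            !is.null(dataset$coords), !is.null(dataset$dim))
  d4 <- c(dataset$dim, ncol(dataset$volumes))
  arr <- array(0, d4)
  for (v in seq_len(ncol(dataset$volumes))) {
    sl <- array(0, dataset$dim)
    sl[dataset$coords] <- dataset$volumes[, v]
    arr[, , , v] <- sl
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixdim, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Per-ROI parameter summary
#'
#' Mean, standard deviation and voxel count of every map over a mask.
#'
#' @param maps a [param_maps()].
#' @param mask logical array (same grid); default: the maps' own mask.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
roi_summary <- function(maps, mask = maps$mask) {
  stopifnot(inherits(maps, "param_maps"))
  if (!identical(dim(mask), dim(maps$mask))) stop("mask geometry mismatch")
  mask <- mask & maps$mask
  if (!any(mask)) stop("empty ROI mask")
  do.call(rbind, lapply(names(maps$maps), function(nm) {
    v <- maps$maps[[nm]][mask]
    v <- v[is.finite(v)]
    data.frame(parameter = nm, mean = mean(v), sd = sd(v), n = length(v))
  }))
}

#' Star-coding of p-values
#'
#' `< 0.0001` = `****`; `0.0001-0.001` = `***`; `0.001-0.01` = `**`;
#' `0.01-0.05` = `*`; otherwise `n.s.`.
#'
#' @param p numeric p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 0.01, "**",
        ifelse(p <= 0.05, "*", "n.s."))))
}

#' Rank-based group comparison of parameter summaries
#'
#' Compares two groups of per-subject (or per-ROI) parameter values with a
#' rank-based test: Wilcoxon rank-sum for unpaired groups (the default here,
#' since the synthetic cohorts are unpaired) or the signed-rank test for
#' paired data of equal size. Identical paired groups (all differences zero)
#' carry no evidence against the null and are reported as p = 1.
#'
#' @param data data frame of values; one row per subject/ROI.
#' @param group name of the grouping column in `data` (two levels).
#' @param parameters columns to test; default: all non-group numeric columns.
#' @param test `"ranksum"` (unpaired) or `"signedrank"` (paired; requires
#'   equal group sizes).
#' @return Data frame with `parameter`, `statistic`, `p_value`, `stars`.
#' @export
compare_groups <- function(data, group, parameters = NULL,
                           test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  if (is.null(parameters)) {
    parameters <- names(data)[vapply(data, is.numeric, logical(1))]
    parameters <- setdiff(parameters, group)
  }
  lev <- levels(g)
  do.call(rbind, lapply(parameters, function(nm) {
    x <- data[[nm]][g == lev[1]]
    y <- data[[nm]][g == lev[2]]
    if (test == "signedrank") {
      if (length(x) != length(y))
        stop("paired signed-rank test requires equal group sizes")
      if (all(x - y == 0)) {
        stat <- 0; p <- 1
      } else {
        w <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
        stat <- unname(w$statistic); p <- w$p.value
      }
    } else {
      w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      stat <- unname(w$statistic); p <- w$p.value
    }
    data.frame(parameter = nm, statistic = stat, p_value = p,
               stars = p_stars(p))
  }))
}
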