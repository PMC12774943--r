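#' Per-voxel normalised signal dataset
#'
#' Holds one normalised measurement vector per masked voxel. The volume
#' ordering is interleaved per combo: for combo j the matched b0 volume comes
#' first (value exactly 1 after matched-b0 division), followed by the
#' spherically-averaged DW volume. A direction-resolved 27-measurement table
#' (combo-major: combo 1 directions 0,1,2; combo 2 ...) can ride along as the
#' `dw_directions` attribute for the protocol selector.
#'
#' @param volumes numeric matrix, voxels x n_volumes; all entries finite and
#'   positive; b0 columns exactly 1.
#' @param scheme the [acq_scheme()] the columns follow.
#' @param coords optional integer matrix (voxels x 3) of grid coordinates.
#' @param dim optional full grid dimensions, for reassembling maps.
#' @param mask_id optional label for the mask the voxels came from.
#' @param dw_directions optional voxels x (combos * n_directions) matrix of
#'   direction-resolved normalised DW measurements.
#' @return An object of class `voxel_dataset`.
#' @export
voxel_dataset <- function(volumes, scheme, coords = NULL, dim = NULL,
                          mask_id = NULL, dw_directions = NULL) {
  stopifnot(inherits(scheme, "acq_scheme"), is.matrix(volumes))
  lay <- .volume_layout(scheme)
  if (ncol(volumes) != lay$n_volumes)
    stop("volumes has ", ncol(volumes), " columns; scheme expects ",
         lay$n_volumes)
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all dataset entries must be finite and positive")
  if (any(volumes[, lay$b0_idx, drop = FALSE] != 1))
    stop("b0 entries must equal 1 exactly (matched-b0 normalised data)")
  structure(list(volumes = volumes, scheme = scheme, coords = coords,
                 dim = dim, mask_id = mask_id, dw_directions = dw_directions),
            class = "voxel_dataset")
}

# column bookkeeping for the interleaved (b0, dw) volume layout
.volume_layout <- function(scheme) {
  nc <- nrow(scheme)
  has_b0 <- scheme$has_matched_b0
  cols <- integer(0); b0_idx <- integer(0); dw_idx <- integer(0)
  k <- 0L
  for (j in seq_len(nc)) {
    if (has_b0[j]) { k <- k + 1L; b0_idx <- c(b0_idx, k) }
    k <- k + 1L; dw_idx <- c(dw_idx, k)
  }
  list(n_volumes = k, b0_idx = b0_idx, dw_idx = dw_idx)
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat("voxel_dataset: ", nrow(x$volumes), " voxels x ", ncol(x$volumes),
      " volumes (", nrow(x$scheme), " combos)",
      if (!is.null(x$dw_directions)) " + direction-resolved DW table", "\n",
      sep = "")
  invisible(x)
}

#' Restrict a voxel dataset to a sub-scheme
#'
#' Keeps only the volumes (matched b0 + DW) of the combos present in
#' `scheme`, e.g. to refit on a reduced protocol without re-acquiring.
#'
#' @param dataset a [voxel_dataset()].
#' @param scheme a sub-scheme of the dataset's scheme (matched by b-value).
#' @return A [voxel_dataset()] over the reduced scheme.
#' @export
subset_dataset <- function(dataset, scheme) {
  stopifnot(inherits(dataset, "voxel_dataset"), inherits(scheme, "acq_scheme"))
  full <- dataset$scheme
  keep <- match(scheme$b, full$b)
  if (anyNA(keep)) stop("scheme is not a subset of the dataset's scheme")
  lay_full <- .volume_layout(full)
  cols <- sort(c(lay_full$b0_idx[keep], lay_full$dw_idx[keep]))
  dw_dirs <- dataset$dw_directions
  if (!is.null(dw_dirs)) {
    nd <- attr(full, "n_directions")
    dir_cols <- sort(unlist(lapply(keep, function(j)
      ((j - 1L) * nd + 1L):(j * nd))))
    dw_dirs <- dw_dirs[, dir_cols, drop = FALSE]
  }
  out <- voxel_dataset(dataset$volumes[, cols, drop = FALSE], scheme,
                       coords = dataset$coords, dim = dataset$dim,
                       mask_id = dataset$mask_id, dw_directions = dw_dirs)
  attr(out, "truth") <- attr(dataset, "truth")
  attr(out, "class_id") <- attr(dataset, "class_id")
  out
}
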