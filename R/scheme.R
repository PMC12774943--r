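#' Construct a PGSE acquisition scheme
#'
#' An acquisition scheme is an ordered table of unique (b, delta, Delta, TE)
#' combinations ("combos"), each acquired along `n_directions` orthogonal
#' gradient directions together with a matched b = 0 volume at the same echo
#' time. Units are fixed at the interface: b in s/mm^2, all times in ms.
#'
#' @param b diffusion weightings, s/mm^2 (numeric vector, >= 0).
#' @param delta gradient pulse durations, ms.
#' @param Delta gradient pulse separations, ms; must exceed `delta` elementwise.
#' @param TE echo times, ms; defaults to `Delta + delta + 10` when unknown.
#'   TE is carried for bookkeeping and the generator's optional T2 channel; the
#'   normalised signal models do not use it (matched-b0 division cancels T2).
#' @param n_directions gradient directions per combo (default 3).
#' @param has_matched_b0 logical, one per combo (default all `TRUE`).
#' @return An object of class `acq_scheme`: a data frame with columns
#'   `b`, `delta`, `Delta`, `TE`, `has_matched_b0` and attribute
#'   `n_directions`.
#' @seealso [kidney_full_protocol()], [load_scheme()], [expand_measurements()]
#' @export
#' @examples
#' acq_scheme(b = c(0, 500), delta = c(4.8, 12), Delta = c(27, 34))
acq_scheme <- function(b, delta, Delta, TE = Delta + delta + 10,
                       n_directions = 3L, has_matched_b0 = TRUE) {
  n <- length(b)
  stopifnot(length(delta) == n, length(Delta) == n, length(TE) == n)
  has_matched_b0 <- rep_len(as.logical(has_matched_b0), n)
  if (n == 0L) stop("no combos")
  if (any(!is.finite(b)) || any(b < 0)) stop("all b-values must be finite and >= 0")
  if (any(delta <= 0) || any(Delta <= 0)) stop("pulse timings must be positive")
  if (any(delta >= Delta)) {
    stop("invalid PGSE timing: delta must be smaller than Delta (combo ",
         paste(which(delta >= Delta), collapse = ", "), ")")
  }
  if (any(TE < Delta + delta)) {
    stop("TE must be at least Delta + delta for every combo")
  }
  key <- paste(b, delta, Delta)
  if (anyDuplicated(key)) stop("combos must be unique by (b, delta, Delta)")
  ord <- order(b, delta)
  out <- data.frame(b = b, delta = delta, Delta = Delta, TE = TE,
                    has_matched_b0 = has_matched_b0)[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_directions") <- as.integer(n_directions)
  class(out) <- c("acq_scheme", "data.frame")
  out
}

#' The packaged full kidney VERDICT protocol
#'
#' Returns the nine-combo kidney acquisition: b = 70, 90, 150, 500, 1000,
#' 1500, 2000, 2200, 2500 s/mm^2 with the corresponding pulse durations,
#' separations and echo times, three orthogonal directions per combo, and a
#' matched b = 0 per echo time.
#'
#' @return An [acq_scheme()] with 9 combos.
#' @export
#' @examples
#' kidney_full_protocol()
kidney_full_protocol <- function() {
  acq_scheme(
    b     = c(70, 90, 150, 500, 1000, 1500, 2000, 2200, 2500),
    delta = c(4.8, 4.8, 4.8, 12.0, 12.0, 26.3, 16.8, 16.8, 21.4),
    Delta = c(27.0, 27.0, 27.0, 34.0, 34.0, 47.0, 37.5, 37.5, 43.5),
    # minimum-TE acquisition, 54-87 ms across combos
    TE    = c(54, 54, 54, 63, 63, 87, 70, 70, 79)
  )
}

#' Read / write acquisition scheme files
#'
#' Plain whitespace-delimited text with a one-line header and one row per
#' combo: `b delta Delta TE n_directions`. All combos in one file share
#' `n_directions`.
#'
#' @param path file path.
#' @return `load_scheme()` returns an [acq_scheme()]; `write_scheme()` returns
#'   `path` invisibly.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) <= 1L) stop("no combos in scheme file: ", path)
  body <- lines[-1L]  # drop header
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 5L || anyNA(v)) {
      stop("malformed scheme row at line ", i + 1L, ": '", body[i], "'")
    }
    v
  })
  m <- do.call(rbind, rows)
  nd <- unique(m[, 5L])
  if (length(nd) != 1L) stop("n_directions must be constant across combos")
  acq_scheme(b = m[, 1L], delta = m[, 2L], Delta = m[, 3L], TE = m[, 4L],
             n_directions = nd)
}

#' @rdname load_scheme
#' @param scheme an [acq_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "acq_scheme"))
  nd <- attr(scheme, "n_directions")
  hdr <- "b_s_mm2 delta_ms Delta_ms TE_ms n_directions"
  rows <- sprintf("%g %g %g %g %d",
                  scheme$b, scheme$delta, scheme$Delta, scheme$TE, nd)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Expand a scheme to its per-measurement table
#'
#' Lists every acquired diffusion-weighted measurement (combo x direction)
#' plus matched b = 0 rows, and derives the volume counts: one
#' spherically-averaged DW volume plus one matched b0 per combo.
#'
#' @param scheme an [acq_scheme()].
#' @return A data frame of class `measurement_table` with columns `combo`,
#'   `direction` (0-based, `NA` for b0 rows), `is_b0`, `b`; attributes
#'   `n_volumes` and `n_dw_measurements`.
#' @export
#' @examples
#' m <- expand_measurements(kidney_full_protocol())
#' attr(m, "n_volumes")          # 18
#' attr(m, "n_dw_measurements")  # 27
expand_measurements <- function(scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  nd <- attr(scheme, "n_directions")
  nc <- nrow(scheme)
  per_combo <- lapply(seq_len(nc), function(j) {
    rows <- data.frame(combo = j, direction = seq_len(nd) - 1L,
                       is_b0 = FALSE, b = scheme$b[j])
    if (scheme$has_matched_b0[j]) {
      rows <- rbind(data.frame(combo = j, direction = NA_integer_,
                               is_b0 = TRUE, b = 0), rows)
    }
    rows
  })
  out <- do.call(rbind, per_combo)
  rownames(out) <- NULL
  attr(out, "n_dw_measurements") <- nc * nd
  attr(out, "n_volumes") <- nc + sum(scheme$has_matched_b0)
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' @export
print.acq_scheme <- function(x, ...) {
  nd <- attr(x, "n_directions")
  m <- expand_measurements(x)
  cat("PGSE acquisition scheme: ", nrow(x), " combos, ", nd,
      " directions each (", attr(m, "n_dw_measurements"),
      " DW measurements, ", attr(m, "n_volumes"), " volumes)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
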