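#' Dynamic MR series
#'
#' Container for a 4D dynamic susceptibility contrast acquisition: signal
#' intensities on an `(x, y, z, t)` grid together with the acquisition
#' metadata the downstream analysis needs (sampling interval, echo time,
#' pre-bolus baseline window and injection time point).
#'
#' Time-point indices are 1-based everywhere in the user interface: the
#' i-th frame is acquired at time `(i - 1) * dt` seconds.
#'
#' @param data numeric array; 4D `(x, y, z, t)`, or 3D `(x, y, t)` which is
#'   promoted to a single-slice 4D array.
#' @param dt sampling interval in seconds (one frame every `dt` s).
#' @param te echo time in seconds.
#' @param baseline integer vector of 1-based time-point indices acquired
#'   before contrast arrival, used to estimate the baseline signal S0.
#' @param injection_tp 1-based time point of contrast injection, or `NA`.
#' @return An object of class `dynamic_series`.
#' @seealso [read_dynamic_series()], [signal_to_concentration()]
#' @export
dynamic_series <- function(data, dt, te, baseline = NULL, injection_tp = NA) {
  if (length(dim(data)) == 3L) {
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  }
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D (x, y, z, t) or 3D (x, y, t) array")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("`dt` must be a positive scalar")
  if (!is.numeric(te) || length(te) != 1L || te <= 0) stop("`te` must be a positive scalar")
  p <- dim(data)[4]
  if (is.null(baseline)) baseline <- integer(0)
  baseline <- as.integer(baseline)
  if (length(baseline) && (min(baseline) < 1L || max(baseline) > p)) {
    stop("`baseline` indices out of range")
  }
  structure(
    list(data = data, dt = dt, te = te, baseline = baseline,
         injection_tp = as.integer(injection_tp)),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d time points (dt = %g s, TE = %g s)\n",
              d[1], d[2], d[3], d[4], x$dt, x$te))
  if (length(x$baseline)) {
    cat(sprintf("  baseline: time points %d-%d; injection at tp %s\n",
                min(x$baseline), max(x$baseline), x$injection_tp))
  }
  invisible(x)
}

#' Time axis of a dynamic series
#'
#' @param series a `dynamic_series` or `concentration_series`.
#' @return numeric vector of acquisition times in seconds, starting at 0.
#' @export
time_axis <- function(series) {
  (seq_len(dim(series$data)[4]) - 1) * series$dt
}

#' Voxel-by-time matrix view of a series
#'
#' Flattens the spatial grid and returns the time courses of the requested
#' voxels as rows, plus the linear voxel indices they came from.
#'
#' @param series a `dynamic_series` (or `concentration_series`).
#' @param mask optional: logical array matching the spatial grid, or an
#'   integer vector of linear voxel indices. Default: all voxels.
#' @return list with `X` (v-by-p matrix), `voxels` (linear indices into the
#'   spatial grid), and `dims` (spatial grid dimensions).
#' @export
series_matrix <- function(series, mask = NULL) {
  d <- dim(series$data)
  nvox <- prod(d[1:3])
  X <- matrix(series$data, nrow = nvox, ncol = d[4])
  if (is.null(mask)) {
    voxels <- seq_len(nvox)
  } else if (is.logical(mask) || is.array(mask)) {
    voxels <- which(as.logical(mask))
  } else {
    voxels <- as.integer(mask)
  }
  if (length(voxels) == 0L) stop("mask selects no voxels")
  if (max(voxels) > nvox) stop("mask indices outside the spatial grid")
  list(X = X[voxels, , drop = FALSE], voxels = voxels, dims = d[1:3])
}

#' Read a 4D dynamic series from NIfTI
#'
#' Reads a 4D NIfTI volume and assembles a [dynamic_series()]. Metadata is
#' taken, in order of precedence, from the function arguments, from a JSON
#' sidecar (`<path minus extension>.json`, as written by
#' [write_dynamic_series()]), and from the NIfTI header (`dt` from the 4th
#' pixdim). The echo time cannot be recovered from a bare NIfTI header, so
#' a missing `te` with no sidecar is an error.
#'
#' Leading frames acquired before steady state ("dummy scans") can be
#' dropped with `discard_first`; the time axis is re-zeroed and the
#' baseline/injection indices are shifted accordingly.
#'
#' @param path path to a 4D NIfTI file.
#' @param te echo time in seconds (overrides sidecar).
#' @param dt sampling interval in seconds (overrides sidecar and header).
#' @param baseline baseline time-point indices (1-based, after discarding).
#' @param injection_tp injection time point (1-based, before discarding).
#' @param discard_first number of leading frames to drop (default 3,
#'   the usual number of non-steady-state dummy scans).
#' @return a `dynamic_series`.
#' @export
read_dynamic_series <- function(path, te = NULL, dt = NULL, baseline = NULL,
                                injection_tp = NULL, discard_first = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D volume, got ", length(dim(arr)), "D: ", path)
  }
  side <- .sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (is.null(dt)) dt <- meta$dt
  if (is.null(dt)) {
    pd <- attr(img, "pixdim")
    if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) dt <- pd[4]
  }
  if (is.null(dt)) stop("sampling interval `dt` not given and not recoverable from header")
  if (is.null(te)) te <- meta$te
  if (is.null(te)) stop("echo time `te` not given and no sidecar found")
  if (is.null(injection_tp)) injection_tp <- if (!is.null(meta$injection_tp)) meta$injection_tp else NA
  discard_first <- as.integer(discard_first)
  if (discard_first > 0L) {
    if (discard_first >= dim(arr)[4]) stop("`discard_first` leaves no frames")
    arr <- arr[, , , -(seq_len(discard_first)), drop = FALSE]
    if (!is.na(injection_tp)) injection_tp <- injection_tp - discard_first
  }
  if (is.null(baseline)) {
    baseline <- meta$baseline
    if (!is.null(baseline) && discard_first > 0L) {
      baseline <- baseline[baseline > discard_first] - discard_first
    }
  }
  dynamic_series(arr, dt = dt, te = te, baseline = baseline,
                 injection_tp = injection_tp)
}

#' Write a dynamic series as NIfTI plus a JSON sidecar
#'
#' @param series a `dynamic_series`.
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @param extra named list merged into the sidecar (e.g. phantom truth).
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path, extra = list()) {
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, series$dt))
  RNifti::writeNifti(img, path)
  meta <- c(list(dt = series$dt, te = series$te, baseline = series$baseline,
                 injection_tp = series$injection_tp), extra)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
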