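#' Signal-to-concentration conversion parameters
#'
#' The standard DSC conversion assumes the transverse relaxation shift is
#' proportional to concentration, giving
#' \deqn{C(t) = -\frac{K}{TE}\,\ln\frac{S(t)}{S_0},}
#' where `K` is the relaxivity constant and S0 the mean signal over the
#' pre-bolus baseline window. `K` (default 7.62, the usual 1.5 T value)
#' and `te` are applied literally; any global scale on the concentration
#' cancels in the AIF/tissue ratio that determines CBF, so the unit
#' convention chosen for `K` only affects labelling, not flow.
#'
#' @param k relaxivity constant (default 7.62).
#' @param te echo time, in the time unit matching `k`'s denominator
#'   (seconds throughout this package).
#' @param baseline_window inclusive 1-based time-point index range used
#'   for the baseline signal S0; must precede contrast arrival.
#' @return object of class `conversion_params`.
#' @export
conversion_params <- function(k = 7.62, te, baseline_window) {
  if (k <= 0) stop("`k` must be positive")
  if (te <= 0) stop("`te` must be positive")
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L) stop("`baseline_window` must be non-empty")
  structure(list(k = k, te = te, baseline_window = baseline_window),
            class = "conversion_params")
}

#' Convert a dynamic signal series to contrast concentration
#'
#' Applies the log conversion voxelwise, using the per-voxel mean over the
#' baseline window as S0. Voxels with non-positive signal (or non-positive
#' S0) cannot be log-converted; they are emitted as `NA` and counted in a
#' message rather than aborting the run.
#'
#' @param series a [dynamic_series()].
#' @param p a [conversion_params()]; if missing, `te` is taken from the
#'   series and `baseline_window` from its baseline metadata.
#' @return a `concentration_series` (same grid, concentration units); the
#'   conversion parameters are stored in `$conversion`.
#' @export
signal_to_concentration <- function(series, p = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(p)) {
    if (!length(series$baseline)) stop("series has no baseline window and no `p` given")
    p <- conversion_params(te = series$te, baseline_window = series$baseline)
  }
  d <- dim(series$data)
  if (max(p$baseline_window) > d[4]) stop("baseline window outside the time axis")
  X <- matrix(series$data, prod(d[1:3]), d[4])
  s0 <- rowMeans(X[, p$baseline_window, drop = FALSE])
  bad <- !is.finite(s0) | s0 <= 0
  nonpos <- is.finite(X) & X <= 0
  X[nonpos] <- NA_real_
  s0[bad] <- NA_real_
  conc <- .curve_to_concentration(X, s0, p)
  if (any(nonpos) || any(bad)) {
    message(sprintf("signal_to_concentration: %d non-positive signal values in %d voxels flagged as NA",
                    sum(nonpos), sum(bad | rowSums(nonpos) > 0)))
  }
  out <- series
  out$data <- array(conc, dim = d)
  out$conversion <- p
  class(out) <- c("concentration_series", "dynamic_series")
  out
}

# rows: voxels; s0: per-row baseline
.curve_to_concentration <- function(X, s0, p) {
  -(p$k / p$te) * log(sweep(X, 1, s0, "/"))
}

#' Convert a single signal curve to concentration
#'
#' Curve-level counterpart of [signal_to_concentration()], used for
#' candidate AIF curves. Near-complete signal voids (an artery at bolus
#' peak) can dip to or below zero once noise is added, where the log is
#' undefined; as is usual in DSC processing the signal is floored at a
#' small fraction of the baseline before conversion, which caps the
#' apparent concentration instead of failing.
#'
#' @param curve signal curve.
#' @param p a [conversion_params()].
#' @param floor_fraction signal floor as a fraction of the baseline S0
#'   (default `1e-4`); set to `NA` to error on non-positive values
#'   instead.
#' @return concentration curve.
#' @export
curve_to_concentration <- function(curve, p, floor_fraction = 1e-4) {
  s0 <- mean(curve[p$baseline_window])
  if (!is.finite(s0) || s0 <= 0) stop("non-positive baseline signal")
  if (is.na(floor_fraction)) {
    if (any(curve <= 0, na.rm = TRUE)) stop("non-positive signal values in curve")
  } else {
    curve <- pmax(curve, floor_fraction * s0)
  }
  drop(.curve_to_concentration(matrix(curve, 1), s0, p))
}

#' @export
print.concentration_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<concentration_series> %d x %d x %d voxels, %d time points (K = %g, TE = %g s)\n",
              d[1], d[2], d[3], d[4], x$conversion$k, x$conversion$te))
  invisible(x)
}
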