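#' Spatial ICA decomposition of a dynamic series
#'
#' Decomposes the time-by-voxel data into spatially independent component
#' maps with associated time courses, the fMRI-style spatial ICA model:
#' the observed matrix is approximated by a sum of q outer products
#' (time course x spatial map), with the maps driven towards statistical
#' independence (maximal non-Gaussianity) across voxels by FastICA.
#'
#' Each voxel's time course is first centred by its temporal mean
#' (removing the baseline signal level). The spatial mean image is *not*
#' removed: the phantom/brain sources tile the field of view, so their
#' maps sum to a near-constant image and spatial centring would make them
#' linearly dependent, forcing ICA to return bipolar contrast maps
#' instead of one unipolar map per source.
#'
#' The dimension is reduced by PCA to `q` components, either given
#' directly (`n_components`) or as the smallest q whose cumulative
#' eigenvalue fraction reaches `variance_fraction`. Component maps are
#' sign-aligned so that each map's skewness is positive, i.e. the voxels
#' expressing the source form the positive tail (the convention under
#' which the top-z selection of [top_k_voxels()] is meaningful).
#'
#' @param series a [dynamic_series()] (or `concentration_series`).
#' @param brain_mask optional logical array or voxel index vector
#'   restricting the analysis.
#' @param n_components number of components q (e.g. 10 for the phantom).
#' @param variance_fraction alternative to `n_components`: the smallest q
#'   covering this fraction of the PCA eigenvalue sum (0.99 reproduces
#'   the "cover 99% of the eigenvalues" rule used on clinical data).
#' @param seed RNG seed for the FastICA initial rotation (mandatory for
#'   reproducibility).
#' @param maxit,tol FastICA iteration controls.
#' @return object of class `ic_result`: `component_maps` (v x q),
#'   `time_courses` (p x q), `explained_variance` (per-retained-PC
#'   fractions), `voxels` (linear indices into the spatial grid), `dims`,
#'   `dt`, `baseline`, `seed`.
#' @export
decompose <- function(series, brain_mask = NULL, n_components = NULL,
                      variance_fraction = NULL, seed = 1,
                      maxit = 300, tol = 1e-7) {
  stopifnot(inherits(series, "dynamic_series"))
  sm <- series_matrix(series, brain_mask)
  X <- sm$X                             # v x p
  v <- nrow(X); p <- ncol(X)
  Xc <- X - rowMeans(X)                 # centre each voxel's time course
  if (all(abs(Xc) < .Machine$double.eps * 100)) stop("degenerate data: zero variance")

  ev <- svd(Xc, nu = 0, nv = 0)$d^2
  ev_frac <- ev / sum(ev)
  if (is.null(n_components)) {
    if (is.null(variance_fraction)) {
      stop("give either `n_components` or `variance_fraction`")
    }
    n_components <- which(cumsum(ev_frac) >= variance_fraction)[1]
  }
  q <- as.integer(n_components)
  if (q > p) stop(sprintf("n_components (%d) exceeds the number of time points (%d)", q, p))
  if (q > v) stop("n_components exceeds the number of voxels")

  rs <- .seeded_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  Rmat <- qr.Q(qr(matrix(rnorm(q * q), q, q)))
  ic <- ica::icafast(Xc, nc = q, center = FALSE, maxit = maxit, tol = tol,
                     Rmat = Rmat)
  maps <- ic$S                          # v x q spatial maps (unit variance)
  tcs <- ic$M                           # p x q mixing time courses
  for (j in seq_len(q)) {
    if (.skewness(maps[, j]) < 0) {
      maps[, j] <- -maps[, j]
      tcs[, j] <- -tcs[, j]
    }
  }
  structure(
    list(component_maps = maps, time_courses = tcs,
         explained_variance = ev_frac[seq_len(q)],
         vafs = ic$vafs, voxels = sm$voxels, dims = sm$dims,
         dt = series$dt, baseline = series$baseline, seed = seed),
    class = "ic_result")
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("<ic_result> %d components over %d voxels x %d time points (seed %s)\n",
              ncol(x$component_maps), nrow(x$component_maps),
              nrow(x$time_courses), format(x$seed)))
  cat(sprintf("  retained PC variance: %.1f%%\n", 100 * sum(x$explained_variance)))
  invisible(x)
}

.skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

#' z-score map of a spatial component
#'
#' Standardises an independent-component map by its own mean and standard
#' deviation, \eqn{z_i = (x_i - \mathrm{mean_{IC}})/\mathrm{Std_{IC}}},
#' using the population (divide-by-n) standard deviation.
#'
#' @param component_map numeric vector (one value per voxel), or an
#'   `ic_result` together with `component` selecting a column.
#' @param component column index when `component_map` is an `ic_result`.
#' @return object of class `zmap`: `values`, `mean_ic`, `std_ic`, and the
#'   originating `voxels`/`dims` when available.
#' @export
zscore_map <- function(component_map, component = NULL) {
  voxels <- NULL; dims <- NULL
  if (inherits(component_map, "ic_result")) {
    stopifnot(!is.null(component))
    voxels <- component_map$voxels
    dims <- component_map$dims
    component_map <- component_map$component_maps[, component]
  }
  if (length(unique(component_map)) < 2L) stop("constant map: z-scores undefined")
  mu <- mean(component_map)
  sdev <- sqrt(mean((component_map - mu)^2))
  structure(list(values = (component_map - mu) / sdev, mean_ic = mu,
                 std_ic = sdev, voxels = voxels, dims = dims),
            class = "zmap")
}

#' Top-k voxels of a z-map
#'
#' The k voxels with the largest z-values; ties are broken by ascending
#' voxel index so the selection is deterministic.
#'
#' @param z a `zmap` (or plain numeric vector of z-values).
#' @param k number of voxels (default 50).
#' @return integer positions into the map (for a `zmap` built from an
#'   `ic_result`, translate with `z$voxels[...]` to grid indices).
#' @export
top_k_voxels <- function(z, k = 50) {
  vals <- if (inherits(z, "zmap")) z$values else z
  if (k > length(vals)) stop("k exceeds the number of voxels in the map")
  order(-vals, seq_along(vals))[seq_len(k)]
}

#' z-weighted arterial input function
#'
#' Averages the selected voxels' time curves with weights taken from the
#' z-map, \deqn{AIF(t) = \frac{1}{n}\sum_{i=1}^{n} Q_i S_i(t),} where the
#' weights \eqn{Q_i} are the z-values of the selected voxels normalised
#' to mean 1 — a weighted average that reduces to the plain ROI mean when
#' all z are equal, keeping the weighted AIF commensurate with the
#' unweighted ROI average it is compared against.
#'
#' Selected voxels with non-positive z (which cannot occur for a top-k
#' selection with k much smaller than the map, but is guarded against)
#' are excluded with a message.
#'
#' @param series a [dynamic_series()]/`concentration_series`, or a
#'   v-by-p matrix of time curves aligned with the z-map's voxel order.
#' @param voxels positions into the z-map (as from [top_k_voxels()]).
#' @param z the `zmap` the selection came from.
#' @param source_label provenance tag (`"artery"`, `"surround"`,
#'   `"manual"`, ...).
#' @return object of class `aif_curve`: `curve`, `voxel_ids` (grid
#'   indices when known, else map positions), `weights`, `dt`,
#'   `source_label`.
#' @export
weighted_aif <- function(series, voxels, z, source_label = "artery") {
  stopifnot(inherits(z, "zmap"))
  if (!length(voxels)) stop("no voxels selected")
  zi <- z$values[voxels]
  keep <- zi > 0
  if (!all(keep)) {
    message(sprintf("weighted_aif: excluding %d selected voxels with non-positive z",
                    sum(!keep)))
    voxels <- voxels[keep]; zi <- zi[keep]
    if (!length(voxels)) stop("all selected voxels had non-positive z")
  }
  if (is.matrix(series)) {
    S <- series[voxels, , drop = FALSE]
    dt <- NA_real_
    ids <- if (!is.null(z$voxels)) z$voxels[voxels] else voxels
  } else {
    sm <- series_matrix(series)
    ids <- if (!is.null(z$voxels)) z$voxels[voxels] else voxels
    S <- sm$X[ids, , drop = FALSE]
    dt <- series$dt
  }
  w <- zi / mean(zi)
  curve <- colSums(S * w) / length(w)
  structure(list(curve = curve, voxel_ids = ids, weights = w, dt = dt,
                 source_label = source_label),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("<aif_curve> '%s': %d time points from %d voxels (weights in [%.2f, %.2f])\n",
              x$source_label, length(x$curve), length(x$voxel_ids),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Rank components by arterial hemodynamic character
#'
#' Scores every component by how artery-like its bolus response is: an
#' artery shows an early, narrow and high concentration peak. For each
#' component the candidate response is built from the data itself — the
#' z-weighted mean signal curve of the component's top-k voxels — then
#' log-converted to concentration and gamma-fitted; the score is
#' \deqn{score = \frac{peak\ height}{FWHM \cdot \max(TTP, dt)} \cdot c,}
#' where `c` is the spatial coherence of the top-k set — the fraction of
#' its voxels in its largest face-connected cluster. The coherence factor
#' implements the region-clustering step of the z-thresholding workflow:
#' a genuine vascular or tissue source selects a compact region
#' (coherence near 1), while a noise component selects scattered voxels
#' whose candidate curve can still look artery-like because it averages
#' over artery voxels. (Fitting the candidate curve rather than the raw
#' mixing time course keeps the score in concentration units and
#' well-defined: raw IC time courses are arbitrary-unit mixtures that
#' cannot be log-converted.)
#'
#' Components whose fit fails score 0 and rank last (with a message)
#' rather than being dropped; ties keep ascending component order. The
#' full ranking is returned so that the semi-automatic workflow can be
#' reviewed by eye before accepting the automatic choice.
#'
#' Candidate curves from components that saturate the signal (an artery
#' at bolus peak drives the signal into the noise floor) become extremely
#' rough after the log conversion; for ranking purposes only, the curve
#' is floored at 1% of baseline and smoothed with a short moving average
#' before fitting, which stabilises the fit without changing the
#' ordering of well-behaved candidates.
#'
#' @param ic an `ic_result`.
#' @param series the series the decomposition came from (signal domain).
#' @param conv a [conversion_params()] for the log conversion; defaults
#'   to the series' own TE/baseline metadata.
#' @param k voxels per candidate ROI (default 50).
#' @param fit_window gamma-fit window (1-based, default `7:25`).
#' @param smooth half-width of the moving-average smoother applied to
#'   the candidate concentration curve before fitting (default 1, i.e. a
#'   3-point window; 0 disables).
#' @return data.frame sorted by descending score with columns
#'   `component`, `score`, `coherence`, `arrival_s` (first crossing of
#'   10% of the candidate peak, a fit-free bolus arrival estimate),
#'   `ttp_s`, `onset_s`, `fwhm_s`, `peak_height`, `fit_ok`.
#' @export
rank_components <- function(ic, series, conv = NULL, k = 50,
                            fit_window = 7:25, smooth = 1) {
  stopifnot(inherits(ic, "ic_result"))
  if (is.null(conv)) {
    if (!length(series$baseline)) stop("series has no baseline window; give `conv`")
    conv <- conversion_params(te = series$te, baseline_window = series$baseline)
  }
  q <- ncol(ic$component_maps)
  dt <- ic$dt
  rows <- vector("list", q)
  for (j in seq_len(q)) {
    row <- data.frame(component = j, score = 0, coherence = NA_real_,
                      arrival_s = NA_real_, ttp_s = NA_real_,
                      onset_s = NA_real_, fwhm_s = NA_real_,
                      peak_height = NA_real_, fit_ok = FALSE)
    res <- tryCatch({
      z <- zscore_map(ic, component = j)
      sel <- top_k_voxels(z, k)
      coh <- .largest_cluster_fraction(ic$voxels[sel], ic$dims)
      cand <- weighted_aif(series, sel, z, source_label = paste0("IC", j))
      conc <- curve_to_concentration(cand$curve, conv, floor_fraction = 0.01)
      if (smooth > 0) conc <- .moving_average(conc, smooth)
      fit <- fit_gamma_variate(conc, dt, fit_window)
      fe <- aif_features(conc, fit, dt)
      row$score <- coh * fe$peak_height / (fe$fwhm * max(fe$ttp, dt))
      row$coherence <- coh
      row$arrival_s <- (which(conc >= 0.1 * max(conc))[1] - 1) * dt
      row$ttp_s <- fe$ttp; row$onset_s <- fe$onset_time
      row$fwhm_s <- fe$fwhm; row$peak_height <- fe$peak_height
      row$fit_ok <- TRUE
      row
    }, error = function(e) {
      message(sprintf("rank_components: component %d unscored (%s)", j,
                      conditionMessage(e)))
      row
    })
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$component), , drop = FALSE]
}

#' Automatic artery / surrounding-tissue component selection
#'
#' Implements the automatic default of the semi-automatic workflow. Only
#' components whose top-k set is spatially compact (coherence — the
#' largest-connected-cluster fraction — at least `min_coherence`) are
#' candidates: a physiological source selects one region, a noise
#' component selects scatter. The top-ranked compact component is taken
#' as the artery; the surrounding-tissue component is chosen among the
#' remaining compact components whose top-k voxel set is essentially
#' distinct from the artery set (overlap fraction at most `max_overlap`
#' — partial-volume voxels may legitimately appear in both) while
#' touching it (at least `min_touch` voxels with a face neighbour in the
#' artery set), reflecting that the tissue of interest hugs the artery.
#' Among those candidates the one with the *narrowest* fitted bolus
#' (smallest FWHM) is taken: of all compartments the peri-arterial
#' tissue shows the narrowest first pass — the parenchyma is broadened
#' by its transit-time distribution and a saturated arterial response is
#' broadened by clipping — which is exactly the pattern clinical
#' feature tables report for peri-arterial ROIs.
#'
#' The vascular anchor is the compact component with the highest fitted
#' peak concentration (clinically the arterial curve towers over every
#' tissue curve; in Table-1-style feature tables the arterial peak is
#' 2-3x the peri-arterial one). When two candidates peak within
#' `anchor_fraction` of each other — e.g. a deep tissue response that
#' also saturates the signal — the earlier bolus arrival wins, then the
#' higher composite score.
#'
#' @param ic an `ic_result`.
#' @param ranking output of [rank_components()].
#' @param k voxels per ROI (default 50).
#' @param max_overlap maximum tolerated overlap fraction between the two
#'   top-k sets (default 0.5).
#' @param min_coherence minimum largest-cluster fraction for a component
#'   to be considered at all (default 0.35).
#' @param anchor_fraction peak-height fraction defining the high-peak
#'   group within which the earliest arrival wins the vascular anchor
#'   (default 0.9).
#' @param min_touch minimum number of candidate voxels that must touch
#'   the artery set for the adjacency requirement (default 1).
#' @return list with elements `artery` and `surround`, each a list of
#'   `component`, `map_positions` (into the map) and `voxels` (grid
#'   indices); `surround` is `NULL` when no candidate qualifies.
#' @export
select_aif_components <- function(ic, ranking, k = 50, max_overlap = 0.5,
                                  min_coherence = 0.35, anchor_fraction = 0.9,
                                  min_touch = 1) {
  stopifnot(inherits(ic, "ic_result"))
  ok <- ranking$fit_ok & ranking$score > 0 &
    !is.na(ranking$coherence) & ranking$coherence >= min_coherence
  if (!any(ok)) stop("no spatially coherent component could be scored")
  rk <- ranking[ok, , drop = FALSE]
  high <- rk[rk$peak_height >= anchor_fraction * max(rk$peak_height), , drop = FALSE]
  art_j <- high$component[order(high$arrival_s, -high$score, high$component)][1]
  scored <- c(art_j, setdiff(rk$component, art_j))
  take <- function(j) {
    pos <- top_k_voxels(zscore_map(ic, component = j), k)
    list(component = j, map_positions = pos, voxels = ic$voxels[pos])
  }
  artery <- take(scored[1])
  candidates <- list()
  for (j in scored[-1]) {
    cand <- take(j)
    ov <- length(intersect(cand$map_positions, artery$map_positions)) / k
    if (ov <= max_overlap &&
        .touch_count(cand$voxels, artery$voxels, ic$dims) >= min_touch) {
      candidates[[length(candidates) + 1L]] <- cand
    }
  }
  surround <- NULL
  if (length(candidates)) {
    fw <- vapply(candidates, function(cand) {
      rk$fwhm_s[rk$component == cand$component]
    }, numeric(1))
    sc <- vapply(candidates, function(cand) {
      rk$score[rk$component == cand$component]
    }, numeric(1))
    ord <- order(fw, -sc, vapply(candidates, `[[`, numeric(1), "component"))
    surround <- candidates[[ord[1]]]
  }
  list(artery = artery, surround = surround)
}

# centred moving average with edge shrinkage; h = half-width
.moving_average <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(x[w])
  }, numeric(1))
}

# fraction of a voxel set lying in its largest face-connected cluster
.largest_cluster_fraction <- function(voxels, dims) {
  n <- length(voxels)
  if (n == 0L) return(0)
  co <- arrayInd(voxels, dims)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      dist <- abs(sweep(co, 2, co[j, ], "-"))
      nb <- which(rowSums(dist) == 1L & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  max(tabulate(lab)) / n
}

# number of voxels in set a with at least one face neighbour in set b
.touch_count <- function(a, b, dims) {
  ca <- arrayInd(a, dims); cb <- arrayInd(b, dims)
  n <- 0L
  for (i in seq_len(nrow(ca))) {
    dist <- abs(sweep(cb, 2, ca[i, ], "-"))
    if (any(rowSums(dist) == 1L)) n <- n + 1L
  }
  n
}
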