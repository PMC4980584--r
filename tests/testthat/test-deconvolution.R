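test_that("convolution matrix is the rectangle-rule Toeplitz operator", {
  dt <- 1.5
  imp <- c(1, numeric(9))
  expect_equal(convolution_matrix(imp, dt), dt * diag(10))
  aif <- ideal_aif((0:39) * dt)
  A <- convolution_matrix(aif, dt)
  expect_equal(A[1, 2], 0)
  expect_true(all(A[upper.tri(A)] == 0))
  set.seed(1)
  r <- rnorm(40)
  expect_equal(drop(A %*% r), brute_convolution(aif, r, dt), tolerance = 1e-12)
  expect_error(convolution_matrix(1, dt), "at least 2")
})

test_that("oscillation index measures second-difference roughness", {
  expect_equal(oscillation_index(seq(0, 10, length.out = 50)), 0)
  expect_equal(oscillation_index(numeric(10)), 0)
  n <- 20
  alt <- rep(c(1, -1), n / 2)
  direct <- sum(abs(diff(alt, differences = 2))) / (n * 1)
  expect_equal(oscillation_index(alt), direct)
  expect_equal(oscillation_index(alt), 4 * (n - 2) / n)
  expect_error(oscillation_index(c(1, 2)), "at least 3")
})

test_that("noise-free deconvolution recovers the known flow within 5%", {
  dt <- 1.5; n <- 80; mtt <- 3
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  f_true <- 0.0133
  tissue <- forward_tissue(aif, f_true, mtt, dt)
  spec <- deconv_spec(threshold_fraction = 1e-6, adaptive = FALSE, dt = dt)
  res <- svd_deconvolve(tissue, aif, spec)
  expect_equal(res$f_max, f_true, tolerance = 0.05)
  # zero tissue -> zero flow
  expect_equal(svd_deconvolve(numeric(n), aif, spec)$f_max, 0)
  # doubling the AIF halves the flow estimate
  res2 <- svd_deconvolve(tissue, 2 * aif, spec)
  expect_equal(res2$f_max, res$f_max / 2, tolerance = 1e-9)
  expect_error(svd_deconvolve(tissue, numeric(n), spec), "identically zero")
  expect_error(svd_deconvolve(tissue[1:10], aif, spec), "time axis")
})

test_that("truncated SVD equals a least-squares solve on the kept subspace", {
  dt <- 1.5; n <- 60
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  A <- convolution_matrix(aif, dt)
  set.seed(2)
  y <- forward_tissue(aif, 0.01, 4, dt) + rnorm(n, 0, 1e-3)
  for (thr in c(0.05, 0.15, 0.3)) {
    res <- svd_deconvolve(y, aif, deconv_spec(threshold_fraction = thr,
                                              adaptive = FALSE, dt = dt))
    sv <- svd(A)
    keep <- sv$d >= thr * sv$d[1]
    Vk <- sv$v[, keep, drop = FALSE]
    # normal equations restricted to span(V_keep): independent arithmetic
    z <- solve(crossprod(A %*% Vk), crossprod(A %*% Vk, y))
    expect_equal(res$residue, drop(Vk %*% z), tolerance = 1e-8)
  }
})

test_that("flow underestimation grows monotonically with truncation", {
  dt <- 1.5; n <- 80
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  tissue <- forward_tissue(aif, 0.0133, 3, dt)
  f <- sapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(thr) {
    svd_deconvolve(tissue, aif,
                   deconv_spec(threshold_fraction = thr, adaptive = FALSE,
                               dt = dt))$f_max
  })
  expect_true(all(diff(f) <= 1e-12))
})

test_that("adaptive threshold reports the grid value it used", {
  dt <- 1.5; n <- 80
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  tissue <- forward_tissue(aif, 0.0133, 3, dt)
  set.seed(3)
  noisy <- tissue + rnorm(n, 0, max(tissue) / 27.7)
  res <- svd_deconvolve(noisy, aif, deconv_spec(dt = dt))
  expect_true(res$threshold_used %in% seq(0.01, 0.60, by = 0.01))
  expect_lte(oscillation_index(res$residue), 0.035 + 1e-12)
})

test_that("CBF maps are uniform on a homogeneous phantom and scale-invariant", {
  dt <- 1.5; n <- 60; f_true <- 0.0133; mtt <- 3
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  tissue <- forward_tissue(aif, f_true, mtt, dt)
  arr <- array(rep(tissue, each = 24), c(4, 6, 1, n))
  conc <- dynamic_series(arr, dt = dt, te = 0.06)
  class(conc) <- c("concentration_series", "dynamic_series")
  spec <- deconv_spec(threshold_fraction = 1e-6, adaptive = FALSE, dt = dt)
  maps <- cbf_map(conc, aif, spec)
  scale <- cbf_unit_scale(spec)
  vals <- maps$cbf[is.finite(maps$cbf)]
  expect_length(vals, 24)
  expect_equal(mean(vals), f_true * scale, tolerance = 0.05)
  expect_lt(sd(vals) / mean(vals), 0.01)
  # common rescaling of AIF and tissue leaves the map unchanged
  conc2 <- conc; conc2$data <- conc2$data * 3.7
  maps2 <- cbf_map(conc2, 3.7 * aif, spec)
  expect_equal(maps2$cbf, maps$cbf, tolerance = 1e-9)
  # empty mask: empty map, no error
  empty <- cbf_map(conc, aif, spec, mask = logical(24))
  expect_true(all(is.na(empty$cbf)))
})

test_that("regional flow ratio reproduces the simulated flow ratio", {
  dt <- 1.5; n <- 60; mtt <- 3
  t <- (seq_len(n) - 1) * dt
  aif <- ideal_aif(t)
  gm <- forward_tissue(aif, 0.01333, mtt, dt)    # 'gray matter' flow
  wm <- forward_tissue(aif, 0.00667, mtt, dt)    # half of it
  arr <- array(0, c(2, 5, 1, n))
  for (i in 1:5) { arr[1, i, 1, ] <- gm; arr[2, i, 1, ] <- wm }
  conc <- dynamic_series(arr, dt = dt, te = 0.06)
  class(conc) <- c("concentration_series", "dynamic_series")
  maps <- cbf_map(conc, aif, deconv_spec(threshold_fraction = 1e-6,
                                         adaptive = FALSE, dt = dt))
  gm_mask <- array(FALSE, c(2, 5, 1)); gm_mask[1, , 1] <- TRUE
  wm_mask <- array(FALSE, c(2, 5, 1)); wm_mask[2, , 1] <- TRUE
  rs <- region_stats(maps, list(GM = gm_mask, WM = wm_mask))
  gw <- rs$ratios$ratio[rs$ratios$numerator == "GM" & rs$ratios$denominator == "WM"]
  expect_equal(gw, 0.01333 / 0.00667, tolerance = 0.05)
})
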