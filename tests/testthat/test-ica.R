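test_that("variance-fraction rule picks the smallest q covering the spectrum", {
  # data built with a prescribed eigenvalue-fraction spectrum
  set.seed(1)
  v <- 60; p <- 12; fr <- c(0.90, 0.08, 0.015, 0.005)
  U <- qr.Q(qr(matrix(rnorm(v * 4), v, 4)))
  # right factors orthonormal and zero-mean so voxel centring is a no-op
  Vr <- qr.Q(qr(cbind(1, matrix(rnorm(p * 4), p, 4))))[, 2:5]
  X <- U %*% diag(sqrt(fr)) %*% t(Vr)   # voxels x time
  series <- dynamic_series(array(X, c(v, 1, 1, p)), dt = 1, te = 0.05)
  ic <- decompose(series, variance_fraction = 0.99, seed = 1)
  # cumulative fractions 0.90, 0.98, 0.995 -> q = 3
  expect_equal(ncol(ic$component_maps), 3)
  expect_equal(ic$explained_variance, fr[1:3], tolerance = 1e-8)
})

test_that("two disjoint non-Gaussian sources are unmixed almost perfectly", {
  set.seed(2)
  v <- 400; p <- 30
  m1 <- numeric(v); m1[1:60] <- 1
  m2 <- numeric(v); m2[201:260] <- 1
  tc1 <- sin(seq(0, 3, length.out = p)) + 2
  tc2 <- exp(-seq(0, 4, length.out = p)) + 1
  A <- matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)  # random-ish mixing
  S <- cbind(m1, m2) %*% A
  X <- S %*% rbind(tc1, tc2) + matrix(rnorm(v * p, 0, 1e-4), v, p)
  series <- dynamic_series(array(X, c(v, 1, 1, p)), dt = 1, te = 0.05)
  ic <- decompose(series, n_components = 2, seed = 3)
  cors <- abs(cor(ic$component_maps, cbind(m1, m2)))
  # best match for each true map
  expect_gte(max(cors[, 1]), 0.99)
  expect_gte(max(cors[, 2]), 0.99)
})

test_that("dimensionality bounds are enforced", {
  ph <- build_phantom(phantom_spec(cnr = 50, seed = 1))
  expect_error(decompose(ph$series, n_components = 81, seed = 1), "exceeds")
  flat <- dynamic_series(array(5, c(4, 4, 1, 10)), dt = 1, te = 0.05)
  expect_error(decompose(flat, n_components = 2, seed = 1), "degenerate")
})

test_that("z-maps are standardised by the population moments", {
  z <- zscore_map(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$mean_ic, 2)
  # any voxel at the map mean scores zero
  expect_equal(zscore_map(c(4, 6, 8, 6))$values[c(2, 4)], c(0, 0))
  # standardisation invariants
  set.seed(4)
  m <- rnorm(243)
  zz <- zscore_map(m)$values
  expect_equal(mean(zz), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((zz - mean(zz))^2)), 1, tolerance = 1e-9)
  expect_error(zscore_map(rep(7, 10)), "constant")
})

test_that("top-k selection matches a full-sort oracle and breaks ties by index", {
  set.seed(5)
  vals <- rnorm(81)
  got <- top_k_voxels(vals, 50)
  oracle <- order(vals, decreasing = TRUE)[1:50]
  expect_setequal(got, oracle)
  # one clear maximum
  vals2 <- c(rep(1, 80), 2)
  expect_equal(top_k_voxels(vals2, 1), 81)
  # ties straddling the cut: lowest indices among the tied values win
  vals3 <- c(5, 3, 3, 3, 3, 1)
  expect_equal(sort(top_k_voxels(vals3, 3)), c(1, 2, 3))
  expect_error(top_k_voxels(vals3, 7), "exceeds")
})

test_that("z-weighted AIF reduces to the plain mean under uniform weights", {
  set.seed(6)
  S <- matrix(rnorm(5 * 20, 100, 1), 5, 20)
  zu <- structure(list(values = rep(2, 5), mean_ic = 0, std_ic = 1,
                       voxels = NULL, dims = NULL), class = "zmap")
  aif <- weighted_aif(S, 1:5, zu)
  expect_equal(aif$curve, colMeans(S), tolerance = 1e-12)
  # single voxel: its own curve
  aif1 <- weighted_aif(S, 3, zu)
  expect_equal(aif1$curve, S[3, ])
  # z = [3, 1] -> mean-1 weights [1.5, 0.5]
  z2 <- structure(list(values = c(3, 1), mean_ic = 0, std_ic = 1,
                       voxels = NULL, dims = NULL), class = "zmap")
  aif2 <- weighted_aif(S[1:2, ], 1:2, z2)
  expect_equal(aif2$curve, (1.5 * S[1, ] + 0.5 * S[2, ]) / 2, tolerance = 1e-12)
  expect_equal(aif2$weights, c(1.5, 0.5))
  # non-positive z voxels are excluded with a message
  z3 <- structure(list(values = c(3, -1), mean_ic = 0, std_ic = 1,
                       voxels = NULL, dims = NULL), class = "zmap")
  expect_message(aif3 <- weighted_aif(S[1:2, ], 1:2, z3), "non-positive")
  expect_equal(aif3$curve, S[1, ])
})

test_that("spatial coherence scores compact sets high and scatter low", {
  dims <- c(9, 21, 1)
  block <- as.vector(outer(1:5, (2:6 - 1) * 9, "+"))       # 5x5 block
  expect_equal(dscaif:::.largest_cluster_fraction(block, dims), 1)
  scatter <- c(1, 30, 60, 90, 120)                          # isolated voxels
  expect_equal(dscaif:::.largest_cluster_fraction(scatter, dims), 0.2)
  mixed <- c(block, 150)
  expect_equal(dscaif:::.largest_cluster_fraction(mixed, dims), 25 / 26)
})

test_that("phantom components are identified and ranked sensibly at high CNR", {
  ph <- build_phantom(phantom_spec(cnr = 70, seed = 9))
  ic <- decompose(ph$series, n_components = 10, seed = 9)
  rk <- suppressMessages(rank_components(ic, ph$series))
  sel <- select_aif_components(ic, rk)
  art <- segmentation_accuracy(sel$artery$voxels, ph$truth, "artery")
  expect_gte(art$true_rate, 0.9)
  expect_false(is.null(sel$surround))
  sur <- segmentation_accuracy(sel$surround$voxels, ph$truth, "surround")
  expect_gte(sur$true_rate, 0.9)
  # ranked table covers every component once
  expect_setequal(rk$component, 1:10)
})

test_that("component maps reconstruct the retained variance of the data", {
  ph <- build_phantom(phantom_spec(cnr = 50, seed = 10))
  sm <- series_matrix(ph$series)
  Xc <- sm$X - rowMeans(sm$X)
  ic <- decompose(ph$series, n_components = 10, seed = 10)
  recon <- ic$component_maps %*% t(ic$time_courses)
  energy_resid <- sum((Xc - recon)^2) / sum(Xc^2)
  varfrac <- sum(ic$explained_variance)
  expect_lte(energy_resid, 1 - varfrac + 0.02)
})

test_that("selection is reproducible for a fixed seed", {
  ph <- build_phantom(phantom_spec(cnr = 40, seed = 12))
  pick <- function() {
    ic <- decompose(ph$series, n_components = 10, seed = 12)
    rk <- suppressMessages(rank_components(ic, ph$series))
    sort(select_aif_components(ic, rk)$artery$voxels)
  }
  expect_identical(pick(), pick())
})
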