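test_that("bolus curve vanishes at zero, peaks at t0, follows the gamma form", {
  p <- bolus_params(c_max = 3, t0 = 7)
  expect_identical(bolus_concentration(0, p), 0)
  expect_equal(bolus_concentration(7, p), 3)
  # maximum is attained exactly at t0
  expect_lt(bolus_concentration(6.9, p), 3)
  expect_lt(bolus_concentration(7.1, p), 3)
  # direct high-precision evaluation at t = 2 t0
  expect_equal(bolus_concentration(14, p), 3 * 2 * exp(-1), tolerance = 1e-12)
  expect_error(bolus_concentration(-1, p), "non-negative")
  expect_error(bolus_params(c_max = -1), "positive")
  # the millisecond flag rescales the time constant
  expect_equal(bolus_params(t0 = 7, literal_ms = TRUE)$t0, 0.007)
})

test_that("dilution-theory tissue curve matches the brute-force convolution oracle", {
  dt <- 0.5; mtt <- 2.6; zeta <- 0.02
  n <- 120
  t <- (seq_len(n) - 1) * dt
  # impulse response
  imp <- c(1, numeric(n - 1))
  got <- tissue_concentration(imp, mtt, zeta, dt)
  expect_equal(got, zeta / mtt * exp(-t / mtt) * dt, tolerance = 1e-12)
  # arbitrary smooth input vs double-loop oracle
  aif <- bolus_concentration(t, bolus_params())
  oracle <- zeta / mtt * brute_convolution(aif, exp(-t / mtt), dt)
  expect_equal(tissue_concentration(aif, mtt, zeta, dt), oracle, tolerance = 1e-12)
  # zero in, zero out; empty input errors
  expect_identical(tissue_concentration(numeric(n), mtt, zeta, dt), numeric(n))
  expect_error(tissue_concentration(numeric(0), mtt, zeta, dt), "empty")
})

test_that("constant input reaches the mass-balance limit zeta * c", {
  dt <- 0.1; mtt <- 2; zeta <- 0.05; c0 <- 4
  n <- ceiling(16 * mtt / dt)  # well past 10 mtt so the transient is < 1e-6
  out <- tissue_concentration(rep(c0, n), mtt, zeta, dt)
  # rectangle-rule discretisation: steady state zeta * c * dt/mtt / (1 - exp(-dt/mtt))
  disc <- (dt / mtt) / (1 - exp(-dt / mtt))
  expect_equal(out[n], zeta * c0 * disc, tolerance = 1e-6)
  expect_equal(out[n], zeta * c0, tolerance = disc - 1 + 1e-6)
})

test_that("relaxation regimes are linear (SDR) and quadratic (DNR) in concentration", {
  p <- kiselev_params()
  conc <- c(0, 0.5, 1, 2, 3)
  expect_identical(relaxation_shift(numeric(5), "SDR", 0.02, p), numeric(5))
  sdr1 <- relaxation_shift(conc, "SDR", 0.02, p)
  expect_equal(relaxation_shift(2 * conc, "SDR", 0.02, p), 2 * sdr1)
  dnr1 <- relaxation_shift(conc, "DNR", 0.02, p)
  expect_equal(relaxation_shift(2 * conc, "DNR", 0.02, p), 4 * dnr1)
  expect_equal(sdr1[1], 0)
  expect_error(relaxation_shift(conc, "XYZ", 0.02, p))
  expect_error(relaxation_shift(-conc, "SDR", 0.02, p), "non-negative")
})

test_that("signal model is exponential in relaxation and inverts exactly", {
  dr2 <- c(0, 1, 5, 20, 0, 0.3)
  s <- concentration_to_signal(dr2, s0 = 100, te = 0.045, r2_baseline = 6.21)
  expect_equal(s[1], 100 * exp(-0.045 * 6.21))
  expect_true(all(s > 0))
  expect_true(all(diff(s[order(dr2)]) <= 0))
  # algebraic inverse: with K = 1 the log conversion recovers delta-R2
  n <- 40
  dr2c <- c(numeric(6), bolus_concentration((0:(n - 7)) * 1.5, bolus_params()))
  sig <- concentration_to_signal(dr2c, s0 = 100, te = 0.045, r2_baseline = 10)
  series <- dynamic_series(array(sig, c(1, 1, 1, n)), dt = 1.5, te = 0.045,
                           baseline = 1:6)
  conc <- signal_to_concentration(series, conversion_params(k = 1, te = 0.045,
                                                            baseline_window = 1:6))
  expect_equal(drop(conc$data), dr2c, tolerance = 1e-10)
})

test_that("phantom geometry, partial-volume mixing and determinism are exact", {
  spec <- phantom_spec(cnr = Inf, seed = 1)
  ph <- build_phantom(spec)
  tr <- ph$truth
  expect_equal(dim(ph$series$data), c(9, 21, 1, 80))
  expect_length(tr$mask_artery, 54)
  expect_length(tr$mask_surround, 27)
  expect_length(tr$mask_tissue, 54)
  expect_length(tr$mask_overlap_12, 27)
  expect_length(tr$mask_overlap_23, 27)
  all_masks <- list(tr$mask_artery, tr$mask_surround, tr$mask_tissue,
                    tr$mask_overlap_12, tr$mask_overlap_23)
  expect_equal(sum(lengths(all_masks)), 9 * 21)
  expect_false(any(duplicated(unlist(all_masks))))

  X <- matrix(ph$series$data, 9 * 21, 80)
  # noise-free: pure artery voxels equal the artery curve exactly
  for (v in tr$mask_artery[c(1, 27, 54)]) {
    expect_identical(X[v, ], unname(tr$pure_signals["artery", ]))
  }
  # an I&II overlap voxel is the exact 0.5/0.5 mixture
  mix <- 0.5 * tr$pure_signals["artery", ] + 0.5 * tr$pure_signals["surround", ]
  expect_equal(X[tr$mask_overlap_12[1], ], unname(mix), tolerance = 1e-12)

  # bit-identical reproduction from an identical spec
  ph2 <- build_phantom(phantom_spec(cnr = 30, seed = 42))
  ph3 <- build_phantom(phantom_spec(cnr = 30, seed = 42))
  expect_identical(ph2$series$data, ph3$series$data)
  # a different seed changes the realisation
  ph4 <- build_phantom(phantom_spec(cnr = 30, seed = 43))
  expect_false(identical(ph2$series$data, ph4$series$data))

  expect_error(phantom_spec(overlap_cols = 9), "smaller")
})

test_that("realised noise matches the requested CNR within 5%", {
  spec <- phantom_spec(cnr = 50, seed = 7)
  ph <- build_phantom(spec)
  tr <- ph$truth
  X <- matrix(ph$series$data, 9 * 21, 80)
  # exact noise samples: residuals of all pure-artery voxels
  resid <- sweep(X[tr$mask_artery, ], 2, tr$pure_signals["artery", ])
  sigma_hat <- sd(as.vector(resid))
  drop_art <- max(tr$pure_signals["artery", ]) - min(tr$pure_signals["artery", ])
  expect_equal(drop_art / sigma_hat, 50, tolerance = 0.05)
})

test_that("noise-free compartment ordering matches the physiology", {
  ph <- build_phantom(phantom_spec(cnr = Inf))
  ps <- ph$truth$pure_signals
  drop <- function(x) max(x) - min(x)
  # the surrounding-tissue drop is smaller and later than the arterial one
  expect_lt(drop(ps["surround", ]), drop(ps["artery", ]))
  expect_gt(which.min(ps["surround", ]), which.min(ps["artery", ]))
})
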