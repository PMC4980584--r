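# Independent brute-force oracles used across tests.

# O(n^2) discrete convolution, rectangle rule
brute_convolution <- function(a, b, dt) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      out[i] <- out[i] + a[j] * b[i - j + 1] * dt
    }
  }
  out
}

# a small phantom spec in the linear (unsaturated, SDR-only) relaxation
# regime where signal change is proportional to concentration and
# quantification is exact up to discretisation
linear_phantom_spec <- function(cnr = 1000, seed = 1, ...) {
  phantom_spec(
    cnr = cnr, seed = seed,
    physics = kiselev_params(chi_per_mM = 0.004e-6, dnr_coeff = 1e-9),
    zeta_surround = 0.10, tissue_delay = 0, ...)
}

# forward tissue curve from an AIF, flow f (1/s) and monoexponential
# residue with the given mtt, matching the deconvolution discretisation
forward_tissue <- function(aif, f, mtt, dt) {
  t <- (seq_along(aif) - 1) * dt
  f * brute_convolution(aif, exp(-t / mtt), dt)
}
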