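# Canonical coupled parameter set used throughout the suite (Gaussian
# kernels, Mexican-hat ring kernel, thresholds 0.5, couplings 1,
# time constants 0.1).
canonical_params <- function(rate_mode = "heaviside", gamma_s = 1,
                             w_s0 = 0.1, anisotropy = "isotropic") {
  laminar_params(w_d0 = 2, sigma_d = 0.1, w_s0 = w_s0, sigma_s = 1,
                 w0 = -1, w1 = 2, kappa_d = 0.5, kappa_s = 0.5,
                 gamma_d = 1, gamma_s = gamma_s, tau_d = 0.1, tau_s = 0.1,
                 eta_d = 10, eta_s = 10, rate_mode = rate_mode,
                 kernel_d = "gaussian", kernel_s = "gaussian",
                 anisotropy = anisotropy)
}

# Ring-model parameter set with a strong Mexican hat that supports bumps
# even without external input.
strong_ring_params <- function() {
  laminar_params(w0 = -2, w1 = 8, w_s0 = 0, kappa_s = 0.5, gamma_d = 1,
                 tau_d = 1, tau_s = 1)
}

# Direct-sum circular 1D convolution oracle (trapezoidal on a periodic
# uniform grid): independent of the FFT path.
direct_conv_1d <- function(f, kernel_vals, dx) {
  n <- length(f)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - seq_len(n)) %% n) + 1L
    out[i] <- sum(kernel_vals[idx] * f) * dx
  }
  out
}

expect_circa <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("%.8g within %g of %.8g", actual, tol,
                              expected))
}
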