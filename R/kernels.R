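#' Exponential synaptic weight kernel
#'
#' \eqn{w(x) = \frac{m}{2\sigma} e^{-|x|/\sigma}}: even, positive, with
#' total integral `mass`. This is the kernel family for which the front
#' speed of the scalar deep-layer field has a closed form.
#'
#' @param x displacement (vectorized).
#' @param mass total kernel mass \eqn{\int w = m}.
#' @param sigma spatial range (> 0).
#' @return Weight density at `x`.
#' @examples
#' exponential_kernel(0, mass = 2, sigma = 1)  # 1
#' @export
exponential_kernel <- function(x, mass, sigma) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be strictly positive", call. = FALSE)
  mass / (2 * sigma) * exp(-abs(x) / sigma)
}

#' Gaussian synaptic weight kernel
#'
#' \eqn{w(x) = \frac{m}{\sqrt{2\pi\sigma^2}} e^{-x^2/2\sigma^2}}: the
#' kernel family used in the simulation parameter sets.
#'
#' @inheritParams exponential_kernel
#' @return Weight density at `x`.
#' @export
gaussian_kernel <- function(x, mass, sigma) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be strictly positive", call. = FALSE)
  mass / sqrt(2 * pi * sigma^2) * exp(-x^2 / (2 * sigma^2))
}

# Dispatch on the kernel family stored in laminar_params.
spatial_kernel <- function(x, mass, sigma, family) {
  switch(family,
         exponential = exponential_kernel(x, mass, sigma),
         gaussian    = gaussian_kernel(x, mass, sigma),
         stop("unknown kernel family '", family, "'", call. = FALSE))
}

# Mass function W_d(y) = integral of the kernel over (y, Inf).
spatial_kernel_mass_above <- function(y, mass, sigma, family) {
  switch(family,
         exponential = ifelse(y >= 0,
                              mass / 2 * exp(-y / sigma),
                              mass - mass / 2 * exp(y / sigma)),
         gaussian    = mass * stats::pnorm(y / sigma, lower.tail = FALSE),
         stop("unknown kernel family '", family, "'", call. = FALSE))
}

#' Local and long-range orientation kernels of the superficial layer
#'
#' The local (within-hypercolumn) ring kernel is the Mexican hat
#' \eqn{w_{loc}(\theta) = (w_0 + w_1 \cos 2\theta)/\pi}; the
#' orientation-dependent factor of the long-range horizontal connections
#' is the non-negative, unit-mass \eqn{w_{hoz}(\theta) = (1 + \cos
#' 2\theta)/\pi}. Both are even and pi-periodic; `theta` is wrapped
#' modulo pi.
#'
#' @param theta orientation difference in radians (vectorized).
#' @param params a [laminar_params()] object (supplies `w0`, `w1`).
#' @return A list with numeric components `loc` and `hoz`.
#' @examples
#' k <- ring_kernels(0, laminar_params(w0 = -2, w1 = 8))
#' k$loc * pi  # 6
#' @export
ring_kernels <- function(theta, params) {
  th <- wrap_orientation(theta)
  list(loc = (params$w0 + params$w1 * cos(2 * th)) / pi,
       hoz = (1 + cos(2 * th)) / pi)
}

# Primitives W(theta) = int_0^theta of the ring kernels (odd functions).
ring_primitive_loc <- function(theta, params) {
  (params$w0 * theta + params$w1 / 2 * sin(2 * theta)) / pi
}

ring_primitive_hoz <- function(theta) {
  (theta + sin(2 * theta) / 2) / pi
}

# Primitive of the combined ring kernel w_loc + w_s0 * w_hoz, the kernel
# that governs bumps behind the full laminar wave.
ring_primitive_combined <- function(theta, params) {
  ring_primitive_loc(theta, params) + params$w_s0 * ring_primitive_hoz(theta)
}

ring_kernel_combined <- function(theta, params) {
  k <- ring_kernels(theta, params)
  k$loc + params$w_s0 * k$hoz
}

#' Anisotropy factor of 2D horizontal connections
#'
#' Angular weighting \eqn{A(\psi)} applied to the long-range kernel in
#' 2D, where `psi` is the angle between the direction of the connection
#' (the vector joining two hypercolumns) and the shared preferred
#' orientation. In `"cosine"` mode \eqn{A(\psi) = 1 + \cos 2\psi}, so
#' patches are coupled predominantly along the axis of their common
#' orientation preference; in `"isotropic"` mode \eqn{A \equiv 1}.
#'
#' @param psi angle in radians (vectorized; wrapped modulo pi).
#' @param mode `"isotropic"` or `"cosine"`.
#' @return Non-negative factor, even and pi-periodic in `psi`.
#' @examples
#' anisotropy(0, "cosine")      # 2
#' anisotropy(pi / 2, "cosine") # 0
#' @export
anisotropy <- function(psi, mode = c("isotropic", "cosine")) {
  mode <- match.arg(mode)
  if (mode == "isotropic") rep(1, length(psi)) else 1 + cos(2 * psi)
}

#' Firing-rate nonlinearity
#'
#' Sigmoid rate \eqn{f(u) = 1 / (1 + e^{-\eta (u - \kappa)})} or its
#' high-gain (Heaviside) limit \eqn{H(u - \kappa)}. At exact threshold
#' the Heaviside convention is \eqn{H(0) = 1}, so the active set is
#' closed.
#'
#' @param u activity (vectorized; matrices preserved).
#' @param gain sigmoid gain eta (> 0; ignored in Heaviside mode).
#' @param threshold firing threshold kappa.
#' @param mode `"heaviside"` or `"sigmoid"`.
#' @return Rate in `[0, 1]`, same shape as `u`.
#' @examples
#' firing_rate(0.7, gain = 10, threshold = 0.5, mode = "sigmoid")
#' @export
firing_rate <- function(u, gain, threshold,
                        mode = c("heaviside", "sigmoid")) {
  mode <- match.arg(mode)
  if (mode == "heaviside") {
    out <- (u >= threshold) + 0
  } else {
    if (gain <= 0) stop("sigmoid gain must be positive", call. = FALSE)
    out <- 1 / (1 + exp(-gain * (u - threshold)))
  }
  out
}

# Layer-specific rate functions reading mode/gain/threshold from params.
rate_deep <- function(u, params) {
  firing_rate(u, params$eta_d, params$kappa_d, params$rate_mode)
}

rate_sup <- function(v, params) {
  firing_rate(v, params$eta_s, params$kappa_s, params$rate_mode)
}

#' Effective horizontal drive onto a bump of half-width Delta
#'
#' \eqn{\Omega_{hoz}(\theta, \Delta) = W_{hoz}(\theta + \Delta) -
#' W_{hoz}(\theta - \Delta)}, the orientation profile of the input that a
#' super-threshold bump of half-width `Delta` delivers through the
#' horizontal connections. It is even in `theta` and maximal at the bump
#' centre, which is why queued sub-threshold bumps inherit the phase of
#' the active region.
#'
#' @param theta orientation offset from the bump centre (vectorized).
#' @param Delta bump half-width in `[0, pi/2]`.
#' @return Drive value(s).
#' @examples
#' omega_hoz(0, pi / 4)
#' @export
omega_hoz <- function(theta, Delta) {
  if (!is.numeric(Delta) || length(Delta) != 1L || Delta < 0 ||
      Delta > pi / 2)
    stop("Delta must lie in [0, pi/2]", call. = FALSE)
  ring_primitive_hoz(theta + Delta) - ring_primitive_hoz(theta - Delta)
}
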