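#' Model parameters for the bilaminar neural field
#'
#' Collects every scalar parameter of the coupled deep/superficial model:
#' the deep-layer recurrent kernel (mass `w_d0`, range `sigma_d`), the
#' long-range horizontal kernel of the superficial layer (mass `w_s0`,
#' range `sigma_s`), the local ring kernel
#' \eqn{w_{loc}(\theta) = (w_0 + w_1 \cos 2\theta)/\pi}, firing thresholds
#' `kappa_d`, `kappa_s`, vertical coupling strengths (`gamma_d`
#' feedforward deep-to-superficial, `gamma_s` feedback
#' superficial-to-deep), relaxation time constants `tau_d`, `tau_s`, and
#' the firing-rate nonlinearity (Heaviside limit or sigmoid with gains
#' `eta_d`, `eta_s`).
#'
#' Units are nondimensional: time is measured in units of `tau_d` and
#' space in units of `sigma_d` unless the caller supplies dimensional
#' values. The ring kernel must be of lateral-inhibition (Mexican hat)
#' type on the orientation circle, which requires
#' `w0 + w1 > 0 > w0 - w1`.
#'
#' Some published parameter sets quote the cosine coefficient as
#' \eqn{2 w_2}; this constructor always stores `w1`, so supply
#' `w1 = 2 * w2` in that convention.
#'
#' @param w_d0 total mass of the deep-layer kernel (dimensionless drive).
#' @param sigma_d spatial range of the deep-layer kernel.
#' @param w_s0 total mass of the horizontal kernel (0 disables horizontal
#'   connections).
#' @param sigma_s spatial range of the horizontal kernel.
#' @param w0,w1 constant and cosine coefficients of the local ring kernel.
#' @param kappa_d,kappa_s firing thresholds of the two layers.
#' @param gamma_d,gamma_s vertical feedforward/feedback strengths
#'   (non-negative).
#' @param tau_d,tau_s relaxation time constants.
#' @param eta_d,eta_s sigmoid gains (used when `rate_mode = "sigmoid"`).
#' @param rate_mode `"heaviside"` (high-gain limit, `H(0) = 1` by
#'   convention) or `"sigmoid"`.
#' @param kernel_d,kernel_s spatial kernel family for each layer,
#'   `"exponential"` or `"gaussian"`.
#' @param anisotropy 2D horizontal-connection anisotropy: `"isotropic"`
#'   (factor identically 1) or `"cosine"` (factor `1 + cos 2psi`).
#' @return An object of class `laminar_params` (a validated list).
#' @examples
#' p <- laminar_params(w_d0 = 2, kappa_d = 0.5)
#' p$w_d0
#' @export
laminar_params <- function(w_d0 = 2, sigma_d = 1,
                           w_s0 = 0.1, sigma_s = 1,
                           w0 = -1, w1 = 2,
                           kappa_d = 0.5, kappa_s = 0.5,
                           gamma_d = 1, gamma_s = 1,
                           tau_d = 1, tau_s = 1,
                           eta_d = 10, eta_s = 10,
                           rate_mode = c("heaviside", "sigmoid"),
                           kernel_d = c("exponential", "gaussian"),
                           kernel_s = c("gaussian", "exponential"),
                           anisotropy = c("isotropic", "cosine")) {
  rate_mode  <- match.arg(rate_mode)
  kernel_d   <- match.arg(kernel_d)
  kernel_s   <- match.arg(kernel_s)
  anisotropy <- match.arg(anisotropy)
  p <- list(w_d0 = w_d0, sigma_d = sigma_d, w_s0 = w_s0, sigma_s = sigma_s,
            w0 = w0, w1 = w1, kappa_d = kappa_d, kappa_s = kappa_s,
            gamma_d = gamma_d, gamma_s = gamma_s,
            tau_d = tau_d, tau_s = tau_s, eta_d = eta_d, eta_s = eta_s,
            rate_mode = rate_mode, kernel_d = kernel_d, kernel_s = kernel_s,
            anisotropy = anisotropy)
  class(p) <- "laminar_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c("w_d0", "sigma_d", "w_s0", "sigma_s", "w0", "w1", "kappa_d",
           "kappa_s", "gamma_d", "gamma_s", "tau_d", "tau_s",
           "eta_d", "eta_s")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  pos <- c("sigma_d", "sigma_s", "kappa_d", "kappa_s", "tau_d", "tau_s")
  for (f in pos)
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  if (p$gamma_d < 0 || p$gamma_s < 0)
    stop("coupling strengths gamma_d, gamma_s must be non-negative",
         call. = FALSE)
  if (p$w_s0 < 0)
    stop("horizontal kernel mass w_s0 must be non-negative", call. = FALSE)
  if (p$rate_mode == "sigmoid" && (p$eta_d <= 0 || p$eta_s <= 0))
    stop("sigmoid gains eta_d, eta_s must be positive", call. = FALSE)
  if (!(p$w0 + p$w1 > 0 && p$w0 - p$w1 < 0))
    stop("ring kernel must satisfy w0 + w1 > 0 > w0 - w1 ",
         "(local excitation, lateral inhibition)", call. = FALSE)
  invisible(p)
}

#' @export
print.laminar_params <- function(x, ...) {
  cat("<laminar_params>\n")
  cat(sprintf("  deep:        w_d0 = %g, sigma_d = %g (%s), kappa_d = %g, tau_d = %g\n",
              x$w_d0, x$sigma_d, x$kernel_d, x$kappa_d, x$tau_d))
  cat(sprintf("  superficial: w0 = %g, w1 = %g, w_s0 = %g, sigma_s = %g (%s), kappa_s = %g, tau_s = %g\n",
              x$w0, x$w1, x$w_s0, x$sigma_s, x$kernel_s, x$kappa_s, x$tau_s))
  cat(sprintf("  vertical:    gamma_d = %g, gamma_s = %g\n",
              x$gamma_d, x$gamma_s))
  cat(sprintf("  rate: %s (eta_d = %g, eta_s = %g); 2D anisotropy: %s\n",
              x$rate_mode, x$eta_d, x$eta_s, x$anisotropy))
  invisible(x)
}

#' Discretization grid for 1D laminar simulations
#'
#' The spatial axis is a uniform periodic grid of `nx` points covering
#' `[x0, x0 + extent)`; the orientation axis is a uniform periodic grid of
#' `ntheta` points on `[-pi/2, pi/2)`. Spatial convolutions are evaluated
#' as Fourier products on the circle (equivalent to the periodic
#' trapezoidal sum), so the extent must comfortably contain the kernels.
#'
#' @param extent length of the periodic spatial domain.
#' @param nx number of spatial points.
#' @param ntheta number of orientation points (`dtheta = pi / ntheta`).
#' @param dt forward-Euler time step.
#' @param x0 coordinate of the first grid point.
#' @return An object of class `laminar_grid`.
#' @examples
#' g <- grid_1d(extent = 4, nx = 400, ntheta = 100, dt = 0.001)
#' range(g$x); g$dtheta
#' @export
grid_1d <- function(extent = 10, nx = 1000, ntheta = 100, dt = 0.001,
                    x0 = 0) {
  stopifnot(extent > 0, nx >= 8, ntheta >= 8, dt > 0)
  g <- list(dim = 1L,
            nx = as.integer(nx), dx = extent / nx, extent = extent,
            x = x0 + extent * (seq_len(nx) - 1L) / nx,
            ntheta = as.integer(ntheta), dtheta = pi / ntheta,
            theta = -pi / 2 + pi * (seq_len(ntheta) - 1L) / ntheta,
            dt = dt)
  class(g) <- "laminar_grid"
  g
}

#' Discretization grid for 2D laminar simulations
#'
#' Square periodic grid of `nx` by `ny` points centred on the origin
#' (coordinates in `[-extent/2, extent/2)`), with the same orientation
#' axis convention as [grid_1d()].
#'
#' @param extent side length of the periodic square domain.
#' @param nx,ny number of grid points per side.
#' @param ntheta number of orientation points.
#' @param dt forward-Euler time step.
#' @return An object of class `laminar_grid` with `dim = 2`.
#' @export
grid_2d <- function(extent = 8, nx = 128, ny = nx, ntheta = 32,
                    dt = 0.002) {
  stopifnot(extent > 0, nx >= 8, ny >= 8, ntheta >= 4, dt > 0)
  g <- list(dim = 2L,
            nx = as.integer(nx), ny = as.integer(ny),
            dx = extent / nx, dy = extent / ny, extent = extent,
            x = -extent / 2 + extent * (seq_len(nx) - 1L) / nx,
            y = -extent / 2 + extent * (seq_len(ny) - 1L) / ny,
            ntheta = as.integer(ntheta), dtheta = pi / ntheta,
            theta = -pi / 2 + pi * (seq_len(ntheta) - 1L) / ntheta,
            dt = dt)
  class(g) <- "laminar_grid"
  g
}

#' @export
print.laminar_grid <- function(x, ...) {
  if (x$dim == 1L)
    cat(sprintf("<laminar_grid 1D> %d x-points (dx = %g, extent %g), %d orientations (dtheta = %g), dt = %g\n",
                x$nx, x$dx, x$extent, x$ntheta, x$dtheta, x$dt))
  else
    cat(sprintf("<laminar_grid 2D> %d x %d points (dx = %g, extent %g), %d orientations, dt = %g\n",
                x$nx, x$ny, x$dx, x$extent, x$ntheta, x$dt))
  invisible(x)
}

# Euler stability guard shared by the 1D and 2D steppers.
check_dt <- function(params, dt) {
  if (dt > 0.1 * min(params$tau_d, params$tau_s))
    stop("time step dt = ", dt, " too large for tau_d = ", params$tau_d,
         ", tau_s = ", params$tau_s,
         " (require dt <= 0.1 * min(tau_d, tau_s))", call. = FALSE)
  invisible(TRUE)
}

# Signed displacement of each grid point from the origin on the periodic
# axis, in FFT order: 0, dx, ..., extent/2 - dx, -extent/2, ..., -dx.
circ_displacement <- function(n, dx) {
  i <- seq_len(n) - 1L
  i[i >= n / 2] <- i[i >= n / 2] - n
  i * dx
}

# Wrap an angle (or difference of angles) to [-pi/2, pi/2).
wrap_orientation <- function(theta) {
  ((theta + pi / 2) %% pi) - pi / 2
}
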