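# Periodicized spatial kernel sampled on the circular grid, returned as
# its DFT times dx so that Re(ifft(fft(f) * kfft)) is the periodic
# trapezoidal convolution sum. A few wrap images make the discrete
# kernel exactly periodic, so no mass is lost on the circle.
kernel_fft_1d <- function(n, dx, mass, sigma, family, images = 3L) {
  x <- circ_displacement(n, dx)
  extent <- n * dx
  w <- spatial_kernel(x, mass, sigma, family)
  for (k in seq_len(images)) {
    w <- w + spatial_kernel(x + k * extent, mass, sigma, family) +
      spatial_kernel(x - k * extent, mass, sigma, family)
  }
  stats::fft(w) * dx
}

# Orientation convolution matrix K[j, i] = w(theta_j - theta_i) * dtheta
# on the periodic ring, so that (f %*% K) is the trapezoidal sum (all
# nodes have equal weight on a periodic uniform grid).
ring_conv_matrix <- function(grid, wfun) {
  d <- outer(grid$theta, grid$theta, function(a, b) wrap_orientation(a - b))
  wfun(d) * grid$dtheta
}

# Per-run precomputed operators for the 1D stepper.
precompute_1d <- function(params, grid) {
  list(
    fft_wd = kernel_fft_1d(grid$nx, grid$dx, params$w_d0, params$sigma_d,
                           params$kernel_d),
    fft_ws = if (params$w_s0 > 0)
      kernel_fft_1d(grid$nx, grid$dx, params$w_s0, params$sigma_s,
                    params$kernel_s),
    K_loc = ring_conv_matrix(grid, function(th)
      ring_kernels(th, params)$loc),
    K_hoz = if (params$w_s0 > 0)
      ring_conv_matrix(grid, function(th) ring_kernels(th, params)$hoz))
}

conv_circ_1d <- function(f, kfft) {
  Re(stats::fft(stats::fft(f) * kfft, inverse = TRUE)) / length(f)
}

conv_circ_cols <- function(f, kfft) {
  Re(stats::mvfft(stats::mvfft(f) * kfft, inverse = TRUE)) / nrow(f)
}

#' Laminar state at one instant (1D)
#'
#' @param u deep-layer activity, length `nx`.
#' @param v superficial activity, `nx` by `ntheta` matrix.
#' @param t simulation time.
#' @return An object of class `laminar_state`.
#' @export
laminar_state <- function(u, v, t = 0) {
  stopifnot(is.numeric(u), is.matrix(v), length(u) == nrow(v))
  s <- list(u = u, v = v, t = t)
  class(s) <- "laminar_state"
  s
}

#' @export
print.laminar_state <- function(x, ...) {
  cat(sprintf("<laminar_state> t = %g, %d x-points, %d orientations; max u = %.4g, max v = %.4g\n",
              x$t, length(x$u), ncol(x$v), max(x$u), max(x$v)))
  invisible(x)
}

#' Single forward-Euler step of the coupled 1D laminar model
#'
#' Advances the coupled fields
#' \deqn{\tau_d \partial_t u = -u + w_d \circ f_d(u)
#'   + \gamma_s \int f_s(v)\, d\theta,}
#' \deqn{\tau_s \partial_t v = -v + w_{loc} * f_s(v)
#'   + w_s \circ w_{hoz} * f_s(v) + \gamma_d f_d(u)}
#' by one explicit Euler step. Spatial convolutions are Fourier products
#' on the periodic grid (equal to the periodic trapezoidal sum);
#' orientation convolutions are periodic trapezoidal quadrature.
#'
#' @param state a [laminar_state()].
#' @param params a [laminar_params()] object.
#' @param grid a [grid_1d()] object.
#' @param ops precomputed operators (internal; recomputed when `NULL`).
#' @return The state at `t + dt`.
#' @export
step_1d <- function(state, params, grid, ops = NULL) {
  if (is.null(ops)) {
    check_dt(params, grid$dt)
    ops <- precompute_1d(params, grid)
  }
  fd <- rate_deep(state$u, params)
  fs <- rate_sup(state$v, params)
  drive_d <- conv_circ_1d(fd, ops$fft_wd)
  if (params$gamma_s > 0)
    drive_d <- drive_d + params$gamma_s * rowSums(fs) * grid$dtheta
  drive_s <- fs %*% ops$K_loc
  if (params$w_s0 > 0)
    drive_s <- drive_s + conv_circ_cols(fs %*% ops$K_hoz, ops$fft_ws)
  if (params$gamma_d > 0)
    drive_s <- drive_s + params$gamma_d * fd
  u <- state$u + grid$dt / params$tau_d * (-state$u + drive_d)
  v <- state$v + grid$dt / params$tau_s * (-state$v + drive_s)
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("non-finite activity at t = ", state$t + grid$dt,
         " (blow-up; reduce dt or check parameters)", call. = FALSE)
  laminar_state(u, v, state$t + grid$dt)
}

#' Traveling-front initial condition for the 1D laminar model
#'
#' Step initial data consistent with the asymptotic wave: behind `x0`
#' the deep layer sits at the up state `w_d0 + 2 gamma_s Delta` and the
#' superficial layer at the stationary bump `V_bump(theta)` of the
#' combined ring kernel under drive `gamma_d`; ahead of `x0` both layers
#' are at rest. With `v_mode = "zero"` the superficial layer starts from
#' rest everywhere (deep plateau `w_d0`), which lets bump phases settle
#' freely — used for decoherence experiments.
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_1d()] object.
#' @param x0 interface position (active for `x <= x0`).
#' @param v_mode `"bump"` or `"zero"`.
#' @param center bump centre for `v_mode = "bump"`.
#' @return A [laminar_state()] at `t = 0`.
#' @export
init_front <- function(params, grid, x0, v_mode = c("bump", "zero"),
                       center = 0) {
  v_mode <- match.arg(v_mode)
  ind <- as.numeric(grid$x <= x0)
  if (v_mode == "zero") {
    u <- params$w_d0 * ind
    v <- matrix(0, grid$nx, grid$ntheta)
    return(laminar_state(u, v))
  }
  bumps <- Filter(function(b) b$stable,
                  bump_solve(params, input_level = params$gamma_d,
                             kernel = "combined", center = center))
  if (!length(bumps))
    stop("no stable bump solution for this parameter set; ",
         "cannot build a bump-mode front initial condition", call. = FALSE)
  b <- bumps[[length(bumps)]]
  u <- feedback_up_state(params, b$Delta) * ind
  v <- outer(ind, b$V(grid$theta))
  laminar_state(u, v)
}

#' Seeded orientation-dependent perturbation
#'
#' Adds independent zero-mean uniform noise of half-width `amplitude` to
#' every `(x, theta)` node of the superficial field. The bilaminar model
#' needs some orientation-dependent symmetry breaking for activated ring
#' networks to tip from the orientation-uniform threshold state into a
#' bump; this is the minimal, structureless perturbation. The RNG state
#' is restored on exit, so simulations are reproducible from `seed`
#' alone.
#'
#' @param state a [laminar_state()] (or 2D field list with a `v` array).
#' @param amplitude noise half-width (0 returns the state unchanged).
#' @param seed integer seed.
#' @return The perturbed state.
#' @export
add_orientation_noise <- function(state, amplitude = 1e-3, seed = 1L) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(state)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  eps <- stats::runif(length(state$v), -amplitude, amplitude)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  state$v <- state$v + array(eps, dim = dim(state$v))
  state
}

#' Run the coupled 1D laminar model
#'
#' Integrates the model from `init` to time `T`, recording the
#' threshold-interface trajectory of both layers at every step and full
#' field snapshots at `snapshot_times`. Parameter overrides can be
#' scheduled mid-run (`ablations`), e.g. removing the feedforward drive
#' at a given time.
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_1d()] object.
#' @param init initial [laminar_state()].
#' @param T final time.
#' @param snapshot_times times at which to store full fields (always
#'   includes 0 and `T`).
#' @param ablations list of `list(time =, set = list(param = value))`
#'   overrides applied from `time` onwards.
#' @param noise_amplitude,noise_seed optional perturbation applied to the
#'   initial superficial field via [add_orientation_noise()].
#' @return A `sim_result_1d`: list with `times`, `snapshots` (list of
#'   states), `trajectory` (data frame: time, deep and superficial
#'   interface positions), `params`, `grid`, and the noise settings.
#' @export
run_1d <- function(params, grid, init, T,
                   snapshot_times = NULL, ablations = list(),
                   noise_amplitude = 0, noise_seed = 1L) {
  check_dt(params, grid$dt)
  stopifnot(T >= 0)
  state <- init
  if (noise_amplitude > 0)
    state <- add_orientation_noise(state, noise_amplitude, noise_seed)
  n_steps <- round(T / grid$dt)
  snap_t <- sort(unique(c(0, snapshot_times, T)))
  snap_steps <- unique(pmin(pmax(round(snap_t / grid$dt), 0), n_steps))
  ab_steps <- vapply(ablations, function(a) round(a$time / grid$dt),
                     numeric(1))
  p <- params
  ops <- precompute_1d(p, grid)
  snapshots <- list()
  times <- numeric(0)
  traj_t <- numeric(n_steps + 1L)
  traj_d <- numeric(n_steps + 1L)
  traj_s <- numeric(n_steps + 1L)
  record <- function(step, st) {
    traj_t[step + 1L] <<- st$t
    traj_d[step + 1L] <<- threshold_interface(st$u, p$kappa_d, grid$x)
    traj_s[step + 1L] <<- threshold_interface(apply(st$v, 1, max),
                                              p$kappa_s, grid$x)
  }
  record(0L, state)
  if (0L %in% snap_steps) {
    snapshots[[length(snapshots) + 1L]] <- state
    times <- c(times, 0)
  }
  wrap_guard <- grid$x[1] + grid$extent -
    3 * max(p$sigma_d, if (p$w_s0 > 0) p$sigma_s else 0)
  warned <- FALSE
  for (step in seq_len(n_steps)) {
    hit <- which(ab_steps == step - 1L)
    if (length(hit)) {
      for (i in hit) for (nm in names(ablations[[i]]$set))
        p[[nm]] <- ablations[[i]]$set[[nm]]
      validate_params(p)
      ops <- precompute_1d(p, grid)
    }
    state <- step_1d(state, p, grid, ops)
    record(step, state)
    if (!warned && is.finite(traj_d[step + 1L]) &&
        traj_d[step + 1L] > wrap_guard) {
      warning("deep interface within 3 kernel ranges of the periodic ",
              "boundary; enlarge the domain for clean front dynamics",
              call. = FALSE)
      warned <- TRUE
    }
    if (step %in% snap_steps) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
    }
  }
  out <- list(times = times, snapshots = snapshots,
              trajectory = data.frame(time = traj_t, deep = traj_d,
                                      superficial = traj_s),
              params = params, grid = grid, ablations = ablations,
              noise_amplitude = noise_amplitude, noise_seed = noise_seed)
  class(out) <- "sim_result_1d"
  out
}

#' Run the scalar deep-layer field on its own
#'
#' Integrates \eqn{\tau_d \partial_t u = -u + w_d \circ f_d(u)} (the
#' deep layer decoupled from the superficial layer), starting from a
#' step profile `u = w_d0` for `x <= x0`. Used to measure simulated
#' front speeds against the closed-form and implicit predictions.
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_1d()] object (orientation axis unused).
#' @param x0 initial interface position.
#' @param T final time.
#' @return List with `trajectory` (time, interface position), final `u`,
#'   `params`, `grid`.
#' @export
run_deep <- function(params, grid, x0, T) {
  check_dt(params, grid$dt)
  kfft <- kernel_fft_1d(grid$nx, grid$dx, params$w_d0, params$sigma_d,
                        params$kernel_d)
  u <- params$w_d0 * as.numeric(grid$x <= x0)
  n_steps <- round(T / grid$dt)
  traj_t <- numeric(n_steps + 1L)
  traj_x <- numeric(n_steps + 1L)
  traj_x[1L] <- threshold_interface(u, params$kappa_d, grid$x)
  r <- grid$dt / params$tau_d
  for (step in seq_len(n_steps)) {
    drive <- conv_circ_1d(rate_deep(u, params), kfft)
    u <- u + r * (-u + drive)
    if (!all(is.finite(u)))
      stop("non-finite activity (blow-up) at step ", step, call. = FALSE)
    traj_t[step + 1L] <- step * grid$dt
    traj_x[step + 1L] <- threshold_interface(u, params$kappa_d, grid$x)
  }
  list(trajectory = data.frame(time = traj_t, deep = traj_x),
       u = u, params = params, grid = grid)
}
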