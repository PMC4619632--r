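# Radially symmetric 2D kernels: same total mass and range as their 1D
# counterparts (a property the Gaussian family shares with its marginal:
# integrating the 2D kernel over one axis returns the 1D kernel).
radial_kernel_2d <- function(r, mass, sigma, family) {
  switch(family,
         gaussian    = mass / (2 * pi * sigma^2) * exp(-r^2 / (2 * sigma^2)),
         exponential = mass / (2 * pi * sigma^2) * exp(-r / sigma),
         stop("unknown kernel family '", family, "'", call. = FALSE))
}

#' Precompute the 2D convolution kernel bank
#'
#' Tabulates, on the periodic grid and in Fourier space, the deep-layer
#' radial kernel and one horizontal kernel per orientation channel:
#' \eqn{w_A(r, \theta_m) = w_s(|r|) A(\arg(r) - \theta_m)}, where `A` is
#' the anisotropy factor (identically 1 in isotropic mode, so all
#' channels coincide). Kernels are periodized by summing wrap images;
#' the removable singularity of `arg` at the origin is closed with the
#' angular mean of `A` (which is 1 for both modes).
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_2d()] object; its extent must be at least
#'   `10 * sigma_s` so the horizontal footprint fits the domain.
#' @return A `kernel_bank`: list with `fft_wd`, `fft_ws` (list of
#'   per-channel transforms, `NULL` when `w_s0 = 0`), and the
#'   orientation matrices `K_loc`, `K_hoz`.
#' @export
build_kernel_bank <- function(params, grid) {
  stopifnot(grid$dim == 2L)
  if (params$w_s0 > 0 && grid$extent < 2 * params$sigma_s)
    stop("grid extent (", grid$extent, ") must be at least 2 * sigma_s = ",
         2 * params$sigma_s, " for the periodized horizontal footprint",
         call. = FALSE)
  dxdy <- grid$dx * grid$dy
  xs <- circ_displacement(grid$nx, grid$dx)
  ys <- circ_displacement(grid$ny, grid$dy)
  images <- expand.grid(ix = -1:1, iy = -1:1)
  acc_radial <- function(mass, sigma, family) {
    w <- matrix(0, grid$nx, grid$ny)
    for (k in seq_len(nrow(images))) {
      gx <- xs + images$ix[k] * grid$nx * grid$dx
      gy <- ys + images$iy[k] * grid$ny * grid$dy
      r <- sqrt(outer(gx^2, gy^2, `+`))
      w <- w + radial_kernel_2d(r, mass, sigma, family)
    }
    w
  }
  fft_wd <- stats::fft(acc_radial(params$w_d0, params$sigma_d,
                                  params$kernel_d)) * dxdy
  fft_ws <- NULL
  if (params$w_s0 > 0) {
    fft_ws <- vector("list", grid$ntheta)
    if (params$anisotropy == "isotropic") {
      shared <- stats::fft(acc_radial(params$w_s0, params$sigma_s,
                                      params$kernel_s)) * dxdy
      for (m in seq_len(grid$ntheta)) fft_ws[[m]] <- shared
    } else {
      for (m in seq_len(grid$ntheta)) {
        th_m <- grid$theta[m]
        w <- matrix(0, grid$nx, grid$ny)
        for (k in seq_len(nrow(images))) {
          gx <- xs + images$ix[k] * grid$nx * grid$dx
          gy <- ys + images$iy[k] * grid$ny * grid$dy
          r <- sqrt(outer(gx^2, gy^2, `+`))
          ang <- atan2(matrix(gy, grid$nx, grid$ny, byrow = TRUE),
                       matrix(gx, grid$nx, grid$ny))
          fac <- anisotropy(ang - th_m, params$anisotropy)
          fac[r == 0] <- 1  # angular mean of A at the origin
          w <- w + radial_kernel_2d(r, params$w_s0, params$sigma_s,
                                    params$kernel_s) * fac
        }
        fft_ws[[m]] <- stats::fft(w) * dxdy
      }
    }
  }
  bank <- list(fft_wd = fft_wd, fft_ws = fft_ws,
               K_loc = ring_conv_matrix(grid, function(th)
                 ring_kernels(th, params)$loc),
               K_hoz = if (params$w_s0 > 0)
                 ring_conv_matrix(grid, function(th)
                   ring_kernels(th, params)$hoz))
  class(bank) <- "kernel_bank"
  bank
}

conv_circ_2d <- function(f, kfft) {
  Re(stats::fft(stats::fft(f) * kfft, inverse = TRUE)) / length(f)
}

#' 2D field state
#'
#' @param u deep activity, `nx` by `ny` matrix.
#' @param v superficial activity, `nx` by `ny` by `ntheta` array.
#' @param t simulation time.
#' @return An object of class `field_2d`.
#' @export
field_2d <- function(u, v, t = 0) {
  stopifnot(is.matrix(u), length(dim(v)) == 3L,
            all(dim(v)[1:2] == dim(u)))
  s <- list(u = u, v = v, t = t)
  class(s) <- "field_2d"
  s
}

#' Single forward-Euler step of the 2D laminar model
#'
#' As [step_1d()] but on the plane: the deep layer is convolved with the
#' radial kernel, the horizontal term uses one 2D Fourier convolution
#' per orientation channel (the anisotropic kernel depends on the
#' receiving orientation), and local/horizontal orientation convolutions
#' use periodic trapezoidal quadrature.
#'
#' @param state a [field_2d()].
#' @param params a [laminar_params()] object.
#' @param grid a [grid_2d()] object.
#' @param bank precomputed [build_kernel_bank()] (rebuilt when `NULL`).
#' @return The state at `t + dt`.
#' @export
step_2d <- function(state, params, grid, bank = NULL) {
  if (is.null(bank)) {
    check_dt(params, grid$dt)
    bank <- build_kernel_bank(params, grid)
  }
  ns <- grid$nx * grid$ny
  fd <- rate_deep(state$u, params)
  fs <- rate_sup(state$v, params)
  fsm <- fs; dim(fsm) <- c(ns, grid$ntheta)
  drive_d <- conv_circ_2d(fd, bank$fft_wd)
  if (params$gamma_s > 0)
    drive_d <- drive_d + params$gamma_s * grid$dtheta *
      matrix(rowSums(fsm), grid$nx, grid$ny)
  drive_s <- fsm %*% bank$K_loc
  if (params$w_s0 > 0) {
    gm <- fsm %*% bank$K_hoz
    for (m in seq_len(grid$ntheta)) {
      g2 <- matrix(gm[, m], grid$nx, grid$ny)
      drive_s[, m] <- drive_s[, m] + as.vector(
        conv_circ_2d(g2, bank$fft_ws[[m]]))
    }
  }
  if (params$gamma_d > 0)
    drive_s <- drive_s + params$gamma_d * as.vector(fd)
  u <- state$u + grid$dt / params$tau_d * (-state$u + drive_d)
  vm <- as.vector(state$v)
  dim(vm) <- c(ns, grid$ntheta)
  vm <- vm + grid$dt / params$tau_s * (-vm + drive_s)
  if (!all(is.finite(u)) || !all(is.finite(vm)))
    stop("non-finite activity at t = ", state$t + grid$dt,
         " (blow-up; reduce dt or check parameters)", call. = FALSE)
  dim(vm) <- dim(state$v)
  field_2d(u, vm, state$t + grid$dt)
}

#' Plane-wave and target-wave initial conditions in 2D
#'
#' `init_plane` sets the deep layer to a unit step active for
#' `x <= x0`; `init_target` to a unit disc of radius `r0` about the
#' origin. The superficial layer starts at rest (`v = 0`) so that bump
#' phases settle freely; seeded orientation noise can be added by the
#' runner.
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_2d()] object.
#' @param x0 plane-front position.
#' @return A [field_2d()] at `t = 0`.
#' @export
init_plane <- function(params, grid, x0) {
  stopifnot(grid$dim == 2L, x0 >= min(grid$x), x0 <= max(grid$x))
  u <- matrix(as.numeric(grid$x <= x0), grid$nx, grid$ny)
  field_2d(u, array(0, c(grid$nx, grid$ny, grid$ntheta)))
}

#' @rdname init_plane
#' @param r0 radius of the active disc.
#' @export
init_target <- function(params, grid, r0) {
  stopifnot(grid$dim == 2L, r0 > 0, r0 < grid$extent / 2)
  r <- sqrt(outer(grid$x^2, grid$y^2, `+`))
  u <- (r <= r0) + 0
  field_2d(u, array(0, c(grid$nx, grid$ny, grid$ntheta)))
}

#' Run the 2D laminar model
#'
#' Forward-Euler integration of the full 2D model with a precomputed
#' kernel bank; records the deep-layer interface along the positive
#' x-axis each step (front position for plane waves, radius for target
#' waves) and stores full snapshots at `snapshot_times`.
#'
#' @param params a [laminar_params()] object.
#' @param grid a [grid_2d()] object.
#' @param init initial [field_2d()].
#' @param T final time.
#' @param snapshot_times times at which to keep full fields (0 and `T`
#'   always included).
#' @param noise_amplitude,noise_seed perturbation of the initial
#'   superficial field, as in [add_orientation_noise()].
#' @return A `sim_result_2d`: list with `times`, `snapshots`,
#'   `trajectory` (time, deep interface along the +x axis), `params`,
#'   `grid`, noise settings.
#' @export
run_2d <- function(params, grid, init, T, snapshot_times = NULL,
                   noise_amplitude = 0, noise_seed = 1L) {
  check_dt(params, grid$dt)
  stopifnot(T >= 0)
  bank <- build_kernel_bank(params, grid)
  state <- init
  if (noise_amplitude > 0)
    state <- add_orientation_noise(state, noise_amplitude, noise_seed)
  n_steps <- round(T / grid$dt)
  snap_t <- sort(unique(c(0, snapshot_times, T)))
  snap_steps <- unique(pmin(pmax(round(snap_t / grid$dt), 0), n_steps))
  iy0 <- which.min(abs(grid$y))
  xpos <- grid$x >= 0
  traj_t <- numeric(n_steps + 1L)
  traj_x <- numeric(n_steps + 1L)
  axis_front <- function(st)
    threshold_interface(st$u[xpos, iy0], params$kappa_d, grid$x[xpos])
  traj_x[1L] <- axis_front(state)
  snapshots <- list(); times <- numeric(0)
  if (0L %in% snap_steps) {
    snapshots[[1L]] <- state; times <- 0
  }
  for (step in seq_len(n_steps)) {
    state <- step_2d(state, params, grid, bank)
    traj_t[step + 1L] <- state$t
    traj_x[step + 1L] <- axis_front(state)
    if (step %in% snap_steps) {
      snapshots[[length(snapshots) + 1L]] <- state
      times <- c(times, state$t)
    }
  }
  out <- list(times = times, snapshots = snapshots,
              trajectory = data.frame(time = traj_t, deep = traj_x),
              params = params, grid = grid,
              noise_amplitude = noise_amplitude, noise_seed = noise_seed)
  class(out) <- "sim_result_2d"
  out
}

#' Phase vector field of a 2D superficial state
#'
#' Per-site tuned orientation (argmax over the orientation channels,
#' refined by quadratic interpolation, modulo pi) together with its unit
#' vector \eqn{(\cos\phi, \sin\phi)}. Sites whose peak activity is below
#' `kappa` (default `kappa_s`) or whose slice is flat are masked `NA`.
#'
#' @param state a [field_2d()].
#' @param grid a [grid_2d()] object.
#' @param params a [laminar_params()] object (threshold source).
#' @param kappa mask threshold; `NULL` disables threshold masking.
#' @return List with matrices `phi`, `ux`, `uy` (`nx` by `ny`).
#' @export
phase_vector_field <- function(state, grid, params,
                               kappa = params$kappa_s) {
  ns <- grid$nx * grid$ny
  M <- grid$ntheta
  vm <- state$v
  dim(vm) <- c(ns, M)
  j <- max.col(vm, ties.method = "first")
  idx <- cbind(seq_len(ns), j)
  f0 <- vm[idx]
  jl <- ifelse(j == 1L, M, j - 1L)
  jr <- ifelse(j == M, 1L, j + 1L)
  fl <- vm[cbind(seq_len(ns), jl)]
  fr <- vm[cbind(seq_len(ns), jr)]
  denom <- fl - 2 * f0 + fr
  delta <- ifelse(denom < 0, 0.5 * (fl - fr) / denom, 0)
  phi <- wrap_orientation(grid$theta[j] + delta * grid$dtheta)
  rng <- apply(vm, 1L, max) - apply(vm, 1L, min)
  phi[rng <= 1e-12] <- NA_real_
  if (!is.null(kappa)) phi[f0 < kappa] <- NA_real_
  dim(phi) <- c(grid$nx, grid$ny)
  list(phi = phi, ux = cos(phi), uy = sin(phi))
}

# Rotate a periodic 2D field counterclockwise by 90 degrees:
# B(x, y) = A(y, -x), with -x mapped by periodic index arithmetic.
rotate_field_90 <- function(A) {
  n <- nrow(A)
  stopifnot(n == ncol(A))
  ineg <- c(1L, seq.int(n, 2L))  # index of -x on the periodic axis
  # B[i, j] = A(y_j, -x_i) = A[j, ineg[i]]
  t(A)[ineg, , drop = FALSE]
}

#' Shift-twist symmetry check between two 2D runs
#'
#' The anisotropically coupled model is invariant under joint rotation
#' of retinotopic space and orientation labels. Given a reference run
#' and a run whose initial condition was the reference rotated by
#' `pi/2`, applies the shift-twist transform
#' \eqn{v(r, \theta) \mapsto v(R_{-\pi/2} r, \theta - \pi/2)} to the
#' reference final state and reports the maximum absolute deviation from
#' the rotated run's final state.
#'
#' @param run_a reference `sim_result_2d`.
#' @param run_b comparison run started from the rotated initial state.
#' @return List with `max_dev_u`, `max_dev_v` and the transformed
#'   reference fields.
#' @export
shift_twist_check <- function(run_a, run_b) {
  ga <- run_a$grid; gb <- run_b$grid
  if (!identical(ga[c("nx", "ny", "ntheta", "dx", "dy", "dt")],
                 gb[c("nx", "ny", "ntheta", "dx", "dy", "dt")]))
    stop("runs use incompatible grids", call. = FALSE)
  sa <- run_a$snapshots[[length(run_a$snapshots)]]
  sb <- run_b$snapshots[[length(run_b$snapshots)]]
  u_t <- rotate_field_90(sa$u)
  M <- ga$ntheta
  shift <- M %/% 2L  # pi/2 in channel units (M even)
  v_t <- array(NA_real_, dim(sa$v))
  for (m in seq_len(M)) {
    src <- ((m - 1L - shift) %% M) + 1L  # theta - pi/2 channel
    v_t[, , m] <- rotate_field_90(sa$v[, , src])
  }
  list(max_dev_u = max(abs(u_t - sb$u)),
       max_dev_v = max(abs(v_t - sb$v)),
       u_twisted = u_t, v_twisted = v_t)
}

#' Apply the shift-twist transform to a 2D state
#'
#' Rotates a [field_2d()] by `pi/2` counterclockwise in space while
#' shifting orientation labels by `pi/2`, producing the initial
#' condition for the comparison run of [shift_twist_check()].
#'
#' @param state a [field_2d()] on a square grid with even `ntheta`.
#' @return The transformed state.
#' @export
shift_twist_state <- function(state) {
  M <- dim(state$v)[3L]
  u_t <- rotate_field_90(state$u)
  v_t <- array(NA_real_, dim(state$v))
  shift <- M %/% 2L
  for (m in seq_len(M)) {
    src <- ((m - 1L - shift) %% M) + 1L
    v_t[, , m] <- rotate_field_90(state$v[, , src])
  }
  field_2d(u_t, v_t, state$t)
}
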