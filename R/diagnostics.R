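#' Sub-grid threshold-interface position
#'
#' Locates the rightmost down-crossing of `kappa` along the axis: the
#' position where the field passes from at-or-above threshold to below
#' threshold, refined by linear interpolation between the bracketing
#' nodes. In the Heaviside limit the entire dynamics is carried by this
#' interface, so its trajectory is the primary wave observable.
#'
#' @param field activity values along the axis.
#' @param kappa threshold.
#' @param x axis coordinates (same length as `field`).
#' @return Interpolated crossing position, or `NA_real_` when the field
#'   never crosses the threshold.
#' @examples
#' threshold_interface(1 - seq(0, 1, 0.01), 0.5, seq(0, 1, 0.01))
#' @export
threshold_interface <- function(field, kappa, x) {
  n <- length(field)
  stopifnot(length(x) == n, n >= 2L)
  above <- field >= kappa
  idx <- which(above[-n] & !above[-1L])
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  x[i] + (x[i + 1L] - x[i]) * (field[i] - kappa) / (field[i] - field[i + 1L])
}

#' Least-squares wave-speed estimate from an interface trajectory
#'
#' Fits position against time over a window (discarding the transient
#' before it) and returns the slope with its standard error.
#'
#' @param time,position trajectory samples (`NA` positions are dropped).
#' @param window optional `c(t_min, t_max)`; defaults to the last 60% of
#'   the trajectory.
#' @return List with `speed`, `stderr`, `n` (points used).
#' @examples
#' t <- seq(0, 1, 0.01)
#' estimate_speed(t, 0.3 + 1.7 * t)$speed  # 1.7
#' @export
estimate_speed <- function(time, position, window = NULL) {
  keep <- is.finite(time) & is.finite(position)
  time <- time[keep]; position <- position[keep]
  if (is.null(window)) {
    t0 <- min(time) + 0.4 * diff(range(time))
    window <- c(t0, max(time))
  }
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 5L)
    stop("need at least 5 trajectory points inside the fit window",
         call. = FALSE)
  fit <- stats::lm(position[sel] ~ time[sel])
  cf <- suppressWarnings(summary(fit))$coefficients
  list(speed = unname(cf[2L, 1L]), stderr = unname(cf[2L, 2L]),
       n = sum(sel))
}

#' Tuned orientation (bump phase) of a ring activity profile
#'
#' The phase is the argmax over orientation of the activity slice,
#' refined by fitting a quadratic through the maximal node and its two
#' periodic neighbours, reported modulo pi in `[-pi/2, pi/2)`. A flat
#' slice has no tuned orientation and returns `NA`; when a second local
#' maximum comes within 1% of the global one the result carries the
#' attribute `multimodal = TRUE`.
#'
#' @param v_slice activity over the orientation ring.
#' @param theta orientation grid (uniform, periodic, same length).
#' @param tol flatness tolerance relative to `max(abs(v_slice))`.
#' @return Phase in radians, or `NA_real_` for an untuned slice.
#' @examples
#' th <- seq(-pi / 2, pi / 2 - pi / 64, length.out = 64)
#' bump_phase(cos(2 * (th - 0.3)), th)
#' @export
bump_phase <- function(v_slice, theta, tol = 1e-12) {
  m <- length(v_slice)
  stopifnot(length(theta) == m, m >= 4L)
  rng <- max(v_slice) - min(v_slice)
  if (rng <= tol * max(1, max(abs(v_slice)))) return(NA_real_)
  j <- which.max(v_slice)
  jl <- if (j == 1L) m else j - 1L
  jr <- if (j == m) 1L else j + 1L
  f0 <- v_slice[j]; fl <- v_slice[jl]; fr <- v_slice[jr]
  denom <- fl - 2 * f0 + fr
  delta <- if (denom < 0) 0.5 * (fl - fr) / denom else 0
  dtheta <- theta[2L] - theta[1L]
  phi <- wrap_orientation(theta[j] + delta * dtheta)
  # multimodality: best local max away from the global one
  is_max <- v_slice >= v_slice[c(m, seq_len(m - 1L))] &
    v_slice >= v_slice[c(2:m, 1L)]
  others <- which(is_max)
  others <- others[abs(others - j) > 1L & abs(others - j) < m - 1L]
  if (length(others) && max(v_slice[others]) >= 0.99 * f0)
    attr(phi, "multimodal") <- TRUE
  phi
}

#' Per-location bump phases of a superficial field
#'
#' Applies [bump_phase()] to every row of an `nx` by `ntheta` activity
#' matrix, optionally masking locations whose peak activity is below
#' threshold (untuned locations are `NA` either way).
#'
#' @param v superficial activity matrix.
#' @param theta orientation grid.
#' @param kappa optional threshold; rows with `max v < kappa` give `NA`.
#' @return Numeric vector of phases (radians mod pi).
#' @export
bump_phases <- function(v, theta, kappa = NULL) {
  phi <- apply(v, 1L, function(row) as.numeric(bump_phase(row, theta)))
  if (!is.null(kappa)) phi[apply(v, 1L, max) < kappa] <- NA_real_
  phi
}

#' Circular statistics for orientations (period pi)
#'
#' Orientations live on a circle of period pi, so statistics are taken
#' on the doubled angles: the mean resultant
#' \eqn{R = |\langle e^{2 i \phi} \rangle|} gives circular variance
#' `1 - R` (0 for perfectly aligned phases, near 1 for phases spread
#' uniformly) and circular mean \eqn{\arg\langle e^{2 i \phi}\rangle/2}.
#'
#' @param phi orientations in radians (`NA` dropped).
#' @return `circ_variance_pi`: variance in `[0, 1]`;
#'   `circ_mean_pi`: mean orientation in `[-pi/2, pi/2)`.
#' @export
circ_variance_pi <- function(phi) {
  phi <- phi[is.finite(phi)]
  if (!length(phi)) return(NA_real_)
  1 - Mod(mean(exp(2i * phi)))
}

#' @rdname circ_variance_pi
#' @export
circ_mean_pi <- function(phi) {
  phi <- phi[is.finite(phi)]
  if (!length(phi)) return(NA_real_)
  wrap_orientation(Arg(mean(exp(2i * phi))) / 2)
}

# Mean absolute circular distance (period pi) between two orientation
# vectors, used for comparing phase fields against a reference pattern.
circ_error_pi <- function(phi, ref) {
  d <- wrap_orientation(phi - ref)
  mean(abs(d), na.rm = TRUE)
}

#' Wave profile in the comoving frame
#'
#' Registers a snapshot to the deep-layer interface: returns the
#' superficial field as a function of `z = x - x_front` (with `z = 0` at
#' the deep threshold crossing), ready for region classification and
#' half-width profiling.
#'
#' @param result a `sim_result_1d` from [run_1d()].
#' @param time snapshot time (nearest stored snapshot is used).
#' @return List with `z` (sorted), `V` (superficial field over z and
#'   theta), `u` (deep profile), `z_front` registration offset, and the
#'   snapshot `time`.
#' @export
comoving_profile <- function(result, time = max(result$times)) {
  i <- which.min(abs(result$times - time))
  st <- result$snapshots[[i]]
  x_front <- threshold_interface(st$u, result$params$kappa_d,
                                 result$grid$x)
  if (!is.finite(x_front))
    stop("deep layer has no threshold interface at t = ", st$t,
         call. = FALSE)
  list(z = result$grid$x - x_front, V = st$v, u = st$u,
       z_front = x_front, time = st$t)
}

# Effective range of the horizontal footprint: smallest L containing all
# but `epsilon` of the kernel mass (reconciles the compact-support
# construction with Gaussian or exponential kernels).
effective_range <- function(params, epsilon = 1e-4) {
  if (params$w_s0 == 0) return(0)
  switch(params$kernel_s,
         gaussian    = params$sigma_s * stats::qnorm(1 - epsilon / 2),
         exponential = params$sigma_s * log(1 / epsilon),
         stop("unknown kernel family", call. = FALSE))
}

#' Classify the four regions of the comoving wave profile
#'
#' Labels every comoving position by the role it plays in the wave:
#' `bump` (super-threshold orientation bump), `integrating`
#' (sub-threshold but already receiving deep-layer drive, `z0 < z <= 0`),
#' `queuing` (ahead of the deep front but within horizontal reach of the
#' active region, forming sub-threshold pre-bumps), and `quiescent`
#' (beyond horizontal reach, activity below a numeric floor). `z0` is
#' the superficial threshold onset and `L` the effective horizontal
#' range.
#'
#' @param profile output of [comoving_profile()].
#' @param params a [laminar_params()] object.
#' @param grid the simulation grid.
#' @param floor_level numeric floor distinguishing quiescent from queued
#'   activity.
#' @return List with `labels` (factor over z), `z0`, `L`,
#'   `queuing_extent` (`L - |z0|`), and `z`.
#' @export
classify_regions <- function(profile, params, grid, floor_level = 1e-6) {
  z <- profile$z
  maxv <- apply(profile$V, 1L, max)
  z0 <- threshold_interface(maxv[order(z)], params$kappa_s, sort(z))
  L <- effective_range(params)
  q_edge <- if (is.finite(z0)) L - abs(z0) else L
  labels <- character(length(z))
  sup <- maxv >= params$kappa_s
  labels[sup] <- "bump"
  labels[!sup & z <= 0] <- "integrating"
  ahead <- !sup & z > 0
  labels[ahead & (z <= q_edge & maxv > floor_level)] <- "queuing"
  labels[ahead & !(z <= q_edge & maxv > floor_level)] <- "quiescent"
  list(labels = factor(labels,
                       levels = c("quiescent", "queuing", "integrating",
                                  "bump")),
       z0 = z0, L = L, queuing_extent = q_edge, z = z)
}

#' Bump half-width along the comoving profile
#'
#' For each comoving position, the half-width `Delta(z)` of the
#' super-threshold orientation arc about the bump centre (0 where the
#' profile is sub-threshold, by convention). Behind the front
#' `Delta(z)` relaxes to the analytic half-width of the combined-kernel
#' bump; at the superficial onset `Delta(z0) = 0`.
#'
#' @param profile output of [comoving_profile()].
#' @param params a [laminar_params()] object.
#' @param grid the simulation grid.
#' @return Numeric vector `Delta(z)` aligned with `profile$z`.
#' @export
halfwidth_profile <- function(profile, params, grid) {
  kappa <- params$kappa_s
  theta <- grid$theta
  m <- length(theta)
  dth <- grid$dtheta
  apply(profile$V, 1L, function(row) {
    above <- row >= kappa
    if (!any(above)) return(0)
    if (all(above)) return(pi / 2)
    j <- which.max(row)
    # walk left and right on the ring to the crossing edges
    step_idx <- function(i, dir) ((i - 1L + dir) %% m) + 1L
    left <- 0L; i <- j
    while (above[step_idx(i, -1L)] && left < m) {
      i <- step_idx(i, -1L); left <- left + 1L
    }
    il_in <- i; il_out <- step_idx(i, -1L)
    right <- 0L; i <- j
    while (above[step_idx(i, 1L)] && right < m) {
      i <- step_idx(i, 1L); right <- right + 1L
    }
    ir_in <- i; ir_out <- step_idx(i, 1L)
    frac_l <- (row[il_in] - kappa) / (row[il_in] - row[il_out])
    frac_r <- (row[ir_in] - kappa) / (row[ir_in] - row[ir_out])
    ((left + right) + frac_l + frac_r) * dth / 2
  })
}
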