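#' Closed-form front speed for the exponential deep-layer kernel
#'
#' In the Heaviside limit the scalar deep-layer field supports a unique
#' traveling front whose speed, for the exponential kernel of mass
#' \eqn{\bar w_d} and range \eqn{\sigma_d}, is
#' \deqn{c = \frac{\sigma_d}{2\tau_d}\left(\bar w_d/\kappa_d - 2\right),
#'   \qquad \kappa_d < \bar w_d / 2,}
#' \deqn{c = \frac{\sigma_d}{2\tau_d}
#'   \frac{\bar w_d/\kappa_d - 2}{\bar w_d/\kappa_d - 1} < 0,
#'   \qquad \bar w_d/2 < \kappa_d < \bar w_d.}
#' No front exists when \eqn{\kappa_d \ge \bar w_d}; at
#' \eqn{\kappa_d = \bar w_d / 2} the front is stationary (`c = 0`).
#'
#' @param params a [laminar_params()] object; `kernel_d` must be
#'   `"exponential"`.
#' @return A `front_solution`: list with `speed`, `exists`,
#'   `direction` (+1 right, -1 left, 0 stationary), `stationary` flag and
#'   a profile sampler `U(z)` with `U(0) = kappa_d`.
#' @examples
#' front_speed_exponential(laminar_params(w_d0 = 2, kappa_d = 0.5))$speed
#' @export
front_speed_exponential <- function(params) {
  if (params$kernel_d != "exponential")
    stop("closed-form speed requires kernel_d = 'exponential'",
         call. = FALSE)
  m <- params$w_d0
  k <- params$kappa_d
  s <- params$sigma_d / (2 * params$tau_d)
  if (k >= m) {
    return(new_front_solution(NA_real_, exists = FALSE, params = params))
  }
  if (k == m / 2) {
    return(new_front_solution(0, exists = TRUE, stationary = TRUE,
                              params = params))
  }
  c_est <- if (k < m / 2) s * (m / k - 2) else s * (m / k - 2) / (m / k - 1)
  new_front_solution(c_est, exists = TRUE, params = params)
}

#' Front speed from the implicit interface equation
#'
#' Solves the implicit relation
#' \deqn{\kappa_d = \frac{1}{|c|} \int_0^\infty e^{-y/|c|}
#'   W_d(\mathrm{sign}(c)\, y)\, dy, \qquad
#'   W_d(y) = \int_y^\infty w_d(x)\, dx,}
#' for the front speed `c` of the scalar deep-layer field, valid for any
#' integrable monotone kernel. The right-hand side decreases
#' monotonically from the total mass to 0 as `c` runs from strongly
#' leftward to strongly rightward, so the root is bracketed and found by
#' bisection-safeguarded root finding; the speed is rescaled by `tau_d`.
#'
#' @param params a [laminar_params()] object (kernel family `kernel_d`).
#' @param c_max upper bound of the nondimensional speed bracket.
#' @param tol relative tolerance of the root.
#' @return A `front_solution` (see [front_speed_exponential()]).
#' @examples
#' p <- laminar_params(w_d0 = 2, kappa_d = 0.5, kernel_d = "gaussian",
#'                     sigma_d = 0.1, tau_d = 0.1)
#' front_speed_implicit(p)$speed
#' @export
front_speed_implicit <- function(params, c_max = 1e4, tol = 1e-12) {
  m <- params$w_d0
  k <- params$kappa_d
  if (k >= m || k <= 0)
    return(new_front_solution(NA_real_, exists = FALSE, params = params))
  if (k == m / 2)
    return(new_front_solution(0, exists = TRUE, stationary = TRUE,
                              params = params))
  Wd <- function(y) spatial_kernel_mass_above(y, m, params$sigma_d,
                                              params$kernel_d)
  # kappa implied by a candidate nondimensional speed (tau_d = 1 units);
  # substitution y = |c| s gives int_0^inf e^-s Wd(sign(c) |c| s) ds.
  implied_kappa <- function(cc) {
    sgn <- sign(cc)
    f <- function(s) exp(-s) * Wd(sgn * abs(cc) * s)
    stats::integrate(f, 0, Inf, rel.tol = 1e-12,
                     abs.tol = 1e-14)$value
  }
  rightward <- k < m / 2
  # g is decreasing in c with g(0) = m/2; bracket on the admissible side.
  g <- function(cc) implied_kappa(cc) - k
  lo <- 1e-9
  hi <- lo * 2
  if (rightward) {
    while (g(hi) > 0 && hi < c_max) hi <- hi * 2
    if (g(hi) > 0)
      return(new_front_solution(NA_real_, exists = FALSE, params = params))
    root <- stats::uniroot(g, c(lo, hi), tol = tol * max(1, hi))$root
  } else {
    while (g(-hi) < 0 && hi < c_max) hi <- hi * 2
    if (g(-hi) < 0)
      return(new_front_solution(NA_real_, exists = FALSE, params = params))
    root <- stats::uniroot(g, c(-hi, -lo), tol = tol * max(1, hi))$root
  }
  new_front_solution(root / params$tau_d, exists = TRUE, params = params)
}

# Construct a front_solution object, including the profile sampler
# U(z) = (1/|c|) int_0^inf e^(-s) W_d(z + c s) ds (U(0) = kappa_d by
# construction of c; plateau w_d0 behind, 0 ahead for c > 0).
new_front_solution <- function(speed, exists, stationary = FALSE,
                               params = NULL) {
  profile <- NULL
  if (exists && !stationary && !is.null(params)) {
    c_nd <- speed * params$tau_d  # nondimensional speed used in U(z)
    Wd <- function(y) spatial_kernel_mass_above(y, params$w_d0,
                                                params$sigma_d,
                                                params$kernel_d)
    profile <- function(z) {
      vapply(z, function(zz) {
        stats::integrate(function(s) exp(-s) * Wd(zz + c_nd * s),
                         0, Inf, rel.tol = 1e-10)$value
      }, numeric(1))
    }
  }
  out <- list(speed = speed, exists = exists, stationary = stationary,
              direction = if (!exists) NA_integer_ else sign(speed),
              profile = profile)
  class(out) <- "front_solution"
  out
}

#' @export
print.front_solution <- function(x, ...) {
  if (!x$exists)
    cat("<front_solution> no traveling front (threshold at or above kernel mass)\n")
  else if (x$stationary)
    cat("<front_solution> stationary interface, c = 0\n")
  else
    cat(sprintf("<front_solution> c = %.8g (%s-moving)\n", x$speed,
                if (x$direction > 0) "right" else "left"))
  invisible(x)
}

#' Stationary orientation bumps of the ring network
#'
#' Finds all bump solutions of the Amari ring equation
#' \eqn{V(\theta) = w * H_s(V) + I} for a constant input `input_level`
#' \eqn{= \gamma \chi}: half-widths `Delta` in `(0, pi/2)` solving
#' \eqn{W(2\Delta) = \kappa_s - I}, where `W` is the odd primitive of the
#' ring kernel. Each root is polished with [stats::uniroot()] from a
#' dense scan and tagged stable when \eqn{W'(2\Delta) = w(2\Delta) < 0}.
#' The bump profile is
#' \eqn{V(\theta) = W(\theta + \Delta) - W(\theta - \Delta) + I},
#' super-threshold exactly on `(-Delta, Delta)` about the centre.
#'
#' @param params a [laminar_params()] object.
#' @param input_level constant orientation-independent input (e.g.
#'   `gamma_d` behind the deep front, 0 ahead of it).
#' @param kernel `"combined"` (local plus `w_s0` times horizontal; the
#'   kernel seen behind the full laminar wave) or `"local"`.
#' @param center bump centre `theta0`.
#' @param scan_res resolution of the dense root scan over `Delta`.
#' @return A list of `bump_solution` objects (empty if only the down
#'   state exists), each with fields `Delta`, `center`, `stable`,
#'   `input_level`, `residual` and profile function `V(theta)`.
#' @examples
#' p <- laminar_params(w0 = -1, w1 = 2, kappa_s = 0.5, gamma_d = 1)
#' bumps <- bump_solve(p, input_level = 1)
#' vapply(bumps, `[[`, numeric(1), "Delta")
#' @export
bump_solve <- function(params, input_level,
                       kernel = c("combined", "local"),
                       center = 0, scan_res = 1e-4) {
  kernel <- match.arg(kernel)
  Wfun <- if (kernel == "combined") {
    function(th) ring_primitive_combined(th, params)
  } else {
    function(th) ring_primitive_loc(th, params)
  }
  wfun <- if (kernel == "combined") {
    function(th) ring_kernel_combined(th, params)
  } else {
    function(th) ring_kernels(th, params)$loc
  }
  level <- params$kappa_s - input_level
  g <- function(Delta) Wfun(2 * Delta) - level
  dg <- seq(scan_res, pi / 2 - scan_res, by = scan_res)
  gv <- g(dg)
  roots <- numeric(0)
  flip <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in flip) {
    r <- stats::uniroot(g, c(dg[i], dg[i + 1]), tol = 1e-14)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, dg[gv == 0])
  lapply(sort(unique(roots)), function(Delta) {
    sol <- list(
      Delta = Delta,
      center = center,
      stable = wfun(2 * Delta) < 0,
      input_level = input_level,
      kernel = kernel,
      residual = g(Delta),
      V = function(theta) {
        th <- wrap_orientation(theta - center)
        Wfun(th + Delta) - Wfun(th - Delta) + input_level
      })
    class(sol) <- "bump_solution"
    sol
  })
}

#' @export
print.bump_solution <- function(x, ...) {
  cat(sprintf("<bump_solution> Delta = %.6f rad, center = %.4f, %s (%s kernel, input %g)\n",
              x$Delta, x$center, if (x$stable) "stable" else "unstable",
              x$kernel, x$input_level))
  invisible(x)
}

#' Operating-condition report for the superficial layer
#'
#' The coherent-wave construction assumes three conditions on the ring
#' kernel primitive \eqn{W} (evaluated as \eqn{W(2\Delta)} over
#' \eqn{\Delta \in (0, \pi/2]}):
#' (i) `W_max < kappa_s` — the down state is the only stable state
#' without deep-layer input; (ii) `W_min < kappa_s - gamma_d < W_max` —
#' a bump exists under deep-layer drive; (iii) `kappa_s - gamma_d < 0` —
#' the down state does not coexist with the bump under drive.
#'
#' @inheritParams bump_solve
#' @param n_grid size of the dense grid used for `W_max`/`W_min`.
#' @return List with booleans `cond_down_state_unique`,
#'   `cond_bump_exists`, `cond_no_coexistence`, the extrema `W_max`,
#'   `W_min`, and `all_satisfied`.
#' @examples
#' operating_conditions(laminar_params())
#' @export
operating_conditions <- function(params, kernel = c("combined", "local"),
                                 n_grid = 20000L) {
  kernel <- match.arg(kernel)
  Wfun <- if (kernel == "combined") {
    function(th) ring_primitive_combined(th, params)
  } else {
    function(th) ring_primitive_loc(th, params)
  }
  s <- seq(pi / n_grid, pi, length.out = n_grid)  # s = 2 Delta
  Wv <- Wfun(s)
  W_max <- max(Wv)
  W_min <- min(Wv)
  level <- params$kappa_s - params$gamma_d
  out <- list(
    W_max = W_max,
    W_min = W_min,
    cond_down_state_unique = W_max < params$kappa_s,
    cond_bump_exists = W_min < level && level < W_max,
    cond_no_coexistence = level < 0)
  out$all_satisfied <- out$cond_down_state_unique && out$cond_bump_exists &&
    out$cond_no_coexistence
  out
}

#' Sub-threshold bound for the queuing region
#'
#' Ahead of the deep front, activity driven purely through the
#' horizontal connections is bounded by
#' \eqn{|V(z,\theta)| \le w_{s,0}\, w_{hoz,0}}, where \eqn{w_{hoz,0}} is
#' the peak of the orientation factor. When this bound is below
#' `kappa_s`, queued bumps provably stay sub-threshold, so weak
#' horizontal connections cannot ignite the superficial layer on their
#' own.
#'
#' @param params a [laminar_params()] object.
#' @return List with `bound` (`w_s0 * w_hoz(0)`) and logical
#'   `guaranteed_subthreshold` (`bound < kappa_s`).
#' @examples
#' queuing_bound(laminar_params(w_s0 = 0.1, kappa_s = 0.5))
#' @export
queuing_bound <- function(params) {
  w_hoz0 <- ring_kernels(0, params)$hoz   # peak value 2/pi
  bound <- params$w_s0 * w_hoz0
  list(bound = bound, w_hoz_peak = w_hoz0,
       guaranteed_subthreshold = bound < params$kappa_s)
}

#' Deep-layer up-state level with feedback
#'
#' With feedback strength `gamma_s` from a superficial bump of
#' half-width `Delta`, the asymptotic deep up state behind the front is
#' \eqn{w_{d,0} + 2\Delta\gamma_s}: the feedback raises the plateau but
#' (in the Heaviside limit) leaves the front speed unchanged, because the
#' superficial threshold crossing lags the deep interface.
#'
#' @param params a [laminar_params()] object.
#' @param Delta bump half-width (radians), typically from [bump_solve()]
#'   of the combined kernel at `input_level = gamma_d`.
#' @return The up-state level.
#' @examples
#' feedback_up_state(laminar_params(w_d0 = 2, gamma_s = 1), Delta = pi / 4)
#' @export
feedback_up_state <- function(params, Delta) {
  stopifnot(is.numeric(Delta), length(Delta) == 1L, Delta >= 0,
            Delta <= pi / 2)
  params$w_d0 + 2 * Delta * params$gamma_s
}

#' One-row summary of the closed-form theory for a parameter set
#'
#' Convenience export used by the command-line `theory` mode: front
#' speed (closed form where available, implicit otherwise), bump
#' half-widths and stability under deep drive, operating conditions and
#' the queuing bound, as a single data frame row.
#'
#' @param params a [laminar_params()] object.
#' @return A one-row `data.frame`.
#' @export
theory_report <- function(params) {
  fr <- if (params$kernel_d == "exponential") {
    front_speed_exponential(params)
  } else {
    front_speed_implicit(params)
  }
  bumps <- bump_solve(params, input_level = params$gamma_d)
  stable <- Filter(function(b) b$stable, bumps)
  oc <- operating_conditions(params)
  qb <- queuing_bound(params)
  Delta0 <- if (length(stable)) stable[[length(stable)]]$Delta else NA_real_
  data.frame(
    speed = fr$speed,
    front_exists = fr$exists,
    n_bumps = length(bumps),
    Delta0 = Delta0,
    up_state = if (is.na(Delta0)) NA_real_ else
      feedback_up_state(params, Delta0),
    W_max = oc$W_max,
    W_min = oc$W_min,
    cond_i = oc$cond_down_state_unique,
    cond_ii = oc$cond_bump_exists,
    cond_iii = oc$cond_no_coexistence,
    queuing_bound = qb$bound,
    queuing_subthreshold = qb$guaranteed_subthreshold)
}

#' Dimensional scale of the deep-layer front speed
#'
#' The nondimensional analysis measures space in units of the kernel
#' range and time in units of the deep relaxation constant, so restoring
#' units multiplies speeds by `sigma_d / tau_d`. For physiological values
#' (`sigma_d` about 1 mm of cortex, `tau_d` about 10 ms) this scale is
#' 10 cm/s, the order of magnitude of cortical wave propagation.
#'
#' @param sigma_mm kernel range in millimetres.
#' @param tau_ms relaxation time constant in milliseconds.
#' @return Speed scale `sigma_d / tau_d` in cm/s.
#' @examples
#' speed_scale_cm_per_s(sigma_mm = 1, tau_ms = 10)  # 10
#' @export
speed_scale_cm_per_s <- function(sigma_mm = 1, tau_ms = 10) {
  stopifnot(sigma_mm > 0, tau_ms > 0)
  (sigma_mm / 10) / (tau_ms / 1000)
}
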