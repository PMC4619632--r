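test_that("closed-form exponential front speed covers all regimes", {
  # rightward: c = sigma/2 (w/k - 2)
  p <- laminar_params(w_d0 = 2, kappa_d = 0.5, sigma_d = 1, tau_d = 1)
  fr <- front_speed_exponential(p)
  expect_true(fr$exists)
  expect_equal(fr$speed, 1)
  expect_equal(fr$direction, 1)
  # boundary kappa = mass/2: stationary
  p0 <- laminar_params(w_d0 = 2, kappa_d = 1)
  f0 <- front_speed_exponential(p0)
  expect_true(f0$stationary)
  expect_equal(f0$speed, 0)
  # leftward branch
  pl <- laminar_params(w_d0 = 2, kappa_d = 1.5)
  fl <- front_speed_exponential(pl)
  expect_equal(fl$speed, -1)
  expect_equal(fl$direction, -1)
  # no front above the kernel mass
  pn <- laminar_params(w_d0 = 2, kappa_d = 2.5)
  expect_false(front_speed_exponential(pn)$exists)
  # dimensional rescaling by sigma_d / tau_d
  pr <- laminar_params(w_d0 = 2, kappa_d = 0.5, sigma_d = 0.2, tau_d = 0.1)
  expect_equal(front_speed_exponential(pr)$speed, 2)
  # profile crosses threshold at the origin with the right limits
  expect_equal(fr$profile(0), p$kappa_d, tolerance = 1e-8)
  expect_equal(fr$profile(-30), p$w_d0, tolerance = 1e-6)
  expect_lt(fr$profile(30), 1e-6)
})

test_that("implicit-equation solver matches the closed form on exponential kernels", {
  kappas <- c(seq(0.1, 0.9, by = 0.08), seq(1.1, 1.9, by = 0.08))
  for (k in kappas) {
    p <- laminar_params(w_d0 = 2, kappa_d = k, sigma_d = 0.7, tau_d = 0.5)
    c_closed <- front_speed_exponential(p)$speed
    c_impl <- front_speed_implicit(p)$speed
    expect_circa(c_impl, c_closed, 1e-8)
  }
  # nonexistence flags agree
  p <- laminar_params(w_d0 = 1, kappa_d = 1.2)
  expect_false(front_speed_implicit(p)$exists)
})

test_that("implicit speed for the Gaussian kernel matches a Heaviside simulation", {
  p <- laminar_params(w_d0 = 2, kappa_d = 0.5, sigma_d = 0.1, tau_d = 0.1,
                      kernel_d = "gaussian", rate_mode = "heaviside")
  c_theory <- front_speed_implicit(p)$speed
  g <- grid_1d(extent = 6, nx = 600, ntheta = 8, dt = 0.001)
  sim <- run_deep(p, g, x0 = 1, T = 3)
  c_sim <- estimate_speed(sim$trajectory$time, sim$trajectory$deep,
                          window = c(1, 3))$speed
  expect_lt(abs(c_sim / c_theory - 1), 0.02)
})

test_that("speed sign flips at kappa = mass/2 and vanishes beyond the mass", {
  for (k in c(0.8, 0.99)) {
    expect_gt(front_speed_exponential(
      laminar_params(w_d0 = 2, kappa_d = k))$speed, 0)
  }
  for (k in c(1.01, 1.6)) {
    expect_lt(front_speed_exponential(
      laminar_params(w_d0 = 2, kappa_d = k))$speed, 0)
  }
  expect_false(front_speed_exponential(
    laminar_params(w_d0 = 2, kappa_d = 2))$exists)
})

test_that("bump solutions satisfy the defining equation and match a dense scan", {
  p <- strong_ring_params()
  input <- 0.2                 # line level 0.3 cuts W(2 Delta) twice
  level <- p$kappa_s - input
  bumps <- bump_solve(p, input_level = input, kernel = "local")
  expect_length(bumps, 2L)
  W <- function(th) laminarwave:::ring_primitive_loc(th, p)
  for (b in bumps) {
    expect_lt(abs(W(2 * b$Delta) - level), 1e-10)
    # stability flag agrees with a finite-difference slope of W(2 Delta)
    h <- 1e-6
    slope <- (W(2 * (b$Delta + h)) - W(2 * (b$Delta - h))) / (2 * h)
    expect_identical(b$stable, slope < 0)
    # profile is symmetric about the centre and super-threshold on
    # exactly (-Delta, Delta)
    th <- seq(0.01, pi / 2 - 0.01, length.out = 40)
    expect_equal(b$V(th), b$V(-th))
    expect_circa(b$V(b$Delta), p$kappa_s, 1e-10)
    inside <- seq(-b$Delta + 1e-3, b$Delta - 1e-3, length.out = 20)
    expect_true(all(b$V(inside) > p$kappa_s))
  }
  # independent dense-grid scan finds the same roots
  dg <- seq(1e-5, pi / 2 - 1e-5, by = 1e-5)
  gv <- W(2 * dg) - level
  scan_roots <- dg[which(gv[-1] * gv[-length(gv)] < 0)]
  expect_length(scan_roots, 2L)
  expect_equal(sort(vapply(bumps, `[[`, numeric(1), "Delta")),
               sort(scan_roots), tolerance = 1e-4)
  # the wider bump is the stable one for the Mexican hat
  expect_true(bumps[[2]]$stable)
  expect_false(bumps[[1]]$stable)
})

test_that("bump_solve returns nothing when the line misses the primitive", {
  p <- strong_ring_params()
  # level above W_max: down state only
  p_high <- laminar_params(w0 = -2, w1 = 8, w_s0 = 0, kappa_s = 2,
                           gamma_d = 0.5)
  expect_length(bump_solve(p_high, input_level = p_high$gamma_d,
                           kernel = "local"), 0L)
  # nearly pure inhibition: W monotone decreasing, at most one root
  p_mono <- laminar_params(w0 = -1, w1 = 1.01, kappa_s = 0.5, gamma_d = 1)
  expect_lte(length(bump_solve(p_mono, input_level = 1,
                               kernel = "local")), 1L)
})

test_that("operating conditions report the canonical regime correctly", {
  p <- canonical_params()
  oc <- operating_conditions(p)
  expect_true(oc$cond_down_state_unique)   # W_max < kappa_s
  expect_true(oc$cond_bump_exists)
  expect_true(oc$cond_no_coexistence)      # kappa_s - gamma_d = -0.5 < 0
  expect_true(oc$all_satisfied)
  # grid-max oracle for W_max
  Wc <- function(th) laminarwave:::ring_primitive_combined(th, p)
  dg <- seq(1e-4, pi / 2, by = 1e-4)
  expect_circa(oc$W_max, max(Wc(2 * dg)), 1e-6)
  expect_circa(oc$W_min, min(Wc(2 * dg)), 1e-6)
  # without feedforward drive condition (iii) fails for positive kappa_s
  p0 <- canonical_params()
  p0$gamma_d <- 0
  expect_false(operating_conditions(p0)$cond_no_coexistence)
})

test_that("queuing bound certifies sub-threshold pre-bumps", {
  p <- canonical_params()  # w_s0 = 0.1, kappa_s = 0.5
  qb <- queuing_bound(p)
  expect_equal(qb$bound, 0.1 * 2 / pi)
  expect_true(qb$guaranteed_subthreshold)
  p0 <- canonical_params(w_s0 = 0)
  expect_equal(queuing_bound(p0)$bound, 0)
  expect_true(queuing_bound(p0)$guaranteed_subthreshold)
  p_big <- canonical_params()
  p_big$w_s0 <- 1
  expect_false(queuing_bound(p_big)$guaranteed_subthreshold)
})

test_that("feedback raises the deep up state by twice the bump half-width", {
  p <- laminar_params(w_d0 = 2, gamma_s = 1)
  expect_equal(feedback_up_state(p, pi / 4), 2 + pi / 2)
  p0 <- laminar_params(w_d0 = 2, gamma_s = 0)
  expect_equal(feedback_up_state(p0, 0.3), 2)
  expect_error(feedback_up_state(p, 2), "pi/2")
})

test_that("the dimensional speed scale restores physiological units", {
  expect_equal(speed_scale_cm_per_s(sigma_mm = 1, tau_ms = 10), 10)
  expect_equal(speed_scale_cm_per_s(sigma_mm = 0.5, tau_ms = 5), 10)
  expect_equal(speed_scale_cm_per_s(sigma_mm = 2, tau_ms = 10), 20)
})
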