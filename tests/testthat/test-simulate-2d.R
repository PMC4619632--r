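test_that("kernel bank channels have the right structure", {
  g <- grid_2d(extent = 6, nx = 32, ntheta = 8, dt = 0.002)
  p_iso <- laminar_params(w_d0 = 2, sigma_d = 0.3, w_s0 = 0.1,
                          sigma_s = 0.5, tau_d = 0.1, tau_s = 0.1,
                          kernel_d = "gaussian", kernel_s = "gaussian",
                          anisotropy = "isotropic")
  bank <- build_kernel_bank(p_iso, g)
  for (m in 2:g$ntheta)
    expect_equal(bank$fft_ws[[m]], bank$fft_ws[[1]])
  # isotropic channel equals the plain radial kernel transform
  expect_equal(Re(bank$fft_ws[[1]][1, 1]), p_iso$w_s0, tolerance = 1e-6)
  p_cos <- p_iso; p_cos$anisotropy <- "cosine"
  bank_c <- build_kernel_bank(p_cos, g)
  # cosine channel theta = -pi/2 (first grid orientation) vanishes along
  # the x-axis where arg(r) - theta = pi/2
  k1 <- Re(stats::fft(bank_c$fft_ws[[1]] / (g$dx * g$dy),
                      inverse = TRUE)) / (g$nx * g$ny)
  expect_lt(max(abs(k1[2:g$nx, 1])), 1e-10)
  # each channel kernel is non-negative
  expect_gt(min(k1), -1e-12)
  # rotating a channel by pi/2 gives the channel pi/2 away
  m0 <- 1L; m90 <- 1L + g$ntheta / 2L
  k90 <- Re(stats::fft(bank_c$fft_ws[[m90]] / (g$dx * g$dy),
                       inverse = TRUE)) / (g$nx * g$ny)
  expect_equal(laminarwave:::rotate_field_90(k1), k90, tolerance = 1e-10)
  # grid far smaller than the horizontal footprint is rejected
  g_small <- grid_2d(extent = 0.8, nx = 16, ntheta = 8, dt = 0.002)
  expect_error(build_kernel_bank(p_iso, g_small), "extent")
})

test_that("2D fields decay exactly when decoupled and the stepper is the 1D stepper for y-invariant data", {
  p <- laminar_params(w_d0 = 2, sigma_d = 0.5, w_s0 = 0.1, sigma_s = 1,
                      w0 = -1, w1 = 2, kappa_d = 50, kappa_s = 50,
                      tau_d = 0.2, tau_s = 0.1, kernel_d = "gaussian",
                      kernel_s = "gaussian", anisotropy = "isotropic")
  g <- grid_2d(extent = 8, nx = 32, ntheta = 8, dt = 0.004)
  st <- field_2d(matrix(0.6, 32, 32), array(0.4, c(32, 32, 8)))
  nxt <- step_2d(st, p, g)
  expect_equal(unique(as.vector(nxt$u)), 0.6 * (1 - g$dt / p$tau_d))
  expect_equal(unique(as.vector(nxt$v)), 0.4 * (1 - g$dt / p$tau_s))
  # y-invariant fields evolve exactly as the 1D model (dimensional
  # reduction: the y-marginal of the radial kernel is the 1D kernel)
  p2 <- laminar_params(w_d0 = 2, sigma_d = 0.5, w_s0 = 0.1, sigma_s = 1,
                       w0 = -1, w1 = 2, tau_d = 0.1, tau_s = 0.1,
                       rate_mode = "sigmoid", kernel_d = "gaussian",
                       kernel_s = "gaussian", anisotropy = "isotropic")
  g2 <- grid_2d(extent = 10, nx = 64, ntheta = 16, dt = 0.001)
  g1 <- grid_1d(extent = 10, nx = 64, ntheta = 16, dt = 0.001, x0 = -5)
  set.seed(3)
  u1 <- runif(64)
  v1 <- matrix(runif(64 * 16), 64, 16)
  v2 <- array(0, c(64, 64, 16))
  for (j in 1:64) v2[, j, ] <- v1
  n1 <- step_1d(laminar_state(u1, v1), p2, g1)
  n2 <- step_2d(field_2d(matrix(u1, 64, 64), v2), p2, g2)
  expect_lt(max(abs(n2$u - matrix(n1$u, 64, 64))), 1e-8)
  expect_lt(max(abs(n2$v[, 17, ] - n1$v)), 1e-8)
})

test_that("one 2D step equals a brute-force direct-sum evaluation", {
  p <- laminar_params(w_d0 = 1.5, sigma_d = 0.6, w_s0 = 0.2, sigma_s = 0.8,
                      w0 = -1, w1 = 2, kappa_d = 0.4, kappa_s = 0.3,
                      gamma_d = 0.8, gamma_s = 0.5, tau_d = 0.3,
                      tau_s = 0.2, rate_mode = "sigmoid", eta_d = 5,
                      eta_s = 5, kernel_d = "gaussian",
                      kernel_s = "gaussian", anisotropy = "cosine")
  g <- grid_2d(extent = 4, nx = 16, ntheta = 8, dt = 0.01)
  set.seed(7)
  st <- field_2d(matrix(runif(256), 16, 16),
                 array(runif(256 * 8), c(16, 16, 8)))
  bank <- build_kernel_bank(p, g)
  fast <- step_2d(st, p, g, bank)
  # reference: direct sums with the same periodized kernels
  kd <- Re(stats::fft(bank$fft_wd / (g$dx * g$dy), inverse = TRUE)) / 256
  ks <- lapply(bank$fft_ws, function(kf)
    Re(stats::fft(kf / (g$dx * g$dy), inverse = TRUE)) / 256)
  fd <- firing_rate(st$u, p$eta_d, p$kappa_d, p$rate_mode)
  fs <- firing_rate(st$v, p$eta_s, p$kappa_s, p$rate_mode)
  conv2_direct <- function(f, k) {
    out <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) {
      ii <- ((i - (1:16)) %% 16) + 1L
      jj <- ((j - (1:16)) %% 16) + 1L
      out[i, j] <- sum(k[ii, jj] * f) * g$dx * g$dy
    }
    out
  }
  du <- conv2_direct(fd, kd) +
    p$gamma_s * g$dtheta * apply(fs, c(1, 2), sum)
  u_ref <- st$u + g$dt / p$tau_d * (-st$u + du)
  wloc <- ring_kernels(outer(g$theta, g$theta, `-`), p)$loc
  whoz <- ring_kernels(outer(g$theta, g$theta, `-`), p)$hoz
  v_ref <- st$v
  for (m in 1:8) {
    loc_m <- matrix(0, 16, 16); hoz_m <- matrix(0, 16, 16)
    for (mm in 1:8) {
      loc_m <- loc_m + wloc[m, mm] * fs[, , mm] * g$dtheta
      hoz_m <- hoz_m + whoz[m, mm] * fs[, , mm] * g$dtheta
    }
    dv <- loc_m + conv2_direct(hoz_m, ks[[m]]) + p$gamma_d * fd
    v_ref[, , m] <- st$v[, , m] + g$dt / p$tau_s * (-st$v[, , m] + dv)
  }
  expect_equal(fast$u, u_ref, tolerance = 1e-12)
  expect_equal(fast$v, v_ref, tolerance = 1e-12)
})

test_that("plane and target initializations match their definitions", {
  p <- canonical_params(anisotropy = "cosine")
  g <- grid_2d(extent = 4, nx = 32, ntheta = 8, dt = 0.002)
  pl <- init_plane(p, g, x0 = -0.5)
  expect_true(all(pl$u[g$x <= -0.5, ] == 1))
  expect_true(all(pl$u[g$x > -0.5, ] == 0))
  expect_equal(max(abs(pl$v)), 0)
  tg <- init_target(p, g, r0 = 0.6)
  r <- sqrt(outer(g$x^2, g$y^2, `+`))
  expect_equal(tg$u, (r <= 0.6) + 0)
  expect_equal(max(abs(tg$v)), 0)
  expect_error(init_target(p, g, r0 = 5), "r0")
})

test_that("phase vector field recovers known maximizers and masks flat sites", {
  p <- canonical_params()
  g <- grid_2d(extent = 4, nx = 16, ntheta = 32, dt = 0.002)
  argr <- atan2(matrix(g$y, 16, 16, byrow = TRUE), matrix(g$x, 16, 16))
  v <- array(0, c(16, 16, 32))
  for (m in 1:32) v[, , m] <- cos(2 * (g$theta[m] - argr))
  pf <- phase_vector_field(field_2d(matrix(1, 16, 16), v), g, p,
                           kappa = NULL)
  err <- laminarwave:::wrap_orientation(pf$phi - argr)
  expect_lt(max(abs(err), na.rm = TRUE), 1e-2)
  # flat slices are masked
  vflat <- array(1, c(16, 16, 32))
  pf2 <- phase_vector_field(field_2d(matrix(1, 16, 16), vflat), g, p,
                            kappa = NULL)
  expect_true(all(is.na(pf2$phi)))
  # threshold masking
  pf3 <- phase_vector_field(field_2d(matrix(1, 16, 16), 0.1 * v), g, p,
                            kappa = 0.5)
  expect_true(all(is.na(pf3$phi)))
})

test_that("the model is shift-twist equivariant under quarter turns", {
  p <- laminar_params(w_d0 = 2, sigma_d = 0.3, w_s0 = 0.1, sigma_s = 0.8,
                      w0 = -1, w1 = 2, kappa_d = 0.5, kappa_s = 0.5,
                      gamma_d = 1, gamma_s = 1, tau_d = 0.1, tau_s = 0.1,
                      rate_mode = "sigmoid", kernel_d = "gaussian",
                      kernel_s = "gaussian", anisotropy = "cosine")
  g <- grid_2d(extent = 4, nx = 32, ntheta = 8, dt = 0.002)
  init_a <- init_plane(p, g, x0 = -0.5)
  init_b <- shift_twist_state(init_a)
  ra <- run_2d(p, g, init_a, T = 0.1)
  rb <- run_2d(p, g, init_b, T = 0.1)
  chk <- shift_twist_check(ra, rb)
  expect_lt(chk$max_dev_u, 1e-10)
  expect_lt(chk$max_dev_v, 1e-10)
  # an identity twist of a run against itself is exact
  chk0 <- shift_twist_check(ra, list(
    grid = g, snapshots = list(shift_twist_state(
      ra$snapshots[[length(ra$snapshots)]]))))
  expect_equal(chk0$max_dev_u, 0)
  expect_equal(chk0$max_dev_v, 0)
  # deliberately mismatched runs score badly
  chk_bad <- shift_twist_check(ra, ra)
  expect_gt(chk_bad$max_dev_u, 0.1)
})
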