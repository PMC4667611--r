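test_that("Taylor-Green matches its closed forms and is solenoidal", {
  case <- tg_fixture(48, dt = 0.01, rho = 1000, nu = 1e-6)
  f <- case$velocity$frames[[1]]
  expect_equal(f$u[1, 1], 0)            # u(0,0,t) = 0
  expect_equal(f$v[1, 1], 0)
  expect_equal(case$pressure_truth[[1]]$p[1, 1], 500)  # (rho/4)(1+1)
  # the central-difference divergence of the separable TG field
  # cancels exactly: only round-off remains
  div_max <- function(n) {
    c2 <- tg_fixture(n)
    fr <- c2$velocity$frames[[1]]
    d <- swimpressure:::ddx_mat(fr$u, c2$velocity$grid$dx) +
      swimpressure:::ddy_mat(fr$v, c2$velocity$grid$dy)
    max(abs(d), na.rm = TRUE)
  }
  expect_lt(div_max(64), 1e-12)
  expect_error(taylor_green(grid2d(16, 16, 0.1)), "domain mismatch")
})

test_that("potential cylinder reproduces surface Cp and far-field decay", {
  # closed form: Cp(R, theta) = 1 - 4 sin^2(theta)
  U <- 0.1; R <- 0.02; rho <- 1000
  # node-aligned grid: (-R, 0) and (0, R) are grid nodes
  g <- grid2d(101, 101, dx = R / 10, origin = c(-5 * R, -5 * R))
  case <- potential_cylinder(g, U, R, rho)
  q <- rho * U^2 / 2
  cp_at <- function(x, y) {
    j <- which.min(abs(grid_x(g) - x)); i <- which.min(abs(grid_y(g) - y))
    case$pressure_truth[[1]]$p[i, j] / q
  }
  # theta = pi (upstream stagnation): node sits exactly at (-R, 0)
  expect_equal(cp_at(-R, 0), 1, tolerance = 1e-9)
  # theta = pi/2 (shoulder): Cp = -3
  expect_equal(cp_at(0, R), -3, tolerance = 1e-9)
  # decay: |Cp| at r = 20 R below 0.011 (evaluate closed form directly)
  r <- 20 * R
  spd2 <- U^2 * ((1 - R^2 / r^2)^2)   # worst case on the axis
  expect_lt(abs(1 - spd2 / U^2), 0.011)
  expect_error(potential_cylinder(g, U, R = 0.1, rho),
               "insufficient clearance")
  expect_error(potential_cylinder(g, U, R = 3 * g$dx, rho), "at least 5 dx")
})

test_that("Lamb-Oseen pressure truth matches the independent quadrature", {
  # closed form for the centre: p(0) = -rho Gamma^2 ln 2 / (4 pi^2 r_c^2)
  Gamma <- 0.01; r_c <- 0.005; rho <- 1000
  p0_closed <- -rho * Gamma^2 * log(2) / (4 * pi^2 * r_c^2)
  p0_quad <- -rho * stats::integrate(function(r)
    (Gamma / (2 * pi * r) * (1 - exp(-r^2 / r_c^2)))^2 / r,
    0, Inf, rel.tol = 1e-12)$value
  expect_equal(p0_quad, p0_closed, tolerance = 1e-9)
  g <- grid2d(81, 81, dx = 0.1 / 80, origin = c(-0.05, -0.05))
  case <- lamb_oseen(g, Gamma, r_c, rho = rho)
  ic <- 41  # centre node coincides with the vortex centre
  expect_equal(case$pressure_truth[[1]]$p[ic, ic], p0_closed,
               tolerance = 1e-3)
  # suction core: minimum at the centre, negative everywhere
  p <- case$pressure_truth[[1]]$p
  expect_equal(which.min(p), (ic - 1) * 81 + ic)
  expect_true(all(p < 0))
  # Gamma = 0 -> quiescent case, not an error
  q <- lamb_oseen(g, 0, r_c, rho = rho)
  expect_true(all(q$velocity$frames[[1]]$u == 0))
  expect_true(all(q$pressure_truth[[1]]$p == 0))
})

test_that("measurement noise is unbiased, seeded, and sigma-accurate", {
  g <- grid2d(320, 320, dx = 0.01)
  f <- velocity_frame(g, 0, matrix(0.3, 320, 320), matrix(-0.1, 320, 320))
  s <- velocity_sequence(list(f))
  expect_identical(add_measurement_noise(s, 0), s)
  n1 <- add_measurement_noise(s, 0.02, seed = 11)
  n2 <- add_measurement_noise(s, 0.02, seed = 11)
  expect_identical(n1$frames[[1]]$u, n2$frames[[1]]$u)
  resid <- c(n1$frames[[1]]$u - 0.3, n1$frames[[1]]$v + 0.1)
  expect_equal(sd(resid), 0.02, tolerance = 0.02)  # 2 x 102400 samples
  expect_equal(mean(resid), 0, tolerance = 3 * 0.02 / sqrt(length(resid)))
})

test_that("swimmer midlines follow the prescribed wave forms", {
  p <- swimmer_params(wave_mode = "traveling")
  A_L <- p$a0 + p$a1 * p$L + p$a2 * p$L^2
  expect_equal(swimpressure:::swimmer_midline_y(p, p$L, 0),
               A_L * sin(2 * pi * p$L / p$lambda), tolerance = 1e-12)
  ps <- swimmer_params(wave_mode = "standing")
  # nodes of the standing wave never move laterally
  s_node <- ps$lambda / 2
  for (t in seq(0, ps$T_p, length.out = 7))
    expect_equal(swimpressure:::swimmer_midline_y(ps, s_node, t), 0,
                 tolerance = 1e-12)
})

test_that("swimmer blob fields are solenoidal to truncation order", {
  p <- small_swimmer_params("traveling", n_frames = 3L)
  div_max <- function(dx) {
    g <- grid2d(ceiling(0.4 / dx), ceiling(0.14 / dx), dx = dx,
                origin = c(0, -0.07))
    ds <- synth_swimmer(p, g, p$T_p / 24)
    fr <- ds$velocity$frames[[2]]
    d <- swimpressure:::ddx_mat(fr$u, dx) + swimpressure:::ddy_mat(fr$v, dx)
    ok <- swimpressure:::stencil_valid(fr$valid)
    max(abs(d[ok])) / max(abs(fr$u))
  }
  d1 <- div_max(0.002); d2 <- div_max(0.001)
  expect_gt(d1 / d2, 2.5)   # ~2nd order shrink
  expect_lt(d1 / d2, 7)
})

test_that("swimmer ground-truth contours agree with rasterised masks", {
  p <- small_swimmer_params("traveling", n_frames = 4L)
  g <- grid2d(201, 71, dx = 0.002, origin = c(0, -0.07))
  ds <- synth_swimmer(p, g, p$T_p / 24)
  for (k in c(1L, 3L)) {
    tr <- extract_contour(ds$masks$frames[[k]], g)
    pts <- ds$contours[[k]]$points
    # distance from each truth point to the mask iso-contour polyline
    d <- vapply(seq_len(nrow(pts)), function(i)
      min(sqrt((tr[, 1] - pts[i, 1])^2 + (tr[, 2] - pts[i, 2])^2)),
      numeric(1))
    expect_lt(max(d), 0.75 * g$dx)
  }
})

test_that("traveling-mode BSR crests advance at the wave phase speed", {
  p <- small_swimmer_params("traveling", n_frames = 8L)
  g <- grid2d(201, 71, dx = 0.002, origin = c(0, -0.07))
  dt <- p$T_p / 24
  ds <- synth_swimmer(p, g, dt)
  # circular cross-correlation of consecutive per-point BSR profiles
  shifts <- vapply(2:8, function(k) {
    a <- ds$bsr[[k - 1]]; b <- ds$bsr[[k]]
    cc <- vapply(0:59, function(s)
      sum(a * b[((seq_len(60) - 1 + s) %% 60) + 1]), numeric(1))
    s <- which.max(cc) - 1L
    if (s > 30L) s - 60L else s
  }, numeric(1))
  ds_pt <- mean(ds$contours[[1]]$seg_lengths)
  crest_speed <- mean(abs(shifts)) * ds_pt / dt
  expect_equal(crest_speed, p$lambda / p$T_p, tolerance = 0.35)
  # standing mode: no systematic profile drift
  ps <- small_swimmer_params("standing", n_frames = 8L)
  ds2 <- synth_swimmer(ps, g, dt)
  sh2 <- vapply(2:5, function(k) {
    a <- ds2$bsr[[k - 1]]; b <- ds2$bsr[[k]]
    cc <- vapply(0:59, function(s)
      sum(a * b[((seq_len(60) - 1 + s) %% 60) + 1]), numeric(1))
    s <- which.max(cc) - 1L
    if (s > 30L) s - 60L else s
  }, numeric(1))
  expect_lte(stats::median(abs(sh2)), 1)
})

test_that("a body too large for the domain is refused", {
  p <- swimmer_params(n_frames = 40L)
  g <- grid2d(60, 30, dx = 0.002)
  expect_error(synth_swimmer(p, g, p$T_p / 12), "body leaves domain")
})
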