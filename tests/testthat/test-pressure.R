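test_that("material acceleration is zero for steady uniform flow", {
  g <- grid2d(16, 16, dx = 0.01)
  mk <- function(t) velocity_frame(g, t, matrix(0.1, 16, 16),
                                   matrix(0, 16, 16))
  acc <- material_acceleration(mk(0), mk(0.01), mk(0.02), 0.01)
  expect_equal(max(abs(acc$ax[acc$valid])), 0)
  expect_equal(max(abs(acc$ay[acc$valid])), 0)
  expect_error(material_acceleration(mk(0), mk(0.01), mk(0.02), 0),
               "dt must be > 0")
})

test_that("material acceleration is centripetal for solid-body rotation", {
  g <- grid2d(41, 41, dx = 0.001, origin = c(-0.02, -0.02))
  co <- grid_coords(g)
  om <- 1
  # steady rotating frame snapshots: u = (-om y, om x) at all times
  mk <- function(t) {
    ang <- om * t
    X <- co$X * cos(ang) + co$Y * sin(ang)
    Y <- -co$X * sin(ang) + co$Y * cos(ang)
    velocity_frame(g, t, -om * co$Y, om * co$X)
  }
  dt <- 1e-4
  acc <- material_acceleration(mk(-dt), mk(0), mk(dt), dt)
  # at r = 0.02 (edge node on the x axis): magnitude om^2 r toward centre
  j <- 41; i <- 21
  expect_equal(acc$ax[i, j - 1], -om^2 * co$X[i, j - 1], tolerance = 1e-9)
  expect_equal(acc$ay[i, j - 1], 0, tolerance = 1e-9)
  expect_equal(sqrt(acc$ax[i, 31]^2 + acc$ay[i, 31]^2),
               om^2 * abs(co$X[i, 31]), tolerance = 1e-9)
})

test_that("Taylor-Green material acceleration matches the closed form", {
  # for nu = 0 the field is steady: Du/Dt = (sin 2x / 2, sin 2y / 2)
  err <- vapply(c(32, 64), function(n) {
    g <- tg_grid(n)
    case <- taylor_green(g, rho = 1000, nu = 0, times = c(0, 0.01, 0.02))
    s <- case$velocity
    acc <- material_acceleration(s$frames[[1]], s$frames[[2]],
                                 s$frames[[3]], s$dt)
    co <- grid_coords(g)
    ok <- acc$valid
    max(abs(acc$ax - sin(2 * co$X) / 2)[ok],
        abs(acc$ay - sin(2 * co$Y) / 2)[ok])
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_gt(log2(err[1] / err[2]), 1.6)   # ~2nd order
})

test_that("Poiseuille flow gives the exact constant pressure gradient", {
  U0 <- 0.1; h <- 0.01; mu <- 1e-3
  g <- grid2d(21, 21, dx = 0.001, dy = 0.001, origin = c(0, -0.01))
  co <- grid_coords(g)
  u <- U0 * (1 - (co$Y / h)^2)
  mk <- function(t) velocity_frame(g, t, u, matrix(0, 21, 21))
  acc <- material_acceleration(mk(0), mk(0.01), mk(0.02), 0.01)
  grd <- pressure_gradient(acc, mk(0.01), fluid_properties(rho = 1000, mu = mu))
  ok <- grd$valid
  expect_equal(max(abs(grd$gx[ok] - (-2 * mu * U0 / h^2))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(grd$gy[ok])), 0, tolerance = 1e-12)
})

test_that("quiescent fluid has zero gradient and zero pressure", {
  g <- grid2d(24, 24, dx = 0.01)
  mk <- function(t) velocity_frame(g, t, matrix(0, 24, 24),
                                   matrix(0, 24, 24))
  acc <- material_acceleration(mk(0), mk(0.1), mk(0.2), 0.1)
  grd <- pressure_gradient(acc, mk(0.1), fluid_properties())
  pf <- integrate_pressure(grd)
  expect_true(all(pf$p == 0))
  expect_true(all(pf$n_paths_used == 8))
})

test_that("a discrete Gaussian-bump gradient integrates back to the bump", {
  n <- 128
  g <- grid2d(n, n, dx = 2 / (n - 1), origin = c(-1, -1))
  co <- grid_coords(g)
  sigma <- 0.35
  pstar <- exp(-(co$X^2 + co$Y^2) / (2 * sigma^2))
  gx <- swimpressure:::ddx_mat(pstar, g$dx)
  gy <- swimpressure:::ddy_mat(pstar, g$dy)
  valid <- is.finite(gx) & is.finite(gy)
  gx[!valid] <- NA; gy[!valid] <- NA
  grad <- list(gx = gx, gy = gy, valid = valid, grid = g, t = 0)
  # the discrete bump tail is truncated at the window edge, so the
  # known edge values are supplied as boundary data
  pf <- integrate_pressure(grad, boundary = pstar)
  ok <- is.finite(pf$p)
  err <- (pf$p - mean(pf$p[ok])) - (pstar - mean(pstar[ok]))
  expect_lt(max(abs(err[ok])), 1e-3 * max(pstar))
  # Poisson oracle recovers the same bump
  po <- poisson_pressure_oracle(grad, boundary = pstar)
  ok2 <- is.finite(po$p)
  err2 <- (po$p - mean(po$p[ok2])) - (pstar - mean(pstar[ok2]))
  expect_lt(max(abs(err2[ok2])), 1e-3 * max(pstar))
})

test_that("the ray median ignores a single corrupted ray", {
  n <- 33
  g <- grid2d(n, n, dx = 0.01)
  z <- matrix(0, n, n)
  valid <- matrix(TRUE, n, n)
  grad <- list(gx = z, gy = z, valid = valid, grid = g, t = 0)
  # corrupt one node on the east ray of the centre node only
  gx <- z; gx[17, 25] <- 1e6
  grad_bad <- list(gx = gx, gy = z, valid = valid, grid = g, t = 0)
  pf <- integrate_pressure(grad_bad)
  expect_equal(pf$p[17, 17], 0)           # median of {7 x 0, outlier}
  expect_equal(pf$n_paths_used[17, 17], 8L)
})

test_that("nodes cut off by the mask are flagged and filled", {
  n <- 41
  g <- grid2d(n, n, dx = 0.01)
  z <- matrix(0, n, n)
  grad <- list(gx = z, gy = z, valid = matrix(TRUE, n, n), grid = g, t = 0)
  # ring mask enclosing a shadow pocket around the centre
  co <- grid_coords(g)
  r <- sqrt((co$X - 0.2)^2 + (co$Y - 0.2)^2)
  ring <- r > 0.05 & r < 0.09
  pf <- integrate_pressure(grad, mask = ring)
  expect_equal(pf$n_paths_used[21, 21], 0L)
  expect_false(pf$valid[21, 21])
  expect_true(pf$filled[21, 21])
  expect_true(is.finite(pf$p[21, 21]))
  expect_error(integrate_pressure(grad, mask = matrix(TRUE, n, n)),
               "no computable nodes")
})

test_that("pressure recovery on Taylor-Green converges at second order", {
  errs <- vapply(c(32, 64), function(n) {
    case <- tg_fixture(n)
    sol <- solve_case_midframe(case, fluid_properties(rho = 1000, mu = 1e-3))
    rel_l2(sol$pf$p, sol$truth$p)
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  slope <- log2(errs[1] / errs[2])
  expect_gt(slope, 1.6); expect_lt(slope, 2.4)
})

test_that("median-of-eight and the Poisson oracle agree on smooth cases", {
  case <- tg_fixture(64)
  sol <- solve_case_midframe(case, fluid_properties(rho = 1000, mu = 1e-3))
  po <- poisson_pressure_oracle(sol$grad, boundary = sol$truth$p)
  both <- is.finite(sol$pf$p) & is.finite(po$p)
  d <- (sol$pf$p - mean(sol$pf$p[both])) - (po$p - mean(po$p[both]))
  rng <- diff(range(sol$truth$p, na.rm = TRUE))
  expect_lt(max(abs(d[both])) / rng, 0.02)
})

test_that("pressure_sequence handles steady input and frame-count errors", {
  g <- grid2d(16, 16, dx = 0.01)
  mk <- function(t) velocity_frame(g, t, matrix(0.1, 16, 16),
                                   matrix(0, 16, 16))
  s3 <- velocity_sequence(list(mk(0), mk(0.01), mk(0.02)))
  out <- pressure_sequence(s3, fluid = fluid_properties())
  expect_length(out, 1)
  expect_true(all(out[[1]]$p == 0))
  s2 <- velocity_sequence(list(mk(0), mk(0.01)))
  expect_error(pressure_sequence(s2, fluid = fluid_properties()),
               ">=3 frames required")
})
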