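test_that("contour extraction traces squares and disks sub-cell accurately", {
  g <- grid2d(64, 64, dx = 0.01)
  co <- grid_coords(g)
  # filled axis-aligned square, side 10 dx
  sq <- co$X >= 0.20 & co$X <= 0.30 & co$Y >= 0.20 & co$Y <= 0.30
  poly <- extract_contour(sq, g)
  per <- sum(sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2)))
  # the 0.5-level iso-contour of a binary raster sits half a cell
  # outside the outermost body nodes, dilating each side by one dx
  expect_equal(per, 4 * (10 + 1) * g$dx, tolerance = 0.05)
  # filled disk radius 20 dx: all boundary points within 0.7 dx of R
  g2 <- grid2d(128, 128, dx = 0.01)
  co2 <- grid_coords(g2)
  R <- 20 * g2$dx; cx <- 0.64; cy <- 0.64
  disk <- (co2$X - cx)^2 + (co2$Y - cy)^2 < R^2
  pd <- extract_contour(disk, g2)
  r <- sqrt((pd[, 1] - cx)^2 + (pd[, 2] - cy)^2)
  expect_lt(max(abs(r - R)), 0.7 * g2$dx)
  # counterclockwise orientation
  expect_gt(swimpressure:::polygon_area(pd), 0)
})

test_that("degenerate masks are rejected with specific errors", {
  g <- grid2d(40, 40, dx = 0.01)
  co <- grid_coords(g)
  two <- (co$X - 0.1)^2 + (co$Y - 0.1)^2 < 0.05^2 |
    (co$X - 0.3)^2 + (co$Y - 0.3)^2 < 0.05^2
  expect_error(extract_contour(two, g), "ambiguous body")
  clipped <- co$X < 0.08
  expect_error(extract_contour(clipped, g), "body clipped")
  tiny <- matrix(FALSE, 40, 40); tiny[20, 20:22] <- TRUE
  expect_error(extract_contour(tiny, g), "ambiguous body")
})

test_that("resampling gives n equally spaced points, 60 by default", {
  ct <- resample_contour(circle_poly(R = 0.05, m = 2000))
  expect_equal(nrow(ct$points), 60)  # default control point count
  expect_equal(max(ct$seg_lengths) / min(ct$seg_lengths), 1,
               tolerance = 1e-6)
  # segments are chords of 6-degree arcs
  expect_equal(mean(ct$seg_lengths), 2 * 0.05 * sin(pi / 60),
               tolerance = 1e-5)
  # outward normals: radial for a circle
  rad <- ct$points / sqrt(rowSums(ct$points^2))
  expect_gt(min(rowSums(rad * ct$normals)), 0.999)
  # square with n = 8: corners and edge midpoints
  sqp <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  c8 <- resample_contour(sqp, n = 8)
  d <- pmin(abs(c8$points - round(c8$points)),
            abs(c8$points - 0.5))
  expect_lt(max(d), 1e-12)
  expect_error(resample_contour(matrix(0, 5, 2)), "degenerate")
})

test_that("resampling an equal-spaced contour is idempotent", {
  ct <- resample_contour(circle_poly(R = 0.04, m = 1440), n = 60)
  ct2 <- resample_contour(ct$points, n = 60)
  expect_equal(ct2$points, ct$points, tolerance = 1e-9)
  expect_equal(ct2$normals, ct$normals, tolerance = 1e-7)
})

test_that("rigid rotation yields uniform BSR and translation zero BSR", {
  ct <- resample_contour(circle_poly(R = 0.05, m = 1440), n = 60)
  dt <- 1e-4
  om <- 1
  prev <- transform_contour(ct, ang = -om * dt)
  nxt <- transform_contour(ct, ang = +om * dt)
  kin <- surface_kinematics(prev, ct, nxt, dt)
  expect_equal(kin$bsr_seg, rep(om, 60), tolerance = 1e-3)
  # pure translation: bsr == 0, u_body equals the translation velocity
  vel <- c(0.3, -0.2)
  prev <- transform_contour(ct, shift = -vel * dt)
  nxt <- transform_contour(ct, shift = +vel * dt)
  kin <- surface_kinematics(prev, ct, nxt, dt)
  expect_equal(max(abs(kin$bsr_seg)), 0, tolerance = 1e-9)
  expect_equal(kin$u_body,
               matrix(vel, 60, 2, byrow = TRUE), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(surface_kinematics(prev, ct, nxt, dt = 0), "dt must be > 0")
})

test_that("vorticity is exact on affine fields and twice the spin rate", {
  g <- grid2d(32, 32, dx = 0.01, origin = c(-0.155, -0.155))
  co <- grid_coords(g)
  om <- 1
  f <- velocity_frame(g, 0, -om * co$Y, om * co$X)
  vf <- vorticity_field(f)
  expect_equal(max(abs(vf$omega[vf$valid] - 2 * om)), 0, tolerance = 1e-12)
  # plane shear u = (3 y, 0) -> omega = -3 exactly
  fs <- velocity_frame(g, 0, 3 * co$Y, matrix(0, 32, 32))
  vs <- vorticity_field(fs)
  expect_equal(max(abs(vs$omega[vs$valid] + 3)), 0, tolerance = 1e-12)
})

test_that("potential-cylinder flow is irrotational away from the body", {
  U <- 0.1; R <- 0.02
  g <- grid2d(121, 121, dx = 8 * R / 120, origin = c(-4 * R, -4 * R))
  case <- potential_cylinder(g, U, R)
  vf <- vorticity_field(case$velocity$frames[[1]])
  co <- grid_coords(g)
  far <- vf$valid & (co$X^2 + co$Y^2 > (2 * R)^2)
  # truncation-level only: |omega| dx / U stays tiny
  expect_lt(max(abs(vf$omega[far])) * g$dx / U, 5e-3)
})

test_that("body surface vorticity samples the nearest valid node", {
  g <- grid2d(41, 41, dx = 0.005, origin = c(-0.1, -0.1))
  vf <- list(omega = matrix(5, 41, 41), valid = matrix(TRUE, 41, 41),
             grid = g, t = 0)
  ct <- resample_contour(circle_poly(R = 0.05, m = 720), n = 20)
  expect_equal(body_surface_vorticity(ct, vf), rep(5, 20))
  # all nodes invalid within reach -> NA, excluded from the norm
  vf$valid[] <- FALSE
  bsv <- body_surface_vorticity(ct, vf)
  expect_true(all(is.na(bsv)))
  # Lamb-Oseen: sampled value equals the closed-form vorticity at the
  # selected node
  Gamma <- 0.01; r_c <- 0.008
  lo <- lamb_oseen(g, Gamma, r_c)
  om <- vorticity_field(lo$velocity$frames[[1]])
  ct2 <- resample_contour(circle_poly(R = 0.03, m = 720), n = 12)
  bsv2 <- body_surface_vorticity(ct2, om)
  co <- grid_coords(g)
  for (i in seq_len(12)) {
    d2 <- (co$X - ct2$points[i, 1])^2 + (co$Y - ct2$points[i, 2])^2
    d2[!om$valid] <- Inf
    k <- which.min(d2)
    expect_equal(bsv2[i], om$omega[k])
  }
})

test_that("normalisation maps body quantities into [-1, 1]", {
  x <- c(-4, 2, NA, 1)
  expect_equal(normalize_on_body(x), c(-1, 0.5, NA, 0.25))
  expect_identical(normalize_on_body(c(0, 0)), c(0, 0))
})

test_that("swim frame recovers direction, speed and body length", {
  ct0 <- resample_contour(circle_poly(R = 0.02, m = 720), n = 40)
  dt <- 0.01
  contours <- lapply(0:9, function(k)
    transform_contour(ct0, shift = c(0.24, 0) * k * dt, t = k * dt))
  sf <- swim_frame(contours, dt)
  expect_equal(sf$s_hat, c(1, 0), tolerance = 1e-9)
  expect_equal(sf$j_hat, c(0, 1), tolerance = 1e-9)
  expect_equal(sf$U, 0.24, tolerance = 1e-9)
  expect_equal(sf$body_length, 0.04, tolerance = 1e-3)
  expect_error(swim_frame(rep(list(ct0), 5), dt), "stationary body")
  sf2 <- swim_frame(rep(list(ct0), 5), dt, mode = "fixed",
                    fixed_vector = c(0, 2))
  expect_equal(sf2$s_hat, c(0, 1))
  expect_equal(sf2$U, 0)
})

test_that("generated swimmer speed is recovered through the pipeline", {
  p <- small_swimmer_params("traveling", n_frames = 10L)
  g <- grid2d(201, 71, dx = 0.002, origin = c(0, -0.07))
  ds <- synth_swimmer(p, g, p$T_p / 24)
  sf <- swim_frame(ds$contours, p$T_p / 24)
  expect_equal(sf$U_bl, p$swim_speed_bl, tolerance = 0.15)
})
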