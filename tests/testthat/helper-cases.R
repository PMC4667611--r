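# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except in the I/O round-trip tests (which write to
# tempdirs first).

tg_grid <- function(n) grid2d(n, n, dx = 2 * pi / (n - 1))

# Taylor-Green 5-frame sequence plus its mid-frame analytic pressure.
tg_fixture <- function(n, dt = 0.01, rho = 1000, nu = 1e-6) {
  taylor_green(tg_grid(n), rho = rho, nu = nu, times = (0:4) * dt)
}

# Relative L2 error between two fields after mean removal, over the
# nodes where both are finite.
rel_l2 <- function(p, truth) {
  ok <- is.finite(p) & is.finite(truth)
  e <- (p - mean(p[ok])) - (truth - mean(truth[ok]))
  sqrt(mean(e[ok]^2)) / sqrt(mean((truth[ok] - mean(truth[ok]))^2))
}

# Mid-frame pressure of an analytic case via the median-of-eight-path
# solver, using the case's own edge pressure as boundary data.
solve_case_midframe <- function(case, fluid, config = analysis_config(),
                                use_truth_boundary = TRUE) {
  seq <- case$velocity
  k <- (length(seq$frames) + 1L) %/% 2L
  acc <- material_acceleration(seq$frames[[k - 1]], seq$frames[[k]],
                               seq$frames[[k + 1]], seq$dt)
  grd <- pressure_gradient(acc, seq$frames[[k]], fluid,
                           include_viscous = config$include_viscous)
  msk <- if (!is.null(case$mask)) case$mask$frames[[k]]
  bnd <- if (use_truth_boundary) case$pressure_truth[[k]]$p
  list(pf = integrate_pressure(grd, msk, config, bnd),
       grad = grd, truth = case$pressure_truth[[k]], k = k, mask = msk)
}

# Closed ring polyline for a circle (points not repeated).
circle_poly <- function(R = 1, center = c(0, 0), m = 720) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

# Rigid-motion copies of a contour: rotated by `ang` about `center`
# and translated by `shift`.
transform_contour <- function(ct, ang = 0, center = c(0, 0),
                              shift = c(0, 0), t = ct$t) {
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  pts <- sweep(ct$points, 2, center) %*% t(Rm)
  pts <- sweep(pts, 2, center + shift, "+")
  resample_contour(pts, n = nrow(ct$points), t = t)
}

# A thin flat plate (length ell along x) as a manually built contour:
# m points on the top face (outward normal +y) and m on the bottom
# (normal -y); used for single-face closed-form checks.
plate_contour <- function(ell = 0.1, m = 11, t = 0) {
  h <- ell / (m - 1)
  xs <- seq(0, ell, length.out = m)
  pts <- rbind(cbind(xs, 0), cbind(rev(xs), 0))
  normals <- rbind(cbind(0, rep(1, m)), cbind(0, rep(-1, m)))
  seg <- rep(c(h, 0), c(m - 1, 1))
  structure(list(points = pts, normals = normals,
                 seg_lengths = c(seg, seg), t = t),
            class = "body_contour")
}

# Swim frame pointing along +x without fitting.
unit_swim_frame <- function(U = 0.1, L = 0.1) {
  structure(list(s_hat = c(1, 0), j_hat = c(0, 1), U = U, U_bl = U / L,
                 body_length = L), class = "swim_frame")
}

# Small, fast swimmer dataset for pipeline tests.
small_swimmer_params <- function(mode, n_frames = 10L, ...) {
  swimmer_params(wave_mode = mode, n_frames = n_frames, ...)
}
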