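#' Analytic flow case
#'
#' Container pairing a velocity sequence with its known gauge-pressure
#' fields, used to validate the pressure solver.
#'
#' @param name Identifier.
#' @param velocity A [velocity_sequence()].
#' @param pressure_truth List of [pressure_frame()]s at the same times.
#' @param mask Optional [mask_sequence()].
#' @export
analytic_flow_case <- function(name, velocity, pressure_truth, mask = NULL) {
  structure(list(name = name, velocity = velocity,
                 pressure_truth = pressure_truth, mask = mask),
            class = "analytic_flow_case")
}

#' Taylor-Green vortex array
#'
#' Decaying vortex lattice on `[0, 2 pi]^2`:
#' `u = sin(x) cos(y) F(t)`, `v = -cos(x) sin(y) F(t)` with
#' `F(t) = exp(-2 nu t)`, and gauge pressure
#' `p = (rho / 4) (cos 2x + cos 2y) F(t)^2`. The velocity is exactly
#' solenoidal, making this the workhorse accuracy case for the
#' pressure solver.
#'
#' @param grid A [grid2d()] spanning `[0, 2 pi]` in both directions.
#' @param rho Density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @param times Frame times (s).
#' @return An [analytic_flow_case()].
#' @export
taylor_green <- function(grid, rho = 1000, nu = 1e-6, times = 0) {
  span_x <- (grid$nx - 1) * grid$dx
  span_y <- (grid$ny - 1) * grid$dy
  if (abs(span_x - 2 * pi) > 1e-6 || abs(span_y - 2 * pi) > 1e-6 ||
      any(abs(grid$origin) > 1e-9))
    stop("domain mismatch: Taylor-Green grid must span [0, 2 pi]^2")
  co <- grid_coords(grid)
  frames <- list(); truth <- list()
  for (k in seq_along(times)) {
    t <- times[k]
    Ft <- exp(-2 * nu * t)
    u <- sin(co$X) * cos(co$Y) * Ft
    v <- -cos(co$X) * sin(co$Y) * Ft
    p <- rho / 4 * (cos(2 * co$X) + cos(2 * co$Y)) * Ft^2
    frames[[k]] <- velocity_frame(grid, t, u, v)
    truth[[k]] <- pressure_frame(grid, t, p)
  }
  analytic_flow_case("taylor_green", velocity_sequence(frames), truth)
}

#' Potential flow past a circular cylinder
#'
#' Irrotational flow `u - i v = U_inf (1 - R^2 / z^2)` around a disk
#' of radius `R`, with Bernoulli gauge pressure
#' `p = rho / 2 (U_inf^2 - |u|^2)`; on the surface
#' `Cp = 1 - 4 sin^2(theta)`. The sequence holds three identical
#' frames so the temporal term of the momentum balance is exactly
#' zero. The disk interior is masked and its nodes invalidated.
#'
#' @param grid A [grid2d()].
#' @param U_inf Free-stream speed (m/s), along +x.
#' @param R Cylinder radius (m), at least `5 dx`.
#' @param rho Density (kg/m^3).
#' @param center Cylinder centre, default the domain centre.
#' @param dt Frame interval of the steady 3-frame sequence (s).
#' @return An [analytic_flow_case()] with a mask.
#' @export
potential_cylinder <- function(grid, U_inf, R, rho = 1000, center = NULL,
                               dt = 0.01) {
  if (R < 5 * grid$dx) stop("R must be at least 5 dx")
  x <- grid_x(grid); y <- grid_y(grid)
  if (is.null(center)) center <- c(mean(range(x)), mean(range(y)))
  if (center[1] - R <= x[1] || center[1] + R >= x[grid$nx] ||
      center[2] - R <= y[1] || center[2] + R >= y[grid$ny])
    stop("insufficient clearance: cylinder touches the domain boundary")
  co <- grid_coords(grid)
  X <- co$X - center[1]; Y <- co$Y - center[2]
  r2 <- X^2 + Y^2
  r4 <- pmax(r2^2, .Machine$double.eps)
  u <- U_inf * (1 - R^2 * (X^2 - Y^2) / r4)
  v <- -2 * U_inf * R^2 * X * Y / r4
  mask <- r2 < R^2 * (1 - 1e-10)   # nodes on the circle stay fluid
  u[mask] <- 0; v[mask] <- 0
  p <- rho / 2 * (U_inf^2 - (u^2 + v^2))
  p[mask] <- NA_real_
  frames <- list(); truth <- list()
  for (k in 1:3) {
    t <- (k - 1) * dt
    frames[[k]] <- velocity_frame(grid, t, u, v, valid = !mask)
    truth[[k]] <- pressure_frame(grid, t, p, valid = !mask)
  }
  analytic_flow_case("potential_cylinder", velocity_sequence(frames), truth,
                     mask = mask_sequence(grid, list(mask, mask, mask)))
}

# Lamb-Oseen swirl profile u_theta(r); vectorised, finite at r = 0.
lamb_oseen_utheta <- function(r, Gamma, r_c) {
  out <- ifelse(r > 0, Gamma / (2 * pi * pmax(r, .Machine$double.xmin)) *
                  (1 - exp(-r^2 / r_c^2)), 0)
  out[r == 0] <- 0
  out
}

#' Lamb-Oseen vortex with quadrature pressure truth
#'
#' Swirl `u_theta(r) = Gamma / (2 pi r) (1 - exp(-r^2 / r_c^2))`; the
#' gauge pressure follows from the radial momentum balance
#' `dp/dr = rho u_theta^2 / r` with `p(infinity) = 0`, evaluated by
#' trapezoidal quadrature on a fine radial table (the far tail is
#' closed analytically with the point-vortex integral
#' `Gamma^2 rho / (8 pi^2 r^2)`) and interpolated to the grid. With
#' `nu > 0` the core spreads as `r_c(t)^2 = r_c^2 + 4 nu t`.
#'
#' @param grid A [grid2d()].
#' @param Gamma Circulation (m^2/s); 0 returns a quiescent case.
#' @param r_c Core radius (m).
#' @param center Vortex centre, default the domain centre.
#' @param rho Density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @param times Frame times (s).
#' @return An [analytic_flow_case()].
#' @export
lamb_oseen <- function(grid, Gamma, r_c, center = NULL, rho = 1000,
                       nu = 0, times = 0) {
  if (!(r_c > 0)) stop("r_c must be > 0")
  x <- grid_x(grid); y <- grid_y(grid)
  if (is.null(center)) center <- c(mean(range(x)), mean(range(y)))
  co <- grid_coords(grid)
  X <- co$X - center[1]; Y <- co$Y - center[2]
  r <- sqrt(X^2 + Y^2)
  rmax <- max(r) * 2 + 10 * r_c
  frames <- list(); truth <- list()
  for (k in seq_along(times)) {
    t <- times[k]
    rct <- sqrt(r_c^2 + 4 * nu * t)
    ut <- lamb_oseen_utheta(r, Gamma, rct)
    with_r <- pmax(r, .Machine$double.xmin)
    u <- -ut * Y / with_r
    v <- ut * X / with_r
    u[r == 0] <- 0; v[r == 0] <- 0
    p <- lamb_oseen_pressure(r, Gamma, rct, rho, rmax)
    frames[[k]] <- velocity_frame(grid, t, u, v)
    truth[[k]] <- pressure_frame(grid, t, p)
  }
  analytic_flow_case("lamb_oseen", velocity_sequence(frames), truth)
}

# Gauge pressure table for the Lamb-Oseen vortex by cumulative
# trapezoid of rho u_theta^2 / r from rmax inward; analytic tail
# beyond rmax.
lamb_oseen_pressure <- function(r, Gamma, r_c, rho, rmax) {
  if (Gamma == 0) return(array(0, dim = dim(r)))
  rt <- seq(0, rmax, length.out = 8192)
  integrand <- ifelse(rt > 0,
                      rho * lamb_oseen_utheta(rt, Gamma, r_c)^2 /
                        pmax(rt, .Machine$double.xmin), 0)
  # u_theta ~ r near 0, so the integrand ~ r and vanishes at the origin
  dr <- diff(rt)
  cum <- c(0, cumsum(dr * (integrand[-1] + integrand[-length(rt)]) / 2))
  tail_val <- rho * Gamma^2 / (8 * pi^2 * rmax^2)
  p_tab <- (cum - cum[length(cum)]) - tail_val
  matrix(stats::approx(rt, p_tab, xout = pmin(as.vector(r), rmax))$y,
         nrow(r), ncol(r))
}

#' Add synthetic measurement noise to a velocity sequence
#'
#' Adds i.i.d. zero-mean Gaussian perturbations to `u` and `v` at all
#' valid nodes, reproducibly under a fixed seed. Used to probe the
#' robustness of the median-of-eight pressure integration.
#'
#' @param seq A [velocity_sequence()].
#' @param sigma Noise standard deviation (m/s); 0 is the identity.
#' @param seed RNG seed.
#' @return A perturbed [velocity_sequence()].
#' @export
add_measurement_noise <- function(seq, sigma, seed = 0L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(seq)
  with_local_seed(seed, {
    frames <- lapply(seq$frames, function(f) {
      nu_ <- f$u; nv_ <- f$v
      nn <- sum(f$valid)
      nu_[f$valid] <- nu_[f$valid] + stats::rnorm(nn, 0, sigma)
      nv_[f$valid] <- nv_[f$valid] + stats::rnorm(nn, 0, sigma)
      velocity_frame(f$grid, f$t, nu_, nv_, f$valid)
    })
    velocity_sequence(frames)
  })
}

#' Synthetic swimmer parameters
#'
#' Defaults mimic a late-larval lamprey: body length 0.12 m, one
#' undulation wavelength on the body, and a nominal swimming speed of
#' 2 body lengths per second in traveling mode (1.2 BL/s in standing
#' mode, matching the slower uncoordinated gait the standing wave
#' emulates). The lateral midline displacement is
#' `y_mid(s, t) = A(s) sin(2 pi (s / lambda - t / T_p))` (traveling) or
#' `A(s) sin(2 pi s / lambda) cos(2 pi t / T_p)` (standing), with the
#' quadratic envelope `A(s) = a0 + a1 s + a2 s^2` growing toward the
#' tail.
#'
#' @param L Body length (m).
#' @param lambda Undulation wavelength (m).
#' @param T_p Undulation period (s).
#' @param a0,a1,a2 Amplitude envelope coefficients (m, -, 1/m).
#' @param w_max Maximum body half-width (m); the half-width profile is
#'   the ellipse `w(s) = w_max sqrt(4 xi (1 - xi))`, `xi = s / L`.
#' @param wave_mode `"traveling"` or `"standing"`.
#' @param swim_speed_bl Forward speed in body lengths per second;
#'   default 2.0 (traveling) or 1.2 (standing).
#' @param gamma0 Vortex-blob circulation scale (m^2/s).
#' @param r_c_blob Blob core radius (m).
#' @param kappa Strength coefficient of the lateral dipole elements
#'   that carry the acceleration-reaction (pushing) part of the flow;
#'   the near-surface jet speed is about `kappa ds / r_c_blob` times
#'   the local body normal velocity. 0 disables them.
#' @param tau_lag Vorticity formation lag (s): blob circulations
#'   follow the body surface rotation of `tau_lag` seconds earlier,
#'   emulating the finite time boundary-layer vorticity needs to
#'   build. Default `T_p / 8`. 0 disables the lag (and with it any
#'   net lateral energy loss of a standing wave, whose ideal-flow
#'   response is perfectly recovered).
#' @param n_frames Number of frames.
#' @param seed RNG seed carried in the dataset provenance.
#' @export
swimmer_params <- function(L = 0.12, lambda = 0.12, T_p = 0.4,
                           a0 = 0.002, a1 = 0, a2 = 100 / 144,
                           w_max = 0.006,
                           wave_mode = c("traveling", "standing"),
                           swim_speed_bl = NULL,
                           gamma0 = 0.025, r_c_blob = 0.005,
                           kappa = 2, r_c_dip = 0.0025, tau_lag = NULL,
                           n_frames = 30L, seed = 0L) {
  wave_mode <- match.arg(wave_mode)
  if (!(L > 0) || !(lambda > 0) || !(T_p > 0) || !(r_c_blob > 0))
    stop("L, lambda, T_p and r_c_blob must be > 0")
  if (is.null(swim_speed_bl))
    swim_speed_bl <- if (wave_mode == "traveling") 2.0 else 1.2
  structure(list(L = L, lambda = lambda, T_p = T_p,
                 a0 = a0, a1 = a1, a2 = a2, w_max = w_max,
                 wave_mode = wave_mode, swim_speed_bl = swim_speed_bl,
                 gamma0 = gamma0, r_c_blob = r_c_blob, kappa = kappa,
                 r_c_dip = r_c_dip,
                 tau_lag = if (is.null(tau_lag)) T_p / 12 else tau_lag,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "swimmer_params")
}

# Midline lateral displacement at body coordinate s (m from the nose)
# and time t.
swimmer_midline_y <- function(params, s, t) {
  A <- params$a0 + params$a1 * s + params$a2 * s^2
  if (params$wave_mode == "traveling")
    A * sin(2 * pi * (s / params$lambda - t / params$T_p))
  else
    A * sin(2 * pi * s / params$lambda) * cos(2 * pi * t / params$T_p)
}

# Closed body outline polyline (x, y) at time t; nose at the leading
# (+x) end, outline = midline offset by +/- the half-width profile
# along the midline normal, closed at nose and tail where w -> 0.
swimmer_outline <- function(params, t, x_nose0 = 0, y0 = 0, n_mid = 200L) {
  U <- params$swim_speed_bl * params$L
  x_nose <- x_nose0 + U * t
  s <- seq(0, params$L, length.out = n_mid)
  xm <- x_nose - s
  ym <- y0 + swimmer_midline_y(params, s, t)
  # midline tangents and normals (central differences)
  dx <- c(xm[2] - xm[1], xm[-(1:2)] - xm[-c(n_mid - 1, n_mid)] ,
          xm[n_mid] - xm[n_mid - 1])
  dy <- c(ym[2] - ym[1], ym[-(1:2)] - ym[-c(n_mid - 1, n_mid)],
          ym[n_mid] - ym[n_mid - 1])
  tl <- sqrt(dx^2 + dy^2)
  nxv <- -dy / tl; nyv <- dx / tl
  xi <- s / params$L
  w <- params$w_max * sqrt(pmax(0, 4 * xi * (1 - xi)))
  upper <- cbind(xm + w * nxv, ym + w * nyv)
  lower <- cbind(xm - w * nxv, ym - w * nyv)
  poly <- rbind(upper, lower[(n_mid - 1L):2, , drop = FALSE])
  colnames(poly) <- c("x", "y")
  poly
}

# Rasterise a closed polygon to a logical mask by even-odd scanline
# crossings.
rasterize_polygon <- function(poly, grid) {
  x <- grid_x(grid); y <- grid_y(grid)
  m <- matrix(FALSE, grid$ny, grid$nx)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (i in seq_len(grid$ny)) {
    yy <- y[i]
    crosses <- (py <= yy & y2 > yy) | (y2 <= yy & py > yy)
    if (!any(crosses)) next
    tt <- (yy - py[crosses]) / (y2[crosses] - py[crosses])
    xc <- sort(px[crosses] + tt * (x2[crosses] - px[crosses]))
    for (k in seq(1, length(xc) - 1, by = 2))
      m[i, x >= xc[k] & x <= xc[k + 1]] <- TRUE
  }
  m
}

#' Generate a synthetic undulatory-swimmer velocimetry dataset
#'
#' Builds, frame by frame, (i) the ground-truth body contour (midline
#' offset by the half-width profile, resampled to `n_points` control
#' points), (ii) the body mask rasterised from it, and (iii) a
#' divergence-free velocity field formed by superposing Gaussian-core
#' vortex blobs seeded at the contour segments. Each blob's
#' circulation is proportional to the local ground-truth body surface
#' rotation, `Gamma_i = gamma0 * BSR_i * ds_i` (clipped at
#' `3 gamma0`), so the near-body fluid rotation tracks the body
#' surface rotation as the no-slip condition dictates. In traveling
#' mode the blob pattern advances with the wave; in standing mode it
#' stays station-bound. The flow is kinematically prescribed, not a
#' Navier-Stokes solution: use it for qualitative pull-vs-push
#' contrasts and integration tests, not for quantitative pressure
#' accuracy (the analytic cases cover that).
#'
#' @param params A [swimmer_params()].
#' @param grid A [grid2d()] large enough to hold the body plus two
#'   body-widths of clearance over the whole swim.
#' @param dt Frame interval (s).
#' @param n_points Contour control points (default 60).
#' @return An object of class `synthetic_swimmer_dataset`: `velocity`,
#'   `masks`, `contours` (ground truth, one per frame), `bsr`
#'   (ground-truth per-point body surface rotation per frame),
#'   `u_body` (ground-truth surface velocity per frame), `params`,
#'   `grid`.
#' @export
synth_swimmer <- function(params, grid, dt, n_points = 60L) {
  x <- grid_x(grid); y <- grid_y(grid)
  times <- (seq_len(params$n_frames) - 1L) * dt
  U <- params$swim_speed_bl * params$L
  # start with the nose near the left + one quarter of the swim span,
  # leaving the downstream wake inside the domain
  x_nose0 <- x[1] + params$L + 4 * params$w_max
  Amax <- params$a0 + abs(params$a1) * params$L + abs(params$a2) * params$L^2
  clear <- 2 * (2 * params$w_max)
  if (x_nose0 + U * max(times) + clear > x[grid$nx] ||
      mean(range(y)) + Amax + params$w_max + clear > y[grid$ny])
    stop("body leaves domain: enlarge the grid or shorten the sequence")
  y0 <- mean(range(y))
  delta <- params$T_p * 1e-3
  contours <- vector("list", params$n_frames)
  masks <- vector("list", params$n_frames)
  frames <- vector("list", params$n_frames)
  bsr <- vector("list", params$n_frames)
  ubody <- vector("list", params$n_frames)
  for (k in seq_len(params$n_frames)) {
    t <- times[k]
    ctr <- function(tt) resample_contour(
      swimmer_outline(params, tt, x_nose0, y0), n = n_points, t = tt)
    c0 <- ctr(t)
    kin <- surface_kinematics(ctr(t - delta), c0, ctr(t + delta), delta)
    # circulations follow the body surface rotation with a formation
    # lag (boundary-layer vorticity takes time to build); the lag is
    # what makes uncoordinated flapping lossy instead of perfectly
    # energy-recovering
    tl <- t - params$tau_lag
    kin_lag <- if (params$tau_lag > 0)
      surface_kinematics(ctr(tl - delta), ctr(tl), ctr(tl + delta), delta)
    else kin
    contours[[k]] <- c0
    bsr[[k]] <- kin$bsr
    ubody[[k]] <- kin$u_body
    masks[[k]] <- rasterize_polygon(
      swimmer_outline(params, t, x_nose0, y0), grid)
    # blobs at segment midpoints, circulation from segment BSR
    n <- nrow(c0$points)
    mid <- (c0$points + c0$points[c(2:n, 1L), , drop = FALSE]) / 2
    gam <- params$gamma0 * kin$bsr_seg * c0$seg_lengths
    gam <- pmin(pmax(gam, -3 * params$gamma0), 3 * params$gamma0)
    uv <- blob_velocity(mid, gam, params$r_c_blob, grid)
    if (params$kappa != 0) {
      # lateral dipole elements: the pushing (acceleration-reaction)
      # near field of each element advancing at its normal velocity
      seg <- c0$points[c(2:n, 1L), , drop = FALSE] - c0$points
      sl <- sqrt(rowSums(seg^2))
      nrm <- cbind(seg[, 2], -seg[, 1]) / pmax(sl, .Machine$double.eps)
      ub_mid <- (kin_lag$u_body +
                   kin_lag$u_body[c(2:n, 1L), , drop = FALSE]) / 2
      vn <- ub_mid[, 1] * nrm[, 1] + ub_mid[, 2] * nrm[, 2]
      dv <- dipole_velocity(mid - params$r_c_dip * nrm, nrm * vn,
                            params$kappa * c0$seg_lengths * params$r_c_dip,
                            params$r_c_dip, grid)
      uv$u <- uv$u + dv$u
      uv$v <- uv$v + dv$v
    }
    frames[[k]] <- velocity_frame(grid, t, uv$u, uv$v, valid = !masks[[k]])
  }
  structure(list(velocity = velocity_sequence(frames),
                 masks = mask_sequence(grid, masks),
                 contours = contours, bsr = bsr, u_body = ubody,
                 params = params, grid = grid),
            class = "synthetic_swimmer_dataset")
}

# Regularized 2-D dipole (doublet) elements: the near field of a body
# element advancing laterally into the fluid at velocity V, i.e. the
# acceleration-reaction / pushing part of the flow. Streamfunction
# psi = C (V x r)_z (1 - exp(-r^2/r_c^2)) / r^2, differentiated
# analytically, so the field is exactly solenoidal.
dipole_velocity <- function(centers, vels, strengths, r_c, grid) {
  co <- grid_coords(grid)
  u <- matrix(0, grid$ny, grid$nx)
  v <- matrix(0, grid$ny, grid$nx)
  rc2 <- r_c^2
  for (b in seq_len(nrow(centers))) {
    if (strengths[b] == 0 ||
        (vels[b, 1] == 0 && vels[b, 2] == 0)) next
    X <- co$X - centers[b, 1]; Y <- co$Y - centers[b, 2]
    w <- X^2 + Y^2
    E <- exp(-w / rc2)
    small <- w < 1e-4 * rc2
    G <- (1 - E) / ifelse(small, 1, w)            # (1 - e^-q)/r^2
    Gp <- (E * w / rc2 - 1 + E) / ifelse(small, 1, w^2)
    G[small] <- 1 / rc2 - w[small] / (2 * rc2^2)
    Gp[small] <- -1 / (2 * rc2^2)
    Vx <- vels[b, 1]; Vy <- vels[b, 2]
    S <- Vx * Y - Vy * X
    C <- strengths[b]
    u <- u + C * (Vx * G + 2 * Y * S * Gp)
    v <- v - C * (-Vy * G + 2 * X * S * Gp)
  }
  list(u = u, v = v)
}

# Superpose Gaussian-core (Lamb-Oseen type) vortex blobs; exactly
# solenoidal since each blob is the curl of a streamfunction.
blob_velocity <- function(centers, gammas, r_c, grid) {
  co <- grid_coords(grid)
  u <- matrix(0, grid$ny, grid$nx)
  v <- matrix(0, grid$ny, grid$nx)
  for (b in seq_len(nrow(centers))) {
    if (gammas[b] == 0) next
    X <- co$X - centers[b, 1]; Y <- co$Y - centers[b, 2]
    r2 <- X^2 + Y^2
    fac <- gammas[b] / (2 * pi) * (1 - exp(-r2 / r_c^2)) /
      pmax(r2, .Machine$double.xmin)
    fac[r2 == 0] <- 0
    u <- u - fac * Y
    v <- v + fac * X
  }
  list(u = u, v = v)
}
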