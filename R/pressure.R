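#' Gauge-pressure frame
#'
#' @param grid A [grid2d()].
#' @param t Time (s).
#' @param p Gauge pressure (Pa; 0 = ambient), `(ny, nx)` matrix, NA
#'   where not computable.
#' @param valid Logical matrix: `TRUE` where the pressure was computed
#'   directly from at least `min_valid_paths` integration rays.
#' @param n_paths_used Integer matrix (0..8) of surviving rays.
#' @param filled Logical matrix flagging nodes recovered by
#'   nearest-valid interpolation rather than direct integration.
#' @export
pressure_frame <- function(grid, t, p, valid = NULL, n_paths_used = NULL,
                           filled = NULL) {
  check_shape(p, grid, "p")
  if (is.null(valid)) valid <- is.finite(p)
  if (is.null(n_paths_used)) n_paths_used <- matrix(8L, grid$ny, grid$nx)
  if (is.null(filled)) filled <- matrix(FALSE, grid$ny, grid$nx)
  structure(list(grid = grid, t = as.numeric(t), p = p, valid = valid,
                 n_paths_used = n_paths_used, filled = filled),
            class = "pressure_frame")
}

#' Material acceleration Du/Dt from three consecutive frames
#'
#' The unsteady term is a central difference in time at the middle
#' frame; the convective term uses second-order central differences in
#' space on the middle frame. Validity is the intersection of all
#' stencil nodes across the three frames.
#'
#' @param prev,curr,nxt Three consecutive [velocity_frame()]s on a
#'   common grid.
#' @param dt Inter-frame interval (s).
#' @return List with acceleration components `ax`, `ay` (m/s^2) and
#'   `valid`.
#' @export
material_acceleration <- function(prev, curr, nxt, dt) {
  if (!(dt > 0)) stop("dt must be > 0")
  g <- curr$grid
  if (!grids_equal(prev$grid, g) || !grids_equal(nxt$grid, g))
    stop("material_acceleration: frames on different grids")
  dudt <- (nxt$u - prev$u) / (2 * dt)
  dvdt <- (nxt$v - prev$v) / (2 * dt)
  dudx <- ddx_mat(curr$u, g$dx); dudy <- ddy_mat(curr$u, g$dy)
  dvdx <- ddx_mat(curr$v, g$dx); dvdy <- ddy_mat(curr$v, g$dy)
  ax <- dudt + curr$u * dudx + curr$v * dudy
  ay <- dvdt + curr$u * dvdx + curr$v * dvdy
  valid <- stencil_valid(curr$valid) & prev$valid & nxt$valid
  ax[!valid] <- NA_real_; ay[!valid] <- NA_real_
  list(ax = ax, ay = ay, valid = valid, grid = g, t = curr$t)
}

#' Pressure gradient from the planar momentum balance
#'
#' Evaluates `grad p = -rho * Du/Dt + mu * laplacian(u)` per node. The
#' Laplacian uses the 5-point stencil; validity requires the full
#' stencil plus the acceleration to be valid.
#'
#' @param accel Output of [material_acceleration()].
#' @param curr The middle [velocity_frame()] (for the viscous term).
#' @param fluid A [fluid_properties()].
#' @param include_viscous Include the viscous term (default TRUE).
#' @return List with components `gx`, `gy` (Pa/m), `valid`, `grid`, `t`.
#' @export
pressure_gradient <- function(accel, curr, fluid,
                              include_viscous = TRUE) {
  g <- accel$grid
  gx <- -fluid$rho * accel$ax
  gy <- -fluid$rho * accel$ay
  valid <- accel$valid
  if (include_viscous && fluid$mu > 0) {
    gx <- gx + fluid$mu * laplacian_mat(curr$u, g$dx, g$dy)
    gy <- gy + fluid$mu * laplacian_mat(curr$v, g$dx, g$dy)
    valid <- valid & stencil_valid(curr$valid)
  }
  gx[!valid] <- NA_real_; gy[!valid] <- NA_real_
  list(gx = gx, gy = gy, valid = valid, grid = g, t = accel$t)
}

# Integrate the pressure gradient along one of the eight ray
# directions. Each ray emanates from a node and terminates at the
# domain boundary; pressure is accumulated by the trapezoidal rule
# from the boundary (where it is known) inward, so p[node] =
# p[neighbour-toward-boundary] - avg(grad).step. Rays touching any
# invalid-gradient node are discarded (NA). `bnd` supplies boundary
# pressures (full-field matrix; only edge values are read).
ray_integral <- function(gx, gy, gvalid, dx, dy, dj, di, bnd) {
  ny <- nrow(gx); nx <- ncol(gx)
  p <- matrix(NA_real_, ny, nx)
  ok <- matrix(FALSE, ny, nx)
  gx0 <- gx; gy0 <- gy
  gx0[!gvalid] <- 0; gy0[!gvalid] <- 0   # never NA inside the sweep
  # seed the boundary sides the direction points to
  if (dj > 0) { p[, nx] <- bnd[, nx]; ok[, nx] <- gvalid[, nx] }
  if (dj < 0) { p[, 1]  <- bnd[, 1];  ok[, 1]  <- gvalid[, 1] }
  if (di > 0) { p[ny, ] <- bnd[ny, ]; ok[ny, ] <- gvalid[ny, ] }
  if (di < 0) { p[1, ]  <- bnd[1, ];  ok[1, ]  <- gvalid[1, ] }
  if (di == 0) {                       # pure E/W sweep, column by column
    cols <- if (dj > 0) (nx - 1):1 else 2:nx
    for (j in cols) {
      jn <- j + dj
      inc <- -0.5 * (gx0[, j] + gx0[, jn]) * dj * dx
      p[, j] <- p[, jn] + inc
      ok[, j] <- gvalid[, j] & ok[, jn]
    }
  } else if (dj == 0) {                # pure N/S sweep, row by row
    rows <- if (di > 0) (ny - 1):1 else 2:ny
    for (i in rows) {
      im <- i + di
      inc <- -0.5 * (gy0[i, ] + gy0[im, ]) * di * dy
      p[i, ] <- p[im, ] + inc
      ok[i, ] <- gvalid[i, ] & ok[im, ]
    }
  } else {                             # diagonal sweep, row wavefronts
    rows <- if (di > 0) (ny - 1):1 else 2:ny
    jj <- if (dj > 0) 1:(nx - 1) else 2:nx
    jn <- jj + dj
    for (i in rows) {
      im <- i + di
      inc <- -0.5 * ((gx0[i, jj] + gx0[im, jn]) * dj * dx +
                     (gy0[i, jj] + gy0[im, jn]) * di * dy)
      # the corner cell on the seeded edge keeps its boundary value
      p[i, jj] <- ifelse(is.na(p[i, jj]), p[im, jn] + inc, p[i, jj])
      ok[i, jj] <- gvalid[i, jj] & (ok[i, jj] | ok[im, jn])
    }
  }
  p[!ok] <- NA_real_
  p
}

#' Pressure by median-of-eight-path integration
#'
#' For every node, the pressure gradient is integrated along eight
#' straight rays (E, NE, N, NW, W, SW, S, SE along grid lines and
#' diagonals) running from the node to the edge of the field of view,
#' where the gauge pressure is taken as ambient (zero) unless
#' `boundary` supplies edge values. Rays crossing any invalid or masked
#' node are discarded; the node pressure is the median of the surviving
#' ray results (even counts average the two central values). Nodes with
#' fewer than `min_valid_paths` survivors are marked invalid and then
#' recovered by nearest-valid interpolation (`filled` flag).
#'
#' @param grad Output of [pressure_gradient()].
#' @param mask Optional logical body mask (`TRUE` = body interior).
#' @param config An [analysis_config()] (uses `min_valid_paths`).
#' @param boundary Optional `(ny, nx)` matrix whose edge values give
#'   the boundary gauge pressure (e.g. from an analytic far field);
#'   default ambient zero on all four edges.
#' @return A [pressure_frame()].
#' @export
integrate_pressure <- function(grad, mask = NULL,
                               config = analysis_config(),
                               boundary = NULL) {
  g <- grad$grid
  gvalid <- grad$valid
  if (!is.null(mask)) {
    check_shape(mask, g, "mask")
    gvalid <- gvalid & !mask
  }
  if (!any(gvalid)) stop("no computable nodes")
  bnd <- if (is.null(boundary)) matrix(0, g$ny, g$nx) else
    check_shape(boundary, g, "boundary")
  # centred stencils cannot reach the outermost node ring; close the
  # boundary ring by copying the gradient from the adjacent interior
  # node (first-order, affects one trapezoid step per ray)
  gx <- grad$gx; gy <- grad$gy
  er <- edge_ring_fill(gvalid, g$ny, g$nx)
  if (nrow(er) > 0) {
    gx[er[, 1:2, drop = FALSE]] <- gx[er[, 3:4, drop = FALSE]]
    gy[er[, 1:2, drop = FALSE]] <- gy[er[, 3:4, drop = FALSE]]
    gvalid[er[, 1:2, drop = FALSE]] <- TRUE
  }
  grad$gx <- gx; grad$gy <- gy
  dirs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  mats <- lapply(dirs, function(d)
    ray_integral(grad$gx, grad$gy, gvalid, g$dx, g$dy, d[1], d[2], bnd))
  arr <- do.call(cbind, lapply(mats, as.vector))
  n_used <- rowSums(!is.na(arr))
  pv <- rep(NA_real_, length(n_used))
  has <- n_used > 0L
  pv[has] <- row_medians(arr[has, , drop = FALSE])
  p <- matrix(pv, g$ny, g$nx)
  n_paths <- matrix(as.integer(n_used), g$ny, g$nx)
  valid <- n_paths >= config$min_valid_paths
  p[!valid] <- NA_real_
  # recover unmasked holes (e.g. ray shadows) by neighbour-mean fill
  body <- if (is.null(mask)) matrix(FALSE, g$ny, g$nx) else mask
  filled <- matrix(FALSE, g$ny, g$nx)
  hole <- !valid & !body
  while (any(hole)) {
    have <- is.finite(p)
    nbr_sum <- shift_mat(ifelse(have, p, 0), 0L, 1L, 0) +
      shift_mat(ifelse(have, p, 0), 0L, -1L, 0) +
      shift_mat(ifelse(have, p, 0), 1L, 0L, 0) +
      shift_mat(ifelse(have, p, 0), -1L, 0L, 0)
    nbr_n <- shift_mat(have * 1, 0L, 1L, 0) + shift_mat(have * 1, 0L, -1L, 0) +
      shift_mat(have * 1, 1L, 0L, 0) + shift_mat(have * 1, -1L, 0L, 0)
    doable <- hole & nbr_n > 0
    if (!any(doable)) break
    p[doable] <- (nbr_sum / pmax(nbr_n, 1))[doable]
    filled[doable] <- TRUE
    hole <- hole & !doable
  }
  # pockets fully enclosed by the mask cannot be reached by neighbour
  # diffusion: take the euclidean-nearest directly computed node
  if (any(hole)) {
    src <- valid & is.finite(p)
    if (any(src)) {
      si <- which(src, arr.ind = TRUE)
      hi <- which(hole, arr.ind = TRUE)
      sp <- p[src]
      for (m in seq_len(nrow(hi))) {
        d2 <- (si[, 1] - hi[m, 1])^2 * g$dy^2 + (si[, 2] - hi[m, 2])^2 * g$dx^2
        p[hi[m, 1], hi[m, 2]] <- sp[which.min(d2)]
      }
      filled[hole] <- TRUE
    }
  }
  pressure_frame(g, grad$t, p, valid = valid, n_paths_used = n_paths,
                 filled = filled)
}

#' Pressure by a Poisson solve (validation oracle)
#'
#' Independent route to the same field: solves
#' `laplacian(p) = div(grad p)` on valid nodes, with Dirichlet ambient
#' (or supplied) pressure on the domain edges and a Neumann closure
#' `dp/dn = g . n` on faces adjacent to masked nodes, by a direct
#' sparse solve. Intended for cross-checking the path-integration
#' solver in tests, not as the production path.
#'
#' @inheritParams integrate_pressure
#' @return A [pressure_frame()] (`n_paths_used` is reported as 8 on
#'   solved nodes).
#' @export
poisson_pressure_oracle <- function(grad, mask = NULL, boundary = NULL) {
  g <- grad$grid; ny <- g$ny; nx <- g$nx
  gvalid <- grad$valid
  if (!is.null(mask)) gvalid <- gvalid & !check_shape(mask, g, "mask")
  bnd <- if (is.null(boundary)) matrix(0, ny, nx) else
    check_shape(boundary, g, "boundary")
  edge <- matrix(FALSE, ny, nx)
  edge[1, ] <- TRUE; edge[ny, ] <- TRUE; edge[, 1] <- TRUE; edge[, nx] <- TRUE
  unknown <- gvalid & !edge
  if (!any(edge)) stop("ill-posed: no Dirichlet nodes")
  idx <- matrix(0L, ny, nx)
  idx[unknown] <- seq_len(sum(unknown))
  n <- sum(unknown)
  if (n == 0L) stop("no computable nodes")
  gx0 <- grad$gx; gy0 <- grad$gy
  gx0[!gvalid] <- 0; gy0[!gvalid] <- 0
  # divergence of the gradient field: central where possible, one-sided
  # next to invalid nodes
  dgx <- one_sided_ddx(gx0, gvalid, g$dx)
  dgy <- one_sided_ddy(gy0, gvalid, g$dy)
  rhs_field <- dgx + dgy
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(n)
  where <- which(unknown, arr.ind = TRUE)
  i0 <- where[, 1]; j0 <- where[, 2]
  rows <- idx[unknown]
  b <- rhs_field[unknown]
  diag_coef <- numeric(n)
  add_dir <- function(di, dj, h, gcomp) {
    i1 <- i0 + di; j1 <- j0 + dj
    nb_lin <- cbind(i1, j1)
    nb_unknown <- unknown[nb_lin]
    nb_edge <- edge[nb_lin]
    # unknown neighbour: off-diagonal entry
    sel <- nb_unknown
    if (any(sel)) {
      ii <<- c(ii, rows[sel]); jj <<- c(jj, idx[nb_lin][sel])
      vv <<- c(vv, rep(1 / h^2, sum(sel)))
      diag_coef[sel] <<- diag_coef[sel] - 1 / h^2
    }
    # Dirichlet edge neighbour: boundary pressure is known there
    sel <- nb_edge
    if (any(sel)) {
      b[rows[sel]] <<- b[rows[sel]] - bnd[nb_lin][sel] / h^2
      diag_coef[sel] <<- diag_coef[sel] - 1 / h^2
    }
    # invalid interior neighbour (mask or dropout): Neumann closure
    # using the gradient component at the node itself
    sel <- !nb_unknown & !nb_edge
    if (any(sel)) {
      gdir <- gcomp[cbind(i0, j0)][sel] * (di + dj)  # signed component
      b[rows[sel]] <<- b[rows[sel]] - gdir / h
    }
    invisible(NULL)
  }
  add_dir(0L, 1L, g$dx, gx0)
  add_dir(0L, -1L, g$dx, gx0)
  add_dir(1L, 0L, g$dy, gy0)
  add_dir(-1L, 0L, g$dy, gy0)
  ii <- c(ii, rows); jj <- c(jj, rows); vv <- c(vv, diag_coef)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, b))
  p <- matrix(NA_real_, ny, nx)
  p[unknown] <- sol
  p[edge & gvalid] <- bnd[edge & gvalid]
  valid <- gvalid
  pressure_frame(g, grad$t, p, valid = valid)
}

# Domain-edge ring nodes with an invalid gradient but a valid inward
# neighbour: returns a matrix of (i, j, i_src, j_src) rows.
edge_ring_fill <- function(gvalid, ny, nx) {
  out <- matrix(0L, 0L, 4L)
  add <- function(i, j, is, js) {
    sel <- !gvalid[cbind(i, j)] & gvalid[cbind(is, js)]
    if (any(sel)) out <<- rbind(out, cbind(i, j, is, js)[sel, , drop = FALSE])
  }
  jmid <- 2:(nx - 1L); imid <- 2:(ny - 1L)
  add(rep(1L, nx - 2L), jmid, rep(2L, nx - 2L), jmid)
  add(rep(ny, nx - 2L), jmid, rep(ny - 1L, nx - 2L), jmid)
  add(imid, rep(1L, ny - 2L), imid, rep(2L, ny - 2L))
  add(imid, rep(nx, ny - 2L), imid, rep(nx - 1L, ny - 2L))
  add(c(1L, 1L, ny, ny), c(1L, nx, 1L, nx),
      c(2L, 2L, ny - 1L, ny - 1L), c(2L, nx - 1L, 2L, nx - 1L))
  out
}

one_sided_ddx <- function(m, valid, dx) {
  mp <- shift_mat(m, 0L, -1L); mm <- shift_mat(m, 0L, 1L)
  vp <- shift_mat(valid, 0L, -1L, FALSE); vm <- shift_mat(valid, 0L, 1L, FALSE)
  out <- matrix(0, nrow(m), ncol(m))
  both <- vp & vm; out[both] <- ((mp - mm) / (2 * dx))[both]
  onlyp <- vp & !vm; out[onlyp] <- ((mp - m) / dx)[onlyp]
  onlym <- vm & !vp; out[onlym] <- ((m - mm) / dx)[onlym]
  out
}

one_sided_ddy <- function(m, valid, dy) {
  mp <- shift_mat(m, -1L, 0L); mm <- shift_mat(m, 1L, 0L)
  vp <- shift_mat(valid, -1L, 0L, FALSE); vm <- shift_mat(valid, 1L, 0L, FALSE)
  out <- matrix(0, nrow(m), ncol(m))
  both <- vp & vm; out[both] <- ((mp - mm) / (2 * dy))[both]
  onlyp <- vp & !vm; out[onlyp] <- ((mp - m) / dy)[onlyp]
  onlym <- vm & !vp; out[onlym] <- ((m - mm) / dy)[onlym]
  out
}

#' Pressure fields for a whole velocity sequence
#'
#' Runs [material_acceleration()], [pressure_gradient()] and
#' [integrate_pressure()] for every frame with a centred temporal
#' stencil (the first and last frames are not emitted).
#'
#' @param seq A [velocity_sequence()] with at least 3 frames.
#' @param masks Optional [mask_sequence()] aligned with `seq`.
#' @param fluid A [fluid_properties()].
#' @param config An [analysis_config()].
#' @param boundary Optional boundary pressure: a matrix reused for all
#'   frames, or a list of matrices (one per emitted frame).
#' @return List of [pressure_frame()]s, length `length(seq$frames) - 2`.
#' @export
pressure_sequence <- function(seq, masks = NULL, fluid = fluid_properties(),
                              config = analysis_config(), boundary = NULL) {
  nf <- length(seq$frames)
  if (nf < 3L) stop(">=3 frames required")
  if (!is.null(masks) && length(masks$frames) != nf)
    stop("mask/velocity frame count mismatch")
  out <- vector("list", nf - 2L)
  for (k in 2:(nf - 1L)) {
    acc <- material_acceleration(seq$frames[[k - 1]], seq$frames[[k]],
                                 seq$frames[[k + 1]], seq$dt)
    grd <- pressure_gradient(acc, seq$frames[[k]], fluid,
                             include_viscous = config$include_viscous)
    msk <- if (is.null(masks)) NULL else masks$frames[[k]]
    bnd <- if (is.list(boundary)) boundary[[k - 1L]] else boundary
    out[[k - 1L]] <- integrate_pressure(grd, msk, config, bnd)
  }
  out
}
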