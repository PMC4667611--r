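#' Extract the body boundary from a mask frame
#'
#' Traces the solid-fluid interface as the 0.5 iso-contour of the 0/1
#' body raster, giving a sub-cell polyline. The mask must contain
#' exactly one connected body component (8-connectivity) of at least 20
#' cells, fully inside the field of view.
#'
#' @param mask Logical `(ny, nx)` matrix, `TRUE` inside the body.
#' @param grid The [grid2d()] the mask lives on.
#' @return A two-column matrix of boundary points (x, y) in metres,
#'   counterclockwise, closed (first point not repeated).
#' @export
extract_contour <- function(mask, grid) {
  check_shape(mask, grid, "mask")
  storage.mode(mask) <- "logical"
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= 20L)
  if (length(big) != 1L)
    stop("ambiguous body: expected exactly one component of >= 20 cells, found ",
         length(big))
  # drop sub-threshold debris (e.g. rasterisation slivers at a tapering
  # tail) before tracing
  if (length(sizes) > 1L) mask <- lab == big
  if (any(mask[1, ]) || any(mask[grid$ny, ]) ||
      any(mask[, 1]) || any(mask[, grid$nx]))
    stop("body clipped: mask touches the domain edge")
  cl <- grDevices::contourLines(x = grid_x(grid), y = grid_y(grid),
                                z = t(mask * 1), levels = 0.5)
  if (length(cl) == 0L) stop("ambiguous body: no boundary found")
  # outermost boundary = the longest contour (holes are shorter)
  len <- vapply(cl, function(c) sum(sqrt(diff(c$x)^2 + diff(c$y)^2)),
                numeric(1))
  c1 <- cl[[which.max(len)]]
  pts <- cbind(x = c1$x, y = c1$y)
  n <- nrow(pts)
  if (n > 1L && all(pts[1, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Signed area (shoelace); positive for counterclockwise rings.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Resample a closed boundary to equally spaced control points
#'
#' Produces `n` control points at equal arc-length spacing around the
#' closed boundary (default 60), anchored so that point 1 sits at the
#' anterior-most vertex, i.e. the vertex of maximum projection on the
#' swimming direction (`s_hat`; +x when no swim frame is available
#' yet). Counterclockwise orientation is enforced, outward unit normals
#' are computed from adjacent-point tangents, and `seg_lengths[i]` is
#' the distance from point i to point i+1 (segment `n` closes the
#' ring).
#'
#' @param polyline Two-column (x, y) matrix of boundary vertices
#'   (closed ring, >= 4 vertices; a repeated end point is tolerated).
#' @param n Number of control points (default 60).
#' @param t Time stamp carried on the contour (s).
#' @param s_hat Anchoring direction, default `c(1, 0)`.
#' @return An object of class `body_contour` with elements `points`
#'   (n x 2), `normals` (n x 2, outward), `seg_lengths`, `t`.
#' @export
resample_contour <- function(polyline, n = 60L, t = 0, s_hat = c(1, 0)) {
  p <- as.matrix(polyline)
  m <- nrow(p)
  if (m > 1L && all(p[1, ] == p[m, ])) { p <- p[-m, , drop = FALSE]; m <- m - 1L }
  if (m < 4L) stop("resample_contour: need a closed polyline with >= 4 vertices")
  if (polygon_area(p) < 0) p <- p[rev(seq_len(m)), , drop = FALSE]
  # rotate vertex order so the ring starts at the anterior-most vertex
  proj <- p %*% s_hat
  k <- which.max(proj)
  p <- p[c(k:m, seq_len(k - 1L)), , drop = FALSE]
  seg <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
  ds <- sqrt(rowSums(seg^2))
  if (all(ds < .Machine$double.eps)) stop("resample_contour: degenerate polyline")
  s <- c(0, cumsum(ds))
  per <- s[m + 1L]
  target <- per * (seq_len(n) - 1L) / n
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (target - s[idx]) / pmax(ds[idx], .Machine$double.eps)
  pts <- p[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  segs <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
  seg_len <- sqrt(rowSums(segs^2))
  # tangent at point i from its neighbours; outward normal for a CCW
  # ring is the tangent rotated -90 degrees
  prv <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  tang <- nxt - prv
  tl <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tl, .Machine$double.eps)
  normals <- cbind(tang[, 2], -tang[, 1])
  structure(list(points = pts, normals = normals, seg_lengths = seg_len,
                 t = as.numeric(t)),
            class = "body_contour")
}

#' @export
print.body_contour <- function(x, ...) {
  cat(sprintf("body_contour: %d control points, perimeter %.4g m, t = %g s\n",
              nrow(x$points), sum(x$seg_lengths), x$t))
  invisible(x)
}

# Element area weights at control points: mean of the two adjacent
# segment lengths (per unit depth in planar mode).
point_ds <- function(contour) {
  ds <- contour$seg_lengths
  n <- length(ds)
  (ds + ds[c(n, seq_len(n - 1L))]) / 2
}

#' Surface velocity and body surface rotation from a contour triple
#'
#' Computes, for the middle frame, the surface velocity `u_body` of
#' every control point (central difference of positions) and the body
#' surface rotation BSR of every segment: the lab-frame angular
#' velocity of the line segment connecting adjacent control points,
#' obtained by central-differencing the segment angle with jumps
#' larger than pi unwrapped by 2 pi. Point-level BSR is the mean of
#' the two adjacent segments.
#'
#' @param prev,curr,nxt [resample_contour()] outputs at consecutive
#'   frames with identical point counts (index correspondence is by
#'   arc-length anchor, not tracking).
#' @param dt Frame interval (s).
#' @return List with `u_body` (n x 2, m/s), `bsr_seg` (n, rad/s, one
#'   per segment), `bsr` (n, rad/s at points).
#' @export
surface_kinematics <- function(prev, curr, nxt, dt) {
  if (!(dt > 0)) stop("dt must be > 0")
  n <- nrow(curr$points)
  if (nrow(prev$points) != n || nrow(nxt$points) != n)
    stop("surface_kinematics: control point counts differ")
  u_body <- (nxt$points - prev$points) / (2 * dt)
  ang <- function(c) {
    s <- rbind(c$points[-1, , drop = FALSE], c$points[1, , drop = FALSE]) -
      c$points
    atan2(s[, 2], s[, 1])
  }
  dth <- wrap_angle(ang(nxt) - ang(prev))
  bsr_seg <- dth / (2 * dt)
  bsr <- (bsr_seg + bsr_seg[c(n, seq_len(n - 1L))]) / 2
  list(u_body = u_body, bsr_seg = bsr_seg, bsr = bsr, t = curr$t)
}

#' Fluid vorticity field
#'
#' `omega = dv/dx - du/dy` by second-order central differences. Nodes
#' whose stencil touches any invalid velocity node are marked invalid
#' (no one-sided fallback), so near-body values are never contaminated
#' by masked nodes.
#'
#' @param frame A [velocity_frame()].
#' @return List with `omega` (1/s) and `valid`.
#' @export
vorticity_field <- function(frame) {
  g <- frame$grid
  omega <- ddx_mat(frame$v, g$dx) - ddy_mat(frame$u, g$dy)
  valid <- stencil_valid(frame$valid)
  omega[!valid] <- NA_real_
  list(omega = omega, valid = valid, grid = g, t = frame$t)
}

#' Body surface vorticity
#'
#' For each control point, the fluid vorticity at the nearest valid
#' grid node, searched within a 4-cell radius; points with no valid
#' node in reach are flagged (`NA`).
#'
#' @param contour A [resample_contour()] output.
#' @param vort A [vorticity_field()] output.
#' @param max_cells Search radius cap in grid cells (default 4).
#' @return Numeric vector of per-point vorticity (1/s), NA where
#'   unreachable.
#' @export
body_surface_vorticity <- function(contour, vort, max_cells = 4) {
  g <- vort$grid
  x <- grid_x(g); y <- grid_y(g)
  n <- nrow(contour$points)
  out <- rep(NA_real_, n)
  r2max <- (max_cells * max(g$dx, g$dy))^2
  for (i in seq_len(n)) {
    px <- contour$points[i, 1]; py <- contour$points[i, 2]
    jc <- round((px - g$origin[1]) / g$dx) + 1
    ic <- round((py - g$origin[2]) / g$dy) + 1
    jr <- max(1, jc - max_cells):min(g$nx, jc + max_cells)
    ir <- max(1, ic - max_cells):min(g$ny, ic + max_cells)
    if (length(jr) == 0L || length(ir) == 0L) next
    sub_v <- vort$valid[ir, jr, drop = FALSE]
    if (!any(sub_v)) next
    d2 <- outer((y[ir] - py)^2, (x[jr] - px)^2, "+")
    d2[!sub_v] <- Inf
    k <- which.min(d2)
    if (d2[k] > r2max) next
    out[i] <- vort$omega[ir, jr, drop = FALSE][k]
  }
  out
}

#' Normalise a per-point body quantity by its on-body maximum
#'
#' Divides by the maximum absolute value over the (non-NA) points,
#' giving values in [-1, 1]; used for BSR and BSV maps.
#'
#' @param x Numeric vector.
#' @return Rescaled vector (all-zero input is returned unchanged).
#' @export
normalize_on_body <- function(x) {
  m <- max(abs(x), na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(x)
  x / m
}

#' Swimming frame: direction, lateral axis and mean speed
#'
#' Fits a least-squares line through the per-frame body centroids to
#' obtain the swimming direction `s_hat` (oriented along the net
#' displacement), takes `j_hat` as `s_hat` rotated +90 degrees, and
#' estimates the mean speed `U` as the net centroid displacement
#' projected on `s_hat` over the elapsed time. Body length is the mean
#' extent of the contour along `s_hat`.
#'
#' @param contours List of [resample_contour()] outputs (>= 3 frames).
#' @param dt Frame interval (s).
#' @param mode `"auto"` (fit the direction) or `"fixed"`.
#' @param fixed_vector Direction used when `mode = "fixed"`.
#' @param min_displacement Net displacement below which `"auto"` mode
#'   refuses to define a direction (m); default `0.1 *` mean contour
#'   segment length.
#' @return An object of class `swim_frame` with `s_hat`, `j_hat`, `U`
#'   (m/s), `U_bl` (body lengths / s), `body_length` (m).
#' @export
swim_frame <- function(contours, dt, mode = c("auto", "fixed"),
                       fixed_vector = c(1, 0), min_displacement = NULL) {
  mode <- match.arg(mode)
  if (length(contours) < 3L) stop(">=3 frames required")
  cent <- t(vapply(contours, function(c) polygon_centroid(c$points),
                   numeric(2)))
  disp <- cent[nrow(cent), ] - cent[1, ]
  if (is.null(min_displacement))
    min_displacement <- 0.1 * mean(contours[[1]]$seg_lengths)
  if (mode == "fixed") {
    s_hat <- fixed_vector / sqrt(sum(fixed_vector^2))
  } else {
    if (sqrt(sum(disp^2)) < min_displacement)
      stop("stationary body: direction undefined")
    cc <- sweep(cent, 2, colMeans(cent))
    ev <- eigen(crossprod(cc), symmetric = TRUE)
    s_hat <- ev$vectors[, 1]
    if (sum(s_hat * disp) < 0) s_hat <- -s_hat
  }
  j_hat <- c(-s_hat[2], s_hat[1])
  elapsed <- (length(contours) - 1L) * dt
  U <- max(0, sum(disp * s_hat) / elapsed)
  bl <- mean(vapply(contours, function(c) {
    pr <- c$points %*% s_hat
    max(pr) - min(pr)
  }, numeric(1)))
  structure(list(s_hat = s_hat, j_hat = j_hat, U = U,
                 U_bl = U / bl, body_length = bl),
            class = "swim_frame")
}

#' @export
print.swim_frame <- function(x, ...) {
  cat(sprintf(
    "swim_frame: s_hat = (%.3f, %.3f), U = %.4g m/s (%.3g BL/s), L = %.4g m\n",
    x$s_hat[1], x$s_hat[2], x$U, x$U_bl, x$body_length))
  invisible(x)
}
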