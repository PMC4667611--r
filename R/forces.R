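# Bilinear interpolation of a gridded field at arbitrary points,
# honouring validity: a point resolves only if all four surrounding
# nodes are valid. Returns NA otherwise.
bilinear_sample <- function(p, valid, grid, xy) {
  fx <- (xy[, 1] - grid$origin[1]) / grid$dx
  fy <- (xy[, 2] - grid$origin[2]) / grid$dy
  j0 <- floor(fx) + 1; i0 <- floor(fy) + 1
  out <- rep(NA_real_, nrow(xy))
  ok <- j0 >= 1 & j0 + 1 <= grid$nx & i0 >= 1 & i0 + 1 <= grid$ny
  if (!any(ok)) return(out)
  j0 <- j0[ok]; i0 <- i0[ok]
  tx <- fx[ok] - (j0 - 1); ty <- fy[ok] - (i0 - 1)
  c00 <- cbind(i0, j0); c01 <- cbind(i0, j0 + 1)
  c10 <- cbind(i0 + 1, j0); c11 <- cbind(i0 + 1, j0 + 1)
  vv <- valid[c00] & valid[c01] & valid[c10] & valid[c11]
  val <- (1 - tx) * (1 - ty) * p[c00] + tx * (1 - ty) * p[c01] +
    (1 - tx) * ty * p[c10] + tx * ty * p[c11]
  val[!vv] <- NA_real_
  out[ok] <- val
  out
}

#' Sample surface pressure at the body control points
#'
#' Evaluates the pressure at each control point displaced outward
#' along its normal by `offset` grid cells (bilinear interpolation;
#' exact on linear fields). Sampling off the surface avoids
#' mask-adjacent nodes whose stencils are damaged. Points that land on
#' invalid nodes are retried stepping outward in half-cell increments
#' up to `offset + 2` cells; still-unresolved elements are returned as
#' NA (and excluded downstream). More than 20% unresolved elements is
#' an error.
#'
#' @param pressure A [pressure_frame()].
#' @param contour A [resample_contour()] output on the same frame.
#' @param offset Outward sampling offset in grid cells (default 2).
#' @return Numeric vector of per-element gauge pressures (Pa) with an
#'   attribute `n_unresolved`.
#' @export
sample_surface_pressure <- function(pressure, contour, offset = 2) {
  g <- pressure$grid
  n <- nrow(contour$points)
  usable <- pressure$valid | pressure$filled
  usable <- usable & is.finite(pressure$p)
  p <- pressure$p
  p[!usable] <- NA_real_
  out <- rep(NA_real_, n)
  for (off in seq(offset, offset + 2, by = 0.5)) {
    todo <- is.na(out)
    if (!any(todo)) break
    xy <- contour$points[todo, , drop = FALSE] +
      off * g$dx * contour$normals[todo, , drop = FALSE]
    out[todo] <- bilinear_sample(p, usable, g, xy)
  }
  n_un <- sum(is.na(out))
  if (n_un > 0.2 * n)
    stop(sprintf("surface sampling failure: %d of %d elements unresolved",
                 n_un, n))
  attr(out, "n_unresolved") <- n_un
  out
}

#' Four-component pull/push force decomposition
#'
#' Each surface element carries the pressure force
#' `f_i = -p_i n_i dA_i` (outward normal `n_i`), classified by the
#' sign pair (pressure, thrust-axis force component): low pressure
#' pulling the body forward is `forward_pull`, low pressure pulling it
#' rearward `rearward_pull`, high pressure pushing forward
#' `forward_push`, high pressure pushing rearward `rearward_push`;
#' elements with exactly zero pressure or zero axial component are
#' `neutral`. Integrated magnitudes satisfy
#' `gross_thrust = F_fpull + F_fpush`,
#' `gross_drag = F_rpull + F_rpush`, and
#' `net_thrust = gross_thrust - gross_drag` exactly.
#'
#' In planar mode `dA_i = ds_i` and forces are per unit depth (N/m);
#' in axisymmetric mode the contour is a meridional half-profile
#' revolved about the symmetry axis, `dA_i = 2 pi r_i ds_i`, and
#' forces are in Newtons. The profile must not cross the axis, and
#' must be ordered so the body interior lies to the left of travel
#' (normals from the -90 degree tangent rotation then point into the
#' fluid).
#'
#' @param p_elems Per-element pressures from
#'   [sample_surface_pressure()] (NA elements are dropped).
#' @param contour A [resample_contour()] output (closed ring in planar
#'   mode; open meridional profile in axisymmetric mode).
#' @param frame A [swim_frame()] (supplies the thrust axis `s_hat`).
#' @param mode `"planar"` or `"axisymmetric"`.
#' @param axis For axisymmetric mode: list with `point` and unit
#'   `direction` defining the symmetry axis; defaults to the line
#'   through the profile's first point along `s_hat`.
#' @param dead_band Pressures with `|p| <= dead_band` count as neutral
#'   (default 0: the classification threshold is exactly ambient).
#' @return An object of class `force_decomposition`: per-element table
#'   `elements` (x, y, p, fx, fy, dA, f_s, class) and scalars
#'   `F_fpull`, `F_rpull`, `F_fpush`, `F_rpush`, `gross_thrust`,
#'   `gross_drag`, `net_thrust`, `t`, `units`.
#' @export
decompose_forces <- function(p_elems, contour, frame,
                             mode = c("planar", "axisymmetric"),
                             axis = NULL, dead_band = 0) {
  mode <- match.arg(mode)
  n <- nrow(contour$points)
  if (length(p_elems) != n) stop("p_elems length != control point count")
  s_hat <- frame$s_hat
  if (mode == "planar") {
    dA <- point_ds(contour)
    normals <- contour$normals
  } else {
    if (is.null(axis))
      axis <- list(point = contour$points[1, ], direction = s_hat)
    d <- axis$direction / sqrt(sum(axis$direction^2))
    rel <- sweep(contour$points, 2, axis$point)
    # signed lateral offset from the axis
    r_sgn <- rel[, 1] * (-d[2]) + rel[, 2] * d[1]
    if (min(r_sgn) < -1e-12 * max(abs(r_sgn)) && max(r_sgn) > 1e-12 * max(abs(r_sgn)))
      stop("invalid meridian: profile crosses the symmetry axis")
    r_i <- abs(r_sgn)
    ds <- open_point_ds(contour)
    dA <- 2 * pi * r_i * ds
    normals <- contour$normals
  }
  fx <- -p_elems * normals[, 1] * dA
  fy <- -p_elems * normals[, 2] * dA
  f_s <- fx * s_hat[1] + fy * s_hat[2]
  cls <- rep("neutral", n)
  use <- !is.na(p_elems)
  low <- use & p_elems < -dead_band
  high <- use & p_elems > dead_band
  cls[low & f_s > 0] <- "forward_pull"
  cls[low & f_s < 0] <- "rearward_pull"
  cls[high & f_s > 0] <- "forward_push"
  cls[high & f_s < 0] <- "rearward_push"
  sum_cls <- function(k) sum(abs(f_s[cls == k]))
  F_fpull <- sum_cls("forward_pull"); F_rpull <- sum_cls("rearward_pull")
  F_fpush <- sum_cls("forward_push"); F_rpush <- sum_cls("rearward_push")
  gross_thrust <- F_fpull + F_fpush
  gross_drag <- F_rpull + F_rpush
  structure(list(
    elements = data.frame(x = contour$points[, 1], y = contour$points[, 2],
                          p = p_elems, fx = fx, fy = fy, dA = dA,
                          f_s = f_s, class = cls),
    F_fpull = F_fpull, F_rpull = F_rpull,
    F_fpush = F_fpush, F_rpush = F_rpush,
    gross_thrust = gross_thrust, gross_drag = gross_drag,
    net_thrust = gross_thrust - gross_drag,
    t = contour$t,
    units = if (mode == "planar") "N/m" else "N"),
    class = "force_decomposition")
}

# Element weights for an open profile: half segments at the ends.
open_point_ds <- function(contour) {
  pts <- contour$points
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  c(seg[1] / 2, (seg[-1] + seg[-(n - 1)]) / 2, seg[n - 1] / 2)
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat(sprintf(
    "force_decomposition (t = %g s, %s):\n  fpull %.4g  rpull %.4g  fpush %.4g  rpush %.4g  net %.4g\n",
    x$t, x$units, x$F_fpull, x$F_rpull, x$F_fpush, x$F_rpush, x$net_thrust))
  invisible(x)
}

#' Cycle-averaged force summary
#'
#' Trapezoidal time averages of the four force components over an
#' integer number of undulation cycles, plus the pull fractions: the
#' share of time-averaged gross thrust carried by forward pull and of
#' gross drag carried by rearward pull.
#'
#' @param decomps List of [decompose_forces()] outputs in time order.
#' @param cycle_bounds Optional `c(t0, t1)` window; default the full
#'   span of `decomps`.
#' @return List with time-averaged components, `pull_thrust_fraction`,
#'   `pull_drag_fraction`, `net_thrust_mean`, and the window used.
#' @export
summarize_cycle <- function(decomps, cycle_bounds = NULL) {
  tt <- vapply(decomps, function(d) d$t, numeric(1))
  if (!is.null(cycle_bounds)) {
    keep <- tt >= cycle_bounds[1] - 1e-12 & tt <= cycle_bounds[2] + 1e-12
    if (!any(keep)) stop("empty cycle window")
    decomps <- decomps[keep]; tt <- tt[keep]
  }
  comp <- function(f) vapply(decomps, function(d) d[[f]], numeric(1))
  avg <- function(y) trapz_mean(tt, y)
  F_fpull <- avg(comp("F_fpull")); F_rpull <- avg(comp("F_rpull"))
  F_fpush <- avg(comp("F_fpush")); F_rpush <- avg(comp("F_rpush"))
  gt <- F_fpull + F_fpush; gd <- F_rpull + F_rpush
  list(F_fpull = F_fpull, F_rpull = F_rpull,
       F_fpush = F_fpush, F_rpush = F_rpush,
       gross_thrust = gt, gross_drag = gd,
       net_thrust_mean = gt - gd,
       pull_thrust_fraction = if (gt > 0) F_fpull / gt else NA_real_,
       pull_drag_fraction = if (gd > 0) F_rpull / gd else NA_real_,
       window = range(tt))
}
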