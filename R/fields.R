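#' Velocity snapshot on a regular grid
#'
#' A single gridded velocimetry frame. Nodes carrying non-finite
#' velocities are demoted to `valid = FALSE` and their components set
#' to zero, so downstream arithmetic never meets NaN: the solver treats
#' validity, not magic values, as the usability signal. Body-interior
#' and velocimetry-dropout nodes are not distinguished here.
#'
#' @param grid A [grid2d()].
#' @param t Time stamp in seconds.
#' @param u,v Velocity components (m/s), matrices shaped `(ny, nx)`.
#' @param valid Optional logical matrix; defaults to all-`TRUE`.
#' @return An object of class `velocity_frame`.
#' @export
velocity_frame <- function(grid, t, u, v, valid = NULL) {
  check_shape(u, grid, "u"); check_shape(v, grid, "v")
  if (is.null(valid)) valid <- matrix(TRUE, grid$ny, grid$nx)
  check_shape(valid, grid, "valid")
  bad <- !is.finite(u) | !is.finite(v)
  valid <- valid & !bad
  u[bad] <- 0; v[bad] <- 0
  structure(list(grid = grid, t = as.numeric(t), u = u, v = v,
                 valid = valid),
            class = "velocity_frame")
}

#' Time-resolved velocity sequence
#'
#' @param frames List of [velocity_frame()]s on a common grid, in time
#'   order. Sampling must be uniform: inter-frame intervals may deviate
#'   from their mean by at most 1e-9 s.
#' @return An object of class `velocity_sequence` with elements
#'   `frames`, `dt`, and `grid`.
#' @export
velocity_sequence <- function(frames) {
  if (length(frames) < 1L) stop("velocity_sequence: no frames")
  times <- vapply(frames, function(f) f$t, numeric(1))
  ord <- order(times)
  frames <- frames[ord]; times <- times[ord]
  g <- frames[[1]]$grid
  for (f in frames) if (!grids_equal(f$grid, g))
    stop("velocity_sequence: frames on different grids")
  dt <- if (length(frames) > 1L) mean(diff(times)) else NA_real_
  if (length(frames) > 2L && max(abs(diff(times) - dt)) > 1e-9)
    stop("non-uniform sampling: frame intervals differ by more than 1e-9 s")
  structure(list(frames = frames, dt = dt, grid = g),
            class = "velocity_sequence")
}

#' @export
print.velocity_sequence <- function(x, ...) {
  cat(sprintf("velocity_sequence: %d frames, dt = %g s, grid %d x %d\n",
              length(x$frames), x$dt, x$grid$nx, x$grid$ny))
  invisible(x)
}

#' Body-mask sequence
#'
#' Per-frame boolean rasters on the measurement grid, `TRUE` inside the
#' body.
#'
#' @param grid A [grid2d()].
#' @param frames List of logical `(ny, nx)` matrices.
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(grid, frames) {
  frames <- lapply(frames, function(m) {
    if (!is.logical(m)) m <- m != 0
    check_shape(m, grid, "mask")
    m
  })
  structure(list(grid = grid, frames = frames), class = "mask_sequence")
}

#' Fluid properties
#'
#' Defaults are fresh water at 25 degrees C.
#'
#' @param rho Density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @export
fluid_properties <- function(rho = 998, mu = 1.0e-3) {
  if (!(rho > 0)) stop("rho must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Analysis configuration
#'
#' Bundle of the tunable choices shared across the pipeline stages.
#'
#' @param fluid A [fluid_properties()].
#' @param swim_axis_mode `"auto"` (least-squares centroid track) or
#'   `"fixed"` (use `fixed_axis`).
#' @param fixed_axis Unit-normalised swimming direction when
#'   `swim_axis_mode = "fixed"`.
#' @param geometry_mode `"planar"` (forces per unit depth, N/m) or
#'   `"axisymmetric"` (meridional half-profile revolved, N).
#' @param n_control_points Number of body-contour control points
#'   (default 60).
#' @param surface_sample_offset Outward pressure-sampling offset from
#'   the surface, in grid cells.
#' @param min_valid_paths Minimum surviving integration rays for a
#'   pressure node to count as directly computed (1..8).
#' @param include_viscous Include the viscous term of the momentum
#'   balance in the pressure gradient.
#' @param cycle_bounds Optional `c(t0, t1)` time window (an integer
#'   number of undulation cycles) for cycle averaging.
#' @param rng_seed Seed governing all stochastic elements.
#' @export
analysis_config <- function(fluid = fluid_properties(),
                            swim_axis_mode = c("auto", "fixed"),
                            fixed_axis = c(1, 0),
                            geometry_mode = c("planar", "axisymmetric"),
                            n_control_points = 60L,
                            surface_sample_offset = 2,
                            min_valid_paths = 3L,
                            include_viscous = TRUE,
                            cycle_bounds = NULL,
                            rng_seed = 0L) {
  swim_axis_mode <- match.arg(swim_axis_mode)
  geometry_mode <- match.arg(geometry_mode)
  n_control_points <- as.integer(n_control_points)
  min_valid_paths <- as.integer(min_valid_paths)
  if (n_control_points < 8L) stop("n_control_points must be >= 8")
  if (min_valid_paths < 1L || min_valid_paths > 8L)
    stop("min_valid_paths must be in 1..8")
  structure(list(fluid = fluid, swim_axis_mode = swim_axis_mode,
                 fixed_axis = as.numeric(fixed_axis),
                 geometry_mode = geometry_mode,
                 n_control_points = n_control_points,
                 surface_sample_offset = surface_sample_offset,
                 min_valid_paths = min_valid_paths,
                 include_viscous = include_viscous,
                 cycle_bounds = cycle_bounds,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}
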