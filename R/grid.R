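#' Regular 2-D measurement grid
#'
#' Node-centred regular lattice describing the velocimetry measurement
#' plane. The x axis points rightward and y upward; matrices defined on
#' the grid are indexed `[iy, ix]` (row = y index, column = x index),
#' with row 1 at the smallest y. All lengths are in metres; pixel-unit
#' data must be scaled at ingest (e.g. by a camera scale factor).
#'
#' @param nx,ny Number of nodes in x and y. Both must be at least 3 so
#'   that centred finite-difference stencils exist.
#' @param dx,dy Node spacing in metres (`dy` defaults to `dx`).
#' @param origin Coordinates `c(x0, y0)` of node `[1, 1]` in metres.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, dx, dy = dx, origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3L || ny < 3L) stop("grid2d: nx and ny must be >= 3")
  if (!(dx > 0) || !(dy > 0)) stop("grid2d: dx and dy must be > 0")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 origin = as.numeric(origin)),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %d x %d nodes, dx = %g m, dy = %g m, origin = (%g, %g)\n",
              x$nx, x$ny, x$dx, x$dy, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid A [grid2d()].
#' @return `grid_x`/`grid_y` give the node coordinate vectors;
#'   `grid_coords` returns matrices `X`, `Y` shaped `(ny, nx)`.
#' @export
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx

#' @rdname grid_x
#' @export
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy

#' @rdname grid_x
#' @export
grid_coords <- function(grid) {
  x <- grid_x(grid); y <- grid_y(grid)
  list(X = matrix(x, grid$ny, grid$nx, byrow = TRUE),
       Y = matrix(y, grid$ny, grid$nx))
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$dx - b$dx) <= tol * a$dx && abs(a$dy - b$dy) <= tol * a$dy &&
    all(abs(a$origin - b$origin) <= tol * max(a$dx, a$dy))
}

check_shape <- function(m, grid, what) {
  if (!is.matrix(m) || nrow(m) != grid$ny || ncol(m) != grid$nx)
    stop(sprintf("%s must be a (%d, %d) matrix", what, grid$ny, grid$nx))
  invisible(m)
}
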