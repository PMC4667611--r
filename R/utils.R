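# Small numerical helpers shared across modules. All operate on
# matrices indexed [iy, ix] (row = y).

# Shift a matrix by (di rows, dj cols); vacated cells become `fill`.
shift_mat <- function(m, di, dj, fill = NA_real_) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ri <- seq_len(ny); ci <- seq_len(nx)
  src_i <- ri - di; src_j <- ci - dj
  keep_i <- src_i >= 1L & src_i <= ny
  keep_j <- src_j >= 1L & src_j <= nx
  out[ri[keep_i], ci[keep_j]] <- m[src_i[keep_i], src_j[keep_j]]
  out
}

# Second-order central differences; edge cells are NA (validity is
# propagated by the callers, not patched with one-sided stencils).
ddx_mat <- function(m, dx) (shift_mat(m, 0L, -1L) - shift_mat(m, 0L, 1L)) / (2 * dx)
ddy_mat <- function(m, dy) (shift_mat(m, -1L, 0L) - shift_mat(m, 1L, 0L)) / (2 * dy)

# 5-point Laplacian; edges NA.
laplacian_mat <- function(m, dx, dy) {
  (shift_mat(m, 0L, -1L) + shift_mat(m, 0L, 1L) - 2 * m) / dx^2 +
    (shift_mat(m, -1L, 0L) + shift_mat(m, 1L, 0L) - 2 * m) / dy^2
}

# TRUE where the full 5-point stencil lies on valid nodes.
stencil_valid <- function(valid) {
  v <- valid
  v & shift_mat(valid, 0L, -1L, FALSE) & shift_mat(valid, 0L, 1L, FALSE) &
    shift_mat(valid, -1L, 0L, FALSE) & shift_mat(valid, 1L, 0L, FALSE)
}

# Row-wise median over the columns of `m`, ignoring NA; ties (even
# counts) resolve to the mean of the two central values.
row_medians <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)

# Run `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# Trapezoidal time average of y(t) over its full span.
trapz_mean <- function(t, y) {
  if (length(t) < 2L) return(mean(y))
  dt <- diff(t)
  sum(dt * (y[-1] + y[-length(y)]) / 2) / (t[length(t)] - t[1])
}
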