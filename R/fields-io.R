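# File formats
#
# Two on-disk layouts for velocity sequences:
#  * "per-frame-table": a directory holding one delimited table per
#    frame (columns x, y, u, v, valid on a complete regular lattice)
#    plus a `sequence.json` index (grid, dt, frame files, times).
#    Matches common velocimetry exports.
#  * "gridded-container": a single delimited table with a frame column,
#    the archival format (header line `# swimpressure gridded-container`
#    followed by a JSON metadata line, then the CSV body).
# Masks are 0/1 text rasters or PNG/PGM images; configuration is flat
# key = value text; reports are JSON plus CSV per-frame tables.

seq_to_table <- function(seq) {
  g <- seq$grid
  co <- grid_coords(g)
  # velocities as full-precision decimal strings so a write/read
  # round trip is bit-identical
  data.table::rbindlist(lapply(seq_along(seq$frames), function(k) {
    f <- seq$frames[[k]]
    data.table::data.table(frame = k, t = sprintf("%.17g", f$t),
                           x = as.vector(co$X), y = as.vector(co$Y),
                           u = sprintf("%.17g", as.vector(f$u)),
                           v = sprintf("%.17g", as.vector(f$v)),
                           valid = as.integer(f$valid))
  }))
}

# Reconstruct grid and (ny, nx) matrices from x/y columns of one frame,
# verifying lattice completeness and uniform spacing (tolerance 1e-6 of
# the spacing).
lattice_from_xy <- function(x, y) {
  ux <- sort(unique(x)); uy <- sort(unique(y))
  nx <- length(ux); ny <- length(uy)
  if (nx < 2L || ny < 2L) stop("irregular grid: degenerate lattice")
  dx <- (ux[nx] - ux[1]) / (nx - 1); dy <- (uy[ny] - uy[1]) / (ny - 1)
  if (max(abs(diff(ux) - dx)) > 1e-6 * dx ||
      max(abs(diff(uy) - dy)) > 1e-6 * dy)
    stop("irregular grid: non-uniform node spacing")
  if (length(x) != nx * ny) stop("irregular grid: missing lattice nodes")
  jj <- round((x - ux[1]) / dx) + 1L
  ii <- round((y - uy[1]) / dy) + 1L
  if (anyDuplicated(cbind(ii, jj))) stop("irregular grid: duplicate nodes")
  list(grid = grid2d(nx, ny, dx, dy, origin = c(ux[1], uy[1])),
       ii = ii, jj = jj)
}

frame_from_table <- function(dt_, grid = NULL) {
  lat <- lattice_from_xy(dt_$x, dt_$y)
  if (!is.null(grid) && !grids_equal(lat$grid, grid))
    stop("irregular grid: frame lattice differs from sequence lattice")
  g <- lat$grid
  put <- function(col) {
    m <- matrix(NA_real_, g$ny, g$nx)
    m[cbind(lat$ii, lat$jj)] <- col
    m
  }
  u <- put(dt_$u); v <- put(dt_$v)
  valid <- if ("valid" %in% names(dt_)) put(as.numeric(dt_$valid)) != 0 else NULL
  t <- if ("t" %in% names(dt_)) dt_$t[1] else 0
  velocity_frame(g, t, u, v, valid)
}

#' Write a velocity sequence to disk
#'
#' @param seq A [velocity_sequence()].
#' @param path Output location: a directory for
#'   `dialect = "per-frame-table"`, a single file for
#'   `dialect = "gridded-container"`.
#' @param dialect See Details in [read_velocity_sequence()].
#' @export
write_velocity_sequence <- function(seq, path,
                                    dialect = c("per-frame-table",
                                                "gridded-container")) {
  dialect <- match.arg(dialect)
  g <- seq$grid
  meta <- list(format = "swimpressure-velocity", version = 1L,
               nx = g$nx, ny = g$ny, dx = g$dx, dy = g$dy,
               origin = g$origin, dt = seq$dt,
               times = vapply(seq$frames, function(f) f$t, numeric(1)))
  if (dialect == "per-frame-table") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("frame_%04d.csv", seq_along(seq$frames))
    tab <- seq_to_table(seq)
    for (k in seq_along(seq$frames))
      data.table::fwrite(tab[tab$frame == k,
                             c("x", "y", "u", "v", "valid")],
                         file.path(path, files[k]))
    meta$files <- files
    jsonlite::write_json(meta, file.path(path, "sequence.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    writeLines("# swimpressure gridded-container", con)
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)), con)
    close(con)
    data.table::fwrite(seq_to_table(seq), path, append = TRUE,
                       col.names = TRUE)
  }
  invisible(path)
}

#' Read a velocity sequence
#'
#' Reads either a directory of per-frame vector tables (with its
#' `sequence.json` index) or a single gridded-container file, verifying
#' that every frame sits on a complete regular lattice (spacing uniform
#' to 1e-6 of the node spacing) and that sampling is uniform in time.
#' Coordinates are metres and velocities m/s; any ingest scaling (e.g.
#' a camera scale factor) must be applied before or while writing the
#' tables.
#'
#' @param path Directory (per-frame tables) or file (gridded
#'   container).
#' @return A [velocity_sequence()].
#' @export
read_velocity_sequence <- function(path) {
  if (dir.exists(path)) {
    idx_file <- file.path(path, "sequence.json")
    if (!file.exists(idx_file))
      stop("cannot read velocity sequence: missing ", idx_file)
    meta <- jsonlite::read_json(idx_file, simplifyVector = TRUE)
    frames <- lapply(seq_along(meta$files), function(k) {
      f <- file.path(path, meta$files[k])
      if (!file.exists(f)) stop("cannot read velocity frame file: ", f)
      d <- data.table::fread(f)
      fr <- frame_from_table(d)
      fr$t <- meta$times[k]
      fr
    })
    return(velocity_sequence(frames))
  }
  if (!file.exists(path)) stop("cannot read velocity sequence: ", path)
  d <- data.table::fread(path, skip = 2L)
  frames <- lapply(split(d, d$frame), frame_from_table)
  velocity_sequence(frames)
}

#' Read a mask sequence from rasters on disk
#'
#' Accepts 0/1 delimited text rasters (ny rows by nx columns, row 1 =
#' smallest y) or PGM (P2/P5) images; any nonzero value maps to
#' `TRUE`. Image rows are stored top-down and are flipped to the
#' package's y-upward convention.
#'
#' @param paths Character vector of raster files, in frame order.
#' @param grid The [grid2d()] the masks must match.
#' @return A [mask_sequence()].
#' @export
read_mask_sequence <- function(paths, grid) {
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read mask file: ", p)
    m <- if (grepl("\\.pgm$", p, ignore.case = TRUE)) read_pgm(p)
         else as.matrix(data.table::fread(p, header = FALSE))
    if (nrow(m) != grid$ny || ncol(m) != grid$nx)
      stop(sprintf("mask/grid shape mismatch: raster %d x %d, grid %d x %d (%s)",
                   nrow(m), ncol(m), grid$ny, grid$nx, p))
    unname(m != 0)
  })
  mask_sequence(grid, frames)
}

#' Write a mask sequence as 0/1 text rasters
#'
#' @param masks A [mask_sequence()].
#' @param paths Output files, one per frame.
#' @export
write_mask_sequence <- function(masks, paths) {
  for (k in seq_along(masks$frames))
    data.table::fwrite(data.table::as.data.table(masks$frames[[k]] * 1L),
                       paths[k], col.names = FALSE)
  invisible(paths)
}

# Minimal PGM reader (P2 ascii / P5 binary), returned y-up.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!magic %in% c("P2", "P5")) stop("unsupported image format: ", path)
  hdr <- integer(0)
  while (length(hdr) < 3L) {
    ln <- readLines(con, 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- hdr[1]; h <- hdr[2]; maxv <- hdr[3]
  vals <- if (magic == "P2") scan(con, integer(), n = w * h, quiet = TRUE)
          else as.integer(readBin(con, "raw", n = w * h))
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m[h:1, , drop = FALSE]
}

#' Read/write a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as logical (`true`/`false`), numeric when possible, else
#' strings; comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(parsed)) parsed
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else if (length(parts) > 1L) parts else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an analysis report
#'
#' Emits a JSON report (efficiencies, cycle summary, swim frame,
#' provenance, QC) plus a CSV of per-frame integrated forces; the pair
#' re-parses losslessly with [read_report()].
#'
#' @param report An `analysis_report` from [run_pipeline()] or a
#'   compatible list with elements `efficiency`, `cycle_summary`,
#'   `swim`, `force_frames` (data frame), `qc`, `provenance`.
#' @param path Output path without extension; writes `<path>.json` and
#'   `<path>_forces.csv`.
#' @export
write_report <- function(report, path) {
  required <- c("efficiency", "cycle_summary", "force_frames")
  miss <- setdiff(required, names(report))
  if (length(miss))
    stop("report is missing required fields: ", paste(miss, collapse = ", "))
  body <- report[setdiff(names(report), "force_frames")]
  body$schema <- "swimpressure-report-1"
  jsonlite::write_json(body, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  data.table::fwrite(report$force_frames, paste0(path, "_forces.csv"))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out$force_frames <- as.data.frame(
    data.table::fread(paste0(path, "_forces.csv")))
  out
}
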