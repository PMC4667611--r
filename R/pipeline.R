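#' Run the full measurement-to-efficiency pipeline
#'
#' Orchestrates ingest, contour kinematics, pressure, surface-force
#' decomposition and efficiency for one recording: masks are traced
#' and resampled to control points, the swimming frame is fitted from
#' the centroid track, pressure fields are computed by
#' median-of-eight-path integration, surface pressure is sampled and
#' decomposed into the four pull/push components, and the cycle
#' summary and pull/push efficiencies are assembled into a report.
#'
#' @param velocity A [velocity_sequence()] (or a path readable by
#'   [read_velocity_sequence()]).
#' @param masks A [mask_sequence()] (or character vector of raster
#'   paths).
#' @param config An [analysis_config()].
#' @param contours Optional list of pre-computed contour polylines or
#'   `body_contour`s (e.g. ground truth from [synth_swimmer()]);
#'   default is extraction from the masks.
#' @param boundary Optional boundary pressure for
#'   [pressure_sequence()].
#' @return An object of class `analysis_report`: `efficiency`
#'   ([partition_efficiencies()] output), `cycle_summary`
#'   ([summarize_cycle()] output), `swim` ([swim_frame()]),
#'   `force_frames` (per-frame integrated force table),
#'   `kinematics_frames` (per-frame per-point table with x, y, normal,
#'   ds, u_body, bsr, bsv and their normalised values), `qc`,
#'   `provenance`.
#' @export
run_pipeline <- function(velocity, masks, config = analysis_config(),
                         contours = NULL, boundary = NULL) {
  if (is.character(velocity)) velocity <- read_velocity_sequence(velocity)
  nf <- length(velocity$frames)
  if (nf < 3L) stop(">=3 frames required")
  g <- velocity$grid
  if (is.character(masks)) masks <- read_mask_sequence(masks, g)
  if (length(masks$frames) != nf)
    stop("mask/velocity frame count mismatch")
  stage <- function(what, k, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s, frame %s] %s", what, k, conditionMessage(e)),
           call. = FALSE))
  }
  times <- vapply(velocity$frames, function(f) f$t, numeric(1))
  # --- contours -----------------------------------------------------
  if (is.null(contours)) {
    contours <- lapply(seq_len(nf), function(k)
      stage("kinematics", k,
            resample_contour(extract_contour(masks$frames[[k]], g),
                             n = config$n_control_points, t = times[k])))
  } else {
    contours <- lapply(seq_len(nf), function(k) {
      c <- contours[[k]]
      if (inherits(c, "body_contour")) c
      else resample_contour(c, n = config$n_control_points, t = times[k])
    })
  }
  swim <- stage("kinematics", "all",
                swim_frame(contours, velocity$dt,
                           mode = if (config$swim_axis_mode == "auto")
                             "auto" else "fixed",
                           fixed_vector = config$fixed_axis))
  # re-anchor control point 1 at the anterior-most point along s_hat
  contours <- lapply(contours, function(c)
    resample_contour(c$points, n = config$n_control_points, t = c$t,
                     s_hat = swim$s_hat))
  # --- pressure -----------------------------------------------------
  pfs <- stage("pressure", "all",
               pressure_sequence(velocity, masks, fluid = config$fluid,
                                 config = config, boundary = boundary))
  # --- per-frame forces, power, kinematics --------------------------
  inner <- 2:(nf - 1L)
  decomps <- vector("list", length(inner))
  powers <- vector("list", length(inner))
  kin_rows <- vector("list", length(inner))
  force_rows <- vector("list", length(inner))
  n_unres <- 0L
  for (m in seq_along(inner)) {
    k <- inner[m]
    kin <- stage("kinematics", k,
                 surface_kinematics(contours[[k - 1]], contours[[k]],
                                    contours[[k + 1]], velocity$dt))
    vort <- vorticity_field(velocity$frames[[k]])
    bsv <- body_surface_vorticity(contours[[k]], vort)
    pe <- stage("forces", k,
                sample_surface_pressure(pfs[[m]], contours[[k]],
                                        offset = config$surface_sample_offset))
    n_unres <- n_unres + attr(pe, "n_unresolved")
    dec <- stage("forces", k,
                 decompose_forces(pe, contours[[k]], swim,
                                  mode = config$geometry_mode))
    pw <- list(P_lat = lateral_power(pe, kin, contours[[k]], swim, "all"),
               P_pull = lateral_power(pe, kin, contours[[k]], swim, "pull"),
               P_push = lateral_power(pe, kin, contours[[k]], swim, "push"))
    decomps[[m]] <- dec
    powers[[m]] <- pw
    force_rows[[m]] <- data.frame(
      t = times[k], F_fpull = dec$F_fpull, F_rpull = dec$F_rpull,
      F_fpush = dec$F_fpush, F_rpush = dec$F_rpush,
      net_pull = dec$F_fpull - dec$F_rpull,
      net_push = dec$F_fpush - dec$F_rpush,
      net_thrust = dec$net_thrust,
      P_lat = pw$P_lat, P_pull = pw$P_pull, P_push = pw$P_push)
    kin_rows[[m]] <- data.frame(
      t = times[k], point = seq_len(config$n_control_points),
      x = contours[[k]]$points[, 1], y = contours[[k]]$points[, 2],
      nx = contours[[k]]$normals[, 1], ny = contours[[k]]$normals[, 2],
      ds = point_ds(contours[[k]]),
      ubx = kin$u_body[, 1], uby = kin$u_body[, 2],
      bsr = kin$bsr, bsv = bsv,
      bsr_norm = normalize_on_body(kin$bsr),
      bsv_norm = normalize_on_body(bsv),
      p = as.numeric(pe))
  }
  cyc <- summarize_cycle(decomps, config$cycle_bounds)
  eff <- partition_efficiencies(decomps, powers, swim, config$cycle_bounds)
  qc <- list(
    frac_filled_pressure = mean(vapply(pfs, function(p)
      mean(p$filled), numeric(1))),
    n_unresolved_elements = n_unres,
    divergence_residual = max(vapply(seq_along(inner), function(m) {
      f <- velocity$frames[[inner[m]]]
      d <- ddx_mat(f$u, g$dx) + ddy_mat(f$v, g$dy)
      ok <- stencil_valid(f$valid)
      umax <- max(abs(f$u), abs(f$v))
      if (!any(ok) || umax == 0) return(0)
      max(abs(d[ok])) * g$dx / umax    # dimensionless truncation level
    }, numeric(1))))
  structure(list(
    efficiency = unclass(eff), cycle_summary = cyc, swim = unclass(swim),
    force_frames = do.call(rbind, force_rows),
    kinematics_frames = do.call(rbind, kin_rows),
    pressure = pfs, decompositions = decomps, contours = contours,
    qc = qc,
    provenance = list(package_version = tryCatch(
      as.character(utils::packageVersion("swimpressure")),
      error = function(e) "dev"),
      n_frames = nf, dt = velocity$dt,
      grid = list(nx = g$nx, ny = g$ny, dx = g$dx, dy = g$dy,
                  origin = g$origin),
      config = config[c("swim_axis_mode", "geometry_mode",
                        "n_control_points", "surface_sample_offset",
                        "min_valid_paths", "include_viscous",
                        "rng_seed")])),
    class = "analysis_report")
}

#' One-call pipeline on a synthetic swimmer dataset
#'
#' Generates a [synth_swimmer()] dataset and runs [run_pipeline()] on
#' it, averaging over the last full undulation cycle. The contour
#' source is the mask-extraction route by default, exercising the
#' whole chain; set `use_truth_contours = TRUE` to bypass extraction
#' with the generator's ground truth.
#'
#' @param params A [swimmer_params()].
#' @param grid A [grid2d()]; default a raceway-like domain sized to
#'   the swim.
#' @param dt Frame interval (s); default `T_p / 24`.
#' @param config An [analysis_config()]; its `cycle_bounds` default to
#'   the last full cycle covered by interior frames.
#' @param use_truth_contours Use generator ground-truth contours.
#' @return The [run_pipeline()] report, with the dataset attached as
#'   attribute `dataset`.
#' @export
swimmer_pipeline <- function(params, grid = NULL, dt = params$T_p / 24,
                             config = NULL, use_truth_contours = FALSE) {
  if (is.null(grid)) {
    U <- params$swim_speed_bl * params$L
    span_x <- params$L + U * (params$n_frames - 1) * dt + params$L / 2 +
      8 * params$w_max
    span_y <- 2 * (params$a0 + abs(params$a1) * params$L +
                     abs(params$a2) * params$L^2 + 5 * params$w_max) +
      4 * (2 * params$w_max)
    dx <- params$L / 60
    grid <- grid2d(ceiling(span_x / dx) + 1, ceiling(span_y / dx) + 1,
                   dx = dx, origin = c(0, -span_y / 2))
  }
  ds <- synth_swimmer(params, grid, dt)
  times <- vapply(ds$velocity$frames, function(f) f$t, numeric(1))
  if (is.null(config)) config <- analysis_config(rng_seed = params$seed)
  if (is.null(config$cycle_bounds)) {
    t_hi <- times[length(times) - 1L]
    config$cycle_bounds <- c(t_hi - params$T_p, t_hi)
  }
  rep <- run_pipeline(ds$velocity, ds$masks, config,
                      contours = if (use_truth_contours) ds$contours,
                      boundary = NULL)
  attr(rep, "dataset") <- ds
  rep
}
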