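#' Instantaneous lateral power
#'
#' Rate of work done by the body on the fluid transverse to the
#' swimming direction: per element,
#' `w_i = p_i (n_i . j) (u_body,i . j) dA_i`, summed over the chosen
#' subset. The pull subset keeps elements with `p_i < 0` (the body is
#' pulled laterally by low adjacent pressure), the push subset those
#' with `p_i > 0`; subset powers add up exactly to the full sum.
#' Signed terms are kept as-is: negative local contributions represent
#' genuine energy recovery, and no rectification is applied.
#'
#' @param p_elems Per-element pressures (Pa), NA elements skipped.
#' @param kin [surface_kinematics()] output for the same frame.
#' @param contour The frame's [resample_contour()] output.
#' @param frame A [swim_frame()] (supplies the lateral unit vector
#'   `j_hat`).
#' @param subset `"all"`, `"pull"` or `"push"`.
#' @return Lateral power (W/m planar; multiply by `dA` convention in
#'   use).
#' @export
lateral_power <- function(p_elems, kin, contour, frame,
                          subset = c("all", "pull", "push")) {
  subset <- match.arg(subset)
  j_hat <- frame$j_hat
  dA <- point_ds(contour)
  nj <- contour$normals[, 1] * j_hat[1] + contour$normals[, 2] * j_hat[2]
  uj <- kin$u_body[, 1] * j_hat[1] + kin$u_body[, 2] * j_hat[2]
  w <- p_elems * nj * uj * dA
  keep <- !is.na(w)
  keep <- keep & switch(subset,
                        all = TRUE,
                        pull = p_elems < 0 & nj != 0,
                        push = p_elems > 0 & nj != 0)
  sum(w[keep])
}

#' Froude-type hydrodynamic efficiency
#'
#' `eta = T U / (T U + P_lat)`: useful thrust power over useful power
#' plus the power lost to the fluid in lateral motions. With no
#' lateral loss `eta = 1`; with `P_lat = T U`, 0.5; with no thrust, 0.
#' A negative cycle-averaged `P_lat` is reported as-is (possibly
#' `eta > 1`) with a warning, never clamped.
#'
#' @param T_thrust Time-averaged gross forward thrust (N/m or N).
#' @param U Mean swimming speed (m/s).
#' @param P_lat Time-averaged lateral power.
#' @return Dimensionless efficiency.
#' @export
hydrodynamic_efficiency <- function(T_thrust, U, P_lat) {
  tu <- T_thrust * U
  if (tu + P_lat == 0) stop("no hydrodynamic work: T U + P_lat = 0")
  if (P_lat < 0) warning("negative cycle-averaged P_lat; eta may exceed 1")
  tu / (tu + P_lat)
}

#' Pull/push-partitioned efficiency report
#'
#' Computes, over a common full-cycle window, the time-averaged gross
#' thrust `T` and its pull/push parts, the lateral powers of the full
#' surface and of the pull/push subsets, and the efficiencies
#' `eta = T U / (T U + P_lat)`,
#' `eta_pull = T_pull U / (T_pull U + P_lat_pull)` and analogously
#' `eta_push`. Thrust parts are the gross forward components:
#' `T_pull = <F_fpull>`, `T_push = <F_fpush>`, so `T = T_pull +
#' T_push`.
#'
#' @param decomps List of [decompose_forces()] outputs in time order.
#' @param powers List (same length) with per-frame `P_lat`, `P_pull`,
#'   `P_push` from [lateral_power()].
#' @param frame A [swim_frame()].
#' @param cycle_bounds Optional `c(t0, t1)` averaging window.
#' @return An object of class `efficiency_report`.
#' @export
partition_efficiencies <- function(decomps, powers, frame,
                                   cycle_bounds = NULL) {
  tt <- vapply(decomps, function(d) d$t, numeric(1))
  keep <- rep(TRUE, length(tt))
  if (!is.null(cycle_bounds))
    keep <- tt >= cycle_bounds[1] - 1e-12 & tt <= cycle_bounds[2] + 1e-12
  if (!any(keep)) stop("empty cycle window")
  tt <- tt[keep]
  gv <- function(f) vapply(decomps[keep], function(d) d[[f]], numeric(1))
  pv <- function(f) vapply(powers[keep], function(p) p[[f]], numeric(1))
  T_pull <- trapz_mean(tt, gv("F_fpull"))
  T_push <- trapz_mean(tt, gv("F_fpush"))
  T_tot <- T_pull + T_push
  P_lat <- trapz_mean(tt, pv("P_lat"))
  P_pull <- trapz_mean(tt, pv("P_pull"))
  P_push <- trapz_mean(tt, pv("P_push"))
  U <- frame$U
  eta <- if (T_tot * U + P_lat != 0)
    hydrodynamic_efficiency(T_tot, U, P_lat) else NA_real_
  eta_pull <- if (T_pull * U + P_pull != 0)
    hydrodynamic_efficiency(T_pull, U, P_pull) else NA_real_
  eta_push <- if (T_push * U + P_push != 0)
    hydrodynamic_efficiency(T_push, U, P_push) else NA_real_
  structure(list(T_thrust = T_tot, T_pull = T_pull, T_push = T_push,
                 U = U, U_bl = frame$U_bl,
                 P_lat = P_lat, P_lat_pull = P_pull, P_lat_push = P_push,
                 eta = eta, eta_pull = eta_pull, eta_push = eta_push,
                 window = range(tt)),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    paste0("efficiency_report: U = %.4g m/s (%.3g BL/s)\n",
           "  T = %.4g (pull %.4g, push %.4g)\n",
           "  P_lat = %.4g (pull %.4g, push %.4g)\n",
           "  eta = %.3f  eta_pull = %.3f  eta_push = %.3f\n"),
    x$U, x$U_bl, x$T_thrust, x$T_pull, x$T_push,
    x$P_lat, x$P_lat_pull, x$P_lat_push,
    x$eta, x$eta_pull, x$eta_push))
  invisible(x)
}
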