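#' Model geometry for nondimensionalization and moment translation
#'
#' @param taxon_id character label.
#' @param snout_vent snout-vent length lambda (m); also the reference length
#'   `L` of the Reynolds number.
#' @param planform_area planform area S (m^2).
#' @param sensor_offset COM-to-sensor offset vector, body coordinates (m).
#' @return object of class `model_geometry`.
#' @export
model_geometry <- function(taxon_id, snout_vent = 0.08,
                           planform_area = 0.02,
                           sensor_offset = c(-0.05, 0, 0)) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1,
            snout_vent > 0, planform_area > 0,
            length(sensor_offset) == 3, all(is.finite(sensor_offset)))
  structure(list(taxon_id = taxon_id, snout_vent = snout_vent,
                 planform_area = planform_area,
                 sensor_offset = sensor_offset),
            class = "model_geometry")
}

truth_coefficients <- function(truth, pts) {
  d2r <- pi / 180
  Cm <- curve_value(truth$pitch_curve, pts$theta_deg)
  Cr <- numeric(nrow(pts))
  Cy <- numeric(nrow(pts))
  is_roll <- pts$series == "roll"
  is_yaw <- pts$series == "yaw"
  Cr[is_roll] <- truth$roll_slopes[pts$regime[is_roll]] *
    pts$phi_deg[is_roll] * d2r
  Cy[is_yaw] <- truth$yaw_slopes[pts$regime[is_yaw]] *
    pts$psi_deg[is_yaw] * d2r
  moved <- pts$movement != "none"
  if (any(moved)) {
    dd <- vapply(which(moved), function(i) {
      control_lookup(truth, pts$series[i], pts$movement[i], pts$regime[i])
    }, numeric(1))
    add <- pts$delta_deg[moved] * d2r * dd
    Cm[moved] <- Cm[moved] + ifelse(pts$series[moved] == "pitch", add, 0)
    Cr[moved] <- Cr[moved] + ifelse(pts$series[moved] == "roll", add, 0)
    Cy[moved] <- Cy[moved] + ifelse(pts$series[moved] == "yaw", add, 0)
  }
  cbind(Cr, Cm, Cy)
}

#' Simulate raw sensor-frame measurement records
#'
#' The inverse of the data-reduction chain: the true coefficient triple at
#' each design point is dimensionalized (`M = 0.5 rho U^2 C lambda S`),
#' expressed at the sensor location (`M_sensor = M_com - r x F`), rotated into
#' the sensor frame by the inverse Euler rotation, and corrupted with the
#' noise model of the truth object: per-recording averaged sensor noise plus
#' a per-sweep tare (zero-drift) offset. Identical `(truth, design, seed)`
#' give byte-identical output.
#'
#' @param truth an [aero_truth()].
#' @param design a [build_test_design()].
#' @param geometry a [model_geometry()].
#' @param seed integer RNG seed.
#' @return data frame with the documented record layout: `taxon, series,
#'   phi_deg, theta_deg, psi_deg, movement, delta_deg, U, rho, fx, fy, fz,
#'   tx, ty, tz, rx, ry, rz, replicate` plus a `regime` convenience column.
#' @export
simulate_records <- function(truth, design, geometry, seed = 1) {
  stopifnot(inherits(truth, "aero_truth"),
            inherits(design, "test_design"),
            inherits(geometry, "model_geometry"))
  pts <- design_points(design)
  reps <- design$replicates
  n0 <- nrow(pts)
  pts <- pts[rep(seq_len(n0), each = reps), , drop = FALSE]
  pts$replicate <- rep(seq_len(reps), times = n0)
  rownames(pts) <- NULL
  n <- nrow(pts)

  C <- truth_coefficients(truth, pts)
  ref <- 0.5 * design$rho * design$U^2 * geometry$snout_vent *
    geometry$planform_area
  M_com <- ref * C                       # tunnel frame: (roll, pitch, yaw)
  F_t <- matrix(0, n, 3)                 # quasi-static: no modeled net force

  # rotate into the sensor frame per unique orientation
  Ms <- matrix(0, n, 3)
  Fs <- matrix(0, n, 3)
  d2r <- pi / 180
  r <- geometry$sensor_offset
  key <- paste(pts$phi_deg, pts$theta_deg, pts$psi_deg, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    i1 <- idx[1]
    R <- euler_rotation(pts$phi_deg[i1] * d2r, pts$theta_deg[i1] * d2r,
                        pts$psi_deg[i1] * d2r)
    r_t <- as.vector(R %*% r)
    M_sens_t <- t(M_com[idx, , drop = FALSE]) -
      vapply(idx, function(i) cross3(r_t, F_t[i, ]), numeric(3))
    Ms[idx, ] <- t(crossprod(R, M_sens_t))
    Fs[idx, ] <- t(crossprod(R, t(F_t[idx, , drop = FALSE])))
  }

  # noise: residual zero offset per recording block + averaged per-sample
  # noise, both in the sensor frame. A recording block is one contiguous
  # wind-on group of positions between sensor re-zeroings; long pitch
  # baseline sweeps are zeroed block-wise (low-alpha / mid / high-alpha /
  # top), shorter sweeps form a single block.
  nm <- truth$noise
  set.seed(seed)
  pitch_base <- pts$series == "pitch" & pts$movement == "none"
  zero_block <- ifelse(pitch_base,
                       cut(pts$theta_deg, c(-1, 27.5, 57.5, 87.5, 91),
                           labels = c("low", "mid", "high", "top")),
                       "all")
  block <- paste(pts$series, pts$movement, pts$delta_deg,
                 ifelse(pitch_base, zero_block, pts$regime),
                 pts$replicate, sep = "|")
  ub <- unique(block)
  tare_f <- matrix(stats::rnorm(3 * length(ub), 0, nm$tare_force),
                   length(ub), 3, dimnames = list(ub, NULL))
  tare_t <- matrix(stats::rnorm(3 * length(ub), 0, nm$tare_torque),
                   length(ub), 3, dimnames = list(ub, NULL))
  Fs <- Fs + tare_f[block, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, 0, nm$sd_force / sqrt(nm$n_samples)), n, 3)
  Ms <- Ms + tare_t[block, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, 0, nm$sd_torque / sqrt(nm$n_samples)), n, 3)

  data.frame(
    taxon = truth$taxon_id, series = pts$series,
    phi_deg = pts$phi_deg, theta_deg = pts$theta_deg, psi_deg = pts$psi_deg,
    movement = pts$movement, delta_deg = pts$delta_deg,
    U = design$U, rho = design$rho,
    fx = Fs[, 1], fy = Fs[, 2], fz = Fs[, 3],
    tx = Ms[, 1], ty = Ms[, 2], tz = Ms[, 3],
    rx = r[1], ry = r[2], rz = r[3],
    replicate = pts$replicate, regime = pts$regime
  )
}

#' Write/read measurement records as CSV
#'
#' @param records record table from [simulate_records()].
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
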