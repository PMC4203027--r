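#' Euler rotation matrix (yaw * pitch * roll)
#'
#' Composes the three elemental right-handed rotations in the standard
#' aerospace intrinsic z-y'-x'' sequence, applied to column vectors as
#' `R = R_yaw(psi) %*% R_pitch(theta) %*% R_roll(phi)`. Rotating a
#' sensor-frame vector by `R` expresses it in the tunnel-aligned frame.
#' Sign conventions: nose-up pitching moment, right-wing-down rolling moment
#' and nose-right yawing moment are positive, so static stability corresponds
#' to a negative derivative of the moment coefficient with respect to the
#' matching body angle.
#'
#' @param phi,theta,psi roll, pitch, yaw angles in radians.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
#' @examples
#' euler_rotation(0, 0, pi / 2)  # maps unit-x to unit-y
euler_rotation <- function(phi, theta, psi) {
  if (!all(is.finite(c(phi, theta, psi)))) {
    stop("euler_rotation: angles must be finite")
  }
  cf <- cos(phi); sf <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(psi); sp <- sin(psi)
  Rx <- matrix(c(1, 0, 0,
                 0, cf, sf,
                 0, -sf, cf), 3, 3)
  Ry <- matrix(c(ct, 0, -st,
                 0, 1, 0,
                 st, 0, ct), 3, 3)
  Rz <- matrix(c(cp, sp, 0,
                 -sp, cp, 0,
                 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Transform raw sensor records to tunnel-frame moments about the COM
#'
#' Rotates each record's sensor-frame force and torque into the tunnel frame
#' and translates the torque from the sensor mount to the center of mass:
#' `F_t = R F_s`, `M_com = R M_s + (R r) x F_t`, with `r` the COM-to-sensor
#' offset in body coordinates. The angle of attack is the pitch angle; the
#' series angle (the abscissa of the downstream slope fits) is the pitch,
#' roll, or yaw angle according to the series.
#'
#' @param records data frame of measurement records as produced by
#'   [simulate_records()] or read from the documented CSV layout.
#' @return data frame of body-frame moments, one row per record, with tunnel
#'   forces `ftx, fty, ftz` (N) and COM moments `m_roll, m_pitch, m_yaw`
#'   (N m).
#' @export
to_com_frame <- function(records) {
  need <- c("taxon", "series", "phi_deg", "theta_deg", "psi_deg", "movement",
            "delta_deg", "U", "rho", "fx", "fy", "fz", "tx", "ty", "tz",
            "rx", "ry", "rz", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("to_com_frame: missing columns: ", paste(miss, collapse = ", "))
  }
  num <- records[, c("fx", "fy", "fz", "tx", "ty", "tz")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("to_com_frame: non-finite force/torque values")
  }
  n <- nrow(records)
  Ft <- matrix(0, n, 3)
  Mc <- matrix(0, n, 3)
  d2r <- pi / 180
  key <- paste(records$phi_deg, records$theta_deg, records$psi_deg,
               records$rx, records$ry, records$rz, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    i1 <- idx[1]
    R <- euler_rotation(records$phi_deg[i1] * d2r,
                        records$theta_deg[i1] * d2r,
                        records$psi_deg[i1] * d2r)
    r_t <- as.vector(R %*% c(records$rx[i1], records$ry[i1], records$rz[i1]))
    Fs <- t(as.matrix(records[idx, c("fx", "fy", "fz")]))
    Ms <- t(as.matrix(records[idx, c("tx", "ty", "tz")]))
    Ftk <- R %*% Fs
    # (R r) x F_t, columnwise
    Mck <- R %*% Ms + rbind(r_t[2] * Ftk[3, ] - r_t[3] * Ftk[2, ],
                            r_t[3] * Ftk[1, ] - r_t[1] * Ftk[3, ],
                            r_t[1] * Ftk[2, ] - r_t[2] * Ftk[1, ])
    Ft[idx, ] <- t(Ftk)
    Mc[idx, ] <- t(Mck)
  }
  series_angle <- ifelse(records$series == "pitch", records$theta_deg,
                         ifelse(records$series == "roll", records$phi_deg,
                                records$psi_deg))
  out <- data.frame(
    taxon = records$taxon, series = records$series,
    movement = records$movement, delta_deg = records$delta_deg,
    alpha_deg = records$theta_deg, series_angle_deg = series_angle,
    replicate = records$replicate, U = records$U, rho = records$rho,
    ftx = Ft[, 1], fty = Ft[, 2], ftz = Ft[, 3],
    m_roll = Mc[, 1], m_pitch = Mc[, 2], m_yaw = Mc[, 3]
  )
  if ("regime" %in% names(records)) out$regime <- records$regime
  out
}

#' Average replicate recordings
#'
#' Component-wise arithmetic mean of body-frame moments over a grouping key,
#' with the replicate count preserved as `n_replicates` for downstream
#' confidence intervals.
#'
#' @param bf body-frame moment table from [to_com_frame()].
#' @param by character vector of grouping columns.
#' @return one row per group with averaged numeric columns.
#' @export
average_replicates <- function(bf,
                               by = c("taxon", "series", "movement",
                                      "delta_deg", "alpha_deg",
                                      "series_angle_deg")) {
  if (!nrow(bf)) stop("average_replicates: empty input")
  miss <- setdiff(by, names(bf))
  if (length(miss)) {
    stop("average_replicates: missing grouping columns: ",
         paste(miss, collapse = ", "))
  }
  val_cols <- intersect(c("ftx", "fty", "ftz", "m_roll", "m_pitch", "m_yaw",
                          "U", "rho"), names(bf))
  agg <- stats::aggregate(bf[val_cols], by = bf[by], FUN = mean)
  cnt <- stats::aggregate(list(n_replicates = bf[[val_cols[1]]]),
                          by = bf[by], FUN = length)
  merge(agg, cnt, by = by, sort = TRUE)
}
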