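#' Sensor noise model for the virtual wind tunnel
#'
#' Two noise components act on the simulated six-axis sensor, both Gaussian
#' and expressed in the sensor frame:
#' \describe{
#'   \item{per-sample noise}{`sd_force` (N) and `sd_torque` (N m) per raw
#'     sample; a recording averages `n_samples` samples, so the recorded value
#'     carries SD `sd/sqrt(n_samples)`.}
#'   \item{residual zero offset}{`tare_force` (N), `tare_torque` (N m): the
#'     sensor is re-zeroed (tunnel stopped) before each recording block --
#'     one contiguous group of positions measured wind-on without
#'     interruption -- and the residual offset left after zeroing is drawn
#'     once per block and held constant across it. Long pitch sweeps are
#'     split into blocks at the boundaries between the low-alpha, mid, and
#'     high-alpha regions, so each slope-fitting window is measured within a
#'     single block. Because the offset is constant within a block it is
#'     orthogonal to the angle regressor there: it widens residual scatter
#'     (and hence the reported confidence intervals) without perturbing the
#'     fitted slopes.}
#' }
#'
#' @param sd_force,sd_torque per-sample SDs (N, N m).
#' @param tare_force,tare_torque residual zero-offset SDs per recording
#'   block (N, N m).
#' @param n_samples samples averaged per recording (default 600).
#' @return a list with the five components, class `tunnel_noise`.
#' @export
noise_model <- function(sd_force = 0.02, sd_torque = 2e-3,
                        tare_force = 1.25e-4, tare_torque = 2.5e-4,
                        n_samples = 600) {
  vals <- c(sd_force, sd_torque, tare_force, tare_torque)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise_model: SDs must be finite and >= 0")
  }
  stopifnot(n_samples >= 1)
  structure(list(sd_force = sd_force, sd_torque = sd_torque,
                 tare_force = tare_force, tare_torque = tare_torque,
                 n_samples = n_samples),
            class = "tunnel_noise")
}

#' Ground-truth aerodynamic description of a virtual taxon
#'
#' Collects everything the virtual wind tunnel needs to emit raw sensor
#' records with known answers: the baseline pitching-moment coefficient curve
#' `C_m(alpha)` (a [hermite_curve()]), linear rolling/yawing coefficient
#' responses to body roll/yaw angle at the low and high angle-of-attack
#' regimes, and the control-effectiveness table giving the true dC/ddelta for
#' each (axis, movement, regime). Control enters additively,
#' `C(alpha, delta) = C0(alpha) + delta * dC/ddelta`, matching the linearized
#' definition of control effectiveness.
#'
#' @param taxon_id character label.
#' @param pitch_curve baseline `C_m(alpha)` as a [hermite_curve()].
#' @param roll_slopes,yaw_slopes named numeric `c(low =, high =)`:
#'   dC_r/dphi and dC_y/dpsi (rad^-1) at the 15 and 75 degree regimes.
#' @param control data frame with columns `axis` (pitch/roll/yaw), `movement`,
#'   `regime` (low/high), `dC_ddelta` (rad^-1).
#' @param noise a [noise_model()].
#' @return an object of class `aero_truth` with derived fields
#'   `equilibrium_angle` (deg, lowest zero crossing of the pitch curve with a
#'   negative local slope if any, else the lowest crossing; NA when the curve
#'   never crosses) and `slope_at` (analytic dC_m/dalpha at 0, 15, 75 and the
#'   equilibrium).
#' @export
aero_truth <- function(taxon_id, pitch_curve,
                       roll_slopes = c(low = 0, high = 0),
                       yaw_slopes = c(low = 0, high = 0),
                       control = NULL,
                       noise = noise_model()) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1,
            inherits(pitch_curve, "hermite_curve"),
            inherits(noise, "tunnel_noise"))
  stopifnot(all(c("low", "high") %in% names(roll_slopes)),
            all(c("low", "high") %in% names(yaw_slopes)))
  if (is.null(control)) {
    control <- data.frame(axis = character(), movement = character(),
                          regime = character(), dC_ddelta = numeric())
  }
  stopifnot(all(c("axis", "movement", "regime", "dC_ddelta") %in%
                  names(control)))

  zeros <- if (all(abs(pitch_curve$y) < 1e-14)) numeric(0) else
    curve_zeros(pitch_curve)
  eq <- NA_real_
  if (length(zeros)) {
    sl <- curve_slope(pitch_curve, zeros)
    eq <- if (any(sl < 0)) zeros[which(sl < 0)[1]] else zeros[1]
  }
  pts <- c(`0` = 0, `15` = 15, `75` = 75)
  slope_at <- as.list(curve_slope(pitch_curve, pts))
  names(slope_at) <- names(pts)
  slope_at$eq <- if (is.na(eq)) NA_real_ else curve_slope(pitch_curve, eq)

  structure(list(taxon_id = taxon_id, pitch_curve = pitch_curve,
                 roll_slopes = roll_slopes, yaw_slopes = yaw_slopes,
                 control = control, noise = noise,
                 equilibrium_angle = eq, slope_at = slope_at),
            class = "aero_truth")
}

#' @export
print.aero_truth <- function(x, ...) {
  cat("<aero_truth> ", x$taxon_id, "\n", sep = "")
  cat("  pitch equilibrium: ",
      if (is.na(x$equilibrium_angle)) "none" else
        sprintf("%.2f deg (slope %.3f rad^-1)",
                x$equilibrium_angle, x$slope_at$eq), "\n", sep = "")
  cat("  dC_m/dalpha at 0/15/75 deg: ",
      sprintf("%.3f / %.3f / %.3f rad^-1",
              x$slope_at$`0`, x$slope_at$`15`, x$slope_at$`75`), "\n", sep = "")
  cat("  control rows: ", nrow(x$control), "\n", sep = "")
  invisible(x)
}

control_lookup <- function(truth, axis, movement, regime) {
  ct <- truth$control
  hit <- ct$axis == axis & ct$movement == movement & ct$regime == regime
  if (!any(hit)) {
    stop(sprintf("aero_truth '%s': no control truth for (%s, %s, %s)",
                 truth$taxon_id, axis, movement, regime))
  }
  ct$dC_ddelta[hit][1]
}

default_control_table <- function(pitch_tail, pitch_prot, roll_tuck,
                                  roll_pron, yaw_tail, yaw_pron) {
  expand_ctrl <- function(axis, movement, low, high) {
    data.frame(axis = axis, movement = movement,
               regime = c("low", "high"), dC_ddelta = c(low, high))
  }
  rbind(
    expand_ctrl("pitch", "tail_dorsiflexion", pitch_tail[1], pitch_tail[2]),
    expand_ctrl("pitch", "sym_protraction",   pitch_prot[1], pitch_prot[2]),
    expand_ctrl("roll",  "asym_wing_tuck",    roll_tuck[1],  roll_tuck[2]),
    expand_ctrl("roll",  "asym_pron_sup",     roll_pron[1],  roll_pron[2]),
    expand_ctrl("yaw",   "tail_lateral",      yaw_tail[1],   yaw_tail[2]),
    expand_ctrl("yaw",   "asym_pron_sup",     yaw_pron[1],   yaw_pron[2])
  )
}

#' Calibration and archetype fixtures for the virtual wind tunnel
#'
#' Four ground-truth objects spanning the qualitative behaviours the physical
#' calibration objects and study taxa exhibit:
#' \describe{
#'   \item{sphere}{all coefficients identically zero: every stability slope is
#'     truly zero and should code marginal; all movements ineffective.}
#'   \item{weathervane}{strongly restoring in pitch and yaw
#'     (slope -0.9 rad^-1, ten times the 0.09 rad^-1 effectiveness threshold,
#'     i.e. the moment that would displace the center of pressure by ~10% of
#'     body length); marginal in roll; codes stable in pitch and yaw.}
#'   \item{longtail}{long-tailed glider archetype: monotonically falling
#'     `C_m(alpha)` with a stable trim point at 17.5 deg (inside the 10-25 deg
#'     band typical of long-tailed forms), tail highly effective in pitch/yaw
#'     at low angle of attack.}
#'   \item{shorttail}{short-tailed archetype: humped `C_m(alpha)` with an
#'     unstable equilibrium near 3 deg, tail ineffective, wings (symmetric
#'     protraction, asymmetric pronation/supination) effective.}
#' }
#'
#' @param noise a [noise_model()] applied to every fixture.
#' @return named list of [aero_truth()] objects.
#' @export
make_fixture_suite <- function(noise = noise_model()) {
  d2r <- pi / 180
  sphere <- aero_truth(
    "sphere",
    hermite_curve(c(0, 90), c(0, 0), c(0, 0)),
    roll_slopes = c(low = 0, high = 0),
    yaw_slopes = c(low = 0, high = 0),
    control = default_control_table(c(0, 0), c(0, 0), c(0, 0),
                                    c(0, 0), c(0, 0), c(0, 0)),
    noise = noise
  )

  # weathervane: linear restoring pitch curve, zero at 20 deg, slope -0.9
  wv_s <- -0.9
  weathervane <- aero_truth(
    "weathervane",
    hermite_curve(c(0, 90), wv_s * d2r * c(0 - 20, 90 - 20), c(wv_s, wv_s)),
    roll_slopes = c(low = 0, high = 0),
    yaw_slopes = c(low = wv_s, high = wv_s),
    control = default_control_table(c(0, 0), c(0, 0), c(0, 0),
                                    c(0, 0), c(0, 0), c(0, 0)),
    noise = noise
  )

  # long-tailed archetype: slope -0.5 through the trim point at 17.5 deg,
  # easing to -0.3 at high angle of attack. Knots are placed so the curve is
  # exactly linear on [0, 25] and [45, 90]: every fitting window (0, 15, 75,
  # equilibrium) sees a pure linear slope.
  lt_c25 <- -0.5 * d2r * (25 - 17.5)
  lt_c45 <- lt_c25 - 0.4 * d2r * 20
  longtail <- aero_truth(
    "longtail",
    hermite_curve(c(0, 25, 45, 90),
                  c(-0.5 * d2r * (0 - 17.5), lt_c25, lt_c45,
                    lt_c45 - 0.3 * d2r * 45),
                  c(-0.5, -0.5, -0.3, -0.3)),
    roll_slopes = c(low = 0.3, high = -0.5),
    yaw_slopes = c(low = -0.5, high = 0),
    control = default_control_table(pitch_tail = c(0.30, 0.12),
                                    pitch_prot = c(0.20, 0.20),
                                    roll_tuck = c(0.30, 0.30),
                                    roll_pron = c(0.25, 0.25),
                                    yaw_tail = c(0.30, 0.05),
                                    yaw_pron = c(0.25, 0.25)),
    noise = noise
  )

  # short-tailed archetype: humped curve, unstable crossing at 3 deg,
  # slope +0.45 at low alpha, peak near 40 deg, shallow descent beyond.
  shorttail <- aero_truth(
    "shorttail",
    hermite_curve(c(0, 15, 40, 90),
                  c(0.45 * d2r * (0 - 3), 0.45 * d2r * (15 - 3), 0.16, 0.05),
                  c(0.45, 0.45, 0, -0.05)),
    roll_slopes = c(low = 0.4, high = -0.5),
    yaw_slopes = c(low = 0.4, high = 0),
    control = default_control_table(pitch_tail = c(0.03, 0.03),
                                    pitch_prot = c(0.30, 0.30),
                                    roll_tuck = c(0.30, 0.30),
                                    roll_pron = c(0.25, 0.25),
                                    yaw_tail = c(0.03, 0.03),
                                    yaw_pron = c(0.25, 0.25)),
    noise = noise
  )

  list(sphere = sphere, weathervane = weathervane,
       longtail = longtail, shorttail = shorttail)
}

#' Rename a ground-truth taxon
#'
#' Convenience for building multi-taxon demos from a fixture archetype.
#'
#' @param truth an [aero_truth()].
#' @param taxon_id new label.
#' @return the truth object with `taxon_id` replaced.
#' @export
rename_truth <- function(truth, taxon_id) {
  stopifnot(inherits(truth, "aero_truth"))
  truth$taxon_id <- taxon_id
  truth
}
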