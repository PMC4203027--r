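#' Nondimensional moment coefficient
#'
#' `C = M / (0.5 rho U^2 lambda S)`: the moment about an axis divided by the
#' dynamic pressure times the snout-vent reference length and planform area.
#'
#' @param M moment, N m (vectorized).
#' @param rho air density, kg/m^3. @param U flow speed, m/s.
#' @param lambda snout-vent length, m. @param S planform area, m^2.
#' @return dimensionless coefficient.
#' @export
#' @examples
#' moment_coefficient(1e-3, 1.204, 6, 0.08, 0.02)  # 0.028839...
moment_coefficient <- function(M, rho, U, lambda, S) {
  if (any(c(rho, U, lambda, S) <= 0) || any(!is.finite(c(rho, U, lambda, S)))) {
    stop("moment_coefficient: rho, U, lambda, S must be positive and finite")
  }
  M / (0.5 * rho * U^2 * lambda * S)
}

#' Reynolds number
#'
#' `Re = U L / nu` with `L` the snout-vent length. At the default tunnel
#' speed of 6 m/s, an 8 cm model in air (`nu = 1.5e-5 m^2/s`) gives
#' Re = 32,000; coefficients are treated as Re-independent over the tested
#' 30,000-70,000 range.
#'
#' @param U flow speed, m/s. @param L reference length, m.
#' @param nu kinematic viscosity, m^2/s.
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(U, L, nu = 1.5e-5) {
  if (any(c(U, L, nu) <= 0) || any(!is.finite(c(U, L, nu)))) {
    stop("reynolds: U, L, nu must be positive and finite")
  }
  U * L / nu
}

#' Reduce body-frame moments to coefficient records
#'
#' Applies [moment_coefficient()] per axis to a body-frame moment table,
#' yielding replicate-level `C_m`, `C_r`, `C_y`.
#'
#' @param bf table from [to_com_frame()] (or replicate averages from
#'   [average_replicates()]).
#' @param geometry a [model_geometry()] for the taxon.
#' @return the input table with `C_m`, `C_r`, `C_y` columns appended and the
#'   dimensional moment columns dropped.
#' @export
coefficient_records <- function(bf, geometry) {
  stopifnot(inherits(geometry, "model_geometry"))
  out <- bf
  out$C_r <- moment_coefficient(bf$m_roll, bf$rho, bf$U,
                                geometry$snout_vent, geometry$planform_area)
  out$C_m <- moment_coefficient(bf$m_pitch, bf$rho, bf$U,
                                geometry$snout_vent, geometry$planform_area)
  out$C_y <- moment_coefficient(bf$m_yaw, bf$rho, bf$U,
                                geometry$snout_vent, geometry$planform_area)
  out[setdiff(names(out), c("m_roll", "m_pitch", "m_yaw"))]
}
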