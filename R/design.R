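#' Appendage movements tested for control effectiveness
#'
#' The default movement set and angular extents: symmetric wing
#' protraction/retraction to +/-45 deg and tail dorsiflexion to +/-15 deg
#' (pitch); tucking of one wing (roll, one-sided, 45 deg) and asymmetric wing
#' pronation/supination to 15 deg (roll and yaw); tail lateral flexion to
#' 30 deg (yaw, one-sided). Each movement feeds the moment axis it
#' predominantly excites; `two_sided` movements are tested at +/- the extent
#' and reduced by central differences, one-sided movements against the
#' undeflected baseline.
#'
#' @return data frame with columns `movement`, `axis`, `extent_deg`,
#'   `two_sided`.
#' @export
default_movements <- function() {
  data.frame(
    movement = c("tail_dorsiflexion", "sym_protraction", "asym_wing_tuck",
                 "asym_pron_sup", "tail_lateral", "asym_pron_sup"),
    axis = c("pitch", "pitch", "roll", "roll", "yaw", "yaw"),
    extent_deg = c(15, 45, 45, 15, 30, 15),
    two_sided = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Build a wind-tunnel test design
#'
#' Defines the automated-sting measurement program: a pitch sweep in 5-degree
#' increments, roll and yaw sweeps at the two angle-of-attack regimes (15 and
#' 75 degrees), and deflected repeats of each movement at grid points inside
#' the derivative-fitting window around each regime.
#'
#' @param pitch_grid angle-of-attack grid, degrees (default 0..90 by 5).
#' @param body_grid roll/yaw body-angle grid, degrees (default -20..20 by 5).
#' @param aoa_regimes named `c(low =, high =)` evaluation angles of attack.
#' @param movements movement table as from [default_movements()].
#' @param replicates recordings per position (>= 1; the study design used at
#'   least 5).
#' @param U tunnel speed, m/s. @param rho air density, kg/m^3.
#' @param nu kinematic viscosity of air, m^2/s.
#' @param window half-width (deg) of the slope-fitting window; control series
#'   are generated at grid points within `window` of the evaluation point.
#' @return object of class `test_design`.
#' @export
build_test_design <- function(pitch_grid = seq(0, 90, by = 5),
                              body_grid = seq(-20, 20, by = 5),
                              aoa_regimes = c(low = 15, high = 75),
                              movements = default_movements(),
                              replicates = 5,
                              U = 6, rho = 1.204, nu = 1.5e-5,
                              window = 10) {
  if (!length(pitch_grid) || !length(body_grid)) {
    stop("build_test_design: empty angle grid")
  }
  if (any(pitch_grid < 0 | pitch_grid > 90)) {
    stop("build_test_design: angle of attack must lie in [0, 90] deg")
  }
  if (any(abs(body_grid) > 90) ||
      (nrow(movements) && any(abs(movements$extent_deg) > 90))) {
    stop("build_test_design: deflections must lie in [-90, 90] deg")
  }
  stopifnot(replicates >= 1, U > 0, rho > 0, nu > 0, window > 0,
            all(c("low", "high") %in% names(aoa_regimes)))
  structure(list(pitch_grid = sort(pitch_grid), body_grid = sort(body_grid),
                 aoa_regimes = aoa_regimes, movements = movements,
                 replicates = replicates, U = U, rho = rho, nu = nu,
                 window = window),
            class = "test_design")
}

#' Enumerate the measurement positions of a design
#'
#' Deterministically expands a [build_test_design()] into one row per
#' (series, orientation, movement, deflection) position, baseline positions
#' first. Replicates are not expanded here; the simulator visits each position
#' `replicates` times.
#'
#' @param design a `test_design`.
#' @return data frame with columns `series`, `phi_deg`, `theta_deg`,
#'   `psi_deg`, `movement`, `delta_deg`, `regime`.
#' @export
design_points <- function(design) {
  stopifnot(inherits(design, "test_design"))
  reg <- design$aoa_regimes
  rows <- list()

  rows[[length(rows) + 1]] <- data.frame(
    series = "pitch", phi_deg = 0, theta_deg = design$pitch_grid, psi_deg = 0,
    movement = "none", delta_deg = 0,
    regime = ifelse(design$pitch_grid < mean(reg), "low", "high")
  )
  for (rname in names(reg)) {
    rows[[length(rows) + 1]] <- data.frame(
      series = "roll", phi_deg = design$body_grid, theta_deg = reg[[rname]],
      psi_deg = 0, movement = "none", delta_deg = 0, regime = rname)
    rows[[length(rows) + 1]] <- data.frame(
      series = "yaw", phi_deg = 0, theta_deg = reg[[rname]],
      psi_deg = design$body_grid, movement = "none", delta_deg = 0,
      regime = rname)
  }

  mv <- design$movements
  if (nrow(mv)) {
    for (k in seq_len(nrow(mv))) {
      signs <- if (mv$two_sided[k]) c(1, -1) else 1
      for (rname in names(reg)) {
        for (sg in signs) {
          if (mv$axis[k] == "pitch") {
            th <- design$pitch_grid[
              abs(design$pitch_grid - reg[[rname]]) <= design$window + 1e-9]
            rows[[length(rows) + 1]] <- data.frame(
              series = "pitch", phi_deg = 0, theta_deg = th, psi_deg = 0,
              movement = mv$movement[k], delta_deg = sg * mv$extent_deg[k],
              regime = rname)
          } else {
            bg <- design$body_grid[abs(design$body_grid) <= design$window + 1e-9]
            rows[[length(rows) + 1]] <- data.frame(
              series = mv$axis[k],
              phi_deg = if (mv$axis[k] == "roll") bg else 0,
              theta_deg = reg[[rname]],
              psi_deg = if (mv$axis[k] == "yaw") bg else 0,
              movement = mv$movement[k], delta_deg = sg * mv$extent_deg[k],
              regime = rname)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random ground-truth taxa with known character states
#'
#' Draws, for each taxon, a random state for each of the 8 stability
#' characters (stable/marginal/unstable, realized as slopes -0.5/0/+0.5
#' rad^-1) and 12 control characters (effective/ineffective, realized as
#' dC/ddelta 0.30/0.03 rad^-1 against the 0.09 threshold), then constructs an
#' [aero_truth()] whose analytic curves realize those states. The pitch curve
#' is piecewise linear-in-window: slope `s0` on [0, 10], `s15` on [10, 30],
#' an equilibrium crossing at 35 deg with slope `s_eq` (or a flat zero plateau
#' on [25, 50] for a marginal equilibrium), and slope `s75` beyond 50 deg.
#'
#' @param n number of taxa.
#' @param seed RNG seed for the state draw.
#' @param noise a [noise_model()].
#' @return list with `truths` (list of `aero_truth`) and `states`
#'   (n x 20 character matrix of true states, rows named by taxon).
#' @export
synth_taxa <- function(n, seed = 1, noise = noise_model()) {
  stopifnot(n >= 1)
  set.seed(seed)
  ord <- character_order()
  d2r <- pi / 180
  slope_of <- c(stable = -0.5, marginal = 0, unstable = 0.5)
  ctrl_of <- c(effective = 0.30, ineffective = 0.03)

  truths <- vector("list", n)
  states <- matrix(NA_character_, n, nrow(ord),
                   dimnames = list(sprintf("taxon%03d", seq_len(n)),
                                   ord$label))
  for (i in seq_len(n)) {
    id <- rownames(states)[i]
    st <- c(sample(names(slope_of), 8, replace = TRUE),
            sample(names(ctrl_of), 12, replace = TRUE))
    names(st) <- ord$label
    states[i, ] <- st
    s0 <- slope_of[[st["stab_pitch_0"]]]
    s15 <- slope_of[[st["stab_pitch_15"]]]
    s75 <- slope_of[[st["stab_pitch_75"]]]
    seq_ <- slope_of[[st["stab_pitch_eq"]]]

    if (st["stab_pitch_eq"] == "marginal") {
      # flat zero plateau spanning the equilibrium-fitting window
      c25 <- 0; c10 <- c25 - s15 * 15 * d2r; c0 <- c10 - s0 * 10 * d2r
      curve <- hermite_curve(
        c(0, 10, 25, 50, 90),
        c(c0, c10, 0, 0, s75 * 40 * d2r),
        c(s0, s15, 0, 0, s75))
    } else {
      # single crossing at 35 deg approached from the sign seq_ demands
      c30 <- -sign(seq_) * 0.05 - seq_ * 5 * d2r
      c10 <- c30 - s15 * 20 * d2r
      c0 <- c10 - s0 * 10 * d2r
      c50 <- seq_ * 15 * d2r
      curve <- hermite_curve(
        c(0, 10, 30, 35, 50, 90),
        c(c0, c10, c30, 0, c50, c50 + s75 * 40 * d2r),
        c(s0, s15, seq_, seq_, s75, s75))
    }

    truths[[i]] <- aero_truth(
      id, curve,
      roll_slopes = c(low = slope_of[[st["stab_roll_15"]]],
                      high = slope_of[[st["stab_roll_75"]]]),
      yaw_slopes = c(low = slope_of[[st["stab_yaw_15"]]],
                     high = slope_of[[st["stab_yaw_75"]]]),
      control = default_control_table(
        pitch_tail = ctrl_of[st[c("ctrl_pitch_taildorsi_15",
                                  "ctrl_pitch_taildorsi_75")]],
        pitch_prot = ctrl_of[st[c("ctrl_pitch_symprot_15",
                                  "ctrl_pitch_symprot_75")]],
        roll_tuck = ctrl_of[st[c("ctrl_roll_wingtuck_15",
                                 "ctrl_roll_wingtuck_75")]],
        roll_pron = ctrl_of[st[c("ctrl_roll_pronsup_15",
                                 "ctrl_roll_pronsup_75")]],
        yaw_tail = ctrl_of[st[c("ctrl_yaw_taillat_15",
                                "ctrl_yaw_taillat_75")]],
        yaw_pron = ctrl_of[st[c("ctrl_yaw_pronsup_15",
                                "ctrl_yaw_pronsup_75")]]),
      noise = noise)
    # the equilibrium character's truth is a property of the whole curve
    # (lowest qualifying crossing), not of the drawn label alone
    eqs <- truths[[i]]$slope_at$eq
    states[i, "stab_pitch_eq"] <-
      if (is.na(eqs)) "?" else
        c("stable", "marginal", "unstable")[sign(eqs) + 2]
  }
  list(truths = truths, states = states)
}
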