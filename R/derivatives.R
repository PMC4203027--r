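#' Locate pitching equilibria (trim points)
#'
#' Every sign change of the replicate-mean pitching-moment coefficient
#' between adjacent grid angles yields one crossing, located by linear
#' interpolation; exact zeros count as crossings at the grid angle.
#'
#' @param angle_deg sorted grid angles, degrees.
#' @param C mean coefficient at each angle.
#' @return data frame with `alpha_eq` (deg), bracketing indices `i_lo`,
#'   `i_hi`, and `local_slope` (rad^-1, secant slope of the bracketing
#'   segment); zero rows when the series never changes sign.
#' @export
find_equilibria <- function(angle_deg, C) {
  stopifnot(length(angle_deg) == length(C), length(angle_deg) >= 2)
  if (is.unsorted(angle_deg, strictly = TRUE)) {
    stop("find_equilibria: angles must be strictly increasing")
  }
  d2r <- pi / 180
  out <- list()
  for (i in seq_len(length(C) - 1)) {
    if (C[i] == 0) {
      out[[length(out) + 1]] <- data.frame(
        alpha_eq = angle_deg[i], i_lo = i, i_hi = i + 1,
        local_slope = (C[i + 1] - C[i]) /
          ((angle_deg[i + 1] - angle_deg[i]) * d2r))
    } else if (C[i] * C[i + 1] < 0) {
      frac <- C[i] / (C[i] - C[i + 1])
      out[[length(out) + 1]] <- data.frame(
        alpha_eq = angle_deg[i] + frac * (angle_deg[i + 1] - angle_deg[i]),
        i_lo = i, i_hi = i + 1,
        local_slope = (C[i + 1] - C[i]) /
          ((angle_deg[i + 1] - angle_deg[i]) * d2r))
    }
  }
  if (length(C) > 1 && C[length(C)] == 0) {
    out[[length(out) + 1]] <- data.frame(
      alpha_eq = angle_deg[length(C)], i_lo = length(C) - 1, i_hi = length(C),
      local_slope = (C[length(C)] - C[length(C) - 1]) /
        ((angle_deg[length(C)] - angle_deg[length(C) - 1]) * d2r))
  }
  if (!length(out)) {
    return(data.frame(alpha_eq = numeric(), i_lo = integer(),
                      i_hi = integer(), local_slope = numeric()))
  }
  do.call(rbind, out)
}

pick_equilibrium <- function(eqs) {
  if (!nrow(eqs)) return(NA_real_)
  neg <- which(eqs$local_slope < 0)
  if (length(neg)) eqs$alpha_eq[neg[1]] else eqs$alpha_eq[1]
}

#' Static-stability slope with 75% confidence interval
#'
#' Ordinary least-squares fit of the coefficient on angle (converted to
#' radians) over all replicate-level points within `window` degrees of the
#' evaluation angle, with a two-sided Student-t interval on the slope at the
#' requested confidence level. The sign of the slope is the stability
#' verdict: negative restores perturbations (stable), positive amplifies
#' them (unstable), zero within the interval is marginal.
#'
#' @param angle_deg,C replicate-level points.
#' @param a0_deg evaluation angle, degrees.
#' @param window half-width of the fitting window, degrees (default 10, i.e.
#'   three grid points at 5-degree spacing).
#' @param ci_level two-sided confidence level (default 0.75).
#' @return list with `slope`, `ci_low`, `ci_high` (rad^-1), `n_points`, `se`.
#'   On noise-free collinear input the interval has zero width.
#' @export
stability_slope <- function(angle_deg, C, a0_deg, window = 10,
                            ci_level = 0.75) {
  stopifnot(length(angle_deg) == length(C), ci_level > 0, ci_level < 1)
  keep <- abs(angle_deg - a0_deg) <= window + 1e-9
  x <- angle_deg[keep] * pi / 180
  y <- C[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2) {
    stop("stability_slope: fewer than 3 points (or <2 distinct angles) in ",
         "the window around ", a0_deg, " deg",
         call. = FALSE)
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  tq <- stats::qt((1 + ci_level) / 2, df = n - 2)
  list(slope = slope, ci_low = slope - tq * se, ci_high = slope + tq * se,
       n_points = n, se = se)
}

#' Control effectiveness from paired deflection series
#'
#' Central difference `(C_plus - C_minus) / (2 delta)` when both deflection
#' signs were tested, else one-sided `(C_plus - C_0) / delta` against the
#' undeflected baseline, averaged over grid points within the window around
#' the evaluation angle. The confidence interval comes from replicate
#' scatter: differences are averaged within each replicate pair (recordings
#' within one sweep share a tare state and are not independent) and a
#' two-sided t-interval is taken over replicates.
#'
#' @param baseline,plus,minus data frames with columns `angle_deg`,
#'   `replicate`, `C`; `minus` may be NULL for one-sided movements, in which
#'   case `baseline` is required.
#' @param delta_deg deflection extent, degrees (positive).
#' @param x0_deg window center on the series angle, degrees.
#' @param window half-width, degrees.
#' @param ci_level two-sided confidence level.
#' @return list with `slope`, `ci_low`, `ci_high` (rad^-1), `n_points`
#'   (number of replicate pairs).
#' @export
control_effectiveness <- function(baseline, plus, minus = NULL,
                                  delta_deg, x0_deg = 0, window = 10,
                                  ci_level = 0.75) {
  stopifnot(delta_deg > 0, ci_level > 0, ci_level < 1)
  clip <- function(d) d[abs(d$angle_deg - x0_deg) <= window + 1e-9, ]
  plus <- clip(plus)
  delta_rad <- delta_deg * pi / 180
  if (!is.null(minus)) {
    minus <- clip(minus)
    m <- merge(plus, minus, by = c("angle_deg", "replicate"),
               suffixes = c("_p", "_m"))
    if (!nrow(m)) stop("control_effectiveness: no shared (angle, replicate)")
    m$d <- (m$C_p - m$C_m) / (2 * delta_rad)
  } else {
    if (is.null(baseline)) {
      stop("control_effectiveness: baseline required for one-sided movement")
    }
    baseline <- clip(baseline)
    m <- merge(plus, baseline, by = c("angle_deg", "replicate"),
               suffixes = c("_p", "_0"))
    if (!nrow(m)) stop("control_effectiveness: no shared (angle, replicate)")
    m$d <- (m$C_p - m$C_0) / delta_rad
  }
  per_rep <- tapply(m$d, m$replicate, mean)
  R <- length(per_rep)
  est <- mean(per_rep)
  if (R >= 3) {
    se <- stats::sd(per_rep) / sqrt(R)
    tq <- stats::qt((1 + ci_level) / 2, df = R - 1)
    ci <- c(est - tq * se, est + tq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(slope = est, ci_low = ci[1], ci_high = ci[2], n_points = R)
}

est_row <- function(taxon, kind, axis, movement, eval_point, fit,
                    equilibrium_angle = NA_real_) {
  data.frame(taxon = taxon, kind = kind, axis = axis, movement = movement,
             evaluation_point = eval_point,
             slope = fit$slope, ci_low = fit$ci_low, ci_high = fit$ci_high,
             n_points = fit$n_points, equilibrium_angle = equilibrium_angle)
}

na_fit <- list(slope = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               n_points = 0L)

#' Estimate the 8 stability and 12 control derivatives for each taxon
#'
#' Stability: dC/dangle for {pitch, roll, yaw} at 15 and 75 degrees angle of
#' attack, plus pitch at 0 degrees and at the pitching equilibrium (the
#' lowest trim point with a locally negative slope if one exists, else the
#' lowest; all crossings are located first from replicate-mean sign changes).
#' Control: dC/ddelta for the six (axis, movement) pairs of
#' [default_movements()] at both regimes. A missing pitching equilibrium
#' yields an NA row (coded "?" downstream).
#'
#' @param coefs replicate-level coefficient records from
#'   [coefficient_records()] applied to [to_com_frame()] output.
#' @param movements movement table (default [default_movements()]).
#' @param aoa_regimes named low/high evaluation angles of attack, degrees.
#' @param window fitting half-width, degrees. @param ci_level CI level.
#' @return data frame of derivative estimates, 20 rows per taxon, with
#'   columns `taxon, kind, axis, movement, evaluation_point, slope, ci_low,
#'   ci_high, n_points, equilibrium_angle`.
#' @export
estimate_derivatives <- function(coefs, movements = default_movements(),
                                 aoa_regimes = c(low = 15, high = 75),
                                 window = 10, ci_level = 0.75) {
  out <- list()
  ccol <- c(pitch = "C_m", roll = "C_r", yaw = "C_y")
  for (tx in unique(coefs$taxon)) {
    dat <- coefs[coefs$taxon == tx, ]

    pb <- dat[dat$series == "pitch" & dat$movement == "none", ]
    for (a0 in c(0, aoa_regimes[["low"]], aoa_regimes[["high"]])) {
      fit <- stability_slope(pb$series_angle_deg, pb$C_m, a0, window, ci_level)
      lab <- if (a0 == 0) "0" else
        names(aoa_regimes)[match(a0, aoa_regimes)]
      lab <- c(`0` = "0", low = "15", high = "75")[[lab]]
      out[[length(out) + 1]] <-
        est_row(tx, "stability", "pitch", "none", lab, fit)
    }
    means <- stats::aggregate(list(C = pb$C_m),
                              by = list(angle = pb$series_angle_deg),
                              FUN = mean)
    means <- means[order(means$angle), ]
    eqs <- find_equilibria(means$angle, means$C)
    a_eq <- pick_equilibrium(eqs)
    fit_eq <- if (is.na(a_eq)) na_fit else
      stability_slope(pb$series_angle_deg, pb$C_m, a_eq, window, ci_level)
    out[[length(out) + 1]] <-
      est_row(tx, "stability", "pitch", "none", "eq", fit_eq, a_eq)

    for (axis in c("roll", "yaw")) {
      for (rname in c("low", "high")) {
        sb <- dat[dat$series == axis & dat$movement == "none" &
                    dat$regime == rname, ]
        fit <- stability_slope(sb$series_angle_deg, sb[[ccol[[axis]]]],
                               0, window, ci_level)
        out[[length(out) + 1]] <-
          est_row(tx, "stability", axis, "none",
                  as.character(aoa_regimes[[rname]]), fit)
      }
    }

    for (k in seq_len(nrow(movements))) {
      axis <- movements$axis[k]
      mvn <- movements$movement[k]
      ext <- movements$extent_deg[k]
      for (rname in c("low", "high")) {
        sel <- dat$series == axis & dat$regime == rname
        x0 <- if (axis == "pitch") aoa_regimes[[rname]] else 0
        mk <- function(d) data.frame(angle_deg = d$series_angle_deg,
                                     replicate = d$replicate,
                                     C = d[[ccol[[axis]]]])
        base <- mk(dat[sel & dat$movement == "none", ])
        plus <- mk(dat[sel & dat$movement == mvn & dat$delta_deg == ext, ])
        fit <- if (movements$two_sided[k]) {
          minus <- mk(dat[sel & dat$movement == mvn & dat$delta_deg == -ext, ])
          control_effectiveness(NULL, plus, minus, ext, x0, window, ci_level)
        } else {
          control_effectiveness(base, plus, NULL, ext, x0, window, ci_level)
        }
        out[[length(out) + 1]] <-
          est_row(tx, "control", axis, mvn,
                  as.character(aoa_regimes[[rname]]), fit)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
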