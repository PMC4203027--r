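# Shared helpers: small designs, quick truth objects, independent oracles.

quick_design <- function(...) {
  build_test_design(pitch_grid = seq(0, 90, by = 5),
                    body_grid = seq(-20, 20, by = 5), ...)
}

zero_noise <- function() noise_model(0, 0, 0, 0, 1)

# linear pitch truth: C_m = slope * (alpha - eq_deg), exact everywhere
linear_truth <- function(id = "lin", slope = -0.5, eq_deg = 20,
                         noise = zero_noise(),
                         control = full_control_table(0.2)) {
  d2r <- pi / 180
  aero_truth(id,
             hermite_curve(c(0, 90), slope * d2r * (c(0, 90) - eq_deg),
                           c(slope, slope)),
             roll_slopes = c(low = slope, high = slope),
             yaw_slopes = c(low = slope, high = slope),
             control = control, noise = noise)
}

full_control_table <- function(value = 0.2) {
  mv <- default_movements()
  do.call(rbind, lapply(seq_len(nrow(mv)), function(k) {
    data.frame(axis = mv$axis[k], movement = mv$movement[k],
               regime = c("low", "high"), dC_ddelta = value)
  }))
}

reduce_records <- function(records, geometry) {
  coefficient_records(to_com_frame(records), geometry)
}

# quaternion oracle for rotation composition (independent of euler_rotation)
quat_axis <- function(axis, angle) {
  h <- angle / 2
  v <- c(0, 0, 0); v[axis] <- sin(h)
  c(cos(h), v)
}
quat_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
quat_rotation <- function(phi, theta, psi) {
  quat_to_matrix(quat_mult(quat_axis(3, psi),
                           quat_mult(quat_axis(2, theta),
                                     quat_axis(1, phi))))
}

# exhaustive-enumeration parsimony oracle for small trees
brute_force_score <- function(tree, states, symbols) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  S <- length(symbols)
  obs <- match(unname(states[tree$tip.label]), symbols)  # NA for "?"
  free_tips <- which(is.na(obs))
  assign_mat <- as.matrix(expand.grid(rep(list(seq_len(S)),
                                          length(free_tips) + nnode)))
  best <- Inf
  edge <- tree$edge
  for (row in seq_len(nrow(assign_mat))) {
    full <- integer(ntip + nnode)
    full[seq_len(ntip)] <- obs
    if (length(free_tips)) {
      full[free_tips] <- assign_mat[row, seq_along(free_tips)]
    }
    full[ntip + seq_len(nnode)] <-
      assign_mat[row, length(free_tips) + seq_len(nnode)]
    changes <- sum(full[edge[, 1]] != full[edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

random_rooted_tree <- function(ntips) {
  tr <- ape::rtree(ntips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(ntips))
  tr
}
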