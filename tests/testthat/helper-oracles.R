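# Shared fixtures and independent oracles, built in code.

random_unit_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-3) return(v / n)
  }
}

# Explicit single-axis rotation matrices: the matrix-product oracle for
# composed rotations, written out independently of rotation_matrix().
oracle_rx <- function(deg) {
  t <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
}
oracle_ry <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), 0, sin(t)), c(0, 1, 0), c(-sin(t), 0, cos(t)))
}
oracle_rz <- function(deg) {
  t <- deg * pi / 180
  rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0), c(0, 0, 1))
}

# Closed-form normal-equations OLS oracle.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - slope * x - intercept
  list(slope = slope, intercept = intercept,
       residual_sd = sqrt(sum(resid^2) / (n - 2)))
}

# Internally consistent angle set: the projection angles of actual 3D
# directions, measured with the package's view conventions.
consistent_angle_set <- function(d_cardiac = random_unit_direction(),
                                 d_sn = random_unit_direction(),
                                 d_avca = random_unit_direction(),
                                 gamma = stats::runif(1, 0, 360),
                                 delta = stats::runif(1, 0, 360)) {
  list(
    cardiac = c(
      X_sgt = measure_plane_angle(d_cardiac, "sagittal"),
      X_frt = measure_plane_angle(d_cardiac, "frontal"),
      X_hzt = measure_plane_angle(d_cardiac, "horizontal")
    ),
    ccs = c(
      alpha_sgt = measure_plane_angle(d_sn, "sagittal"),
      alpha_frt = measure_plane_angle(d_sn, "frontal"),
      alpha_hzt = measure_plane_angle(d_sn, "horizontal"),
      beta_sgt = measure_plane_angle(d_avca, "sagittal"),
      beta_frt = measure_plane_angle(d_avca, "frontal"),
      beta_hzt = measure_plane_angle(d_avca, "horizontal", "sagittal-line"),
      gamma = gamma, delta = delta
    )
  )
}

# Minimal hand-placed geometry for axis-extraction tests.
simple_geometry <- function() {
  ccs_geometry("simple", list(
    aortic_valve_center = c(0, 0, 0),
    lv_apex = c(0, 0, -80),
    sn_head_center = c(-10, 30, 30),
    terminal_crest_top = c(-5, 15, 15),
    compact_node_end = c(-5, 5, -5),
    rbb_branch_point = c(5, 10, -10),
    rbb_distal_point = c(10, 20, -12),
    lbb_center_point = c(15, 2, -12)
  ))
}
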