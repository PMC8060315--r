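# Stepwise standing-to-lying rotation simulation: rotate a canonical heart
# through a k*SD grid on the three body axes, measure the angle trajectories
# and classify concomitant vs counter rotation per component and plane.

#' Simulation grid for the stepwise rotation
#'
#' Five positions by default: k in {-2, -1, 0, +1, +2} standard deviations
#' from the mean pose on each axis, with the per-axis steps equal to the
#' published cardiac inclination SDs. Standing is the k = -1 pose and lying
#' the k = +1 pose.
#'
#' @param k_values Strictly increasing multipliers of the per-axis step.
#' @param step_sgt,step_frt,step_hzt Per-axis steps in degrees (the cohort
#'   SDs; a step of 0 freezes that axis).
#' @return Object of class `simulation_grid`.
#' @export
simulation_grid <- function(k_values = -2:2, step_sgt = 12.1,
                            step_frt = 8.1, step_hzt = 13.4) {
  if (length(k_values) < 1 || any(diff(k_values) <= 0))
    stop_ccs("k_values must be strictly increasing",
             "ccsmorph_invalid_params")
  steps <- c(sagittal = step_sgt, frontal = step_frt, horizontal = step_hzt)
  if (!all(is.finite(steps)) || any(steps < 0))
    stop_ccs("steps must be finite and non-negative",
             "ccsmorph_invalid_params")
  structure(list(k_values = as.numeric(k_values), steps = steps),
            class = "simulation_grid")
}

#' Rotation increments of the grid positions
#'
#' Position k is rotated by `(k * step_sgt, k * step_frt, k * step_hzt)`
#' relative to the k = 0 (mean) pose — absolute offsets from the mean, not
#' cumulative steps.
#'
#' @param grid A [simulation_grid()].
#' @return Data.frame: `position`, `k`, `sgt`, `frt`, `hzt` (degrees).
#' @export
stepwise_positions <- function(grid) {
  stopifnot(inherits(grid, "simulation_grid"))
  data.frame(position = seq_along(grid$k_values), k = grid$k_values,
             sgt = grid$k_values * grid$steps[["sagittal"]],
             frt = grid$k_values * grid$steps[["frontal"]],
             hzt = grid$k_values * grid$steps[["horizontal"]])
}

sim_pivot <- function(geometry, pivot = NULL) {
  if (!is.null(pivot)) {
    if (is.character(pivot)) return(landmark_point(geometry, pivot))
    stopifnot(is.numeric(pivot), length(pivot) == 3)
    return(as.numeric(pivot))
  }
  if (has_landmark(geometry, "venous_anchor"))
    landmark_point(geometry, "venous_anchor")
  else
    landmark_point(geometry, "aortic_valve_center")
}

#' Simulate the stepwise standing-to-lying transformation
#'
#' Two simulation modes:
#' * `"rigid"`: at each grid position the whole geometry (heart and CCS
#'   together) is rotated by [compose_standing_lying_rotation()] about the
#'   pivot and all angles are re-measured. This is what a volume-rotation in
#'   a DICOM viewer physically does; projected CCS angles may then respond
#'   non-concomitantly in one plane because all three axis rotations alter
#'   each 2D projection.
#' * `"regression"`: the cardiac angles move by the grid increments
#'   plane-by-plane and each CCS angle is propagated from the measured base
#'   pose along its fitted slope,
#'   `ccs(k) = ccs(0) + slope * (X(k) - X(0))`. This is what the per-plane
#'   published fits describe. Both modes reproduce the base measurement at
#'   k = 0.
#'
#' @param geometry Base [ccs_geometry()] at the mean pose.
#' @param grid A [simulation_grid()].
#' @param mode `"rigid"` or `"regression"`.
#' @param models Regression table used in regression mode
#'   (default [default_regression_models()]).
#' @param pivot Rotation center for rigid mode: a landmark name, a length-3
#'   point, or `NULL` for the default (the `venous_anchor` landmark when
#'   present — the venous fixation region that tethers the sinus node —
#'   else the aortic valve center).
#' @return Data.frame of class `rotation_trajectory`: one row per position
#'   with `position`, `k`, the applied increments, and all eleven measured
#'   (rigid) or propagated (regression) angles. Attributes: `mode`, `base`
#'   (base-pose measurement) and, in rigid mode, `geometries` (the rotated
#'   geometries).
#' @export
simulate_transformation <- function(geometry, grid = simulation_grid(),
                                    mode = c("rigid", "regression"),
                                    models = default_regression_models(),
                                    pivot = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "ccs_geometry"),
            inherits(grid, "simulation_grid"))
  pos <- stepwise_positions(grid)
  base <- measure_all_angles(geometry, on_degenerate = "na")
  angle_cols <- ANGLE_DEFS$angle

  if (mode == "rigid") {
    ctr <- sim_pivot(geometry, pivot)
    geoms <- vector("list", nrow(pos))
    rows <- vector("list", nrow(pos))
    for (i in seq_len(nrow(pos))) {
      R <- compose_standing_lying_rotation(pos$sgt[i], pos$frt[i], pos$hzt[i])
      g <- apply_rotation(geometry, R, center = ctr)
      g$heart_id <- sprintf("%s_k%+g", geometry$heart_id, pos$k[i])
      geoms[[i]] <- g
      rows[[i]] <- measure_all_angles(g, on_degenerate = "na")
    }
    ang <- do.call(rbind, rows)[, angle_cols]
  } else {
    ang <- base[rep(1, nrow(pos)), angle_cols, drop = FALSE]
    inc <- list(sagittal = pos$sgt, frontal = pos$frt, horizontal = pos$hzt)
    # cardiac angles move plane-by-plane by the grid increments
    for (i in seq_len(3)) {
      xv <- c("X_sgt", "X_frt", "X_hzt")[i]
      ang[[xv]] <- base[[xv]] + inc[[PLANE_NAMES[i]]]
    }
    for (j in seq_len(nrow(models))) {
      m <- models[j, ]
      ang[[m$pair_id]] <- base[[m$pair_id]] +
        m$slope * (ang[[m$x_var]] - base[[m$x_var]])
    }
    rownames(ang) <- NULL
  }

  out <- cbind(pos, ang)
  attr(out, "mode") <- mode
  attr(out, "base") <- base
  if (mode == "rigid") attr(out, "geometries") <- geoms
  class(out) <- c("rotation_trajectory", class(out))
  out
}

# Unwrap a degree sequence onto a contiguous branch (removes 360-degree
# jumps between consecutive positions).
unwrap_degrees <- function(deg) {
  if (length(deg) < 2) return(deg)
  out <- deg
  for (i in 2:length(deg)) {
    if (is.na(out[i]) || is.na(out[i - 1])) next
    out[i] <- out[i - 1] + circular_diff_deg(deg[i], out[i - 1] %% 360)
  }
  out
}

component_angle_column <- function(component, plane) {
  component <- match.arg(component, c("sn", "avca", "rbb", "lbb"))
  plane <- match.arg(plane, PLANE_NAMES)
  suffix <- c(sagittal = "sgt", frontal = "frt", horizontal = "hzt")[plane]
  col <- switch(component,
    sn = paste0("alpha_", suffix),
    avca = paste0("beta_", suffix),
    rbb = if (plane == "horizontal") "gamma" else NA_character_,
    lbb = if (plane == "horizontal") "delta" else NA_character_
  )
  if (is.na(col))
    stop_ccs("bundle-branch angles are measured in the horizontal plane only",
             "ccsmorph_invalid_input")
  col
}

#' Classify a component's rotation direction in one plane
#'
#' Sign of the least-squares slope of the component's (unwrapped) projected
#' angle against the (unwrapped) cardiac angle of the same plane across the
#' trajectory positions: `"concomitant"` for a positive slope, `"counter"`
#' for a negative one, `"flat"` when |slope| < 0.01 deg/deg (numerical
#' guard).
#'
#' @param trajectory A [simulate_transformation()] result.
#' @param component One of `"sn"`, `"avca"`, `"rbb"`, `"lbb"`.
#' @param plane Plane name (`"horizontal"` only for `rbb`/`lbb`).
#' @return List with `classification`, `slope` (deg/deg) and `n_positions`.
#' @export
classify_rotation_direction <- function(trajectory, component, plane) {
  stopifnot(inherits(trajectory, "rotation_trajectory"))
  col <- component_angle_column(component, plane)
  xcol <- c(sagittal = "X_sgt", frontal = "X_frt",
            horizontal = "X_hzt")[plane]
  x <- unwrap_degrees(trajectory[[xcol]])
  y <- unwrap_degrees(trajectory[[col]])
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 2)
    stop_ccs("need at least 2 positions with valid angles",
             "ccsmorph_invalid_input")
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) < 1e-12)
    stop_ccs("cardiac angle does not vary across positions: cannot classify",
             "ccsmorph_invalid_input")
  slope <- stats::cov(x, y) / stats::var(x)
  cls <- if (abs(slope) < 0.01) "flat"
         else if (slope > 0) "concomitant" else "counter"
  list(classification = cls, slope = slope, n_positions = sum(keep))
}

#' Classify all component/plane pairs of a trajectory
#'
#' @param trajectory A [simulate_transformation()] result.
#' @return Data.frame: `component`, `plane`, `slope`, `classification`.
#' @export
classify_all_directions <- function(trajectory) {
  pairs <- data.frame(
    component = c("sn", "sn", "sn", "avca", "avca", "avca", "rbb", "lbb"),
    plane = c(PLANE_NAMES, PLANE_NAMES, "horizontal", "horizontal"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cl <- tryCatch(
      classify_rotation_direction(trajectory, pairs$component[i],
                                  pairs$plane[i]),
      ccsmorph_error = function(e) list(classification = NA_character_,
                                        slope = NA_real_)
    )
    data.frame(component = pairs$component[i], plane = pairs$plane[i],
               slope = cl$slope, classification = cl$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standing-versus-lying comparison
#'
#' Pairs the k = -1 (standing) and k = +1 (lying) poses of the rigid
#' simulation: the two-pose angle table, per-component/plane direction
#' classifications over the full grid, and the positional displacement (mm)
#' of the sinus-node head landmark and of the AV-conduction-axis midpoint
#' between the two poses. With the default pivot at the venous anchor the
#' SN, tethered near the pivot, moves less than the AVCA deep in the
#' ventricular mass (the lever-arm effect).
#'
#' @param geometry Base [ccs_geometry()] at the mean pose.
#' @param grid A [simulation_grid()] containing k = -1 and k = +1.
#' @param mode,models,pivot Passed to [simulate_transformation()].
#' @return List with `angles` (rows k = -1 and +1), `directions`
#'   (classification table), `sn_displacement_mm`, `avca_displacement_mm`,
#'   and `trajectory` (the full simulation).
#' @export
standing_lying_comparison <- function(geometry, grid = simulation_grid(),
                                      mode = "rigid",
                                      models = default_regression_models(),
                                      pivot = NULL) {
  if (!all(c(-1, 1) %in% grid$k_values))
    stop_ccs("grid must contain k = -1 (standing) and k = +1 (lying)",
             "ccsmorph_invalid_params")
  traj <- simulate_transformation(geometry, grid, mode = mode,
                                  models = models, pivot = pivot)
  two <- traj[traj$k %in% c(-1, 1), , drop = FALSE]

  displacement <- function(point_fn) {
    if (identical(attr(traj, "mode"), "rigid")) {
      g <- attr(traj, "geometries")
      i_st <- which(traj$k == -1); i_ly <- which(traj$k == 1)
      vec_norm(point_fn(g[[i_ly]]) - point_fn(g[[i_st]]))
    } else NA_real_
  }
  sn_disp <- displacement(function(g) landmark_point(g, "sn_head_center"))
  avca_disp <- displacement(function(g)
    (landmark_point(g, "compact_node_end") +
       landmark_point(g, "rbb_branch_point")) / 2)

  list(angles = two,
       directions = classify_all_directions(traj),
       sn_displacement_mm = sn_disp,
       avca_displacement_mm = avca_disp,
       trajectory = traj)
}
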