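# Thoracic coordinate frame, body-axis rotations, plane projections and
# signed projection-angle measurement.
#
# Frame convention (right-handed): origin at the center of the aortic valvar
# orifice; +x toward the subject's left, +y dorsal, +z cranial.

#' Thoracic coordinate frame
#'
#' Constructs the body-axis frame all geometry in this package lives in:
#' origin at the aortic valve center, `+x` toward the subject's left,
#' `+y` dorsal, `+z` cranial (right-handed).
#'
#' @param origin Numeric length-3, frame origin in mm.
#' @return An object of class `thoracic_frame` with fields `origin`,
#'   `axis_left`, `axis_dorsal`, `axis_cranial`.
#' @export
#' @examples
#' f <- thoracic_frame()
#' crossprod(cbind(f$axis_left, f$axis_dorsal, f$axis_cranial))  # identity
thoracic_frame <- function(origin = c(0, 0, 0)) {
  stopifnot(is.numeric(origin), length(origin) == 3, all(is.finite(origin)))
  structure(
    list(
      origin       = as.numeric(origin),
      axis_left    = c(1, 0, 0),
      axis_dorsal  = c(0, 1, 0),
      axis_cranial = c(0, 0, 1)
    ),
    class = "thoracic_frame"
  )
}

#' @export
print.thoracic_frame <- function(x, ...) {
  cat("Thoracic frame: origin (", paste(format(x$origin), collapse = ", "),
      ") mm; +x left, +y dorsal, +z cranial\n", sep = "")
  invisible(x)
}

PLANE_NAMES <- c("sagittal", "frontal", "horizontal")

# Viewing/reference conventions per plane. Each view is defined by an ordered
# in-plane basis (e1 = reference line, e2 = the 90-degree direction in the
# positive rotational sense) so that the in-plane angle of a direction d is
# atan2(d.e2, d.e1):
#   sagittal   (y-z plane, seen from the subject's right): reference is the
#              horizontal (dorso-ventral) line +y, positive toward cranial;
#   frontal    (x-z plane, seen from the front): reference is the vertical
#              sagittal line +z, positive toward the subject's left;
#   horizontal (x-y plane, seen from above): reference is either the
#              horizontal (left-right) line +x (cardiac and sinus-node
#              angles) or the sagittal line +y (AV-axis and bundle-branch
#              angles); both share the same positive sense (x toward y).
# With these choices a positive rotation about each plane's normal (+x, +y,
# +z respectively, all standard right-handed rotations) advances every
# in-plane angle by the rotation angle.
plane_view <- function(plane = PLANE_NAMES,
                       reference = c("default", "horizontal-line", "sagittal-line")) {
  plane <- match.arg(plane)
  reference <- match.arg(reference)
  if (reference == "default") {
    reference <- switch(plane,
      sagittal = "horizontal-line",
      frontal = "sagittal-line",
      horizontal = "horizontal-line"
    )
  }
  v <- switch(plane,
    sagittal = {
      if (reference != "horizontal-line")
        stop("the sagittal view is referenced to the horizontal line",
             call. = FALSE)
      list(e1 = c(0, 1, 0), e2 = c(0, 0, 1), normal = c(1, 0, 0),
           viewer = "right-lateral")
    },
    frontal = {
      if (reference != "sagittal-line")
        stop("the frontal view is referenced to the vertical sagittal line",
             call. = FALSE)
      list(e1 = c(0, 0, 1), e2 = c(1, 0, 0), normal = c(0, 1, 0),
           viewer = "frontal")
    },
    horizontal = {
      if (reference == "horizontal-line")
        list(e1 = c(1, 0, 0), e2 = c(0, 1, 0), normal = c(0, 0, 1),
             viewer = "superior")
      else
        list(e1 = c(0, 1, 0), e2 = c(-1, 0, 0), normal = c(0, 0, 1),
             viewer = "superior")
    }
  )
  c(list(name = plane, reference = reference), v)
}

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12)
    stop_ccs("cannot normalize a zero vector", "ccsmorph_degenerate_axis")
  v / n
}

stop_ccs <- function(msg, class) {
  stop(structure(
    class = c(class, "ccsmorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

wrap_degrees <- function(deg) {
  out <- deg %% 360
  # map exact 360 (possible through floating error on values just below 0)
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Rotation matrix about a body axis
#'
#' Rotation about the thoracic axis normal to the named plane (sagittal ->
#' left axis, frontal -> dorsal axis, horizontal -> cranial axis). A positive
#' angle advances every in-plane projection angle of that plane by the same
#' amount.
#'
#' @param plane One of `"sagittal"`, `"frontal"`, `"horizontal"`.
#' @param degrees Rotation angle in degrees.
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(plane, degrees) {
  plane <- match.arg(plane, PLANE_NAMES)
  if (!is.numeric(degrees) || length(degrees) != 1 || !is.finite(degrees))
    stop_ccs("rotation angle must be a single finite number",
             "ccsmorph_invalid_input")
  th <- degrees * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(plane,
    sagittal = matrix(c(1, 0, 0,
                        0, c_, -s_,
                        0, s_, c_), 3, 3, byrow = TRUE),
    frontal = matrix(c(c_, 0, s_,
                       0, 1, 0,
                       -s_, 0, c_), 3, 3, byrow = TRUE),
    horizontal = matrix(c(c_, -s_, 0,
                          s_, c_, 0,
                          0, 0, 1), 3, 3, byrow = TRUE)
  )
}

#' Rotate a direction, point set or geometry about a body axis
#'
#' Applies the rigid rotation [rotation_matrix()] about the named body axis.
#' Directions and landmark coordinates may be supplied as a length-3 vector,
#' an n x 3 matrix (rows rotated), or a [ccs_geometry()] (all landmarks and
#' centerline points rotated about `center`).
#'
#' @param x Length-3 numeric vector, n x 3 matrix, or `ccs_geometry`.
#' @param plane Plane whose normal is the rotation axis.
#' @param degrees Rotation angle in degrees.
#' @param center Length-3 rotation center in mm (ignored for bare
#'   directions, which are translation-free).
#' @return Object of the same kind as `x`, rigidly rotated.
#' @export
#' @examples
#' d <- c(0, 1, 0)
#' rotate_about_body_axis(d, "sagittal", 90)  # ~ c(0, 0, 1)
rotate_about_body_axis <- function(x, plane, degrees, center = c(0, 0, 0)) {
  R <- rotation_matrix(plane, degrees)
  apply_rotation(x, R, center = center)
}

#' Compose the three-axis standing/lying rotation
#'
#' Returns the single rigid rotation obtained by rotating about the fixed
#' thoracic axes in the documented extrinsic order: sagittal first, then
#' frontal, then horizontal.
#'
#' @param sgt_deg,frt_deg,hzt_deg Rotation angles in degrees about the
#'   sagittal, frontal and horizontal plane normals.
#' @param order Character vector permutation of the three plane names giving
#'   the application order (first applied first).
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
compose_standing_lying_rotation <- function(sgt_deg, frt_deg, hzt_deg,
                                            order = c("sagittal", "frontal",
                                                      "horizontal")) {
  if (!setequal(order, PLANE_NAMES) || length(order) != 3)
    stop_ccs("`order` must be a permutation of the three plane names",
             "ccsmorph_invalid_input")
  ang <- c(sagittal = sgt_deg, frontal = frt_deg, horizontal = hzt_deg)
  if (!all(is.finite(ang)))
    stop_ccs("rotation angles must be finite", "ccsmorph_invalid_input")
  R <- diag(3)
  for (pl in order) R <- rotation_matrix(pl, ang[[pl]]) %*% R
  R
}

#' Apply a rotation operator to a direction, point set or geometry
#'
#' @param x Length-3 vector, n x 3 matrix, or `ccs_geometry`.
#' @param R 3x3 rotation matrix.
#' @param center Rotation center for point sets and geometries.
#' @return Rotated object of the same kind.
#' @export
apply_rotation <- function(x, R, center = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (inherits(x, "ccs_geometry")) {
    x$landmarks <- apply_rotation(x$landmarks, R, center)
    x$centerlines <- lapply(x$centerlines, apply_rotation, R = R,
                            center = center)
    return(x)
  }
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop_ccs("point matrix must have 3 columns",
                               "ccsmorph_invalid_input")
    if (!all(is.finite(x))) stop_ccs("non-finite coordinates",
                                     "ccsmorph_invalid_input")
    ctr <- matrix(center, nrow(x), 3, byrow = TRUE)
    out <- (x - ctr) %*% t(R) + ctr
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (is.numeric(x) && length(x) == 3) {
    if (!all(is.finite(x))) stop_ccs("non-finite coordinates",
                                     "ccsmorph_invalid_input")
    return(as.numeric(R %*% x))
  }
  stop_ccs("cannot rotate object of this kind", "ccsmorph_invalid_input")
}

#' Project a direction onto a thoracic plane
#'
#' Orthogonal projection, returned in the plane's 2D view coordinates
#' (u along the reference line, v along the 90-degree positive-sense
#' direction).
#'
#' @param direction Length-3 numeric, non-zero.
#' @param plane Plane name.
#' @param reference Reference line for the view (`"default"` picks the
#'   plane's conventional reference).
#' @return Length-2 numeric `c(u, v)`.
#' @export
project_to_plane <- function(direction, plane, reference = "default") {
  v <- plane_view(plane, reference)
  if (!is.numeric(direction) || length(direction) != 3 ||
      !all(is.finite(direction)))
    stop_ccs("direction must be a finite length-3 numeric",
             "ccsmorph_invalid_input")
  p <- c(sum(direction * v$e1), sum(direction * v$e2))
  if (vec_norm(p) < 1e-9)
    stop_ccs(sprintf("direction is normal to the %s plane: degenerate projection",
                     v$name),
             "ccsmorph_degenerate_projection")
  p
}

#' Measure a signed projection angle in a thoracic plane
#'
#' Angle of the projected direction from the plane's reference line,
#' increasing in the view's positive rotational sense, wrapped to [0, 360).
#'
#' @inheritParams project_to_plane
#' @return Angle in degrees in `[0, 360)`.
#' @export
#' @examples
#' measure_plane_angle(c(0, 1, 0), "sagittal")          # 0
#' measure_plane_angle(c(0, 0, 1), "sagittal")          # 90
measure_plane_angle <- function(direction, plane, reference = "default") {
  p <- project_to_plane(direction, plane, reference)
  wrap_degrees(atan2(p[2], p[1]) * 180 / pi)
}

#' Unit direction realizing a given in-plane angle
#'
#' Inverse of [measure_plane_angle()] restricted to the plane: the unit
#' vector lying in `plane` whose view angle from the reference line equals
#' `degrees`.
#'
#' @param plane Plane name.
#' @param degrees Target angle in degrees.
#' @param reference Reference line for the view.
#' @return Unit length-3 numeric lying in the plane.
#' @export
direction_from_plane_angle <- function(plane, degrees, reference = "default") {
  v <- plane_view(plane, reference)
  th <- degrees * pi / 180
  cos(th) * v$e1 + sin(th) * v$e2
}

# Smallest signed circular difference a - b in degrees, in (-180, 180].
circular_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Least-squares 3D direction from plane projection angles
#'
#' A 3D axis has two degrees of freedom but up to three plane projection
#' angles may be prescribed, so the system is over-determined. Each target
#' angle constrains the axis to be orthogonal to the in-plane vector
#' perpendicular to the target direction; the axis is taken as the unit
#' vector minimizing the sum of squared residuals of those constraints
#' (the smallest-eigenvalue eigenvector of the constraint scatter matrix,
#' a weighted circular least-squares fit where each plane's angular residual
#' is weighted by the axis' projection magnitude in that plane). For an
#' internally consistent set of angles the fit is exact.
#'
#' @param targets A data.frame with columns `plane`, `reference`, `angle`
#'   (degrees), one row per prescribed projection angle (2 or 3 rows).
#' @return List with `direction` (unit length-3), `residual_deg` (RMS
#'   circular residual of the re-measured angles, degrees) and
#'   `residuals_deg` (per-plane signed residuals).
#' @export
#' @examples
#' tg <- data.frame(plane = c("sagittal", "horizontal"),
#'                  reference = c("default", "default"),
#'                  angle = c(99.8, 61.5))
#' fit <- ls_direction_from_plane_angles(tg)
#' measure_plane_angle(fit$direction, "sagittal")
ls_direction_from_plane_angles <- function(targets) {
  stopifnot(is.data.frame(targets),
            all(c("plane", "angle") %in% names(targets)),
            nrow(targets) >= 2)
  if (is.null(targets$reference)) targets$reference <- "default"
  if (!all(is.finite(targets$angle)))
    stop_ccs("target angles must be finite", "ccsmorph_invalid_input")
  W <- matrix(0, 3, 3)
  us <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    v <- plane_view(targets$plane[i], targets$reference[i])
    th <- targets$angle[i] * pi / 180
    u <- cos(th) * v$e1 + sin(th) * v$e2        # target in-plane direction
    w <- -sin(th) * v$e1 + cos(th) * v$e2       # in-plane perpendicular
    us[[i]] <- u
    W <- W + tcrossprod(w)
  }
  eg <- eigen(W, symmetric = TRUE)
  d <- eg$vectors[, 3]                           # smallest eigenvalue
  # orient: the projections should point along the targets, not against them
  score <- sum(vapply(us, function(u) sum(d * u), numeric(1)))
  if (score < 0) d <- -d
  d <- unit_vector(d)
  res <- vapply(seq_len(nrow(targets)), function(i) {
    m <- tryCatch(
      measure_plane_angle(d, targets$plane[i], targets$reference[i]),
      ccsmorph_degenerate_projection = function(e) NA_real_
    )
    if (is.na(m)) return(NA_real_)
    circular_diff_deg(m, targets$angle[i])
  }, numeric(1))
  list(direction = d,
       residual_deg = sqrt(mean(res^2, na.rm = TRUE)),
       residuals_deg = stats::setNames(res, targets$plane))
}

# Total-least-squares direction of the line through a small set of 3D points
# (first principal axis of the centered coordinates).
tls_line_direction <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 2)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  if (max(abs(X)) < 1e-9)
    stop_ccs("points are coincident: degenerate axis",
             "ccsmorph_degenerate_axis")
  sv <- svd(X)
  unit_vector(sv$v[, 1])
}

landmark_point <- function(geometry, name) {
  lm <- geometry$landmarks
  if (!(name %in% rownames(lm)))
    stop_ccs(sprintf("missing landmark '%s'", name),
             "ccsmorph_missing_landmark")
  as.numeric(lm[name, ])
}

has_landmark <- function(geometry, name) name %in% rownames(geometry$landmarks)

axis_between <- function(geometry, from, to) {
  a <- landmark_point(geometry, from)
  b <- landmark_point(geometry, to)
  if (vec_norm(b - a) < 1e-9)
    stop_ccs(sprintf("landmarks '%s' and '%s' are coincident: degenerate axis",
                     from, to),
             "ccsmorph_degenerate_axis")
  unit_vector(b - a)
}

#' Extract the anatomical reference axes of one heart
#'
#' * cardiac axis: from the aortic valve center to the left-ventricular apex;
#' * sinus-node (SN) axis: total-least-squares line through the SN head
#'   center, the top of the terminal crest and the aortic valve center,
#'   oriented from the SN head toward the valve center;
#' * atrioventricular conduction axis (AVCA): from the end of the compact AV
#'   node to the branching point of the right bundle branch.
#'
#' @param geometry A [ccs_geometry()].
#' @return List with unit directions `cardiac`, `sn`, `avca` and
#'   `sn_fit_rms_mm`, the RMS orthogonal distance of the three SN landmarks
#'   from the fitted line.
#' @export
extract_reference_axes <- function(geometry) {
  stopifnot(inherits(geometry, "ccs_geometry"))
  cardiac <- axis_between(geometry, "aortic_valve_center", "lv_apex")
  sn_pts <- rbind(
    landmark_point(geometry, "sn_head_center"),
    landmark_point(geometry, "terminal_crest_top"),
    landmark_point(geometry, "aortic_valve_center")
  )
  sn <- tls_line_direction(sn_pts)
  head_to_valve <- landmark_point(geometry, "aortic_valve_center") -
    landmark_point(geometry, "sn_head_center")
  if (vec_norm(head_to_valve) < 1e-9)
    stop_ccs("SN head coincides with the aortic valve center: degenerate axis",
             "ccsmorph_degenerate_axis")
  if (sum(sn * head_to_valve) < 0) sn <- -sn
  ctr <- colMeans(sn_pts)
  off <- sweep(sn_pts, 2, ctr)
  perp <- off - tcrossprod(off %*% sn, sn)
  avca <- axis_between(geometry, "compact_node_end", "rbb_branch_point")
  list(cardiac = cardiac, sn = sn, avca = avca,
       sn_fit_rms_mm = sqrt(mean(rowSums(perp^2))))
}

# Measurement conventions for the full angle set: which axis, plane and
# reference line each reported angle uses. Cardiac and SN horizontal angles
# are referenced to the horizontal line; AV-axis and bundle-branch
# horizontal angles to the sagittal line.
ANGLE_DEFS <- data.frame(
  angle = c("X_sgt", "X_frt", "X_hzt",
            "alpha_sgt", "alpha_frt", "alpha_hzt",
            "beta_sgt", "beta_frt", "beta_hzt",
            "gamma", "delta"),
  axis = c(rep("cardiac", 3), rep("sn", 3), rep("avca", 3), "rbb", "lbb"),
  plane = c(rep(c("sagittal", "frontal", "horizontal"), 3),
            "horizontal", "horizontal"),
  reference = c("horizontal-line", "sagittal-line", "horizontal-line",
                "horizontal-line", "sagittal-line", "horizontal-line",
                "horizontal-line", "sagittal-line", "sagittal-line",
                "sagittal-line", "sagittal-line"),
  stringsAsFactors = FALSE
)

#' Measure the full cardiac and CCS angle set of one heart
#'
#' Extracts the reference axes and measures the three cardiac projection
#' angles (`X_sgt`, `X_frt`, `X_hzt`), the three sinus-node angles
#' (`alpha_*`), the three proximal AV-conduction-axis angles (`beta_*`), and
#' the horizontal-plane right and left bundle-branch angles (`gamma`,
#' `delta`; `NA` when the bundle-branch landmarks are absent, as they are
#' measured in the horizontal plane only).
#'
#' @param geometry A [ccs_geometry()].
#' @param on_degenerate `"error"` (default) to fail on a degenerate
#'   projection, `"na"` to record `NA` with a warning.
#' @return One-row data.frame: `heart_id` plus the eleven angle columns in
#'   degrees, each in `[0, 360)`.
#' @export
measure_all_angles <- function(geometry, on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  axes <- extract_reference_axes(geometry)
  axes$rbb <- if (has_landmark(geometry, "rbb_branch_point") &&
                  has_landmark(geometry, "rbb_distal_point"))
    axis_between(geometry, "rbb_branch_point", "rbb_distal_point") else NULL
  axes$lbb <- if (has_landmark(geometry, "rbb_branch_point") &&
                  has_landmark(geometry, "lbb_center_point"))
    axis_between(geometry, "rbb_branch_point", "lbb_center_point") else NULL
  vals <- vapply(seq_len(nrow(ANGLE_DEFS)), function(i) {
    def <- ANGLE_DEFS[i, ]
    ax <- axes[[def$axis]]
    if (is.null(ax)) return(NA_real_)
    if (on_degenerate == "error")
      return(measure_plane_angle(ax, def$plane, def$reference))
    tryCatch(measure_plane_angle(ax, def$plane, def$reference),
             ccsmorph_degenerate_projection = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  out <- as.data.frame(as.list(stats::setNames(vals, ANGLE_DEFS$angle)))
  cbind(data.frame(heart_id = geometry$heart_id, stringsAsFactors = FALSE),
        out)
}

#' Measure angles for a whole cohort
#'
#' @param cohort List of [ccs_geometry()] objects.
#' @param on_degenerate Passed to [measure_all_angles()].
#' @return Data.frame with one row per heart.
#' @export
measure_cohort_angles <- function(cohort, on_degenerate = "error") {
  stopifnot(length(cohort) >= 1)
  do.call(rbind, lapply(cohort, measure_all_angles,
                        on_degenerate = on_degenerate))
}
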