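# Geometry container: named landmarks and per-component centerlines of one
# heart in the thoracic frame.

#' CCS geometry of one heart
#'
#' Container for the named 3D landmarks (mm, thoracic frame) and optional
#' per-component centerline polylines of a single heart. Required landmarks
#' for axis extraction are `aortic_valve_center`, `lv_apex`,
#' `sn_head_center`, `terminal_crest_top`, `compact_node_end`,
#' `rbb_branch_point`; optional ones are `rbb_distal_point`,
#' `lbb_center_point` and `venous_anchor` (rotation pivot of the
#' standing/lying simulation).
#'
#' @param heart_id Character identifier.
#' @param landmarks Named n x 3 numeric matrix (rownames are landmark names,
#'   columns x/y/z in mm) or a named list of length-3 vectors.
#' @param centerlines Named list of m x 3 matrices (polylines, mm).
#' @param provenance Optional list of generator truth (true angles,
#'   dimensions, fit residuals) carried along for synthetic hearts.
#' @return Object of class `ccs_geometry`.
#' @export
ccs_geometry <- function(heart_id, landmarks, centerlines = list(),
                         provenance = NULL) {
  if (is.list(landmarks) && !is.data.frame(landmarks))
    landmarks <- do.call(rbind, landmarks)
  stopifnot(is.matrix(landmarks), ncol(landmarks) == 3)
  if (is.null(rownames(landmarks)) || anyDuplicated(rownames(landmarks)))
    stop_ccs("landmarks must have unique row names", "ccsmorph_schema_error")
  if (!all(is.finite(landmarks)))
    stop_ccs("landmark coordinates must be finite", "ccsmorph_invalid_input")
  colnames(landmarks) <- c("x_mm", "y_mm", "z_mm")
  stopifnot(is.list(centerlines))
  for (nm in names(centerlines)) {
    cl <- centerlines[[nm]]
    stopifnot(is.matrix(cl), ncol(cl) == 3)
    if (!all(is.finite(cl)))
      stop_ccs(sprintf("centerline '%s' has non-finite coordinates", nm),
               "ccsmorph_invalid_input")
  }
  structure(
    list(heart_id = as.character(heart_id), landmarks = landmarks,
         centerlines = centerlines, provenance = provenance),
    class = "ccs_geometry"
  )
}

#' @export
print.ccs_geometry <- function(x, ...) {
  cat("CCS geometry '", x$heart_id, "': ", nrow(x$landmarks), " landmarks",
      sep = "")
  if (length(x$centerlines))
    cat(", centerlines: ", paste(names(x$centerlines), collapse = ", "),
        sep = "")
  if (!is.null(x$provenance)) cat(" [synthetic]")
  cat("\n")
  invisible(x)
}

#' Arc length of a centerline polyline
#'
#' @param geometry A [ccs_geometry()].
#' @param component Name of the centerline.
#' @return Arc length in mm.
#' @export
centerline_length <- function(geometry, component) {
  cl <- geometry$centerlines[[component]]
  if (is.null(cl))
    stop_ccs(sprintf("no centerline '%s'", component),
             "ccsmorph_missing_landmark")
  sum(sqrt(rowSums(diff(cl)^2)))
}

# Straight polyline of n_points between two points (inclusive endpoints).
straight_polyline <- function(from, to, n_points = 5) {
  t <- seq(0, 1, length.out = n_points)
  out <- outer(1 - t, from) + outer(t, to)
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}

pairwise_distances <- function(points) as.numeric(stats::dist(points))

all_points <- function(geometry) {
  pts <- geometry$landmarks
  if (length(geometry$centerlines))
    pts <- rbind(pts, do.call(rbind, unname(geometry$centerlines)))
  pts
}
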