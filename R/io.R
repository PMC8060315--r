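# Landmark/angle CSV formats, run configuration (YAML/JSON, strict keys),
# and the end-to-end pipeline driver with its JSON manifest.
#
# CSV dialect throughout: UTF-8, comma separator, '.' decimal, LF line
# endings, header mandatory.

LANDMARK_HEADER <- c("name", "x_mm", "y_mm", "z_mm")
KNOWN_COMPONENTS <- c("sinus_node", "compact_node", "pbh", "bbh",
                      "lbb_origin", "lbb_bending", "rbb_proximal",
                      "rbb_distal")

#' Read a landmark CSV into a geometry
#'
#' Schema: header `name,x_mm,y_mm,z_mm`, one row per named 3D point in mm.
#' Rows named `<component>_01 ... <component>_NN` for a known component are
#' assembled into that component's centerline polyline (in index order);
#' all other rows become landmarks.
#'
#' @param path Path to the CSV file.
#' @param heart_id Identifier; defaults to the file name without extension.
#' @return A [ccs_geometry()].
#' @export
read_landmarks <- function(path, heart_id = NULL) {
  if (!file.exists(path))
    stop_ccs(paste0("no such file: ", path), "ccsmorph_io_error")
  if (is.null(heart_id))
    heart_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1 ||
      !identical(trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]]),
                 LANDMARK_HEADER))
    stop_ccs(paste0("malformed or missing header in ", path,
                    " (expected 'name,x_mm,y_mm,z_mm')"),
             "ccsmorph_parse_error")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    stop_ccs(paste0("no landmark rows in ", path), "ccsmorph_parse_error")
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 4)
      stop_ccs(sprintf("parse error in %s line %d: expected 4 fields, got %d",
                       path, i + 1, length(parts[[i]])),
               "ccsmorph_parse_error")
    v <- suppressWarnings(as.numeric(parts[[i]][2:4]))
    if (any(is.na(v)) || any(!is.finite(v)))
      stop_ccs(sprintf("parse error in %s line %d: non-numeric coordinate",
                       path, i + 1),
               "ccsmorph_parse_error")
  }
  nm <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(nm))
    stop_ccs(sprintf("duplicate landmark name '%s' in %s",
                     nm[duplicated(nm)][1], path),
             "ccsmorph_schema_error")
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  rownames(xyz) <- nm

  cl_pattern <- paste0("^(", paste(KNOWN_COMPONENTS, collapse = "|"),
                       ")_(\\d+)$")
  is_cl <- grepl(cl_pattern, nm)
  centerlines <- list()
  if (any(is_cl)) {
    comp <- sub(cl_pattern, "\\1", nm[is_cl])
    idx <- as.integer(sub(cl_pattern, "\\2", nm[is_cl]))
    for (cp in unique(comp)) {
      sel <- which(is_cl)[comp == cp]
      sel <- sel[order(idx[comp == cp])]
      centerlines[[cp]] <- xyz[sel, , drop = FALSE]
    }
  }
  ccs_geometry(heart_id = heart_id,
               landmarks = xyz[!is_cl, , drop = FALSE],
               centerlines = centerlines)
}

fmt_num <- function(x, digits) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  sub("^-(0\\.?0*)$", "\\1", out)  # avoid "-0.000000"
}

#' Write a geometry to a landmark CSV
#'
#' Deterministic output: rows sorted by name, coordinates at 6 decimals, LF
#' line endings. Centerline points are written as rows named
#' `<component>_01 ...` and round-trip through [read_landmarks()].
#'
#' @param geometry A [ccs_geometry()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(geometry, path) {
  stopifnot(inherits(geometry, "ccs_geometry"))
  pts <- geometry$landmarks
  for (cp in names(geometry$centerlines)) {
    cl <- geometry$centerlines[[cp]]
    rownames(cl) <- sprintf("%s_%02d", cp, seq_len(nrow(cl)))
    pts <- rbind(pts, cl)
  }
  pts <- pts[order(rownames(pts)), , drop = FALSE]
  rows <- sprintf("%s,%s,%s,%s", rownames(pts),
                  fmt_num(pts[, 1], 6), fmt_num(pts[, 2], 6),
                  fmt_num(pts[, 3], 6))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(LANDMARK_HEADER, collapse = ","), rows), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write an angle report CSV
#'
#' One row per heart, angles in degrees at 4 decimal places.
#'
#' @param angle_table Data.frame from [measure_cohort_angles()] or
#'   [sample_cohort_angles()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_angle_table <- function(angle_table, path) {
  write_numeric_csv(angle_table, path, digits = 4)
}

write_numeric_csv <- function(df, path, digits = 6) {
  cols <- lapply(df, function(col)
    if (is.numeric(col)) fmt_num(col, digits) else as.character(col))
  rows <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","), rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

RUN_CONFIG_KEYS <- list(
  top = c("seed", "cohort", "grid", "simulation", "recovery", "output_dir",
          "verbose"),
  cohort = c("n"),
  grid = c("k_values", "step_sgt", "step_frt", "step_hzt"),
  simulation = c("mode", "pivot"),
  recovery = c("enabled", "replicates")
)

#' Default run configuration
#'
#' @param seed Master seed.
#' @param n Cohort size.
#' @param output_dir Output directory for [run_pipeline()].
#' @return A validated `run_config` list.
#' @export
default_run_config <- function(seed = 1L, n = 23L,
                               output_dir = tempfile("ccsmorph_run_")) {
  validate_run_config(list(
    seed = as.integer(seed),
    cohort = list(n = as.integer(n)),
    grid = list(k_values = -2:2, step_sgt = 12.1, step_frt = 8.1,
                step_hzt = 13.4),
    simulation = list(mode = "rigid", pivot = "venous_anchor"),
    recovery = list(enabled = FALSE, replicates = 200L),
    output_dir = output_dir,
    verbose = FALSE
  ))
}

#' Validate a run configuration
#'
#' Strict key validation: unknown keys are rejected, never silently
#' ignored or coerced.
#'
#' @param config A named list.
#' @return The config, invisibly classed `run_config`.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop_ccs(sprintf("unknown %s config key(s): %s", where,
                       paste(extra, collapse = ", ")),
               "ccsmorph_schema_error")
  }
  check_keys(config, RUN_CONFIG_KEYS$top, "top-level")
  for (sec in c("cohort", "grid", "simulation", "recovery"))
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], RUN_CONFIG_KEYS[[sec]], sec)
  if (is.null(config$seed) || !is.finite(config$seed))
    stop_ccs("config must set an integer seed", "ccsmorph_schema_error")
  if (!is.null(config$simulation$mode) &&
      !config$simulation$mode %in% c("rigid", "regression"))
    stop_ccs("simulation mode must be 'rigid' or 'regression'",
             "ccsmorph_schema_error")
  class(config) <- c("run_config", "list")
  invisible(config)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_ccs(paste0("no such file: ", path), "ccsmorph_io_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(validate_run_config(config))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_checksum <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # scientific content only, not run placement
  cfg$verbose <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 4294967291)
}

#' Run the end-to-end pipeline
#'
#' Stages, in order: `generate` (sample the synthetic cohort; one landmark
#' CSV per heart, `cohort_provenance.csv` with the generated true angles,
#' `cohort_dims.csv`, and a config snapshot), `measure` (re-measure all
#' angles from the written geometries; `angles.csv`), `fit` (the eight
#' regressions on the generated angle table; `regressions.csv`), `simulate`
#' (stepwise rotation of the canonical mean heart; `trajectory.csv`,
#' `directions.csv`), optional `recover` (`recovery_report.csv`), then the
#' JSON run manifest. Fully reproducible from config + seed.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return The manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (isTRUE(config$verbose)) message(...)
  files <- character(0)
  warnings <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  stage <- "generate"
  manifest <- tryCatch({
    params <- default_cohort_params(n = config$cohort$n, seed = config$seed)
    if (any(!params$pairs$consistent))
      warnings <- c(warnings, paste0(
        "printed equation(s) inconsistent with the printed means: ",
        paste(params$pairs$pair_id[!params$pairs$consistent],
              collapse = ", ")))
    cohort <- sample_cohort(params)
    log_line("generate: n = ", params$n, ", seed = ", params$seed)
    for (g in cohort)
      emit(paste0(g$heart_id, "_landmarks.csv"),
           function(p) write_landmarks(g, p))
    emit("cohort_provenance.csv",
         function(p) write_numeric_csv(attr(cohort, "angles"), p, digits = 6))
    emit("cohort_dims.csv",
         function(p) write_numeric_csv(attr(cohort, "dims"), p, digits = 6))
    emit("config_snapshot.yaml", function(p) write_run_config(config, p))

    stage <- "measure"
    reread <- lapply(list.files(out_dir, "_landmarks\\.csv$",
                                full.names = TRUE),
                     function(p) read_landmarks(
                       p, heart_id = sub("_landmarks$", "",
                                         sub("\\.[^.]*$", "", basename(p)))))
    measured <- measure_cohort_angles(reread, on_degenerate = "error")
    emit("angles.csv", function(p) write_angle_table(measured, p))

    stage <- "fit"
    fits <- fit_all_pairs(attr(cohort, "angles"))
    emit("regressions.csv", function(p) write_numeric_csv(fits, p, 6))

    stage <- "simulate"
    grid <- simulation_grid(config$grid$k_values, config$grid$step_sgt,
                            config$grid$step_frt, config$grid$step_hzt)
    base <- canonical_mean_geometry(params)
    pivot <- config$simulation$pivot
    if (identical(pivot, "venous_anchor") && !has_landmark(base, pivot))
      pivot <- NULL
    traj <- simulate_transformation(base, grid,
                                    mode = config$simulation$mode,
                                    pivot = pivot)
    emit("trajectory.csv", function(p)
      write_numeric_csv(as.data.frame(traj), p, 4))
    emit("directions.csv", function(p)
      write_numeric_csv(classify_all_directions(traj), p, 4))

    if (isTRUE(config$recovery$enabled)) {
      stage <- "recover"
      rec <- recover_parameters(params,
                                replicates = config$recovery$replicates,
                                seed = config$seed)
      emit("recovery_report.csv", function(p)
        write_numeric_csv(as.data.frame(rec), p, 6))
    }

    list(
      package = "ccsmorph",
      version = as.character(utils::packageVersion("ccsmorph")),
      seed = config$seed,
      config_checksum = config_checksum(config),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      files = files,
      warnings = warnings
    )
  }, ccsmorph_error = function(e) {
    stop_ccs(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)),
             "ccsmorph_pipeline_error")
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  missing <- manifest$files[!file.exists(file.path(out_dir, manifest$files))]
  if (length(missing))
    stop_ccs(paste0("manifest lists missing file(s): ",
                    paste(missing, collapse = ", ")),
             "ccsmorph_pipeline_error")
  invisible(manifest)
}
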