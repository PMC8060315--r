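# Bivariate cardiac -> CCS inclination regressions: fitting, prediction,
# the published default models, cohort summaries and parameter-recovery
# experiments.

#' Round half away from zero
#'
#' Decimal rounding with halves going up in magnitude (0.05 -> 0.1),
#' matching how the published angle values are presented, unlike base R's
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Default regression models (published equations)
#'
#' The eight fitted cardiac-to-CCS inclination regressions as printed:
#' sinus-node angles against the matching cardiac plane angle
#' (`alpha_sgt`, `alpha_frt`, `alpha_hzt`), proximal AV-conduction-axis
#' angles (`beta_sgt`, `beta_frt`, `beta_hzt`), and the horizontal-plane
#' bundle-branch angles (`gamma`, `delta`) against the horizontal cardiac
#' angle. `residual_sd` is calibrated from the marginal spreads (see
#' [calibrate_residual_sd()]); `consistent` flags whether the printed
#' equation passes through the printed marginal means (the horizontal SN
#' equation does not).
#'
#' @return Data.frame with columns `pair_id`, `x_var`, `plane`, `slope`,
#'   `intercept`, `residual_sd`, `mean_x`, `mean_y`, `consistent`, `n`.
#' @export
default_regression_models <- function() {
  p <- PAIR_DEFAULTS
  data.frame(pair_id = p$pair_id, x_var = p$x_var, plane = p$plane,
             slope = p$slope, intercept = p$intercept,
             residual_sd = calibrate_residual_sd(p$slope, p$sd_x, p$sd_y),
             mean_x = p$mean_x, mean_y = p$mean_y,
             consistent = p$consistent, n = 23L,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares fit for one angle pair
#'
#' @param x,y Equal-length numeric vectors of paired angles in degrees
#'   (length >= 3, `x` not constant).
#' @param pair_id Optional label.
#' @return List of class `ccs_ols` with `pair_id`, `slope`, `intercept`,
#'   `residual_sd` (`sqrt(SSE / (n - 2))`), `r2`, `n`, `mean_x`, `mean_y`.
#' @export
fit_ols <- function(x, y, pair_id = NA_character_) {
  if (length(x) != length(y))
    stop_ccs("x and y must have equal length", "ccsmorph_invalid_input")
  if (length(x) < 3)
    stop_ccs("need at least 3 points", "ccsmorph_invalid_input")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_ccs("non-finite values in x or y", "ccsmorph_invalid_input")
  if (stats::sd(x) < 1e-12)
    stop_ccs("x is constant: degenerate fit", "ccsmorph_degenerate_fit")
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(pair_id = pair_id,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_sd = sqrt(sse / (length(x) - 2)),
         r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         n = length(x),
         mean_x = mean(x), mean_y = mean(y)),
    class = "ccs_ols"
  )
}

#' @export
print.ccs_ols <- function(x, ...) {
  cat(sprintf("OLS %s: y = %.4f x %+.4f (residual SD %.3f, R2 %.3f, n = %d)\n",
              if (is.na(x$pair_id)) "" else x$pair_id,
              x$slope, x$intercept, x$residual_sd, x$r2, x$n))
  invisible(x)
}

#' Predict a CCS angle from a regression model
#'
#' Evaluates `slope * x + intercept`. Raw (unwrapped) degrees by default,
#' because the printed horizontal SN equation produces raw values outside
#' `[0, 360)`; set `wrap = TRUE` to wrap.
#'
#' @param model A `ccs_ols` object, a one-row data.frame, or any list with
#'   `slope` and `intercept`.
#' @param x Cardiac angle(s) in degrees.
#' @param wrap Wrap the prediction to `[0, 360)`.
#' @return Predicted angle(s) in degrees.
#' @export
#' @examples
#' m <- default_regression_models()
#' predict_ccs_angle(m[m$pair_id == "alpha_sgt", ], 99.8)  # 87.767
predict_ccs_angle <- function(model, x, wrap = FALSE) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1)
    model <- as.list(model)
  }
  if (!is.finite(model$slope) || !is.finite(model$intercept))
    stop_ccs("model coefficients must be finite", "ccsmorph_invalid_input")
  out <- model$slope * x + model$intercept
  if (wrap) wrap_degrees(out) else out
}

#' Fit all eight cardiac-to-CCS regressions on a cohort angle table
#'
#' Pairing follows the published analysis: each sinus-node and AV-axis angle
#' is regressed on the cardiac angle of the same plane; the bundle-branch
#' angles `gamma` and `delta` are regressed on the horizontal cardiac angle
#' only.
#'
#' @param angle_table Data.frame with the cardiac (`X_*`) and CCS angle
#'   columns, e.g. from [measure_cohort_angles()] or
#'   [sample_cohort_angles()].
#' @return Data.frame with one row per pair: `pair_id`, `x_var`, `slope`,
#'   `intercept`, `residual_sd`, `r2`, `n`.
#' @export
fit_all_pairs <- function(angle_table) {
  pairs <- PAIR_DEFAULTS[, c("pair_id", "x_var")]
  missing_cols <- setdiff(unique(c(pairs$x_var, pairs$pair_id)),
                          names(angle_table))
  if (length(missing_cols))
    stop_ccs(paste0("angle table is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "ccsmorph_invalid_input")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    keep <- is.finite(angle_table[[pairs$x_var[i]]]) &
      is.finite(angle_table[[pairs$pair_id[i]]])
    f <- fit_ols(angle_table[[pairs$x_var[i]]][keep],
                 angle_table[[pairs$pair_id[i]]][keep],
                 pair_id = pairs$pair_id[i])
    data.frame(pair_id = f$pair_id, x_var = pairs$x_var[i], slope = f$slope,
               intercept = f$intercept, residual_sd = f$residual_sd,
               r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate the published equations at the published mean inclinations
#'
#' The OLS through-the-means identity: a fitted line passes through the
#' sample mean point, so evaluating each printed equation at the printed
#' mean cardiac angle should reproduce the printed mean CCS angle. Six pairs
#' do to one decimal; the horizontal SN pair is internally inconsistent as
#' printed (flagged, `consistent = FALSE`), and the LBB pair agrees only to
#' coefficient rounding (120.0 vs 120.2).
#'
#' @param models Regression model table, default [default_regression_models()].
#' @return Data.frame: `pair_id`, `mean_x`, `predicted`,
#'   `predicted_rounded` (half-up, 1 decimal), `published_mean`,
#'   `consistent`, `abs_error`.
#' @export
regression_through_means <- function(models = default_regression_models()) {
  pred <- models$slope * models$mean_x + models$intercept
  data.frame(pair_id = models$pair_id, mean_x = models$mean_x,
             predicted = pred,
             predicted_rounded = round_half_up(pred, 1),
             published_mean = models$mean_y,
             consistent = models$consistent,
             abs_error = abs(round_half_up(pred, 1) - models$mean_y),
             stringsAsFactors = FALSE)
}

#' Summarize a cohort angle or dimension table
#'
#' @param x Data.frame of numeric columns (non-numeric columns are skipped).
#' @return Data.frame: `variable`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_cohort <- function(x) {
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  rows <- lapply(num, function(v) {
    vals <- x[[v]][is.finite(x[[v]])]
    data.frame(variable = v, mean = mean(vals), sd = stats::sd(vals),
               min = min(vals), max = max(vals), n = length(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parameter-recovery experiment for the eight regressions
#'
#' Simulate-and-refit loop: `replicates` synthetic cohorts of `n` hearts are
#' drawn from the generator, the eight OLS fits are recomputed on each, and
#' slope recovery is summarized per pair (mean estimate, bias, RMSE and the
#' Monte-Carlo standard error of the mean estimate). Deterministic for a
#' fixed seed.
#'
#' @param params Generator parameters ([default_cohort_params()]).
#' @param replicates Number of simulated cohorts (>= 2).
#' @param seed Integer seed for the experiment (replicate seeds are derived
#'   from it).
#' @param n Cohort size per replicate (default `params$n`).
#' @return Data.frame of class `recovery_report`: per pair `true_slope`,
#'   `mean_slope`, `bias`, `rmse`, `mc_se`, `true_intercept`,
#'   `mean_intercept`, `replicates`, `n`, `seed`.
#' @export
recover_parameters <- function(params = default_cohort_params(),
                               replicates = 1000, seed = 1L,
                               n = params$n) {
  validate_cohort_params(params)
  if (replicates < 2)
    stop_ccs("need at least 2 replicates", "ccsmorph_invalid_params")
  base <- derive_seed(seed, "recover")
  slopes <- matrix(NA_real_, replicates, nrow(params$pairs),
                   dimnames = list(NULL, params$pairs$pair_id))
  intercepts <- slopes
  for (r in seq_len(replicates)) {
    p_r <- params
    p_r$seed <- as.integer((as.numeric(base) + r) %% 2147483647)
    fits <- fit_all_pairs(sample_cohort_angles(p_r, n = n))
    slopes[r, fits$pair_id] <- fits$slope
    intercepts[r, fits$pair_id] <- fits$intercept
  }
  # generator truth: printed slope, mean-anchored intercept
  true_slope <- params$pairs$slope
  true_intercept <- params$pairs$mean_y -
    params$pairs$slope * params$pairs$mean_x
  out <- data.frame(
    pair_id = params$pairs$pair_id,
    true_slope = true_slope,
    mean_slope = colMeans(slopes),
    bias = colMeans(slopes) - true_slope,
    rmse = sqrt(colMeans(sweep(slopes, 2, true_slope)^2)),
    mc_se = apply(slopes, 2, stats::sd) / sqrt(replicates),
    true_intercept = true_intercept,
    mean_intercept = colMeans(intercepts),
    replicates = replicates, n = n, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("recovery_report", class(out))
  out
}
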