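# Stepwise standing-to-lying simulation and rotation-direction
# classification.

test_that("grid positions are mean + k*SD per axis", {
  g <- simulation_grid()
  pos <- stepwise_positions(g)
  expect_equal(pos$k, -2:2)
  expect_equal(pos[pos$k == 0, c("sgt", "frt", "hzt")],
               data.frame(sgt = 0, frt = 0, hzt = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(pos[pos$k == -2, c("sgt", "frt", "hzt")]),
               c(sgt = -24.2, frt = -16.2, hzt = -26.8))
  expect_equal(unlist(pos[pos$k == 1, c("sgt", "frt", "hzt")]),
               c(sgt = 12.1, frt = 8.1, hzt = 13.4))
  expect_error(simulation_grid(k_values = c(1, 1, 2)),
               class = "ccsmorph_invalid_params")
  expect_error(simulation_grid(step_sgt = -1),
               class = "ccsmorph_invalid_params")
})

test_that("rigid simulation conserves geometry and matches single-axis closed forms", {
  base <- canonical_mean_geometry()
  m0 <- measure_all_angles(base, on_degenerate = "na")

  # a single k = 0 position reproduces the base measurement
  tr0 <- simulate_transformation(base, simulation_grid(k_values = 0))
  expect_equal(unlist(tr0[1, names(m0)[-1]]), unlist(m0[-1]),
               tolerance = 1e-9)

  # inter-landmark distances are conserved at every position
  tr <- simulate_transformation(base, simulation_grid(), mode = "rigid")
  d0 <- as.numeric(dist(ccsmorph:::all_points(base)))
  for (g in attr(tr, "geometries")) {
    dk <- as.numeric(dist(ccsmorph:::all_points(g)))
    expect_lt(max(abs(dk - d0)) / max(d0), 1e-9)
  }

  # horizontal-only rotation shifts every horizontal-plane angle by exactly
  # the applied increment, so those sequences are linear and monotone
  gh <- simulation_grid(step_sgt = 0, step_frt = 0, step_hzt = 13.4)
  trh <- simulate_transformation(base, gh, mode = "rigid")
  for (col in c("X_hzt", "alpha_hzt", "beta_hzt", "gamma", "delta")) {
    expect_equal(
      ccsmorph:::circular_diff_deg(trh[[col]], m0[[col]] + trh$k * 13.4),
      rep(0, 5), tolerance = 1e-9)
    expect_true(all(diff(ccsmorph:::unwrap_degrees(trh[[col]])) > 0))
  }
  # while sagittal and frontal angles are untouched by a horizontal rotation
  # of the cardiac axis only through its in-plane component, the cardiac
  # X_sgt/X_frt generally change; the increments applied are exactly k*SD
  expect_equal(trh$sgt, rep(0, 5))
  expect_equal(trh$frt, rep(0, 5))
})

test_that("rigid and regression modes agree at k = 0", {
  base <- canonical_mean_geometry()
  grid <- simulation_grid()
  tr_r <- simulate_transformation(base, grid, mode = "rigid")
  tr_g <- simulate_transformation(base, grid, mode = "regression")
  cols <- ccsmorph:::ANGLE_DEFS$angle
  expect_equal(unlist(tr_r[tr_r$k == 0, cols]),
               unlist(tr_g[tr_g$k == 0, cols]), tolerance = 1e-9)
  # regression mode is exactly linear in k, hence monotone per plane
  expect_equal(diff(tr_g$X_hzt), rep(13.4, 4), tolerance = 1e-12)
  expect_equal(diff(tr_g$alpha_sgt), rep(1.165 * 12.1, 4), tolerance = 1e-9)
})

test_that("rotation-direction classification follows the trajectory slopes", {
  fake <- data.frame(position = 1:5, k = -2:2,
                     sgt = 0, frt = (-2:2) * 8.1, hzt = 0,
                     X_frt = 46.8 + (-2:2) * 8.1)
  fake$alpha_frt <- fake$X_frt            # identical: concomitant
  fake$beta_frt <- 200 - fake$X_frt       # mirrored: counter
  fake$X_sgt <- 99.8 + (-2:2) * 12.1
  fake$alpha_sgt <- 50 + 0.001 * fake$X_sgt  # below threshold: flat
  class(fake) <- c("rotation_trajectory", class(fake))
  expect_identical(
    classify_rotation_direction(fake, "sn", "frontal")$classification,
    "concomitant")
  expect_identical(
    classify_rotation_direction(fake, "avca", "frontal")$classification,
    "counter")
  expect_identical(
    classify_rotation_direction(fake, "sn", "sagittal")$classification,
    "flat")
  expect_error(classify_rotation_direction(fake, "rbb", "frontal"),
               class = "ccsmorph_invalid_input")

  # regression-calibrated simulation: frontal AVCA counter-rotates while
  # all three SN pairs are concomitant
  tr <- simulate_transformation(canonical_mean_geometry(), simulation_grid(),
                                mode = "regression")
  expect_identical(
    classify_rotation_direction(tr, "avca", "frontal")$classification,
    "counter")
  for (pl in c("sagittal", "frontal", "horizontal"))
    expect_identical(
      classify_rotation_direction(tr, "sn", pl)$classification,
      "concomitant")
})

test_that("standing-vs-lying comparison reports poses and displacements", {
  base <- canonical_mean_geometry()

  # zero-step grid: identical poses, zero displacement
  g0 <- simulation_grid(k_values = c(-1, 0, 1), step_sgt = 0, step_frt = 0,
                        step_hzt = 0)
  cmp0 <- standing_lying_comparison(base, g0)
  expect_equal(cmp0$sn_displacement_mm, 0, tolerance = 1e-9)
  expect_equal(cmp0$avca_displacement_mm, 0, tolerance = 1e-9)
  cols <- ccsmorph:::ANGLE_DEFS$angle
  expect_equal(unlist(cmp0$angles[1, cols]), unlist(cmp0$angles[2, cols]),
               tolerance = 1e-9)

  # default grid: the AVCA, deep in the ventricular mass and far from the
  # venous-anchor pivot, moves more than the tethered SN head
  cmp <- standing_lying_comparison(base, simulation_grid())
  expect_gt(cmp$avca_displacement_mm, cmp$sn_displacement_mm)
  expect_equal(nrow(cmp$angles), 2)
  expect_equal(nrow(cmp$directions), 8)

  # lying minus standing spans 2 SD per axis: exact for the horizontal
  # cardiac angle in regression mode
  cmpr <- standing_lying_comparison(base, simulation_grid(),
                                    mode = "regression")
  expect_equal(cmpr$angles$X_hzt[cmpr$angles$k == 1] -
                 cmpr$angles$X_hzt[cmpr$angles$k == -1],
               2 * 13.4, tolerance = 1e-9)

  expect_error(standing_lying_comparison(base, simulation_grid(k_values = 0)),
               class = "ccsmorph_invalid_params")
})
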