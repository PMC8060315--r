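# Synthetic-cohort generator: residual-noise calibration, determinism,
# marginal fidelity, truncation, canonical geometry.

test_that("residual SD calibration follows the variance-addition law", {
  # no-signal case: all response spread is residual
  expect_identical(calibrate_residual_sd(0, 5, 7.3), 7.3)
  # closed-form oracle values: sqrt(sd_y^2 - slope^2 sd_x^2)
  expect_equal(calibrate_residual_sd(1.165, 12.1, 18.6), 12.134606,
               tolerance = 1e-6)
  expect_equal(calibrate_residual_sd(0.913, 8.1, 10.4), 7.312287,
               tolerance = 1e-6)
  # over-explained spread clips to zero with a warning
  expect_warning(out <- calibrate_residual_sd(2, 10, 5))
  expect_identical(out, 0)
  expect_error(calibrate_residual_sd(1, -1, 5),
               class = "ccsmorph_invalid_params")
  expect_error(calibrate_residual_sd(1, 1, 0),
               class = "ccsmorph_invalid_params")
})

test_that("cohort sampling is deterministic for a fixed seed", {
  p <- default_cohort_params(n = 3, seed = 99L)
  c1 <- sample_cohort(p)
  c2 <- sample_cohort(p)
  expect_identical(attr(c1, "angles"), attr(c2, "angles"))
  expect_identical(attr(c1, "dims"), attr(c2, "dims"))
  expect_identical(c1[[2]]$landmarks, c2[[2]]$landmarks)
  c3 <- sample_cohort(default_cohort_params(n = 3, seed = 100L))
  expect_false(identical(attr(c1, "angles"), attr(c3, "angles")))
})

test_that("zero-noise cohorts lie exactly on the configured regression lines", {
  p <- default_cohort_params(n = 200, seed = 5L)
  p$pairs$residual_sd <- 0
  ang <- sample_cohort_angles(p)
  for (i in seq_len(nrow(p$pairs))) {
    pr <- p$pairs[i, ]
    expect_lt(max(abs(ang[[pr$pair_id]] -
                        (pr$mean_y + pr$slope * (ang[[pr$x_var]] - pr$mean_x)))),
              1e-9)
  }
})

test_that("generated marginal means and SDs match the configured cohort statistics", {
  p <- default_cohort_params(seed = 31L)
  ang <- sample_cohort_angles(p, n = 20000)
  targets <- rbind(
    data.frame(var = p$cardiac$angle, mean = p$cardiac$mean, sd = p$cardiac$sd),
    data.frame(var = p$pairs$pair_id, mean = p$pairs$mean_y, sd = p$pairs$sd_y)
  )
  for (i in seq_len(nrow(targets))) {
    v <- ang[[targets$var[i]]]
    expect_lt(abs(mean(v) - targets$mean[i]) / targets$mean[i], 0.02)
    expect_lt(abs(sd(v) - targets$sd[i]) / targets$sd[i], 0.02)
  }
})

test_that("sampled dimensions respect the published truncation ranges", {
  p <- default_cohort_params(seed = 8L)
  d <- sample_component_dims(p, n = 5000)
  key <- paste(d$component, d$dimension)
  pkey <- paste(p$dims$component, p$dims$dimension)
  expect_setequal(unique(key), pkey)
  for (i in seq_len(nrow(p$dims))) {
    v <- d$value_mm[key == pkey[i]]
    expect_true(all(v >= p$dims$min[i] & v <= p$dims$max[i]))
  }
  bad <- default_cohort_params()
  bad$dims$min[1] <- bad$dims$mean[1] + 1
  expect_error(validate_cohort_params(bad), class = "ccsmorph_invalid_params")
  expect_error(sample_cohort_angles(default_cohort_params(n = 23), n = 0),
               class = "ccsmorph_invalid_params")
})

test_that("canonical geometry realizes requested lengths and angles", {
  # published mean dimensions: the bundle of His spans PBH + BBH = 14.3 mm
  g <- canonical_mean_geometry()
  his <- centerline_length(g, "pbh") + centerline_length(g, "bbh")
  expect_equal(his, 4.7 + 9.6, tolerance = 1e-9)
  expect_equal(
    sqrt(sum((g$landmarks["rbb_branch_point", ] -
                g$landmarks["compact_node_end", ])^2)),
    14.3, tolerance = 1e-9
  )
  expect_equal(centerline_length(g, "sinus_node"), 33.9, tolerance = 1e-9)

  # inconsistent requested means are a reported residual, not an error
  expect_gt(max(g$provenance$axis_fit_residual_deg), 1)

  # sampled cohorts carry their generated lengths into the centerlines
  co <- sample_cohort(default_cohort_params(n = 4, seed = 2L))
  dims <- attr(co, "dims")
  for (g in co) {
    for (cp in c("sinus_node", "compact_node", "pbh", "bbh")) {
      want <- dims$value_mm[dims$heart_id == g$heart_id &
                              dims$component == cp &
                              dims$dimension == "length"]
      expect_equal(centerline_length(g, cp), want, tolerance = 1e-6)
    }
    # single-plane angles (gamma, delta) are exactly realized even in
    # sampled (over-determined) hearts
    m <- measure_all_angles(g)
    expect_equal(m$gamma %% 360,
                 g$provenance$requested_ccs[["gamma"]] %% 360,
                 tolerance = 1e-6)
    expect_equal(m$delta %% 360,
                 g$provenance$requested_ccs[["delta"]] %% 360,
                 tolerance = 1e-6)
  }

  expect_error(build_canonical_geometry(c(X_sgt = 1, X_frt = 2), c()),
               class = "ccsmorph_invalid_input")
  expect_error(
    build_canonical_geometry(c(X_sgt = 1, X_frt = 2, X_hzt = NA),
                             consistent_angle_set()$ccs),
    class = "ccsmorph_invalid_input"
  )
})
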