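test_that("scene configs validate nesting, fractions and ranges", {
  expect_error(scene_config(extent_px = c(100, 99)), "divisible by 3")
  fr <- c("Populus" = 0.5, "Salix" = 0.3, "Pinus tabuliformis" = 0.1,
          "other" = 0.05, "shrub" = 0.04)
  expect_error(scene_config(species_fractions = fr), "sum to 1")
  dp <- default_density_params(); dp$min[1] <- -1
  expect_error(scene_config(density_params = dp), "positive")
})

test_that("a fixed seed reproduces the scene bit-identically", {
  cfg <- scene_config(extent_px = c(30, 30), seed = 42)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$stack_10m, s2$stack_10m)
  expect_identical(band(s1$true_density_10m, "density"),
                   band(s2$true_density_10m, "density"))
  expect_identical(band(s1$factor_rasters$stratumA, "stratum"),
                   band(s2$factor_rasters$stratumA, "stratum"))
  p1 <- generate_plots(s1); p2 <- generate_plots(s2)
  expect_identical(plots_carbon_density(p1), plots_carbon_density(p2))
})

test_that("30 m bands are exact 3x3 block means of the 10 m bands before sensor noise", {
  sc <- med_scene()
  pick <- c(b3 = "b3", b4 = "b4", b5 = "b8")  # OLI b5 is the NIR child band
  for (b30 in names(pick)) {
    m10 <- band(sc$stack_10m, pick[[b30]])
    m30 <- band(sc$stack_30m_clean, b30)
    manual <- (m10[seq(1, 150, 3), ] + m10[seq(2, 150, 3), ] +
                 m10[seq(3, 150, 3), ])
    manual <- (manual[, seq(1, 150, 3)] + manual[, seq(2, 150, 3)] +
                 manual[, seq(3, 150, 3)]) / 9
    expect_lt(max(abs(m30 - manual)), 1e-9)
  }
})

test_that("reflectance stays in [0, 1] and species classes partition the forest", {
  sc <- med_scene()
  for (b in band_names(sc$stack_10m)) {
    v <- band(sc$stack_10m, b)
    expect_true(all(v >= 0 & v <= 1))
  }
  cls <- band(sc$species_mask_10m, "class")
  expect_true(all(cls[sc$forest_mask_10m] %in% 1:5))
  expect_true(all(cls[!sc$forest_mask_10m] == 0))
  den <- band(sc$true_density_10m, "density")
  expect_identical(!is.na(den), sc$forest_mask_10m)
  dp <- sc$config$density_params
  for (ci in 1:5) {
    d <- den[cls == ci]
    expect_true(all(d >= dp$min[ci] - 1e-9 & d <= dp$max[ci] + 1e-9))
  }
})

test_that("the NDVI-density correlation hits its calibration target", {
  sc <- med_scene()  # target 0.9
  ndvi <- band(compute_vi(sc$stack_10m, "NDVI", "s2a"), "NDVI")
  den <- band(sc$true_density_10m, "density")
  f <- sc$forest_mask_10m
  expect_gt(sum(f), 1e4)
  expect_equal(cor(ndvi[f], den[f]), 0.9, tolerance = 0.05)
  # noiseless, near-perfect signal
  hi <- generate_scene(scene_config(extent_px = c(90, 90), seed = 5,
                                    sensor_noise_sd = 0,
                                    vi_signal_r = 0.99))
  nh <- band(compute_vi(hi$stack_10m, "NDVI", "s2a"), "NDVI")
  dh <- band(hi$true_density_10m, "density")
  expect_gte(cor(nh[hi$forest_mask_10m], dh[hi$forest_mask_10m]), 0.95)
})

test_that("a degenerate single-class mixture fills the forest with that class", {
  fr <- c("Populus" = 0, "Salix" = 0, "Pinus tabuliformis" = 0,
          "other" = 0, "shrub" = 1)
  sc <- generate_scene(scene_config(extent_px = c(30, 30), seed = 2,
                                    species_fractions = fr))
  cls <- band(sc$species_mask_10m, "class")
  expect_true(all(cls[sc$forest_mask_10m] == 5))
})

test_that("the configured plot layout yields 96 records with the surveyed design", {
  sc <- med_scene()
  plots <- generate_plots(sc)
  expect_length(plots, 96)
  by_class <- table(vapply(plots, `[[`, character(1), "class_label"))
  expect_equal(as.integer(by_class[forest_classes()]),
               c(20L, 18L, 20L, 18L, 20L))
  areas <- vapply(plots, `[[`, numeric(1), "plot_area_ha")
  expect_true(all(areas[vapply(plots, `[[`, character(1),
                               "class_label") == "shrub"] == 0.01))
  expect_true(all(areas[vapply(plots, `[[`, character(1),
                               "class_label") != "shrub"] == 0.04))
  # every plot carries three herb quadrats; layers match the class
  expect_true(all(vapply(plots, function(p) nrow(p$herb_quadrats), 0L) == 3L))
})

test_that("zero plot noise round-trips through the allometry to within 1%", {
  sc <- noiseless_scene()
  plots <- generate_plots(sc)
  pd <- plots_carbon_density(plots)
  truth <- extract_at_points(sc$true_density_10m, pd)
  expect_lt(max(abs(pd$carbon_density - truth) / truth), 0.01)
})

test_that("an empty class mask skips its plots with a warning", {
  fr <- c("Populus" = 0.5, "Salix" = 0.2, "Pinus tabuliformis" = 0.15,
          "other" = 0.15, "shrub" = 0)
  sc <- generate_scene(scene_config(extent_px = c(30, 30), seed = 4,
                                    species_fractions = fr))
  expect_warning(plots <- generate_plots(sc), "shrub")
  expect_equal(attr(plots, "skipped"), "shrub")
  expect_false(any(vapply(plots, `[[`, character(1),
                          "class_label") == "shrub"))
})

test_that("factor strata achieve the requested explained-variance share", {
  sc <- med_scene()
  fs0 <- generate_factor_strata(sc, k = 4, effect_fraction = 0, seed = 1)
  expect_equal(attr(fs0, "target_q"), 0)
  expect_lt(attr(fs0, "realized_q"), 0.01)
  expect_warning(
    fs1 <- generate_factor_strata(sc, k = 6, effect_fraction = 1, seed = 1),
    "maximum share")
  expect_equal(attr(fs1, "target_q"), 1)   # capped at the k-slice maximum
  fs6 <- generate_factor_strata(sc, k = 8, effect_fraction = 0.6, seed = 1)
  expect_equal(attr(fs6, "realized_q"), 0.6, tolerance = 0.01)
  expect_error(generate_factor_strata(sc, k = 1e9, effect_fraction = 0.5),
               "exceeds")
})
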