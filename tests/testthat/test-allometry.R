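reg <- default_allometry_registry()

test_that("organ power laws evaluate the registry coefficients", {
  # D^2 H = 1 makes every organ equal its leading coefficient
  b <- tree_biomass(reg$Populus, dbh_cm = 1, height_m = 1)
  expect_equal(unname(b$organs[1, "trunk"]), 0.0859)
  expect_equal(unname(b$organs[1, "branch"]), 0.0036)
  # independent scalar evaluation at D = 20, H = 10 (D^2 H = 4000)
  expect_equal(unname(tree_biomass(reg$Populus, 20, 10)$organs[1, "trunk"]),
               0.0859 * 4000^0.8001, tolerance = 1e-12)
  # total is exactly the four-organ sum
  expect_equal(b$total, sum(b$organs[1, ]))
  expect_error(tree_biomass(reg$Populus, -1, 5), "positive")
  expect_error(tree_biomass(reg[["Caragana korshinskii"]], 10, 5),
               "organ_power")
})

test_that("tree biomass increases strictly in DBH and height", {
  d <- seq(2, 40, by = 2)
  tot_d <- tree_biomass(reg$Salix, d, 10)$total
  tot_h <- tree_biomass(reg$Salix, 15, seq(2, 30, by = 2))$total
  expect_true(all(diff(tot_d) > 0))
  expect_true(all(diff(tot_h) > 0))
})

test_that("shrub models evaluate their registered functional forms", {
  pow <- allometric_model("x", "whole_power", 0.5,
                          whole_coefficients = c(1, 1))
  # identity power: W = V; pick M, H whose ellipsoid volume is 2
  h <- 1; m <- sqrt(2 * 6 / (pi * h))
  expect_equal(shrub_biomass(pow, m, h), 2, tolerance = 1e-12)
  con <- allometric_model("y", "whole_poly", 0.5,
                          whole_coefficients = c(0.061, 0, 0))
  expect_equal(shrub_biomass(con, 1.3, 0.7), 0.061)
  poly <- allometric_model("z", "whole_poly", 0.5,
                           whole_coefficients = c(0, 1, 2))
  expect_equal(shrub_biomass(poly, crown_width_m = 3, height_m = 1), 21)
})

test_that("carbon conversion is the product with the carbon fraction", {
  expect_equal(individual_carbon(100, 0.48), 48)
  expect_equal(individual_carbon(0, 0.48), 0)
  expect_equal(individual_carbon(10, 0.47), 4.7)
})

test_that("herb carbon averages quadrats and scales masses to kg C/m^2", {
  q3 <- data.frame(above_g = c(70, 70, 70), below_g = c(30, 30, 30))
  expect_equal(herb_carbon(q3, 0.45), 0.045)
  expect_equal(herb_carbon(data.frame(above_g = 0, below_g = 0)), 0)
  q1 <- data.frame(above_g = 120, below_g = 40)
  expect_equal(herb_carbon(q1, 0.5), 0.16 * 0.5)
})

test_that("plot density converts kg to t/ha and adds the herb layer", {
  # 0.04 ha plot holding 800 kg woody C -> 20 t/ha; solve one Populus stem
  # carrying 800/cc kg biomass is awkward, so check with explicit stems:
  p <- plot_record("p1", "Populus", c(x = 5, y = -5),
                   stems = data.frame(species = "Populus",
                                      dbh_cm = 20, height_m = 10))
  d <- plot_carbon_density(p, reg)
  manual_kg <- 0.48 * sum(tree_biomass(reg$Populus, 20, 10)$total)
  expect_equal(d$carbon_density, manual_kg / 1000 / 0.04)
  expect_equal(d$carbon_density, d$tree + d$shrub + d$herb)
  # empty plot
  p0 <- plot_record("p0", "other", c(x = 0, y = 0))
  expect_equal(plot_carbon_density(p0, reg)$carbon_density, 0)
  # herb-only: 1 kg C/m^2 equals 10 t/ha
  ph <- plot_record("ph", "shrub", c(x = 0, y = 0),
                    herb_quadrats = data.frame(above_g = 2000 / 0.45 * 0.7,
                                               below_g = 2000 / 0.45 * 0.3))
  expect_equal(plot_carbon_density(ph, reg)$herb, 20)
})

test_that("unresolved species name the label unless a fallback is allowed", {
  p <- plot_record("p", "other", c(x = 0, y = 0),
                   stems = data.frame(species = "Picea", dbh_cm = 10,
                                      height_m = 5))
  expect_error(plot_carbon_density(p, reg), "Picea")
  expect_no_error(plot_carbon_density(p, reg, fallback = TRUE))
})

test_that("plot density is additive over stem-list splits and halves when area doubles", {
  stems <- data.frame(species = rep("Salix", 6),
                      dbh_cm = c(5, 8, 11, 14, 17, 20),
                      height_m = c(4, 5, 6, 7, 8, 9))
  whole <- plot_carbon_density(
    plot_record("w", "Salix", c(x = 0, y = 0), stems = stems), reg)
  parts <- lapply(list(1:2, 3:6), function(i) plot_carbon_density(
    plot_record("p", "Salix", c(x = 0, y = 0),
                stems = stems[i, ]), reg)$carbon_density)
  expect_equal(whole$carbon_density, Reduce(`+`, parts))
  double <- plot_carbon_density(
    plot_record("d", "Salix", c(x = 0, y = 0), plot_area_ha = 0.08,
                stems = stems), reg)
  expect_equal(double$carbon_density, whole$carbon_density / 2)
})

test_that("plot CSV and registry YAML round-trip", {
  sc <- noiseless_scene()
  plots <- generate_plots(sc)[c(1, 40, 90)]
  f <- withr::local_tempfile(fileext = ".csv")
  write_plot_csv(plots, f)
  back <- read_plot_csv(f)
  expect_equal(plots_carbon_density(back)$carbon_density,
               plots_carbon_density(plots)$carbon_density)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_allometry_registry(reg, fy)
  reg2 <- read_allometry_registry(fy)
  expect_equal(tree_biomass(reg2$Populus, 20, 10)$total,
               tree_biomass(reg$Populus, 20, 10)$total)
  expect_equal(shrub_biomass(reg2[["Artemisia ordosica"]], 1.2, 0.8),
               shrub_biomass(reg[["Artemisia ordosica"]], 1.2, 0.8))
})
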