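# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# mid-sized scene used by most raster-level tests
med_scene <- function() cached("med_scene",
  generate_scene(scene_config(extent_px = c(150, 150), seed = 7)))

# small zero-plot-noise scene for round-trip checks
noiseless_scene <- function() cached("noiseless_scene",
  generate_scene(scene_config(extent_px = c(60, 60), seed = 3,
                              plot_noise = 0)))

# a tiny uniform reflectance stack for VI arithmetic
flat_stack <- function(vals, res_m = 10) {
  raster_stack(lapply(vals, function(v) matrix(v, 3, 3)), res_m = res_m)
}

# per-class species density mosaic of the medium scene via MLR fits
med_mosaic <- function() cached("med_mosaic", {
  sc <- med_scene()
  pd <- plots_carbon_density(generate_plots(sc))
  vis10 <- compute_vis(sc$stack_10m,
                       c("NDVI", "gNDVI", "SAVI", "DVI", "SR", "RDVI"),
                       sensor = "s2a")
  mask10 <- band(sc$species_mask_10m, "class")
  preds <- list(); masks <- list()
  for (ci in seq_along(sc$class_labels)) {
    cl <- sc$class_labels[ci]
    rows <- pd[pd$class_label == cl, ]
    vip <- extract_vis_at_points(vis10, rows)
    sel <- select_predictors(vip, rows$carbon_density, top_k = 3)
    m <- train_carbon_model(carbon_model_spec("mlr", sel$selected),
                            vip, rows$carbon_density)
    masks[[cl]] <- mask10 == ci
    preds[[cl]] <- predict_density_map(m, vis10, mask = masks[[cl]])
  }
  mosaic_species(preds, masks)
})
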