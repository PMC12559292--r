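#' Configuration of a synthetic paired-resolution scene
#'
#' Defines the study conditions emulated by the generator: a 10 m grid whose
#' extent is divisible by 3 so that a 30 m grid nests it exactly (3x3
#' children per coarse cell); five forest classes (*Populus*, *Salix*,
#' *Pinus tabuliformis*, other species, shrub) partitioning the forest
#' extent; per-class carbon density means and ranges defaulting to the
#' surveyed-plot statistics of the emulated inventory (e.g. *Populus* mean
#' 32.31 t/ha, range 4.04-70.70; shrub mean 9.13, range 3.36-15.69); a
#' target correlation between an NDVI-like index and true density; and the
#' plot layout 20/18/20/18/20 giving 96 plots.
#'
#' @param extent_px integer pair (rows, cols) of the 10 m grid, each
#'   divisible by 3.
#' @param seed root RNG seed; every stage draws from sub-seeds split off
#'   this one.
#' @param species_fractions named fractions of the forest extent per class,
#'   summing to 1 (order: Populus, Salix, Pinus tabuliformis, other,
#'   shrub).
#' @param density_params data.frame `class, mean, min, max` in t/ha.
#' @param vi_signal_r target corr(NDVI, density) over forest pixels, in
#'   (0, 1).
#' @param sensor_noise_sd additive Gaussian reflectance noise (applied to
#'   the 10 m bands, and independently to the 30 m bands after block
#'   aggregation).
#' @param n_plots_per_class integer vector (recycled to the five classes).
#' @param forest_fraction fraction of the scene covered by forest.
#' @param smoothness_px Gaussian smoothing radius (pixels) of the latent
#'   fields; controls patch size.
#' @param plot_noise relative noise between a plot's inventory-derived
#'   density and the underlying pixel truth (default 10%).
#' @return a `scene_config` object.
#' @export
scene_config <- function(extent_px = c(150, 150), seed = 1,
                         species_fractions = c(
                           "Populus" = 0.10, "Salix" = 0.05,
                           "Pinus tabuliformis" = 0.05, "other" = 0.08,
                           "shrub" = 0.72),
                         density_params = default_density_params(),
                         vi_signal_r = 0.9, sensor_noise_sd = 0.005,
                         n_plots_per_class = c(20L, 18L, 20L, 18L, 20L),
                         forest_fraction = 0.6, smoothness_px = 6,
                         plot_noise = 0.10) {
  extent_px <- as.integer(extent_px)
  if (length(extent_px) != 2L || any(extent_px < 3L))
    stop("'extent_px' must be two integers >= 3")
  if (any(extent_px %% 3L != 0L))
    stop("rows and cols must each be divisible by 3 for exact 10 m -> 30 m nesting")
  classes <- forest_classes()
  if (!all(classes %in% names(species_fractions)))
    stop("'species_fractions' must name all five classes: ",
         paste(classes, collapse = ", "))
  species_fractions <- species_fractions[classes]
  if (abs(sum(species_fractions) - 1) > 1e-9)
    stop("species fractions must sum to 1")
  if (any(species_fractions < 0)) stop("species fractions must be >= 0")
  density_params <- as.data.frame(density_params)
  stopifnot(all(c("class", "mean", "min", "max") %in% names(density_params)))
  if (any(density_params$min <= 0) ||
      any(density_params$max <= density_params$min))
    stop("density ranges must be positive with max > min")
  if (vi_signal_r <= 0 || vi_signal_r >= 1)
    stop("'vi_signal_r' must be in (0, 1)")
  if (sensor_noise_sd < 0) stop("'sensor_noise_sd' must be >= 0")
  if (forest_fraction <= 0 || forest_fraction > 1)
    stop("'forest_fraction' must be in (0, 1]")
  structure(list(extent_px = extent_px, seed = as.integer(seed),
                 species_fractions = species_fractions,
                 density_params = density_params,
                 vi_signal_r = vi_signal_r,
                 sensor_noise_sd = sensor_noise_sd,
                 n_plots_per_class =
                   rep_len(as.integer(n_plots_per_class), length(classes)),
                 forest_fraction = forest_fraction,
                 smoothness_px = smoothness_px,
                 plot_noise = plot_noise),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
forest_classes <- function()
  c("Populus", "Salix", "Pinus tabuliformis", "other", "shrub")

#' @rdname scene_config
#' @export
landuse_classes <- function()
  c("cropland", "forest", "shrub", "grassland", "water", "other")

#' Default per-class carbon density statistics (t/ha)
#'
#' Mean, minimum and maximum plot carbon density per forest class, matching
#' the surveyed 96-plot inventory the generator emulates.
#' @return data.frame `class, mean, min, max`.
#' @export
default_density_params <- function() data.frame(
  class = forest_classes(),
  mean = c(32.31, 24.01, 18.25, 23.31, 9.13),
  min = c(4.04, 2.09, 8.73, 6.53, 3.36),
  max = c(70.70, 65.87, 73.86, 45.03, 15.69),
  stringsAsFactors = FALSE)

# Gaussian-smoothed standardized white-noise field. Smoothing is exact
# matrix convolution with row-normalized kernels, so edges stay unbiased.
smooth_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  kmat <- function(n) {
    k <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  s <- kmat(nr) %*% z %*% t(kmat(nc))
  (s - mean(s)) / stats::sd(s)
}

# mean over each 3x3 block; input dimensions divisible by 3
block_mean_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 3L || nc %% 3L) stop("dimensions must be divisible by 3")
  r <- m[seq(1, nr, 3), , drop = FALSE] + m[seq(2, nr, 3), , drop = FALSE] +
    m[seq(3, nr, 3), , drop = FALSE]
  (r[, seq(1, nc, 3), drop = FALSE] + r[, seq(2, nc, 3), drop = FALSE] +
     r[, seq(3, nc, 3), drop = FALSE]) / 9
}

# per-class count of 10 m children under each 30 m cell
block_count_3x3 <- function(m, value) block_mean_3x3((m == value) * 9)

#' Generate a synthetic paired-resolution scene
#'
#' Builds, deterministically for a fixed seed: a smooth latent carbon
#' density field rescaled per class to the configured mean/range; a species
#' mask partitioning the forest extent; a 6-band 10 m reflectance stack
#' (b2, b3, b4, b5, b8, b8A) whose red and NIR bands are monotone saturating
#' (Michaelis-type) functions of density plus Gaussian noise scaled so that
#' corr(NDVI, density) over forest pixels hits the configured target; a
#' 3-band 30 m stack (b3, b4, b5) formed by exact 3x3 block means of the
#' matching 10 m bands plus independent sensor noise; a six-class land-use
#' truth map at 30 m (majority of the nine children); and two categorical
#' factor rasters with known explained-variance shares for geodetector
#' recovery tests.
#'
#' @param config a [scene_config].
#' @return a `synthetic_scene` list with elements `true_density_10m`,
#'   `species_mask_10m`, `forest_mask_10m`, `stack_10m`, `stack_30m`,
#'   `stack_30m_clean`, `landuse_truth_10m`, `landuse_truth_30m`,
#'   `landuse_purity_30m`, `factor_rasters`, `config`, `calibration`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$extent_px[1]; nc <- config$extent_px[2]
  seeds <- with_seed(config$seed, sample.int(2^31 - 2, 10))
  classes <- forest_classes()

  # latent structure fields
  f_forest <- with_seed(seeds[1], smooth_field(nr, nc, config$smoothness_px))
  f_species <- with_seed(seeds[2], smooth_field(nr, nc, config$smoothness_px))
  f_density <- with_seed(seeds[3], smooth_field(nr, nc, config$smoothness_px))
  f_backgr <- with_seed(seeds[4], smooth_field(nr, nc, config$smoothness_px))

  forest <- f_forest >= stats::quantile(f_forest, 1 - config$forest_fraction,
                                        names = FALSE)
  if (config$forest_fraction >= 1) forest[] <- TRUE

  # species mask: quantile partition of a smooth field within the forest
  species <- matrix(0L, nr, nc)
  fr <- config$species_fractions
  # classes with zero fraction get no pixels (breaks collapse over them)
  keep <- which(fr > 0)
  lab <- keep[findInterval(f_species[forest],
                           c(-Inf, stats::quantile(f_species[forest],
                                                   cumsum(fr[keep]) / sum(fr[keep]),
                                                   names = FALSE)[-length(keep)]))]
  species[forest] <- lab

  # density: per class, standardized latent field mapped to mean/range
  density <- matrix(NA_real_, nr, nc)
  dp <- config$density_params
  for (ci in seq_along(classes)) {
    idx <- which(species == ci)
    if (!length(idx)) next
    p <- dp[dp$class == classes[ci], ]
    z <- f_density[idx]
    z <- if (length(idx) > 1L && stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else 0
    d <- p$mean + z * (p$max - p$min) / 6
    density[idx] <- pmin(pmax(d, p$min), p$max)
  }

  # reflectance: saturating vegetation signal + class spectra backgrounds
  refl <- synth_reflectance(density, species, forest, f_backgr, nr, nc,
                            seeds, config)

  stack_10m <- raster_stack(refl$bands10, res_m = 10)
  clean30 <- lapply(refl$bands10[c("b3", "b4", "b8")], block_mean_3x3)
  names(clean30) <- c("b3", "b4", "b5")   # OLI naming: b5 is NIR
  noise30 <- with_seed(seeds[7], lapply(clean30, function(b)
    matrix(stats::rnorm(length(b), sd = config$sensor_noise_sd),
           nrow(b), ncol(b))))
  noisy30 <- Map(function(b, e) pmin(pmax(b + e, 0), 1), clean30, noise30)
  stack_30m_clean <- raster_stack(clean30, res_m = 30)
  stack_30m <- raster_stack(noisy30, res_m = 30)

  # land use truth: 10 m labels -> 30 m majority
  lu_classes <- landuse_classes()
  lu10 <- refl$landuse10
  counts <- lapply(seq_along(lu_classes), function(ci)
    block_count_3x3(lu10, ci))
  cnt <- simplify2array(counts)
  lu30 <- apply(cnt, c(1, 2), which.max)          # first max wins ties
  purity <- apply(cnt, c(1, 2), max) / 9

  scene <- structure(list(
    true_density_10m = raster_stack(list(density = density), res_m = 10),
    species_mask_10m = raster_stack(list(class = species + 0), res_m = 10),
    forest_mask_10m = forest,
    stack_10m = stack_10m,
    stack_30m = stack_30m,
    stack_30m_clean = stack_30m_clean,
    landuse_truth_10m = raster_stack(list(class = lu10 + 0), res_m = 10),
    landuse_truth_30m = raster_stack(list(class = lu30 + 0), res_m = 30),
    landuse_purity_30m = raster_stack(list(purity = purity), res_m = 30),
    class_labels = classes,
    landuse_labels = lu_classes,
    factor_rasters = list(),
    calibration = refl$calibration,
    config = config), class = "synthetic_scene")

  scene$factor_rasters <- list(
    stratumA = generate_factor_strata(scene, k = 5, effect_fraction = 0.5,
                                      seed = seeds[8]),
    stratumB = generate_factor_strata(scene, k = 4, effect_fraction = 0.25,
                                      seed = seeds[9]))
  scene
}

# Reflectance construction. Vegetated pixels follow a Michaelis saturating
# response g = d / (d + K): red decreases, NIR increases in g. Shrub canopies
# carry a brighter red/green soil-background signature than closed tree
# canopies. Non-forest pixels take one of four background spectra
# (cropland, grassland, water, bare/other) partitioned by a smooth field.
synth_reflectance <- function(density, species, forest, f_backgr, nr, nc,
                              seeds, config, half_sat = 50) {
  g <- matrix(0, nr, nc)
  g[forest] <- density[forest] / (density[forest] + half_sat)
  shrub <- species == 5L
  tree <- forest & !shrub

  bands <- list(b2 = matrix(0.07, nr, nc), b3 = matrix(0.10, nr, nc),
                b4 = matrix(0.13, nr, nc), b5 = matrix(0.16, nr, nc),
                b8 = matrix(0.20, nr, nc), b8A = matrix(0.21, nr, nc))
  veg <- function(base, slope) base + slope * g
  set_px <- function(bands, px, vals) {
    for (b in names(vals)) bands[[b]][px] <- vals[[b]][px]
    bands
  }
  # tree and shrub canopies share the density-driven red/NIR response (so a
  # pooled NDVI stays informative); the sparser shrub canopy is told apart
  # by its brighter green/red-edge soil background
  tree_spec <- list(b2 = veg(0.05, -0.02), b3 = veg(0.09, 0.01),
                    b4 = veg(0.17, -0.13), b5 = veg(0.19, 0.06),
                    b8 = veg(0.15, 0.30), b8A = veg(0.16, 0.31))
  shrub_spec <- list(b2 = veg(0.06, -0.02), b3 = veg(0.14, 0.01),
                     b4 = veg(0.17, -0.13), b5 = veg(0.24, 0.06),
                     b8 = veg(0.15, 0.30), b8A = veg(0.16, 0.31))
  bands <- set_px(bands, which(tree), tree_spec)
  bands <- set_px(bands, which(shrub), shrub_spec)

  # non-forest background classes: cropland/grassland/water/other
  bg_fr <- c(cropland = 0.30, grassland = 0.45, water = 0.05, other = 0.20)
  bg_spec <- list(
    cropland = c(b2 = 0.07, b3 = 0.11, b4 = 0.13, b5 = 0.18, b8 = 0.30, b8A = 0.31),
    grassland = c(b2 = 0.06, b3 = 0.09, b4 = 0.11, b5 = 0.14, b8 = 0.21, b8A = 0.22),
    water = c(b2 = 0.07, b3 = 0.08, b4 = 0.05, b5 = 0.04, b8 = 0.02, b8A = 0.02),
    other = c(b2 = 0.15, b3 = 0.19, b4 = 0.24, b5 = 0.27, b8 = 0.31, b8A = 0.31))
  nonf <- which(!forest)
  landuse10 <- matrix(0L, nr, nc)
  lu_classes <- landuse_classes()
  landuse10[tree] <- match("forest", lu_classes)
  landuse10[shrub] <- match("shrub", lu_classes)
  if (length(nonf)) {
    qs <- stats::quantile(f_backgr[nonf], cumsum(bg_fr), names = FALSE)
    bg_lab <- findInterval(f_backgr[nonf], c(-Inf, qs[-length(qs)]))
    for (bi in seq_along(bg_spec)) {
      px <- nonf[bg_lab == bi]
      for (b in names(bands)) bands[[b]][px] <- bg_spec[[bi]][b]
    }
    landuse10[nonf] <- match(names(bg_fr), lu_classes)[bg_lab]
  }

  # base sensor noise on every band, then extra noise on the vegetation
  # signal bands, bisected so corr(NDVI, density) hits the target
  base_noise <- with_seed(seeds[5], lapply(bands, function(b)
    matrix(stats::rnorm(nr * nc, sd = config$sensor_noise_sd), nr, nc)))
  cal_noise <- with_seed(seeds[6], lapply(
    stats::setNames(nm = c("b4", "b5", "b8", "b8A")), function(b)
      matrix(stats::rnorm(nr * nc), nr, nc)))
  fpix <- which(forest)
  ndvi_cor <- function(s) {
    nirv <- bands$b8[fpix] + base_noise$b8[fpix] + s * cal_noise$b8[fpix]
    redv <- bands$b4[fpix] + base_noise$b4[fpix] + s * cal_noise$b4[fpix]
    stats::cor((nirv - redv) / (nirv + redv), density[fpix])
  }
  s_lo <- 0; s_hi <- 0.5
  achieved <- ndvi_cor(0)
  if (achieved <= config$vi_signal_r) {
    s <- 0
  } else {
    for (i in 1:40) {
      s <- (s_lo + s_hi) / 2
      if (ndvi_cor(s) > config$vi_signal_r) s_lo <- s else s_hi <- s
    }
    s <- (s_lo + s_hi) / 2
    achieved <- ndvi_cor(s)
  }
  for (b in names(bands)) {
    bands[[b]] <- bands[[b]] + base_noise[[b]]
    if (b %in% names(cal_noise)) bands[[b]] <- bands[[b]] + s * cal_noise[[b]]
    bands[[b]] <- pmin(pmax(bands[[b]], 0), 1)
  }
  list(bands10 = bands, landuse10 = landuse10,
       calibration = list(noise_scale = s, achieved_r = achieved,
                          target_r = config$vi_signal_r))
}

#' Synthesize plot inventories matching the scene's true density
#'
#' Samples plot centers within each class's mask and inverts the class's
#' allometric model so that the computed plot carbon density reproduces the
#' local true density up to the configured relative noise. Tree plots
#' (0.04 ha) carry identical stems solved for a common `D^2 H`; shrub plots
#' (0.01 ha) carry individuals solved for a common crown volume; every plot
#' carries three 1 m^2 herb quadrats whose dry masses encode a small herb
#' carbon component.
#'
#' @param scene a `synthetic_scene`.
#' @param config its [scene_config] (defaults to the one stored in the
#'   scene).
#' @param registry allometric registry used for the inversion; must be the
#'   same registry later used to compute plot densities for an exact
#'   round-trip.
#' @return list of [plot_record]s; classes with an empty mask are skipped
#'   with a warning and recorded in attribute `skipped`.
#' @export
generate_plots <- function(scene, config = scene$config,
                           registry = default_allometry_registry()) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (any(config$n_plots_per_class < 2L))
    stop("'n_plots_per_class' must be >= 2 for every class")
  classes <- scene$class_labels
  species_for_class <- c("Populus" = "Populus", "Salix" = "Salix",
                         "Pinus tabuliformis" = "Pinus tabuliformis",
                         "other" = "Ulmus pumila",
                         "shrub" = "Caragana korshinskii")
  mask <- band(scene$species_mask_10m, "class")
  density <- band(scene$true_density_10m, "density")
  seeds <- with_seed(config$seed + 1L, sample.int(2^31 - 2, length(classes)))
  plots <- list(); skipped <- character(0)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    idx <- which(mask == ci)
    n <- config$n_plots_per_class[ci]
    if (!length(idx)) {
      warning(sprintf("class '%s' has zero mask area; no plots generated", cl))
      skipped <- c(skipped, cl)
      next
    }
    sel <- with_seed(seeds[ci], {
      pick <- sample(idx, n, replace = length(idx) < n)
      noise <- stats::rnorm(n)
      jit <- stats::runif(n, -0.25, 0.25)
      list(pick = pick, noise = noise, jit = jit)
    })
    rc <- arrayInd(sel$pick, dim(density))
    centers <- cell_center(scene$true_density_10m, rc[, 1], rc[, 2])
    for (i in seq_len(n)) {
      d_true <- density[sel$pick[i]]
      fac <- pmin(pmax(1 + config$plot_noise * sel$noise[i], 0.5), 1.5)
      d_target <- d_true * fac
      plots[[length(plots) + 1L]] <-
        build_plot(sprintf("%s_%02d", gsub(" ", "_", cl), i), cl,
                   centers[i, ], d_target, species_for_class[[cl]],
                   registry)
    }
  }
  attr(plots, "skipped") <- skipped
  plots
}

# Invert the class allometry so the plot computes to d_target (t/ha).
build_plot <- function(plot_id, class_label, center, d_target, species,
                       registry, herb_cc = 0.45) {
  model <- registry[[species]]
  herb_d <- min(0.5, 0.1 * d_target)      # small herb layer, t/ha
  woody_d <- d_target - herb_d
  area_ha <- if (class_label == "shrub") 0.01 else 0.04
  woody_kg_c <- woody_d * area_ha * 1000
  # herb: mean quadrat mass must encode herb_d exactly; jitter sums to zero
  mass_kg_m2 <- herb_d / (10 * herb_cc)
  q_tot <- mass_kg_m2 * 1000 * c(1.1, 0.9, 1.0)
  quadrats <- data.frame(above_g = 0.7 * q_tot, below_g = 0.3 * q_tot)
  if (class_label == "shrub") {
    w_tot <- woody_kg_c / model$carbon_coefficient
    n_s <- max(5L, min(200L, round(w_tot / 3)))
    w_each <- w_tot / n_s
    co <- model$whole_coefficients
    v <- (w_each / co[1])^(1 / co[2])
    m_cr <- (6 * v / (pi * 0.8))^(1 / 3)  # aspect: H = 0.8 M
    h <- 0.8 * m_cr
    shrubs <- data.frame(species = species, crown_m = rep(m_cr, n_s),
                         height_m = rep(h, n_s))
    plot_record(plot_id, class_label, center, plot_area_ha = area_ha,
                shrubs = shrubs, herb_quadrats = quadrats)
  } else {
    n_s <- max(3L, min(60L, round(woody_kg_c / 50)))
    target_each <- woody_kg_c / n_s
    cc <- model$carbon_coefficient
    f <- function(lx) {
      x <- 10^lx
      cc * sum(vapply(model$organ_coefficients,
                      function(co) co[1] * x^co[2], numeric(1))) - target_each
    }
    lx <- stats::uniroot(f, c(-4, 9), tol = 1e-12)$root
    x <- 10^lx                            # x = D^2 H
    h <- min(2 + 0.35 * x^(1 / 3), 30)
    d_cm <- sqrt(x / h)
    stems <- data.frame(species = species, dbh_cm = rep(d_cm, n_s),
                        height_m = rep(h, n_s))
    plot_record(plot_id, class_label, center, plot_area_ha = area_ha,
                stems = stems, herb_quadrats = quadrats)
  }
}

#' Construct categorical strata with a chosen explained-variance share
#'
#' Builds a stratification of the forest pixels whose between-stratum share
#' of the density variance (the geodetector q of the construction) equals
#' `effect_fraction`. A fraction of pixels is assigned to equal-count
#' density-rank slices (maximally informative) and the remainder uniformly
#' at random (uninformative); the mixing fraction is bisected until the
#' realized between/total variance-share — computed from plain group sums,
#' independently of the geodetector module — is within 0.005 of the target.
#'
#' @param scene a `synthetic_scene`.
#' @param k number of strata (>= 2, at most the number of forest pixels).
#' @param effect_fraction target variance share in `[0, 1]`.
#' @param seed RNG seed for the random component.
#' @return single-band [raster_stack] `"stratum"` (NA outside the forest)
#'   with attributes `target_q` (the requested share), `realized_q` (the
#'   achieved share) and `k`.
#' @export
generate_factor_strata <- function(scene, k, effect_fraction, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"))
  density <- band(scene$true_density_10m, "density")
  idx <- which(!is.na(density))
  n <- length(idx)
  if (k < 2) stop("'k' must be >= 2")
  if (k > n) stop("'k' exceeds the number of forest pixels")
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("'effect_fraction' must be in [0, 1]")
  y <- density[idx]
  slices <- as.integer(cut(rank(y, ties.method = "first"), k,
                           labels = FALSE))
  rand <- with_seed(seed, list(lab = sample.int(k, n, replace = TRUE),
                               perm = sample.int(n)))
  share <- function(lab) {
    ybar <- mean(y)
    gm <- tapply(y, lab, mean); gn <- tapply(y, lab, length)
    sum(gn * (gm - ybar)^2) / sum((y - ybar)^2)
  }
  mix <- function(m) {                    # first m (permuted) pixels informative
    lab <- rand$lab
    take <- rand$perm[seq_len(m)]
    lab[take] <- slices[take]
    lab
  }
  s_max <- share(slices)
  if (effect_fraction >= s_max - 1e-9) {
    lab <- slices
    realized <- s_max
    if (effect_fraction > s_max + 0.005)
      warning(sprintf(
        "effect_fraction %.3f exceeds the maximum share %.3f attainable with k = %d rank slices",
        effect_fraction, s_max, k))
  } else {
    lo <- 0L; hi <- n
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (share(mix(mid)) < effect_fraction) lo <- mid else hi <- mid
    }
    m_star <- if (abs(share(mix(lo)) - effect_fraction) <
                  abs(share(mix(hi)) - effect_fraction)) lo else hi
    lab <- mix(m_star)
    realized <- share(lab)
  }
  strata <- matrix(NA_real_, nrow(density), ncol(density))
  strata[idx] <- lab
  out <- raster_stack(list(stratum = strata),
                      res_m = scene$true_density_10m$res_m)
  attr(out, "target_q") <- effect_fraction
  attr(out, "realized_q") <- realized
  attr(out, "k") <- k
  out
}
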