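#' Allometric biomass model for one species group
#'
#' Three functional forms are supported, matching regional biomass equation
#' registries for semi-arid forest inventories:
#' \describe{
#'   \item{`organ_power`}{trees: per-organ power laws
#'     `W_organ = a * (D^2 H)^b` with DBH `D` in cm, height `H` in m and `W`
#'     in kg dry mass; all four organs (trunk, branch, leaf, root) must be
#'     defined.}
#'   \item{`whole_power`}{shrubs: whole-plant `W = a * V^b` with crown volume
#'     `V` in m^3 derived from crown width and height (see
#'     [crown_volume_ellipsoid()]).}
#'   \item{`whole_poly`}{shrubs: whole-plant quadratic in the height-crown
#'     product, `W = c0 + c1 (H M) + c2 (H M)^2` with `M` the crown width in
#'     m.}
#' }
#' The carbon coefficient is the dry-mass carbon fraction (e.g. 0.48 for
#' *Populus*, 0.47 for *Salix*).
#'
#' @param species_label species or species-group name used to resolve stems.
#' @param form one of `"organ_power"`, `"whole_power"`, `"whole_poly"`.
#' @param carbon_coefficient carbon fraction of dry biomass, in (0, 1).
#' @param organ_coefficients for `organ_power`: named list
#'   `trunk/branch/leaf/root`, each `c(a, b)`.
#' @param whole_coefficients for `whole_power`: `c(a, b)`; for `whole_poly`:
#'   `c(c0, c1, c2)`.
#' @return an `allometric_model` object.
#' @export
allometric_model <- function(species_label, form,
                             carbon_coefficient,
                             organ_coefficients = NULL,
                             whole_coefficients = NULL) {
  form <- match.arg(form, c("organ_power", "whole_power", "whole_poly"))
  if (!is.numeric(carbon_coefficient) || length(carbon_coefficient) != 1L ||
      carbon_coefficient <= 0 || carbon_coefficient >= 1)
    stop("'carbon_coefficient' must be a single number in (0, 1)")
  if (form == "organ_power") {
    organs <- c("trunk", "branch", "leaf", "root")
    if (is.null(organ_coefficients) ||
        !all(organs %in% names(organ_coefficients)))
      stop("organ_power models must define coefficients for all of: ",
           paste(organs, collapse = ", "))
    for (o in organs) {
      co <- organ_coefficients[[o]]
      if (length(co) != 2L || !is.numeric(co) || co[1] <= 0)
        stop(sprintf("organ '%s' needs c(a, b) with a > 0", o))
    }
    organ_coefficients <- lapply(organ_coefficients[organs], as.numeric)
  } else {
    if (is.null(whole_coefficients))
      stop(sprintf("form '%s' requires 'whole_coefficients'", form))
    whole_coefficients <- as.numeric(whole_coefficients)
    if (form == "whole_power" &&
        (length(whole_coefficients) != 2L || whole_coefficients[1] <= 0))
      stop("whole_power requires c(a, b) with a > 0")
    if (form == "whole_poly" && length(whole_coefficients) != 3L)
      stop("whole_poly requires c(c0, c1, c2)")
  }
  structure(list(species_label = species_label, form = form,
                 carbon_coefficient = carbon_coefficient,
                 organ_coefficients = organ_coefficients,
                 whole_coefficients = whole_coefficients),
            class = "allometric_model")
}

#' Shipped allometric registry
#'
#' Organ-wise power-law coefficients and carbon fractions for the five tree
#' species groups used by regional inventories of the Ordos plateau
#' (*Populus*, *Salix*, *Pinus tabuliformis*, *Ulmus pumila*,
#' *Pinus sylvestris* var. *mongholica*), plus whole-plant shrub models for
#' *Caragana korshinskii*, *Artemisia ordosica* and *Salix cheilophila*.
#'
#' The published shrub equations for this region are typographically
#' corrupted in their printed source (an impossible exponent and a missing
#' operator), so the shrub entries shipped here are corrected placeholder
#' forms — synthetic values chosen to give plausible shrub masses, not
#' published coefficients. They are meant to be overridden from a YAML
#' registry ([read_allometry_registry()]) when measured equations are
#' available. The `fallback` entry is used for species absent from the
#' registry when `plot_carbon_density(..., fallback = TRUE)`.
#'
#' @return named list of [allometric_model] objects.
#' @export
default_allometry_registry <- function() {
  op <- function(lab, cc, trunk, branch, leaf, root)
    allometric_model(lab, "organ_power", cc,
                     organ_coefficients = list(trunk = trunk, branch = branch,
                                               leaf = leaf, root = root))
  reg <- list(
    "Populus" = op("Populus", 0.48,
                   c(0.0859, 0.8001), c(0.0036, 0.8437),
                   c(0.0291, 0.6136), c(0.0143, 0.8772)),
    "Salix" = op("Salix", 0.47,
                 c(0.0535, 0.8977), c(0.0064, 0.9495),
                 c(0.0070, 0.7347), c(0.0253, 0.8435)),
    "Pinus tabuliformis" = op("Pinus tabuliformis", 0.50,
                              c(0.0455, 0.8716), c(1.1125, 0.3455),
                              c(0.0280, 0.6399), c(0.0191, 0.8682)),
    "Ulmus pumila" = op("Ulmus pumila", 0.48,
                        c(0.0455, 0.8716), c(0.0814, 0.7510),
                        c(0.0178, 0.7584), c(0.0772, 0.8176)),
    "Pinus sylvestris var. mongholica" =
      op("Pinus sylvestris var. mongholica", 0.41,
         c(0.0805, 0.8063), c(0.0669, 0.6268),
         c(0.0961, 0.6553), c(0.2385, 0.5227)),
    # corrected placeholder shrub forms (synthetic coefficients, see above)
    "Caragana korshinskii" =
      allometric_model("Caragana korshinskii", "whole_power", 0.47,
                       whole_coefficients = c(0.90, 1.06)),
    "Artemisia ordosica" =
      allometric_model("Artemisia ordosica", "whole_poly", 0.47,
                       whole_coefficients = c(0.061, 0.2854, 0.0516)),
    "Salix cheilophila" =
      allometric_model("Salix cheilophila", "whole_power", 0.47,
                       whole_coefficients = c(0.90, 1.06))
  )
  reg$fallback <- reg[["Ulmus pumila"]]
  reg
}

#' Ellipsoid crown volume
#'
#' Convention used by the shipped `whole_power` shrub models:
#' `V = (pi / 6) M^2 H` (m^3), the volume of an ellipsoid with two horizontal
#' axes equal to the crown width `M` and vertical axis equal to the height
#' `H`. Any function of `(crown_width_m, height_m)` may be substituted via
#' the `crown_volume` argument of [shrub_biomass()].
#'
#' @param crown_width_m crown width in m.
#' @param height_m shrub height in m.
#' @return volume in m^3.
#' @export
crown_volume_ellipsoid <- function(crown_width_m, height_m)
  (pi / 6) * crown_width_m^2 * height_m

#' Individual tree biomass by organ
#'
#' Evaluates the four organ power laws `W = a (D^2 H)^b` of an `organ_power`
#' model. Units: DBH in cm, height in m, biomass in kg dry mass.
#'
#' @param model an [allometric_model] with `form == "organ_power"`.
#' @param dbh_cm,height_m positive stem measurements (vectorised).
#' @return list with `organs` (matrix, one column per organ) and `total`
#'   (numeric vector, sum of the four organs).
#' @examples
#' reg <- default_allometry_registry()
#' tree_biomass(reg$Populus, dbh_cm = 20, height_m = 10)$total
#' @export
tree_biomass <- function(model, dbh_cm, height_m) {
  stopifnot(inherits(model, "allometric_model"))
  if (model$form != "organ_power")
    stop("tree_biomass() requires an organ_power model")
  if (any(dbh_cm <= 0) || any(height_m <= 0))
    stop("dbh and height must be positive")
  x <- dbh_cm^2 * height_m
  organs <- vapply(model$organ_coefficients,
                   function(co) co[1] * x^co[2],
                   numeric(length(x)))
  organs <- matrix(organs, nrow = length(x),
                   dimnames = list(NULL, names(model$organ_coefficients)))
  list(organs = organs, total = rowSums(organs))
}

#' Individual shrub biomass
#'
#' Evaluates a whole-plant shrub model: `W = a V^b` (crown volume form) or
#' `W = c0 + c1 (H M) + c2 (H M)^2` (height-crown polynomial form).
#'
#' @param model an [allometric_model] with form `whole_power` or
#'   `whole_poly`.
#' @param crown_width_m,height_m positive measurements (vectorised).
#' @param crown_volume function mapping `(crown_width_m, height_m)` to crown
#'   volume in m^3; used by `whole_power` only.
#' @return biomass in kg dry mass.
#' @export
shrub_biomass <- function(model, crown_width_m, height_m,
                          crown_volume = crown_volume_ellipsoid) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(crown_width_m <= 0) || any(height_m <= 0))
    stop("crown width and height must be positive")
  w <- switch(model$form,
    whole_power = {
      v <- crown_volume(crown_width_m, height_m)
      model$whole_coefficients[1] * v^model$whole_coefficients[2]
    },
    whole_poly = {
      hm <- height_m * crown_width_m
      co <- model$whole_coefficients
      co[1] + co[2] * hm + co[3] * hm^2
    },
    stop("shrub_biomass() requires a whole_power or whole_poly model"))
  if (any(!is.finite(w)))
    warning("non-finite shrub biomass for some individuals; they are dropped")
  w
}

#' Carbon content of an individual's biomass
#'
#' @param biomass_kg dry biomass in kg (non-negative).
#' @param carbon_coefficient carbon fraction of dry mass.
#' @return carbon in kg.
#' @export
individual_carbon <- function(biomass_kg, carbon_coefficient) {
  if (any(biomass_kg < 0)) stop("biomass must be non-negative")
  if (carbon_coefficient <= 0) stop("carbon coefficient must be positive")
  biomass_kg * carbon_coefficient
}

#' Herb-layer carbon from quadrat dry masses
#'
#' Above- and belowground dry masses from 1 m^2 quadrats are summed, scaled
#' by the herb carbon coefficient, and averaged over quadrats.
#'
#' @param quadrats data.frame with columns `above_g` and `below_g` (dry mass
#'   in g per 1 m^2 quadrat), one row per quadrat.
#' @param herb_carbon_coefficient carbon fraction of herb dry mass. The
#'   regional measurement guideline value is not published; 0.45 is a
#'   configurable default.
#' @return carbon in kg C per m^2.
#' @export
herb_carbon <- function(quadrats, herb_carbon_coefficient = 0.45) {
  quadrats <- as.data.frame(quadrats)
  if (nrow(quadrats) < 1L) stop("at least one quadrat is required")
  if (!all(c("above_g", "below_g") %in% names(quadrats)))
    stop("quadrats need columns 'above_g' and 'below_g'")
  total_kg <- (quadrats$above_g + quadrats$below_g) / 1000
  if (any(total_kg < 0)) stop("quadrat masses must be non-negative")
  mean(total_kg * herb_carbon_coefficient)
}

#' One field plot with its woody and herb inventory
#'
#' Tree plots cover 20 x 20 m (0.04 ha), shrub plots 10 x 10 m (0.01 ha);
#' every plot carries herb quadrats of 1 m^2.
#'
#' @param plot_id identifier.
#' @param class_label one of `"Populus"`, `"Salix"`, `"Pinus tabuliformis"`,
#'   `"other"`, `"shrub"`.
#' @param center list or vector with `x`, `y` in the raster CRS.
#' @param plot_area_ha plot area in ha.
#' @param stems data.frame `species, dbh_cm, height_m` (trees; may be empty).
#' @param shrubs data.frame `species, crown_m, height_m` (may be empty).
#' @param herb_quadrats data.frame `above_g, below_g` (may be empty).
#' @return a `plot_record` object.
#' @export
plot_record <- function(plot_id, class_label, center,
                        plot_area_ha = if (identical(class_label, "shrub")) 0.01 else 0.04,
                        stems = NULL, shrubs = NULL, herb_quadrats = NULL) {
  empty <- function(cols) stats::setNames(
    as.data.frame(rep(list(numeric(0)), length(cols))), cols)
  if (is.null(stems)) stems <- cbind(species = character(0),
                                     empty(c("dbh_cm", "height_m")))
  if (is.null(shrubs)) shrubs <- cbind(species = character(0),
                                       empty(c("crown_m", "height_m")))
  if (is.null(herb_quadrats)) herb_quadrats <- empty(c("above_g", "below_g"))
  if (plot_area_ha <= 0) stop("plot area must be positive")
  stems <- as.data.frame(stems); shrubs <- as.data.frame(shrubs)
  if (nrow(stems) && (any(stems$dbh_cm < 0) || any(stems$height_m < 0)))
    stop("stem measurements must be non-negative")
  if (nrow(shrubs) && (any(shrubs$crown_m < 0) || any(shrubs$height_m < 0)))
    stop("shrub measurements must be non-negative")
  structure(list(plot_id = as.character(plot_id),
                 class_label = class_label,
                 center = list(x = as.numeric(center[["x"]] %||% center[1]),
                               y = as.numeric(center[["y"]] %||% center[2])),
                 plot_area_ha = plot_area_ha,
                 stems = stems, shrubs = shrubs,
                 herb_quadrats = as.data.frame(herb_quadrats)),
            class = "plot_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot carbon density from a full inventory
#'
#' Sums tree and shrub carbon (kg) over all individuals, converts to t/ha
#' via the plot area, and adds the herb layer (kg C/m^2 scaled by 10 to
#' t/ha). Components are reported separately; their sum is the plot carbon
#' density.
#'
#' @param plot a [plot_record].
#' @param registry named list of [allometric_model]s (see
#'   [default_allometry_registry()]).
#' @param herb_carbon_coefficient see [herb_carbon()].
#' @param fallback if `TRUE`, species missing from the registry use the
#'   registry's `fallback` entry (substituting coefficients of a similar
#'   species); if `FALSE` they are an error naming the label.
#' @return one-row data.frame: `plot_id, class_label, carbon_density,
#'   tree, shrub, herb` (t/ha).
#' @export
plot_carbon_density <- function(plot, registry = default_allometry_registry(),
                                herb_carbon_coefficient = 0.45,
                                fallback = FALSE) {
  stopifnot(inherits(plot, "plot_record"))
  resolve <- function(sp) {
    m <- registry[[sp]]
    if (is.null(m)) {
      if (fallback && !is.null(registry$fallback)) m <- registry$fallback
      else stop(sprintf("species '%s' not found in the allometric registry", sp))
    }
    m
  }
  tree_kg <- 0
  if (nrow(plot$stems)) {
    for (i in seq_len(nrow(plot$stems))) {
      m <- resolve(plot$stems$species[i])
      w <- tree_biomass(m, plot$stems$dbh_cm[i], plot$stems$height_m[i])$total
      tree_kg <- tree_kg + individual_carbon(w, m$carbon_coefficient)
    }
  }
  shrub_kg <- 0
  if (nrow(plot$shrubs)) {
    for (i in seq_len(nrow(plot$shrubs))) {
      m <- resolve(plot$shrubs$species[i])
      w <- shrub_biomass(m, plot$shrubs$crown_m[i], plot$shrubs$height_m[i])
      if (is.finite(w))
        shrub_kg <- shrub_kg + individual_carbon(w, m$carbon_coefficient)
    }
  }
  herb_tha <- 0
  if (nrow(plot$herb_quadrats))
    # kg C / m^2 -> t/ha: x kg/m^2 = 10 x t/ha
    herb_tha <- 10 * herb_carbon(plot$herb_quadrats, herb_carbon_coefficient)
  tree_tha <- (tree_kg / 1000) / plot$plot_area_ha
  shrub_tha <- (shrub_kg / 1000) / plot$plot_area_ha
  data.frame(plot_id = plot$plot_id, class_label = plot$class_label,
             carbon_density = tree_tha + shrub_tha + herb_tha,
             tree = tree_tha, shrub = shrub_tha, herb = herb_tha,
             stringsAsFactors = FALSE)
}

#' Carbon density for a list of plots
#'
#' @param plots list of [plot_record]s.
#' @inheritParams plot_carbon_density
#' @return data.frame with one row per plot, plus columns `x`, `y` of the
#'   plot centers.
#' @export
plots_carbon_density <- function(plots, registry = default_allometry_registry(),
                                 herb_carbon_coefficient = 0.45,
                                 fallback = FALSE) {
  rows <- lapply(plots, function(p) {
    r <- plot_carbon_density(p, registry, herb_carbon_coefficient, fallback)
    r$x <- p$center$x; r$y <- p$center$y
    r
  })
  do.call(rbind, rows)
}

#' Plot inventory CSV interchange
#'
#' One row per individual with columns `plot_id, class_label, layer, species,
#' dbh_cm, height_m, crown_m, above_g, below_g, x, y`; `layer` is one of
#' `tree`, `shrub`, `herb`. Fields that do not apply to a layer are left
#' `NA`.
#'
#' @param plots list of [plot_record]s.
#' @param path CSV path.
#' @return `write_plot_csv()` returns `path` invisibly; `read_plot_csv()`
#'   returns a list of [plot_record]s.
#' @export
write_plot_csv <- function(plots, path) {
  rows <- lapply(plots, function(p) {
    base <- data.frame(plot_id = p$plot_id, class_label = p$class_label,
                       x = p$center$x, y = p$center$y,
                       plot_area_ha = p$plot_area_ha,
                       stringsAsFactors = FALSE)
    out <- list()
    if (nrow(p$stems))
      out$tree <- cbind(base, layer = "tree", species = p$stems$species,
                        dbh_cm = p$stems$dbh_cm, height_m = p$stems$height_m,
                        crown_m = NA_real_, above_g = NA_real_,
                        below_g = NA_real_)
    if (nrow(p$shrubs))
      out$shrub <- cbind(base, layer = "shrub", species = p$shrubs$species,
                         dbh_cm = NA_real_, height_m = p$shrubs$height_m,
                         crown_m = p$shrubs$crown_m, above_g = NA_real_,
                         below_g = NA_real_)
    if (nrow(p$herb_quadrats))
      out$herb <- cbind(base, layer = "herb", species = NA_character_,
                        dbh_cm = NA_real_, height_m = NA_real_,
                        crown_m = NA_real_, above_g = p$herb_quadrats$above_g,
                        below_g = p$herb_quadrats$below_g)
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_csv
#' @export
read_plot_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$plot_id)[unique(tab$plot_id)], function(d) {
    tr <- d[d$layer == "tree", , drop = FALSE]
    sh <- d[d$layer == "shrub", , drop = FALSE]
    hb <- d[d$layer == "herb", , drop = FALSE]
    plot_record(d$plot_id[1], d$class_label[1],
                center = c(x = d$x[1], y = d$y[1]),
                plot_area_ha = d$plot_area_ha[1],
                stems = if (nrow(tr)) tr[, c("species", "dbh_cm", "height_m")],
                shrubs = if (nrow(sh)) sh[, c("species", "crown_m", "height_m")],
                herb_quadrats = if (nrow(hb)) hb[, c("above_g", "below_g")])
  })
}

#' Read or write an allometric registry as YAML
#'
#' One block per species with fields `form`, `carbon_coefficient` and either
#' `organs: {trunk: [a, b], ...}` or `whole: [coefficients]`.
#'
#' @param registry named list of [allometric_model]s.
#' @param path YAML path.
#' @return `read_allometry_registry()` returns the registry list.
#' @export
write_allometry_registry <- function(registry, path) {
  out <- lapply(registry, function(m) {
    x <- list(form = m$form, carbon_coefficient = m$carbon_coefficient)
    if (m$form == "organ_power") x$organs <- lapply(m$organ_coefficients, as.numeric)
    else x$whole <- as.numeric(m$whole_coefficients)
    x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_allometry_registry
#' @export
read_allometry_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    allometric_model(nm, x$form, x$carbon_coefficient,
                     organ_coefficients = x$organs,
                     whole_coefficients = x$whole)
  })
  stats::setNames(out, names(raw))
}
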