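# Reduction of concentration maps, field measurements and dose figures to
# impact and risk quantities: exceedance areas and extents, exposure
# durations, contour polygons, dilution factors, formulation masses and
# sediment risk margins.

#' Threshold set for impact classification
#'
#' @param lethal_water lethal water concentration for northern shrimp,
#'   ng L^-1 (default 2, derived from the laboratory exposures).
#' @param contour_high secondary high-concentration contour, ng L^-1
#'   (default 200).
#' @param treatment nominal treatment concentration, ng L^-1 (default 2000).
#' @param sediment_pnec sediment predicted-no-effect concentration,
#'   ng g^-1 dw (default 0.33, the SEPA screening value).
#' @param sediment_lc50 10-day sediment LC50 for amphipods, ng g^-1 dw
#'   (default 16).
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(lethal_water = 2, contour_high = 200,
                          treatment = 2000, sediment_pnec = 0.33,
                          sediment_lc50 = 16) {
  vals <- c(lethal_water, contour_high, treatment, sediment_pnec, sediment_lc50)
  if (any(vals < 0)) abort_domain("thresholds must be >= 0")
  if (!(lethal_water < contour_high && contour_high < treatment))
    abort_config("need lethal_water < contour_high < treatment")
  structure(list(lethal_water = lethal_water, contour_high = contour_high,
                 treatment = treatment, sediment_pnec = sediment_pnec,
                 sediment_lc50 = sediment_lc50),
            class = "threshold_set")
}

#' Area above a concentration threshold
#'
#' Counts full cells whose value exceeds the threshold and converts to km^2.
#' (For a sub-cell alternative see [contour_polygons()].)
#'
#' @param map concentration matrix (ng L^-1).
#' @param threshold threshold, same units as `map`.
#' @param cell_area cell area in m^2.
#' @return area in km^2.
#' @export
area_above <- function(map, threshold, cell_area) {
  if (cell_area <= 0) abort_config("'cell_area' must be > 0")
  sum(map > threshold) * cell_area / 1e6
}

#' Maximum extent of an exceedance zone
#'
#' Largest Euclidean distance from `origin` to the centre of any cell above
#' the threshold; 0 when nothing exceeds.
#'
#' @param map concentration matrix on `grid`.
#' @param threshold threshold (same units as `map`).
#' @param grid the [tracer_grid()] the map lives on.
#' @param origin length-2 reference point (m), typically the release point.
#' @return distance in km.
#' @export
max_extent <- function(map, threshold, grid, origin) {
  cc <- cell_centres(grid)
  exc <- which(map > threshold, arr.ind = TRUE)
  if (nrow(exc) == 0L) return(0)
  d <- sqrt((cc$x[exc[, 1L]] - origin[1])^2 + (cc$y[exc[, 2L]] - origin[2])^2)
  max(d) / 1000
}

#' Maximum accumulated exposure duration
#'
#' @param time_above_map matrix of hours from [time_above()].
#' @return global maximum, hours.
#' @export
max_duration <- function(time_above_map) {
  if (any(!is.finite(time_above_map))) abort_config("non-finite cells in map")
  max(time_above_map, 0)
}

#' Threshold contour polygons
#'
#' Marching-squares isolines of the map at the threshold level, as closed
#' polygons with shoelace areas. The summed polygon area approximates
#' [area_above()] to within a one-cell ring around the contour.
#'
#' @param map concentration matrix on `grid`.
#' @param threshold contour level.
#' @param grid the [tracer_grid()] the map lives on.
#' @return object of class `contour_set`: list of polygons (`x`, `y` in m,
#'   `area_km2`) plus `total_area_km2` and the threshold.
#' @export
contour_polygons <- function(map, threshold, grid) {
  if (any(is.na(map))) abort_config("NaN/NA cells in map")
  cc <- cell_centres(grid)
  # uniform fields have no isoline; contourLines warns, we just return empty
  lines <- withCallingHandlers(
    grDevices::contourLines(cc$x, cc$y, map, levels = threshold),
    warning = function(w) {
      if (grepl("all z values are equal", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  polys <- lapply(lines, function(l) {
    x <- l$x; y <- l$y
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) { # close open contours
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    n <- length(x)
    a <- abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
    list(x = x, y = y, area_km2 = a / 1e6)
  })
  structure(list(polygons = polys,
                 total_area_km2 = sum(vapply(polys, `[[`, 0, "area_km2")),
                 threshold = threshold),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> level %g: %d polygon(s), total area %.3g km^2\n",
              x$threshold, length(x$polygons), x$total_area_km2))
  invisible(x)
}

#' Export contour polygons as GeoJSON
#'
#' Writes the polygon set as a GeoJSON FeatureCollection (planar coordinates
#' in metres; one feature per polygon, area in properties).
#'
#' @param contours a [contour_polygons()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(contours, path) {
  feats <- lapply(contours$polygons, function(p) {
    list(type = "Feature",
         properties = list(threshold = contours$threshold,
                           area_km2 = p$area_km2),
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, p$x, p$y))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Dilution arithmetic
#'
#' `dilution_percent()` expresses an ambient concentration as a percentage of
#' the treatment dose (2 ng L^-1 is 0.1% of 2000 ng L^-1);
#' `fold_dilution()` is the reciprocal view (2000 to 2 ng L^-1 is a
#' 1000-fold dilution).
#'
#' @param ambient ambient concentration, ng L^-1.
#' @param treatment treatment concentration, ng L^-1 (> 0 for percent; the
#'   ambient must be > 0 for fold).
#' @return percentage, or dimensionless fold factor.
#' @examples
#' dilution_percent(2, 2000)  # 0.1
#' fold_dilution(2000, 2)     # 1000
#' @export
dilution_percent <- function(ambient, treatment) {
  if (any(treatment <= 0)) abort_domain("'treatment' must be > 0")
  100 * ambient / treatment
}

#' @rdname dilution_percent
#' @export
fold_dilution <- function(treatment, ambient) {
  if (any(ambient <= 0)) abort_domain("'ambient' must be > 0")
  treatment / ambient
}

#' Active-ingredient mass of a formulation volume
#'
#' The delousing formulation carries 10 g of active ingredient per litre by
#' default (27 L corresponds to 270 g deltamethrin).
#'
#' @param volume_l formulation volume, L (>= 0).
#' @param strength_g_per_l active-ingredient strength, g L^-1.
#' @return mass of active ingredient, g.
#' @examples
#' formulation_mass(27)    # 270
#' formulation_mass(17.5)  # 175
#' @export
formulation_mass <- function(volume_l, strength_g_per_l = 10) {
  if (any(volume_l < 0) || any(strength_g_per_l < 0))
    abort_domain("volume and strength must be >= 0")
  volume_l * strength_g_per_l
}

#' Scale a recommended dose
#'
#' Off-label dosing is common; e.g. 1.5x the recommended 2000 ng L^-1 gives
#' 3000 ng L^-1.
#'
#' @param recommended recommended dose, ng L^-1.
#' @param factor multiplier (> 0).
#' @return scaled dose, ng L^-1.
#' @export
dose_scaling <- function(recommended, factor) {
  if (any(factor <= 0)) abort_domain("'factor' must be > 0")
  recommended * factor
}

#' Safety margin of a sediment measurement against a reference
#'
#' How many times below a reference level (PNEC or LC50) a measured sediment
#' concentration lies: `reference / measured`. Censored measurements
#' propagate as bounds: the margin computed at the LOD is a lower bound on
#' the true margin ("at least x-fold below"), flagged `censored`.
#'
#' @param reference reference concentration, ng g^-1 dw.
#' @param measured measured concentration, ng g^-1 dw (> 0), or `NA` for a
#'   censored value.
#' @param lod limit of detection for censored values.
#' @return list `margin` (fold below reference), `censored` (logical),
#'   `bound` (`"exact"` or `">="`).
#' @examples
#' sediment_margin(0.33, 0.03)  # 11-fold below the PNEC
#' @export
sediment_margin <- function(reference, measured, lod = NULL) {
  if (is.na(measured)) {
    if (is.null(lod) || lod <= 0)
      abort_domain("censored measurement needs a positive 'lod'")
    return(list(margin = reference / lod, censored = TRUE, bound = ">="))
  }
  if (measured <= 0) abort_domain("'measured' must be > 0 (or NA with an LOD)")
  list(margin = reference / measured, censored = FALSE, bound = "exact")
}

#' Classify records against a threshold
#'
#' Classifies each water or sediment record as `above` the relevant
#' threshold, `within 10x below` it, or `below`. Censored records are
#' classified by their LOD (an upper bound on the true value), so a
#' `below` verdict is conservative.
#'
#' @param records data frame with columns `value` (NA if censored), `lod`,
#'   `censored`, and `medium` (`"water"` or `"sediment"`).
#' @param thresholds a [threshold_set()]; water records are judged against
#'   `lethal_water`, sediment against `sediment_pnec`.
#' @return the input with columns `threshold` and `class` appended.
#' @export
exceedance_report <- function(records, thresholds = threshold_set()) {
  if (nrow(records) == 0L) {
    records$threshold <- numeric(0)
    records$class <- character(0)
    return(records)
  }
  if (!all(records$medium %in% c("water", "sediment")))
    abort_config("'medium' must be 'water' or 'sediment'")
  th <- ifelse(records$medium == "water",
               thresholds$lethal_water, thresholds$sediment_pnec)
  val <- ifelse(records$censored, records$lod, records$value)
  records$threshold <- th
  records$class <- ifelse(val > th, "above",
                          ifelse(val > th / 10, "within 10x below", "below"))
  records
}
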