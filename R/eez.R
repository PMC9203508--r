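# Exclusive Economic Zone aggregation.

# Even-odd ray-casting point-in-polygon; ring is a closed data frame of
# lon/lat vertices. Points exactly on an edge follow the crossing parity
# (cells are assigned to at most one EEZ by first-containing-polygon order).
point_in_polygon <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring$lon[i]; yi <- ring$lat[i]
    xj <- ring$lon[j]; yj <- ring$lat[j]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Mean ESI per Exclusive Economic Zone
#'
#' Unweighted mean of the ensemble ESI over valid marine cells whose centres
#' fall inside each polygon; cells are assigned to at most one EEZ (first
#' containing polygon). An EEZ with no valid cell gets `NA` with a warning.
#'
#' @param map a `suitability_map`.
#' @param polygons named list of closed lon/lat rings.
#' @return data frame `eez`, `mean_esi`, `n_cells`.
#' @export
esi_by_eez <- function(map, polygons) {
  stopifnot(length(polygons) >= 1)
  cells <- which(map$mask & !is.na(map$esi))
  cc <- cell_coords(map$grid, cells)
  assigned <- rep(NA_character_, length(cells))
  for (nm in names(polygons)) {
    free <- is.na(assigned)
    if (!any(free)) break
    hit <- point_in_polygon(cc$lon[free], cc$lat[free], polygons[[nm]])
    assigned[free][hit] <- nm
  }
  out <- data.frame(eez = names(polygons), mean_esi = NA_real_, n_cells = 0L)
  for (i in seq_along(polygons)) {
    idx <- which(assigned == out$eez[i])
    out$n_cells[i] <- length(idx)
    if (length(idx)) out$mean_esi[i] <- mean(map$esi[cells[idx]])
  }
  if (any(out$n_cells == 0))
    warning("EEZ(s) with no valid cells: ",
            paste(out$eez[out$n_cells == 0], collapse = ", "))
  out
}

#' Attach catch statistics to EEZ summaries
#'
#' Joins log10 mean annual catch (tonnes) to per-EEZ summaries and flags
#' entries under the display threshold (they are retained in the data, only
#' marked as not-to-display, following the convention of omitting countries
#' with catches below 1000 t from maps).
#'
#' @param summaries data frame with an `eez` column (e.g. from
#'   [esi_by_eez()]).
#' @param catch_table data frame `species`, `eez`, `catch_t` (tonnes, >= 0).
#' @param species species to join (default: the table's first).
#' @param min_catch display threshold in tonnes.
#' @return `summaries` with `catch_t`, `log10_catch`, `below_threshold`.
#' @export
attach_catch <- function(summaries, catch_table, species = NULL,
                         min_catch = 1000) {
  stopifnot(all(catch_table$catch_t >= 0, na.rm = TRUE))
  species <- species %||% catch_table$species[1]
  ct <- catch_table[catch_table$species == species, , drop = FALSE]
  m <- match(summaries$eez, ct$eez)
  if (anyNA(m))
    warning("EEZ id(s) without catch entry: ",
            paste(summaries$eez[is.na(m)], collapse = ", "))
  summaries$catch_t <- ct$catch_t[m]
  summaries$log10_catch <- ifelse(!is.na(summaries$catch_t) &
                                    summaries$catch_t > 0,
                                  log10(summaries$catch_t), NA_real_)
  summaries$below_threshold <- !is.na(summaries$catch_t) &
    summaries$catch_t < min_catch
  summaries
}

#' EEZ-level change summary across scenarios
#'
#' Contemporary and future per-EEZ ESI means with their difference, for one
#' (RCP, decade) of a corrected scenario set.
#'
#' @param fit an [esm] fit.
#' @param grid contemporary [env_grid].
#' @param scenario corrected scenario set.
#' @param polygons EEZ polygons.
#' @param rcp,decade scenario coordinates.
#' @param mask validity mask.
#' @return data frame `eez`, `esi_now`, `esi_future`, `delta_esi`.
#' @export
eez_change <- function(fit, grid, scenario, polygons, rcp, decade,
                       mask = NULL) {
  now <- esi_by_eez(project_ensemble(fit, grid, mask), polygons)
  fut <- esi_by_eez(project_ensemble(fit, grid, mask, scenario, rcp, decade),
                    polygons)
  data.frame(eez = now$eez, esi_now = now$mean_esi, esi_future = fut$mean_esi,
             delta_esi = fut$mean_esi - now$mean_esi)
}
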