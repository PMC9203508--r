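#' Project the ensemble onto a grid or scenario
#'
#' Produces a suitability map from a fitted ensemble. For the contemporary
#' climatology the members are (retained algorithm x cross-validation run)
#' predictions on every valid cell; for a future scenario each member is
#' additionally indexed by GCM, i.e. `|retained| x runs x n_gcm` members
#' (50 simulations per algorithm with 10 runs and 5 GCMs). The ensemble ESI
#' is the unweighted member mean and the member standard deviation
#' accompanies it; cells failing the depth/coast filter are masked.
#'
#' @param fit an [esm] fit.
#' @param grid the contemporary [env_grid] (supplies coordinates, `SSS` and
#'   the mask context).
#' @param mask logical matrix of valid cells (from
#'   [apply_depth_coast_filter()]); default: all marine cells.
#' @param scenario optional corrected [scenario_set][make_scenarios()]; if
#'   supplied, `rcp` and `decade` select the future fields.
#' @param rcp,decade scenario coordinates (required with `scenario`).
#' @return a `suitability_map`: list with `esi` and `sd` matrices, `n_members`,
#'   `mask` and provenance fields.
#' @export
project_ensemble <- function(fit, grid, mask = NULL, scenario = NULL,
                             rcp = NULL, decade = NULL) {
  if (is.null(mask)) mask <- grid$layers$bathymetry < 0
  cells <- which(mask)
  envs <- list()
  if (is.null(scenario)) {
    envs[["obs"]] <- env_at_cells(grid, cells, fit$variables)
  } else {
    stopifnot(!is.null(rcp), !is.null(decade))
    for (g in scenario$gcms) {
      fields <- scenario$fields[[g]][[as.character(rcp)]][[decade]]
      miss <- setdiff(fit$variables, c(names(fields), "SSS"))
      if (length(miss))
        stop("covariate(s) missing from scenario fields: ",
             paste(miss, collapse = ", "))
      e <- data.frame(cell_id = cells)
      for (v in fit$variables) {
        e[[v]] <- if (v %in% names(fields)) fields[[v]][cells]
          else grid$layers[[v]][cells]   # SSS etc. held constant in time
      }
      envs[[g]] <- e
    }
  }
  members <- list()
  for (nm in names(envs)) {
    M <- predict(fit, envs[[nm]], type = "members")
    for (j in seq_len(ncol(M)))
      members[[paste(nm, colnames(M)[j], sep = ".")]] <- M[, j]
  }
  mm <- do.call(cbind, members)
  esi <- sd_ <- matrix(NA_real_, length(grid$lat), length(grid$lon))
  esi[cells] <- rowMeans(mm)
  sd_[cells] <- apply(mm, 1, function(z) sqrt(mean((z - mean(z))^2)))
  structure(list(esi = esi, sd = sd_, n_members = ncol(mm), mask = mask,
                 grid = grid,
                 retained = fit$selection$retained, runs = fit$runs,
                 scenario = if (is.null(scenario)) "contemporary"
                   else paste0("RCP", rcp, " ", decade)),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat("suitability_map (", x$scenario, "):", sum(x$mask), "valid cells,",
      x$n_members, "members (", paste(x$retained, collapse = ", "), ")\n")
  cat("  ESI range:", round(min(x$esi, na.rm = TRUE), 3), "-",
      round(max(x$esi, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Plot a suitability map
#'
#' @param x a `suitability_map`.
#' @param what `"esi"` or `"sd"`.
#' @param ... passed to [graphics::image].
#' @export
plot.suitability_map <- function(x, what = c("esi", "sd"), ...) {
  what <- match.arg(what)
  z <- t(x[[what]])
  graphics::image(x$grid$lon, x$grid$lat, z, xlab = "lon", ylab = "lat",
                  main = paste(toupper(what), "-", x$scenario),
                  col = grDevices::hcl.colors(25, "viridis"), ...)
  invisible(NULL)
}

#' Difference between two suitability maps
#'
#' @param future,contemporary `suitability_map`s on the same grid and mask.
#' @return matrix of per-cell `future - contemporary` ESI, in `[-1, 1]`.
#' @export
diff_map <- function(future, contemporary) {
  if (!identical(dim(future$esi), dim(contemporary$esi)) ||
      !identical(future$mask, contemporary$mask))
    stop("maps are not on the same grid/mask")
  future$esi - contemporary$esi
}

#' Suitable habitat area
#'
#' Area (square km) of valid cells whose ensemble ESI meets the threshold,
#' with latitude-weighted cell areas (see [cell_area_km2()]).
#'
#' @param map a `suitability_map`.
#' @param threshold ESI defining "suitable" (in `(0, 1)`).
#' @return area in square km.
#' @export
suitable_area <- function(map, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  a <- cell_area_km2(map$grid)
  ok <- map$mask & !is.na(map$esi) & map$esi >= threshold
  sum(a[ok])
}

#' Range change between periods
#'
#' @param contemporary_area,future_area suitable areas in square km.
#' @return signed percentage change; negative = contraction.
#' @export
range_change <- function(contemporary_area, future_area) {
  if (contemporary_area <= 0) {
    warning("contemporary suitable area is zero; change undefined")
    return(NA_real_)
  }
  100 * (future_area - contemporary_area) / contemporary_area
}

#' ESI-weighted centroid of a suitability map
#'
#' Latitude/longitude centroid weighted by ESI over valid cells; its poleward
#' drift under warming is the synthetic analogue of a biogeographical
#' displacement toward higher latitudes.
#'
#' @param map a `suitability_map`.
#' @return named numeric `c(lon, lat)`.
#' @export
esi_centroid <- function(map) {
  cells <- which(map$mask & !is.na(map$esi))
  cc <- cell_coords(map$grid, cells)
  w <- map$esi[cells]
  c(lon = sum(cc$lon * w) / sum(w), lat = sum(cc$lat * w) / sum(w))
}

#' Range-change matrix across scenarios and periods
#'
#' Tabulates suitable-area change (per cent, relative to the contemporary
#' map) for every (RCP, decade) of a corrected scenario set, at one or more
#' ESI thresholds.
#'
#' @param fit an [esm] fit.
#' @param grid contemporary [env_grid].
#' @param scenario corrected [scenario_set][make_scenarios()].
#' @param mask validity mask.
#' @param thresholds ESI thresholds to sweep.
#' @return data frame `rcp`, `decade`, `threshold`, `contemporary_km2`,
#'   `future_km2`, `change_pct`.
#' @export
range_change_table <- function(fit, grid, scenario, mask = NULL,
                               thresholds = c(0.3, 0.5, 0.7)) {
  contemp <- project_ensemble(fit, grid, mask)
  rows <- list()
  for (r in scenario$rcps) {
    for (d in scenario$decades) {
      fut <- project_ensemble(fit, grid, mask, scenario, rcp = r, decade = d)
      for (th in thresholds) {
        a0 <- suitable_area(contemp, th)
        a1 <- suitable_area(fut, th)
        rows[[length(rows) + 1L]] <- data.frame(
          rcp = r, decade = d, threshold = th,
          contemporary_km2 = a0, future_km2 = a1,
          change_pct = range_change(a0, a1))
      }
    }
  }
  do.call(rbind, rows)
}
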