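#' Regular lat/lon environmental grid
#'
#' An `env_grid` holds a stack of named environmental layers (matrices with
#' rows indexed by latitude, columns by longitude) on a regular grid of square
#' cells, together with the cell-centre coordinate vectors. Layers follow the
#' naming used throughout the package: `SBT`, `SBTr`, `SBTvar` (sea-bottom
#' temperature mean, annual range, monthly variance, all degrees C), the
#' surface analogues `SST`, `SSTr`, `SSTvar`, salinity `SSS` (psu),
#' log-transformed primary production `Log_PP`, `bathymetry` (m, negative at
#' sea) and `dcoast` (distance to the nearest coast, km).
#'
#' @param lon,lat numeric vectors of cell-centre coordinates (degrees).
#' @param layers named list of matrices, each `length(lat) x length(lon)`.
#' @param cell_size cell edge length in degrees.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(lon, lat, layers, cell_size) {
  stopifnot(is.list(layers), length(names(layers)) == length(layers))
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(length(lat), length(lon))))
      stop("layer '", nm, "' does not match the grid dimensions")
  }
  structure(list(lon = lon, lat = lat, layers = layers, cell_size = cell_size),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat("env_grid:", length(x$lat), "x", length(x$lon), "cells at",
      x$cell_size, "deg\n")
  cat("  lon:", min(x$lon) - x$cell_size / 2, "to", max(x$lon) + x$cell_size / 2,
      " lat:", min(x$lat) - x$cell_size / 2, "to", max(x$lat) + x$cell_size / 2, "\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if ("bathymetry" %in% names(x$layers))
    cat("  marine cells:", sum(x$layers$bathymetry < 0), "\n")
  invisible(x)
}

n_cells <- function(grid) length(grid$lon) * length(grid$lat)

# Linear cell id for (row, col) = (lat index, lon index); column-major over the
# layer matrices so `layer[cell_id]` indexes directly.
cell_id_of <- function(grid, row, col) (col - 1L) * length(grid$lat) + row

# Map lon/lat points to cell ids using half-open cells [edge, edge + size).
# Points outside the domain get NA.
locate_cells <- function(grid, lon, lat) {
  cs <- grid$cell_size
  lon0 <- min(grid$lon) - cs / 2
  lat0 <- min(grid$lat) - cs / 2
  col <- floor((lon - lon0) / cs) + 1L
  row <- floor((lat - lat0) / cs) + 1L
  bad <- col < 1L | col > length(grid$lon) | row < 1L | row > length(grid$lat) |
    !is.finite(lon) | !is.finite(lat)
  id <- cell_id_of(grid, row, col)
  id[bad] <- NA_integer_
  id
}

cell_coords <- function(grid, cell_id) {
  nlat <- length(grid$lat)
  col <- ((cell_id - 1L) %/% nlat) + 1L
  row <- ((cell_id - 1L) %% nlat) + 1L
  data.frame(cell_id = cell_id, lon = grid$lon[col], lat = grid$lat[row],
             row = row, col = col)
}

# Environmental covariates at a set of cell ids, as a data frame with one
# column per requested layer.
env_at_cells <- function(grid, cell_id, variables = names(grid$layers)) {
  out <- data.frame(cell_id = cell_id)
  for (v in variables) out[[v]] <- grid$layers[[v]][cell_id]
  out
}

marine_cells <- function(grid) which(grid$layers$bathymetry < 0)

#' Per-cell surface area of grid cells
#'
#' Cell area on the sphere at cell-centre latitude `phi`:
#' `(111.195 * cell_size) * (111.195 * cell_size * cos(phi))` square km.
#'
#' @param grid an [env_grid].
#' @return matrix of cell areas (square km) with the grid's layer dimensions.
#' @export
cell_area_km2 <- function(grid) {
  cs <- grid$cell_size
  a <- (111.195 * cs) * (111.195 * cs * cos(grid$lat * pi / 180))
  matrix(rep(a, length(grid$lon)), nrow = length(grid$lat))
}

#' Convert a grid to a long-format data frame
#'
#' @param x an [env_grid].
#' @param row.names,optional unused, for generic compatibility.
#' @param ... unused.
#' @return data frame with `cell_id`, `lon`, `lat` and one column per layer.
#' @export
as.data.frame.env_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  ids <- seq_len(n_cells(x))
  cbind(cell_coords(x, ids)[, c("cell_id", "lon", "lat")],
        env_at_cells(x, ids)[, names(x$layers), drop = FALSE])
}

#' Write / read a grid as plain-text CSV
#'
#' Long-format CSV with one row per cell; the companion reader restores the
#' `env_grid` structure. Used as the package's on-disk grid interchange format.
#'
#' @param grid an [env_grid].
#' @param path file path.
#' @return `read_grid_csv` returns an [env_grid]; `write_grid_csv` its path,
#'   invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid)
  utils::write.csv(cbind(df, cell_size = grid$cell_size), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  cs <- df$cell_size[1]
  keep <- setdiff(names(df), c("cell_id", "lon", "lat", "cell_size"))
  layers <- lapply(keep, function(v) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df[[v]]
    m
  })
  names(layers) <- keep
  env_grid(lon, lat, layers, cs)
}
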