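#' Occurrence record quality control
#'
#' Applies, in order: (i) removal of records flagged unreliable, (ii) removal
#' of exact duplicates (lon/lat rounded to 4 decimal places, plus year),
#' (iii) removal of out-of-domain and on-land records, (iv) the dating rule:
#' records from 1990 onwards are kept unconditionally, while older or undated
#' records are kept only within `rules$edge_distance` km of a recent (>= 1990)
#' record, so the distribution edge is confirmed by recent data, and
#' (v) removal of isolated geographic outliers (no other record within
#' `rules$outlier_distance` km). The whole procedure is idempotent.
#'
#' @param raw data frame with at least `lon` and `lat`; optional `year` and
#'   `flag` columns.
#' @param grid an [env_grid] carrying bathymetry (defines the domain and the
#'   land mask).
#' @param rules list of thresholds; see [prep_rules()].
#' @return the cleaned data frame.
#' @export
clean_occurrences <- function(raw, grid, rules = prep_rules()) {
  if (!all(c("lon", "lat") %in% names(raw)))
    stop("raw occurrences must have 'lon' and 'lat' columns")
  x <- raw
  if (!"year" %in% names(x)) x$year <- NA_integer_
  if ("flag" %in% names(x)) x <- x[x$flag != "unreliable", , drop = FALSE]

  key <- paste(round(x$lon, 4), round(x$lat, 4), x$year)
  x <- x[!duplicated(key), , drop = FALSE]

  id <- locate_cells(grid, x$lon, x$lat)
  sea <- !is.na(id) & grid$layers$bathymetry[id] < 0
  x <- x[sea, , drop = FALSE]

  recent <- !is.na(x$year) & x$year >= 1990
  if (any(!recent)) {
    if (any(recent)) {
      dm <- geo_dist_mat(x$lon, x$lat, x$lon[recent], x$lat[recent])
      near <- apply(dm, 1, min) <= rules$edge_distance
      keep <- recent | near
    } else keep <- recent
    x <- x[keep, , drop = FALSE]
  }

  # Isolation rule runs last: a record's within-distance witness is always
  # itself retained (mutual witness), keeping the whole procedure idempotent.
  if (nrow(x) > 1) {
    dm <- geo_dist_mat(x$lon, x$lat)
    diag(dm) <- Inf
    x <- x[apply(dm, 1, min) <= rules$outlier_distance, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

# Pairwise haversine distances in km; second set defaults to the first.
geo_dist_mat <- function(lon1, lat1, lon2 = lon1, lat2 = lat1) {
  m <- matrix(0, length(lon1), length(lon2))
  for (j in seq_along(lon2)) {
    m[, j] <- geosphere::distHaversine(cbind(lon1, lat1),
                                       c(lon2[j], lat2[j])) / 1000
  }
  m
}

#' Default occurrence-preparation thresholds
#'
#' @param edge_distance km within which an old/undated record must sit of a
#'   recent record to be kept (the "distribution edge" radius).
#' @param outlier_distance km beyond which a record with no neighbour is
#'   treated as a locational error.
#' @return a list of rules.
#' @export
prep_rules <- function(edge_distance = 100, outlier_distance = 1000) {
  list(edge_distance = edge_distance, outlier_distance = outlier_distance)
}

#' Aggregate cleaned records onto the grid
#'
#' One presence per occupied cell, cells being half-open intervals
#' `[edge, edge + cell_size)`. Per-cell provenance (record count, most recent
#' year) is retained.
#'
#' @param clean a QC-passed occurrence data frame.
#' @param grid an [env_grid].
#' @return an `occurrence_set`: data frame of presence cells (`cell_id`,
#'   `lon`, `lat`, `n_records`, `last_year`) with the species id attached.
#' @export
grid_occurrences <- function(clean, grid) {
  if (nrow(clean) == 0) {
    warning("no occurrence records to grid; returning empty set")
    out <- data.frame(cell_id = integer(), lon = numeric(), lat = numeric(),
                      n_records = integer(), last_year = integer())
  } else {
    id <- locate_cells(grid, clean$lon, clean$lat)
    stopifnot(!anyNA(id))
    yr <- clean$year %||% rep(NA_integer_, nrow(clean))
    agg <- split(seq_along(id), id)
    cells <- as.integer(names(agg))
    out <- cell_coords(grid, cells)[, c("cell_id", "lon", "lat")]
    out$n_records <- vapply(agg, length, 0L)
    out$last_year <- vapply(agg, function(i) {
      y <- yr[i]
      if (all(is.na(y))) NA_integer_ else as.integer(max(y, na.rm = TRUE))
    }, 0L)
    out <- out[order(out$cell_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "species") <- if (nrow(clean) && "species" %in% names(clean))
    clean$species[1] else NA_character_
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Species depth range
#'
#' Observed depth range of a species (m below the surface) used by the
#' hierarchical bathymetry / distance-to-coast filter.
#'
#' @param min_depth,max_depth observed depth limits, `0 <= min < max`.
#' @param coast_buffer km; cells outside the depth range still pass within
#'   this distance of the coast (default 50 km).
#' @return a `depth_range` list.
#' @export
depth_range <- function(min_depth = 0, max_depth = 1000, coast_buffer = 50) {
  stopifnot(min_depth >= 0, min_depth < max_depth, coast_buffer >= 0)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 coast_buffer = coast_buffer), class = "depth_range")
}

#' Hierarchical bathymetry / distance-to-coast filter
#'
#' A marine cell passes iff its depth lies within the species' observed depth
#' range, or it lies within `coast_buffer` km of the coast (so shelf-poor
#' near-coastal areas are not excluded). Land cells never pass. Applied both
#' to candidate prediction cells and as a sanity screen on presences.
#'
#' @param depth a [depth_range].
#' @param grid an [env_grid] with `bathymetry` and `dcoast` layers.
#' @return logical matrix mask over the grid.
#' @export
apply_depth_coast_filter <- function(depth, grid) {
  if (is.null(depth)) stop("depth range undefined for species")
  b <- grid$layers$bathymetry
  marine <- b < 0
  d <- abs(b)
  in_range <- marine & d >= depth$min_depth & d <= depth$max_depth
  near_coast <- marine & grid$layers$dcoast <= depth$coast_buffer
  in_range | near_coast
}
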