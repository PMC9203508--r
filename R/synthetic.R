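#' Synthetic world generator
#'
#' Builds a self-contained synthetic marine domain with the statistical
#' structure the modelling pipeline assumes: smooth environmental climatologies
#' on a regular grid, a known Gaussian niche truth, occurrence records sampled
#' under spatially biased effort with realistic data-quality noise, emulated
#' general-circulation-model scenario fields, and EEZ polygons with a catch
#' table. Every generator is deterministic given its seed.
#'
#' @name synthetic_world
NULL

#' Generate a synthetic environmental grid
#'
#' Produces smooth climatological layers on a regular `cell_size` grid:
#' sea-bottom temperature (`SBT`) decreasing poleward with a fixed lapse rate,
#' its annual range (`SBTr`) with a mid-latitude maximum, monthly variance
#' (`SBTvar`) strongly correlated with `SBTr`, surface analogues (`SST`,
#' `SSTr`, `SSTvar`) tracking the bottom fields, salinity (`SSS`) tracking
#' `SBT`, log primary production (`Log_PP`) varying mostly zonally, a
#' bathymetry deepening away from a sinuous eastern coastline (negative at
#' sea), and distance-to-coast (km, zero on land). Smooth seeded texture
#' fields add spatial heterogeneity so the environmental space is well
#' populated.
#'
#' @param domain_bounds numeric of length 4: `c(lon_min, lon_max, lat_min,
#'   lat_max)` in degrees.
#' @param cell_size cell edge length in degrees; must divide both extents.
#' @param seed integer seed.
#' @return an [env_grid] with the layers described above.
#' @export
make_env_grid <- function(domain_bounds = c(0, 5, 35, 40), cell_size = 0.1,
                          seed = 1L) {
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  ext <- c(domain_bounds[2] - domain_bounds[1], domain_bounds[4] - domain_bounds[3])
  if (any(abs(ext / cell_size - round(ext / cell_size)) > 1e-8))
    stop("cell_size must divide the domain extents")
  lon <- seq(domain_bounds[1] + cell_size / 2, domain_bounds[2] - cell_size / 2,
             by = cell_size)
  lat <- seq(domain_bounds[3] + cell_size / 2, domain_bounds[4] - cell_size / 2,
             by = cell_size)
  nlat <- length(lat); nlon <- length(lon)
  latm <- matrix(rep(lat, nlon), nlat)
  lonm <- matrix(rep(lon, each = nlat), nlat)

  tx <- lapply(1:7, function(k) smooth_field(lon, lat, derive_seed(seed, paste0("tex", k))))

  # Coastline along the eastern edge; land where lon >= coast_lon(lat).
  lat_mid <- mean(range(lat))
  coast_lon <- domain_bounds[2] - 0.15 * ext[1] +
    0.05 * ext[1] * sin(2 * pi * (latm - domain_bounds[3]) / ext[2])
  sea <- lonm < coast_lon
  depth <- 1800 * pmax(0, (coast_lon - lonm) / (0.85 * ext[1]))^1.2 +
    30 * pmax(0, tx[[6]])
  bathymetry <- ifelse(sea, -pmax(depth, 5), 100)

  # Distance to coast: nearest land cell centre, haversine km. Land cells = 0.
  dcoast <- matrix(0, nlat, nlon)
  land_idx <- which(!sea)
  sea_idx <- which(sea)
  if (length(land_idx) == 0L) stop("synthetic domain has no land; widen bounds")
  land_pts <- cbind(lonm[land_idx], latm[land_idx])
  # coastline proxy: for each latitude row use land cells in that row (the coast
  # is a function of latitude here), exact enough and fast.
  for (r in seq_len(nlat)) {
    cols <- which(sea[r, ])
    if (!length(cols)) next
    land_cols <- which(!sea[r, ])
    ref <- cbind(lon[min(land_cols)], lat[r])
    dcoast[r, cols] <- geosphere::distHaversine(cbind(lon[cols], lat[r]), ref) / 1000
  }

  lapse <- 1.8  # deg C per degree latitude
  SBT <- 24 - lapse * (latm - domain_bounds[3]) + 0.5 * tx[[1]]
  SBTr <- 3 + 2.5 * exp(-((latm - lat_mid) / 2)^2) + 0.8 * tx[[2]]
  SBTvar <- 1 + 0.5 * (SBTr - mean(SBTr)) + 0.28 * tx[[3]]
  SST <- SBT + 4 + 0.3 * tx[[4]]
  SSTr <- 1.2 * SBTr + 0.3 * tx[[4]]
  SSTvar <- 1.1 * SBTvar + 0.2 * tx[[5]]
  SSS <- 30 + 0.35 * SBT + 0.15 * tx[[5]]
  Log_PP <- 0.8 - 0.15 * (lonm - mean(range(lon))) + 0.5 * tx[[7]]

  env_grid(lon, lat,
           list(SBT = SBT, SBTr = SBTr, SBTvar = SBTvar, SST = SST,
                SSTr = SSTr, SSTvar = SSTvar, SSS = SSS, Log_PP = Log_PP,
                bathymetry = bathymetry, dcoast = dcoast),
           cell_size)
}

#' Known niche truth
#'
#' The realized niche the synthetic species occupies: a product of independent
#' Gaussian responses over named environmental variables,
#' `s(x) = max_s * prod_v exp(-(x_v - opt_v)^2 / (2 tol_v^2))`, bounded in
#' `[0, 1]`.
#'
#' @param optima named numeric vector of niche optima (variable units).
#' @param tolerances named numeric vector of positive niche breadths.
#' @param max_suitability peak suitability in `(0, 1]`.
#' @return an object of class `niche_truth`.
#' @export
niche_truth <- function(optima = c(SBT = 17, SBTr = 5, Log_PP = 0.8),
                        tolerances = c(SBT = 1.5, SBTr = 1.5, Log_PP = 1.0),
                        max_suitability = 1) {
  stopifnot(all(names(optima) == names(tolerances)), all(tolerances > 0),
            max_suitability > 0, max_suitability <= 1)
  structure(list(optima = optima, tolerances = tolerances,
                 max_suitability = max_suitability), class = "niche_truth")
}

#' True suitability of environmental conditions
#'
#' @param truth a [niche_truth].
#' @param env data frame (or named list of equal-shape arrays) holding the
#'   truth's variables.
#' @return numeric suitability in `[0, 1]`, shaped like the inputs.
#' @export
true_suitability <- function(truth, env) {
  s <- NULL
  for (v in names(truth$optima)) {
    z <- (env[[v]] - truth$optima[[v]]) / truth$tolerances[[v]]
    g <- exp(-z^2 / 2)
    s <- if (is.null(s)) g else s * g
  }
  truth$max_suitability * s
}

#' Default data-quality noise specification
#'
#' Fractions of extra records appended to a clean occurrence sample to
#' exercise quality control: exact duplicates, on-land positional errors and
#' unreliable-source records. Year structure of the clean records is set by
#' `p_recent`/`p_old`/`p_undated` (defaults mirror the observed shares of
#' post-1990, pre-1990 and undated records in compiled occurrence databases:
#' roughly 73%, 11% and 16%).
#'
#' @param duplicate_fraction,land_fraction,unreliable_fraction fractions of
#'   `n` appended as noise records.
#' @param p_recent,p_old,p_undated year-class probabilities (sum to 1).
#' @return a list with class `noise_spec`.
#' @export
noise_spec <- function(duplicate_fraction = 0.05, land_fraction = 0.02,
                       unreliable_fraction = 0.02,
                       p_recent = 0.73, p_old = 0.11, p_undated = 0.16) {
  p <- c(p_recent, p_old, p_undated)
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  structure(list(duplicate_fraction = duplicate_fraction,
                 land_fraction = land_fraction,
                 unreliable_fraction = unreliable_fraction,
                 p_recent = p_recent, p_old = p_old, p_undated = p_undated),
            class = "noise_spec")
}

#' Sample synthetic occurrence records
#'
#' Marine cells are sampled with probability proportional to
#' `true suitability x sampling effort`; records are jittered uniformly within
#' their cell, assigned a year class (recent >= 1990, pre-1990, or undated)
#' and a reliability flag. The noise specification appends exact duplicates,
#' on-land positional errors and unreliable records so downstream quality
#' control is exercised.
#'
#' @param grid an [env_grid].
#' @param truth a [niche_truth].
#' @param n number of core (pre-noise) records.
#' @param effort_bias matrix of non-negative sampling effort per cell, or
#'   `NULL` for the default coastal-heavy effort `1 + 1.5 exp(-dcoast/75)`.
#' @param noise a [noise_spec].
#' @param seed integer seed.
#' @return data frame with columns `species`, `lon`, `lat`, `year`, `flag`.
#' @export
sample_occurrences <- function(grid, truth, n = 1000, effort_bias = NULL,
                               noise = noise_spec(), seed = 1L,
                               species = "synthspecies") {
  stopifnot(n > 0)
  if (is.null(effort_bias))
    effort_bias <- 1 + 1.5 * exp(-grid$layers$dcoast / 75)
  if (any(effort_bias < 0)) stop("effort_bias must be non-negative everywhere")
  sea <- marine_cells(grid)
  env <- env_at_cells(grid, sea, names(truth$optima))
  s <- true_suitability(truth, env)
  w <- s * effort_bias[sea]
  if (all(w == 0)) stop("all sampling weights are zero")
  with_seed(seed, {
    pick <- sample(sea, n, replace = TRUE, prob = w)
    cc <- cell_coords(grid, pick)
    cs <- grid$cell_size
    lon <- cc$lon + stats::runif(n, -cs / 2, cs / 2)
    lat <- cc$lat + stats::runif(n, -cs / 2, cs / 2)
    ycls <- sample(c("recent", "old", "undated"), n, replace = TRUE,
                   prob = c(noise$p_recent, noise$p_old, noise$p_undated))
    year <- ifelse(ycls == "recent", sample(1990:2017, n, TRUE),
                   ifelse(ycls == "old", sample(1950:1989, n, TRUE), NA))
    rec <- data.frame(species = species, lon = lon, lat = lat,
                      year = as.integer(year), flag = "ok",
                      stringsAsFactors = FALSE)

    n_dup <- floor(noise$duplicate_fraction * n)
    if (n_dup > 0) rec <- rbind(rec, rec[sample(n, n_dup, TRUE), ])
    n_land <- floor(noise$land_fraction * n)
    if (n_land > 0) {
      land <- which(grid$layers$bathymetry >= 0)
      lc <- cell_coords(grid, sample(land, n_land, TRUE))
      rec <- rbind(rec, data.frame(species = species, lon = lc$lon, lat = lc$lat,
                                   year = sample(1990:2017, n_land, TRUE),
                                   flag = "ok", stringsAsFactors = FALSE))
    }
    n_unr <- floor(noise$unreliable_fraction * n)
    if (n_unr > 0) {
      ur <- rec[sample(n, n_unr, TRUE), ]
      ur$flag <- "unreliable"
      rec <- rbind(rec, ur)
    }
    rownames(rec) <- NULL
    rec
  })
}

#' Default per-decade warming deltas (degrees C)
#'
#' Domain-mean warming applied to mean temperatures per (RCP, decade),
#' monotone increasing across RCPs within each decade; the end-of-century
#' RCP8.5 value is 3.2 degrees C.
#'
#' @return data frame with columns `rcp`, `decade`, `delta`.
#' @export
default_deltas <- function() {
  expand <- expand.grid(rcp = c("2.6", "4.5", "8.5"),
                        decade = c("2030-2039", "2050-2059", "2090-2099"),
                        stringsAsFactors = FALSE)
  expand$delta <- c(0.6, 0.7, 0.9,   # 2030s
                    0.8, 1.2, 1.8,   # 2050s
                    0.9, 1.8, 3.2)   # 2090s
  expand
}

#' Emulate GCM scenario fields
#'
#' Each of `n_gcm` general circulation models is the observed climatology plus
#' a persistent per-cell model bias (smooth field + i.i.d. cell noise, frozen
#' per GCM) plus small transient noise; future fields additionally carry the
#' prescribed warming delta on mean temperature variables (`SBT`, `SST`).
#' `Log_PP` is perturbed multiplicatively and declines mildly with warming.
#' A "common period" field per GCM (bias + noise, no delta) is emitted for
#' bias correction. Salinity is not emulated: future `SSS` is held constant at
#' the contemporary field.
#'
#' @param grid an [env_grid] carrying the observed climatology.
#' @param bias_sd standard deviation (degrees C) of the per-GCM persistent bias.
#' @param deltas data frame `rcp`/`decade`/`delta`, monotone in RCP per decade.
#' @param noise_sd standard deviation of transient per-field noise.
#' @param variables variables to emulate.
#' @param n_gcm number of emulated GCMs.
#' @param seed integer seed.
#' @return object of class `scenario_set`: `fields[[gcm]][[rcp]][[decade]]`
#'   named lists of matrices, `common[[gcm]]`, the bias maps and the delta
#'   table.
#' @export
make_scenarios <- function(grid, bias_sd = 0.5, deltas = default_deltas(),
                           noise_sd = 0.1,
                           variables = c("SBT", "SBTr", "Log_PP"),
                           n_gcm = 5L, seed = 1L) {
  rcps <- sort(unique(deltas$rcp))
  decades <- sort(unique(deltas$decade))
  for (d in decades) {
    dd <- deltas$delta[match(paste(rcps, d), paste(deltas$rcp, deltas$decade))]
    if (anyNA(dd)) stop("missing decade in deltas: ", d)
    if (is.unsorted(dd)) stop("deltas must be monotone non-decreasing in RCP")
  }
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  mean_temp <- intersect(variables, c("SBT", "SST"))
  gcm_ids <- paste0("GCM", seq_len(n_gcm))

  bias <- list(); common <- list(); fields <- list()
  for (g in seq_len(n_gcm)) {
    bmaps <- list(); cfields <- list()
    for (v in variables) {
      b <- bias_sd * (0.7 * smooth_field(grid$lon, grid$lat,
                                         derive_seed(seed, paste0("bias", g, v))) +
                      0.3 * with_seed(derive_seed(seed, paste0("biasn", g, v)),
                                      matrix(stats::rnorm(nlat * nlon), nlat)))
      bmaps[[v]] <- b
      eps <- if (noise_sd > 0)
        with_seed(derive_seed(seed, paste0("cn", g, v)),
                  noise_sd * matrix(stats::rnorm(nlat * nlon), nlat)) else 0
      cfields[[v]] <- if (v == "Log_PP")
        grid$layers[[v]] + b + eps else grid$layers[[v]] + b + eps
    }
    bias[[gcm_ids[g]]] <- bmaps
    common[[gcm_ids[g]]] <- cfields

    per_rcp <- list()
    for (r in rcps) {
      per_dec <- list()
      for (d in decades) {
        delta <- deltas$delta[deltas$rcp == r & deltas$decade == d]
        fut <- list()
        for (v in variables) {
          eps <- if (noise_sd > 0)
            with_seed(derive_seed(seed, paste0("fn", g, r, d, v)),
                      noise_sd * matrix(stats::rnorm(nlat * nlon), nlat)) else 0
          base <- grid$layers[[v]] + bias[[gcm_ids[g]]][[v]] + eps
          fut[[v]] <- if (v %in% mean_temp) base + delta
            else if (v == "Log_PP") base + log(1 - 0.02 * delta)
            else base
        }
        per_dec[[d]] <- fut
      }
      per_rcp[[r]] <- per_dec
    }
    fields[[gcm_ids[g]]] <- per_rcp
  }
  structure(list(fields = fields, common = common, bias = bias,
                 deltas = deltas, variables = variables,
                 gcms = gcm_ids, rcps = rcps, decades = decades),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("scenario_set:", length(x$gcms), "GCMs x", length(x$rcps), "RCPs x",
      length(x$decades), "decades; variables:",
      paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic EEZ polygons and catch table
#'
#' Tiles the marine domain into `k` latitudinal Exclusive Economic Zones
#' (rectangular rings from the western edge to the coast) and draws a
#' log-normal mean-annual-catch table per (species, EEZ) whose lower tail
#' falls below the 1000 t display threshold.
#'
#' @param grid an [env_grid] (supplies the domain and the number of coastal
#'   segments available).
#' @param k number of EEZs (`>= 2`, at most the number of grid rows).
#' @param species character vector of species ids for the catch table.
#' @param seed integer seed.
#' @return list with `polygons` (named list of closed lon/lat rings) and
#'   `catch` (data frame `species`, `eez`, `catch_t`).
#' @export
make_eez_and_catch <- function(grid, k = 4L, species = "synthspecies", seed = 1L) {
  stopifnot(k >= 2)
  if (k > length(grid$lat)) stop("k exceeds available coastline segments")
  cs <- grid$cell_size
  lat_min <- min(grid$lat) - cs / 2; lat_max <- max(grid$lat) + cs / 2
  lon_min <- min(grid$lon) - cs / 2; lon_max <- max(grid$lon) + cs / 2
  bounds <- seq(lat_min, lat_max, length.out = k + 1)
  polygons <- lapply(seq_len(k), function(i) {
    data.frame(lon = c(lon_min, lon_max, lon_max, lon_min, lon_min),
               lat = c(bounds[i], bounds[i], bounds[i + 1], bounds[i + 1], bounds[i]))
  })
  names(polygons) <- paste0("EEZ", seq_len(k))
  catch <- with_seed(derive_seed(seed, "catch"), {
    g <- expand.grid(species = species, eez = names(polygons),
                     stringsAsFactors = FALSE)
    g$catch_t <- round(stats::rlnorm(nrow(g), meanlog = 7.5, sdlog = 1.6), 1)
    g
  })
  list(polygons = polygons, catch = catch)
}

#' Write polygons as GeoJSON
#'
#' @param polygons named list of closed lon/lat rings (data frames).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(names(polygons), function(nm) {
    ring <- lapply(seq_len(nrow(polygons[[nm]])), function(i)
      c(polygons[[nm]]$lon[i], polygons[[nm]]$lat[i]))
    list(type = "Feature", properties = list(id = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON file with Polygon features carrying an `id` property.
#' @return named list of closed lon/lat rings.
#' @export
read_polygons_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  out <- list()
  for (f in js$features) {
    ring <- f$geometry$coordinates[[1]]
    out[[f$properties$id]] <- data.frame(
      lon = vapply(ring, function(p) as.numeric(p[[1]]), 0),
      lat = vapply(ring, function(p) as.numeric(p[[2]]), 0))
  }
  out
}
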