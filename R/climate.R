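#' Bilinear regridding onto the analysis grid
#'
#' Interpolates a coarse field bilinearly at the target cell centres. Target
#' centres falling outside the coarse cell-centre hull (up to one coarse cell
#' beyond) take the nearest-neighbour value; beyond that the coverage is
#' considered insufficient and an error is raised.
#'
#' @param coarse list with `lon`, `lat` (centre vectors) and `field` (matrix
#'   `length(lat) x length(lon)`).
#' @param target an [env_grid].
#' @return matrix on the target grid.
#' @export
regrid_bilinear <- function(coarse, target) {
  dlon <- if (length(coarse$lon) > 1) diff(coarse$lon[1:2]) else Inf
  dlat <- if (length(coarse$lat) > 1) diff(coarse$lat[1:2]) else Inf
  if (min(target$lon) < min(coarse$lon) - dlon ||
      max(target$lon) > max(coarse$lon) + dlon ||
      min(target$lat) < min(coarse$lat) - dlat ||
      max(target$lat) > max(coarse$lat) + dlat)
    stop("target grid extends beyond coarse coverage by more than one coarse cell")
  pts <- expand.grid(lat = target$lat, lon = target$lon)
  xp <- clamp(pts$lon, min(coarse$lon), max(coarse$lon))
  yp <- clamp(pts$lat, min(coarse$lat), max(coarse$lat))
  z <- pracma::interp2(coarse$lon, coarse$lat, coarse$field, xp, yp,
                       method = "linear")
  matrix(z, nrow = length(target$lat))
}

#' Average yearly fields over a decade
#'
#' @param yearly named list of matrices, names = years (e.g. `"2030"`).
#' @param decade character `"first-last"` (e.g. `"2030-2039"`).
#' @return per-cell arithmetic mean over the decade's ten years.
#' @export
decade_average <- function(yearly, decade) {
  yrs <- as.integer(strsplit(decade, "-")[[1]])
  want <- as.character(seq(yrs[1], yrs[2]))
  missing <- setdiff(want, names(yearly))
  if (length(missing))
    stop("missing year(s): ", paste(missing, collapse = ", "))
  Reduce(`+`, yearly[want]) / length(want)
}

#' Taylor statistics between a model field and observations
#'
#' Pearson correlation, centered root-mean-square difference (means removed;
#' the Taylor-diagram convention), standard-deviation difference and mean
#' bias, computed over the cells of a common validity mask.
#'
#' @param model,obs numeric matrices on a common grid.
#' @param mask logical matrix of valid cells (default: finite in both).
#' @return list with `r`, `rmsd`, `sd_diff`, `bias`, `n`.
#' @export
taylor_stats <- function(model, obs, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(model) & is.finite(obs)
  m <- model[mask]; o <- obs[mask]
  if (length(m) < 3) stop("fewer than 3 common cells")
  ma <- m - mean(m); oa <- o - mean(o)
  list(r = stats::cor(m, o),
       rmsd = sqrt(mean((ma - oa)^2)),
       sd_diff = stats::sd(m) - stats::sd(o),
       bias = mean(m - o),
       n = length(m))
}

#' Per-cell delta bias correction
#'
#' Adjusts a future model field cell by cell by the observation-minus-model
#' difference over the common period:
#' `corrected = future + (obs_common - gcm_common)` (additive, temperature
#' variables) or `corrected = future * clamp(obs/gcm, ratio_bounds)`
#' (multiplicative). The corrected common-period field is identically the
#' observational field (r = 1, zero centered RMSD, equal SD) and the change
#' signal `future - common` is preserved exactly.
#'
#' @param gcm_common model field over the common period.
#' @param gcm_future model field for the target period.
#' @param obs_common observational climatology.
#' @param method `"additive"` or `"multiplicative"`.
#' @param ratio_bounds clamp for the multiplicative ratio.
#' @return corrected future field.
#' @export
bias_correct <- function(gcm_common, gcm_future, obs_common,
                         method = c("additive", "multiplicative"),
                         ratio_bounds = c(0.1, 10)) {
  method <- match.arg(method)
  if (!all(dim(gcm_common) == dim(obs_common)) ||
      !all(dim(gcm_future) == dim(gcm_common)))
    stop("field masks/dimensions do not match")
  if (method == "additive") {
    gcm_future + (obs_common - gcm_common)
  } else {
    gcm_future * clamp(obs_common / gcm_common, ratio_bounds[1], ratio_bounds[2])
  }
}

#' Bias-correct an emulated scenario set against the observed climatology
#'
#' Applies the per-cell delta correction to every (GCM, RCP, decade) field.
#' All emulated variables live on additive scales (`Log_PP` is already
#' logarithmic, so its additive correction is a clamped multiplicative ratio
#' on the raw production scale). Future `SSS`, when present among the model
#' covariates, is the contemporary field held constant.
#'
#' @param scen a [make_scenarios()] result.
#' @param grid the observed [env_grid].
#' @return a `scenario_set` with corrected future fields.
#' @export
correct_scenarios <- function(scen, grid) {
  out <- scen
  for (g in scen$gcms) {
    for (r in scen$rcps) {
      for (d in scen$decades) {
        for (v in scen$variables) {
          out$fields[[g]][[r]][[d]][[v]] <- bias_correct(
            scen$common[[g]][[v]],
            scen$fields[[g]][[r]][[d]][[v]],
            grid$layers[[v]])
        }
      }
    }
    for (v in scen$variables)
      out$common[[g]][[v]] <- bias_correct(scen$common[[g]][[v]],
                                           scen$common[[g]][[v]],
                                           grid$layers[[v]])
  }
  out$corrected <- TRUE
  out
}
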