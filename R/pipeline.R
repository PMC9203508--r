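#' Default pipeline configuration
#'
#' All tunable constants of the pipeline as a single nested list: grid
#' geometry, occurrence-cleaning thresholds, environmental-filter bin widths
#' (0.5 units per variable), hull trimming percentiles (2.5/97.5),
#' cross-validation settings (10 runs, 70/30), the CBI selection threshold
#' (0.5), the coastal buffer (50 km), suitable-area thresholds, warming
#' deltas, and the master seed. Values can be overridden by name via `...`.
#'
#' @param ... named overrides of top-level entries.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    species = "synthspecies",
    domain_bounds = c(0, 5, 35, 40),
    cell_size = 0.1,
    n_occurrences = 1000,
    priority = c("SBT", "SBTr", "Log_PP", "SBTvar", "SST", "SSTr", "SSTvar", "SSS"),
    r_max = 0.7,
    bin_width = 0.5,
    hull_percentiles = c(2.5, 97.5),
    depth_min = 0, depth_max = 1000, coast_buffer = 50,
    edge_distance = 100, outlier_distance = 1000,
    cv_runs = 10L, train_frac = 0.7,
    cbi_threshold = 0.5, curve_tolerance = 0.02,
    area_thresholds = c(0.3, 0.5, 0.7),
    bias_sd = 0.5, noise_sd = 0.1, n_gcm = 5L,
    deltas = default_deltas(),
    n_eez = 4L, min_catch = 1000,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

pipeline_stages <- c("synth", "prep", "envspace", "fit", "project", "eez")

#' Run the pipeline end to end
#'
#' Executes the stages in order — synthetic world generation, occurrence
#' preparation, environmental-space construction, ensemble fitting and
#' selection, scenario correction and projection, and EEZ aggregation —
#' writing versioned artifacts and a manifest (parameters, derived seed,
#' input hashes) per stage under `out_dir`. Stages not requested are loaded
#' from their cached artifacts; a missing upstream artifact is an error
#' naming the stage to rerun. Identical configurations yield bit-identical
#' manifests.
#'
#' @param config a [default_config()] list.
#' @param stages subset of `c("synth","prep","envspace","fit","project","eez")`
#'   or `"all"`.
#' @param out_dir run directory.
#' @param quiet suppress progress messages.
#' @return the run directory, invisibly; artifacts and `manifest.json` files
#'   are written per stage.
#' @export
run_pipeline <- function(config = default_config(), stages = "all",
                         out_dir = tempfile("nichecast_run_"), quiet = FALSE) {
  if (identical(stages, "all")) stages <- pipeline_stages
  stopifnot(all(stages %in% pipeline_stages))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[nichecast] ", ...)
  state <- new.env(parent = emptyenv())

  art <- function(stage, name) file.path(out_dir, paste0(stage, "_", name))
  need <- function(stage, obj_name, loader) {
    if (!is.null(state[[obj_name]])) return(state[[obj_name]])
    v <- tryCatch(suppressWarnings(loader()), error = function(e)
      stop("missing upstream artifact for stage '", stage,
           "'; rerun stage '", stage, "' (", conditionMessage(e), ")"))
    state[[obj_name]] <- v
    v
  }
  manifest <- function(stage, params, files) {
    m <- list(stage = stage, params = params,
              seed = derive_seed(config$seed, stage),
              files = lapply(files, function(f)
                list(name = basename(f), md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(m, file.path(out_dir, paste0(stage, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- synth ------------------------------------------------------------
  if ("synth" %in% stages) {
    say("synth: generating world")
    seed <- derive_seed(config$seed, "synth")
    grid <- make_env_grid(config$domain_bounds, config$cell_size, seed)
    truth <- niche_truth()
    occ <- sample_occurrences(grid, truth, n = config$n_occurrences,
                              seed = seed, species = config$species)
    scen <- make_scenarios(grid, bias_sd = config$bias_sd,
                           deltas = config$deltas, noise_sd = config$noise_sd,
                           n_gcm = config$n_gcm, seed = seed)
    ez <- make_eez_and_catch(grid, k = config$n_eez,
                             species = config$species, seed = seed)
    write_grid_csv(grid, art("synth", "grid.csv"))
    utils::write.csv(occ, art("synth", "occurrences.csv"), row.names = FALSE)
    write_polygons_geojson(ez$polygons, art("synth", "eez.geojson"))
    utils::write.csv(ez$catch, art("synth", "catch.csv"), row.names = FALSE)
    saveRDS(scen, art("synth", "scenarios.rds"))
    saveRDS(truth, art("synth", "truth.rds"))
    state$grid <- grid; state$occ <- occ; state$scen <- scen
    state$eez <- ez; state$truth <- truth
    manifest("synth", config[c("domain_bounds", "cell_size", "n_occurrences",
                               "bias_sd", "noise_sd", "n_gcm", "n_eez")],
             list(art("synth", "grid.csv"), art("synth", "occurrences.csv"),
                  art("synth", "eez.geojson"), art("synth", "catch.csv")))
  }
  wants <- function(...) any(c(...) %in% stages)
  if (!wants("prep", "envspace", "fit", "project", "eez"))
    return(invisible(out_dir))
  grid <- need("synth", "grid", function() read_grid_csv(art("synth", "grid.csv")))
  occ <- if (wants("prep"))
    need("synth", "occ", function() utils::read.csv(art("synth", "occurrences.csv")))

  # -- prep -------------------------------------------------------------
  if ("prep" %in% stages) {
    say("prep: cleaning and gridding occurrences")
    rules <- prep_rules(config$edge_distance, config$outlier_distance)
    cleaned <- clean_occurrences(occ, grid, rules)
    presences <- grid_occurrences(cleaned, grid)
    utils::write.csv(as.data.frame(presences), art("prep", "presences.csv"),
                     row.names = FALSE)
    state$presences <- presences
    manifest("prep", config[c("edge_distance", "outlier_distance")],
             list(art("prep", "presences.csv")))
  }
  if (!wants("envspace", "fit", "project", "eez"))
    return(invisible(out_dir))
  presences <- if (wants("envspace"))
    need("prep", "presences", function() {
      p <- utils::read.csv(art("prep", "presences.csv"))
      class(p) <- c("occurrence_set", "data.frame"); p
    })

  # -- envspace ---------------------------------------------------------
  if ("envspace" %in% stages) {
    say("envspace: variable selection, thinning, hull, pseudo-absences")
    seed <- derive_seed(config$seed, "envspace")
    depth <- depth_range(config$depth_min, config$depth_max, config$coast_buffer)
    mask <- apply_depth_coast_filter(depth, grid)
    pres_env <- env_at_cells(grid, presences$cell_id, config$priority)
    vars <- select_uncorrelated_variables(pres_env[config$priority],
                                          config$priority, config$r_max)
    filtered <- environmental_filter(presences, grid, vars,
      stats::setNames(rep(config$bin_width, length(vars)), vars))
    hull <- build_trimmed_hull(as.data.frame(filtered)[vars],
                               config$hull_percentiles[1],
                               config$hull_percentiles[2])
    dom_cells <- which(mask)
    domain <- cbind(cell_coords(grid, dom_cells)[c("cell_id", "lon", "lat")],
                    env_at_cells(grid, dom_cells, vars)[vars])
    pa <- sample_pseudo_absences(hull, nrow(filtered), domain, seed)
    table <- make_pa_table(filtered, pa, vars)
    utils::write.csv(table, art("envspace", "pa_table.csv"), row.names = FALSE)
    writeLines(vars, art("envspace", "variables.txt"))
    state$pa_table <- table; state$mask <- mask; state$variables <- vars
    manifest("envspace", config[c("priority", "r_max", "bin_width",
                                  "hull_percentiles", "depth_min", "depth_max",
                                  "coast_buffer")],
             list(art("envspace", "pa_table.csv"), art("envspace", "variables.txt")))
  }
  if (!wants("fit", "project", "eez"))
    return(invisible(out_dir))
  pa_table <- if (wants("fit"))
    need("envspace", "pa_table", function() {
    t <- utils::read.csv(art("envspace", "pa_table.csv"))
      attr(t, "variables") <- readLines(art("envspace", "variables.txt"))
      class(t) <- c("pa_table", "data.frame"); t
    })
  mask <- need("envspace", "mask", function() {
    depth <- depth_range(config$depth_min, config$depth_max, config$coast_buffer)
    apply_depth_coast_filter(depth, grid)
  })

  # -- fit --------------------------------------------------------------
  if ("fit" %in% stages) {
    say("fit: cross-validated ensemble + selection")
    fit <- esm(pa_table, runs = config$cv_runs, train_frac = config$train_frac,
               cbi_threshold = config$cbi_threshold,
               curve_tolerance = config$curve_tolerance,
               seed = derive_seed(config$seed, "fit"))
    saveRDS(fit, art("fit", "esm.rds"))
    cbi_df <- data.frame(algorithm = rownames(fit$cbi), fit$cbi,
                         mean_cbi = fit$selection$mean_cbi,
                         retained = rownames(fit$cbi) %in% fit$selection$retained)
    utils::write.csv(cbi_df, art("fit", "cbi.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(retained = fit$selection$retained,
           mean_cbi = as.list(fit$selection$mean_cbi),
           curves_ok = as.list(fit$curves_ok),
           threshold = config$cbi_threshold),
      art("fit", "selection.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    state$fit <- fit
    manifest("fit", config[c("cv_runs", "train_frac", "cbi_threshold",
                             "curve_tolerance")],
             list(art("fit", "cbi.csv"), art("fit", "selection.json")))
  }
  if (!wants("project", "eez"))
    return(invisible(out_dir))
  fit <- need("fit", "fit", function() readRDS(art("fit", "esm.rds")))

  # -- project ----------------------------------------------------------
  if ("project" %in% stages) {
    say("project: scenario correction + ESI maps + range change")
    scen <- need("synth", "scen", function() readRDS(art("synth", "scenarios.rds")))
    corrected <- correct_scenarios(scen, grid)
    contemp <- project_ensemble(fit, grid, mask)
    rc <- range_change_table(fit, grid, corrected, mask, config$area_thresholds)
    utils::write.csv(rc, art("project", "range_change.csv"), row.names = FALSE)
    esi_df <- as.data.frame(grid)[c("cell_id", "lon", "lat")]
    esi_df$esi <- as.vector(contemp$esi); esi_df$sd <- as.vector(contemp$sd)
    utils::write.csv(esi_df, art("project", "contemporary_esi.csv"),
                     row.names = FALSE)
    state$corrected <- corrected; state$contemp <- contemp; state$range <- rc
    manifest("project", config["area_thresholds"],
             list(art("project", "range_change.csv"),
                  art("project", "contemporary_esi.csv")))
  }

  # -- eez --------------------------------------------------------------
  if ("eez" %in% stages) {
    say("eez: aggregation + catch join")
    ezp <- need("synth", "eez", function()
      list(polygons = read_polygons_geojson(art("synth", "eez.geojson")),
           catch = utils::read.csv(art("synth", "catch.csv"))))
    corrected <- state$corrected %||%
      correct_scenarios(need("synth", "scen", function()
        readRDS(art("synth", "scenarios.rds"))), grid)
    last_rcp <- max(corrected$rcps); last_dec <- max(corrected$decades)
    ch <- eez_change(fit, grid, corrected, ezp$polygons, last_rcp, last_dec, mask)
    ch <- attach_catch(ch, ezp$catch, config$species, config$min_catch)
    utils::write.csv(ch, art("eez", "eez_summary.csv"), row.names = FALSE)
    manifest("eez", config[c("n_eez", "min_catch")],
             list(art("eez", "eez_summary.csv")))
  }
  say("done: ", out_dir)
  invisible(out_dir)
}

validate_config <- function(cfg) {
  req <- names(default_config())
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config is missing entries: ", paste(miss, collapse = ", "))
  stopifnot(cfg$cell_size > 0, cfg$cv_runs >= 1,
            cfg$train_frac > 0, cfg$train_frac < 1,
            cfg$bin_width > 0, length(cfg$hull_percentiles) == 2)
  invisible(TRUE)
}
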