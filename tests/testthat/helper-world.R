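# Shared synthetic-world fixtures, built once per session and cached.

.world_cache <- new.env(parent = emptyenv())

# Full default world through the environmental-space stage.
test_world <- function(seed = 7) {
  key <- paste0("world", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  grid <- make_env_grid(seed = seed)
  truth <- niche_truth()
  occ <- sample_occurrences(grid, truth, n = 1000, seed = seed)
  pres <- grid_occurrences(clean_occurrences(occ, grid), grid)
  vars <- c("SBT", "SBTr", "Log_PP")
  filt <- environmental_filter(pres, grid, vars)
  hull <- build_trimmed_hull(as.data.frame(filt)[vars])
  mask <- apply_depth_coast_filter(depth_range(), grid)
  cells <- which(mask)
  domain <- cbind(nichecast:::cell_coords(grid, cells)[c("cell_id", "lon", "lat")],
                  nichecast:::env_at_cells(grid, cells, vars)[vars])
  pa <- sample_pseudo_absences(hull, nrow(filt), domain, seed = seed)
  tab <- make_pa_table(filt, pa, vars)
  w <- list(grid = grid, truth = truth, occ = occ, presences = pres,
            variables = vars, filtered = filt, hull = hull, mask = mask,
            domain = domain, pa = pa, table = tab, seed = seed)
  .world_cache[[key]] <- w
  w
}

# Cross-validated ensemble fit on the default world (the expensive fixture).
test_fit <- function(seed = 7) {
  key <- paste0("fit", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  w <- test_world(seed)
  f <- esm(w$table, runs = 10, seed = seed)
  .world_cache[[key]] <- f
  f
}

# Small linearly separable toy table: presences cold, absences warm.
toy_pa_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  pres <- data.frame(label = 1L, cell_id = seq_len(n), lon = 0, lat = 0,
                     SBT = rnorm(n, 15, 0.5), SBTr = rnorm(n, 5, 0.5),
                     Log_PP = rnorm(n, 1, 0.3))
  abs_ <- data.frame(label = 0L, cell_id = n + seq_len(n), lon = 0, lat = 0,
                     SBT = rnorm(n, 25, 0.5), SBTr = rnorm(n, 5, 0.5),
                     Log_PP = rnorm(n, 1, 0.3))
  out <- rbind(pres, abs_)
  attr(out, "variables") <- c("SBT", "SBTr", "Log_PP")
  class(out) <- c("pa_table", "data.frame")
  out
}
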