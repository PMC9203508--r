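test_that("environmental grid has the stated geometry and structure", {
  grid <- make_env_grid(c(0, 10, 30, 40), cell_size = 0.1, seed = 3)
  expect_equal(length(grid$lon), 100)
  expect_equal(length(grid$lat), 100)
  expect_equal(dim(grid$layers$SBT), c(100, 100))

  # determinism
  grid2 <- make_env_grid(c(0, 10, 30, 40), cell_size = 0.1, seed = 3)
  expect_identical(grid, grid2)
  grid3 <- make_env_grid(c(0, 10, 30, 40), cell_size = 0.1, seed = 4)
  expect_false(identical(grid$layers$SBT, grid3$layers$SBT))

  # SBT decreases poleward: equatorward edge warmer than poleward edge
  expect_gt(mean(grid$layers$SBT[1, ]), mean(grid$layers$SBT[100, ]))
  # and monotone in the latitudinal mean profile (lapse dominates texture)
  prof <- rowMeans(grid$layers$SBT)
  expect_true(all(diff(prof) < 0))

  # SBTr peaks at mid latitudes
  rprof <- rowMeans(grid$layers$SBTr)
  expect_gt(which.max(rprof), 25)
  expect_lt(which.max(rprof), 75)

  expect_true(any(grid$layers$bathymetry < 0))
  expect_true(all(grid$layers$dcoast >= 0))
  # sea cells are below sea level, land cells at dcoast 0
  expect_true(all(grid$layers$dcoast[grid$layers$bathymetry >= 0] == 0))

  expect_error(make_env_grid(cell_size = 0), "positive")
  expect_error(make_env_grid(c(0, 5, 35, 40.03), cell_size = 0.1), "divide")
})

test_that("true suitability is a bounded product of Gaussians", {
  tr <- niche_truth()
  env <- data.frame(SBT = seq(10, 25, 0.5), SBTr = 5, Log_PP = 0.8)
  s <- true_suitability(tr, env)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1, tolerance = 1e-6)  # passes through the optimum
  # monotone decline moving away from the optimum along one axis
  up <- s[env$SBT >= 17]
  expect_true(all(diff(up) < 0))
  dn <- s[env$SBT <= 17]
  expect_true(all(diff(dn) > 0))
  expect_error(niche_truth(tolerances = c(SBT = -1, SBTr = 1, Log_PP = 1)))
})

test_that("occurrence sampler follows suitability-times-effort weights", {
  grid <- make_env_grid(seed = 11)
  # flat niche + uniform effort: occupancy approximately uniform over sea
  flat <- niche_truth(tolerances = c(SBT = 1e6, SBTr = 1e6, Log_PP = 1e6))
  uniform_effort <- matrix(1, length(grid$lat), length(grid$lon))
  occ <- sample_occurrences(grid, flat, n = 2000, effort_bias = uniform_effort,
                            noise = noise_spec(0, 0, 0), seed = 2)
  sea <- nichecast:::marine_cells(grid)
  counts <- table(factor(nichecast:::locate_cells(grid, occ$lon, occ$lat),
                         levels = sea))
  gof <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)

  # zero-suitability cells receive no presences
  tr <- niche_truth()
  occ2 <- sample_occurrences(grid, tr, n = 1000, noise = noise_spec(0, 0, 0),
                             seed = 3)
  env2 <- nichecast:::env_at_cells(
    grid, nichecast:::locate_cells(grid, occ2$lon, occ2$lat),
    names(tr$optima))
  expect_true(all(true_suitability(tr, env2) > 0))

  # duplicate injection count
  occ3 <- sample_occurrences(grid, tr, n = 1000,
                             noise = noise_spec(duplicate_fraction = 0.1,
                                                land_fraction = 0,
                                                unreliable_fraction = 0),
                             seed = 4)
  expect_equal(nrow(occ3), 1100)
  expect_equal(sum(duplicated(occ3[c("lon", "lat", "year")])), 100)

  # determinism and error contracts
  expect_identical(sample_occurrences(grid, tr, n = 100, seed = 5),
                   sample_occurrences(grid, tr, n = 100, seed = 5))
  expect_error(sample_occurrences(grid, tr, n = 100,
                                  effort_bias = uniform_effort * 0),
               "zero")
  expect_error(sample_occurrences(grid, tr, n = 100,
                                  effort_bias = -uniform_effort),
               "non-negative")
})

test_that("year classes of sampled records mirror the database proportions", {
  grid <- make_env_grid(seed = 11)
  occ <- sample_occurrences(grid, niche_truth(), n = 5000,
                            noise = noise_spec(0, 0, 0), seed = 6)
  p_recent <- mean(!is.na(occ$year) & occ$year >= 1990)
  p_old <- mean(!is.na(occ$year) & occ$year < 1990)
  p_undated <- mean(is.na(occ$year))
  expect_equal(p_recent, 0.73, tolerance = 0.05)
  expect_equal(p_old, 0.11, tolerance = 0.3)
  expect_equal(p_undated, 0.16, tolerance = 0.2)
})

test_that("scenario emulation carries bias, delta and the common period", {
  grid <- make_env_grid(seed = 9)
  # noiseless, biasless, delta-free: common period equals observations
  d0 <- default_deltas(); d0$delta <- 0
  sc0 <- make_scenarios(grid, bias_sd = 0, deltas = d0, noise_sd = 0, seed = 1)
  expect_equal(sc0$common$GCM1$SBT, grid$layers$SBT)
  expect_equal(sc0$fields$GCM1$`2.6`$`2030-2039`$SBT, grid$layers$SBT)

  sc <- make_scenarios(grid, seed = 2)
  # bookkeeping: 5 GCMs x 3 RCPs x 3 decades = 45 fields per variable
  n_fields <- sum(vapply(sc$fields, function(g)
    sum(vapply(g, length, 0L)), 0L))
  expect_equal(n_fields, 45)

  # end-of-century RCP8.5 delta: domain-mean SBT difference ~ +3.2 C
  dmean <- mean(sc$fields$GCM1$`8.5`$`2090-2099`$SBT - grid$layers$SBT)
  expect_equal(dmean, 3.2, tolerance = 0.15)

  # warming monotone in RCP for every GCM and decade (after correction)
  cc <- correct_scenarios(sc, grid)
  for (g in cc$gcms) for (d in cc$decades) {
    m <- vapply(cc$rcps, function(r) mean(cc$fields[[g]][[r]][[d]]$SBT), 0)
    expect_true(all(diff(m) >= 0))
  }

  expect_error(make_scenarios(grid, deltas = default_deltas()[1:5, ]),
               "missing decade|monotone")
  bad <- default_deltas()
  bad$delta[bad$rcp == "8.5"] <- 0  # high scenario cooler than low
  expect_error(make_scenarios(grid, deltas = bad), "monotone")
})

test_that("EEZ polygons tile the marine domain and the catch table is usable", {
  grid <- make_env_grid(seed = 9)
  ez <- make_eez_and_catch(grid, k = 4, seed = 1)
  expect_length(ez$polygons, 4)

  sea <- nichecast:::marine_cells(grid)
  cc <- nichecast:::cell_coords(grid, sea)
  membership <- vapply(ez$polygons, function(p)
    nichecast:::point_in_polygon(cc$lon, cc$lat, p), logical(length(sea)))
  # each marine cell belongs to at most one polygon, coverage >= 95%
  expect_true(all(rowSums(membership) <= 1))
  expect_gte(mean(rowSums(membership) > 0), 0.95)

  expect_equal(nrow(ez$catch), 4)
  expect_true(all(ez$catch$catch_t >= 0))
  expect_error(make_eez_and_catch(grid, k = 1), "k >= 2")
  expect_error(make_eez_and_catch(grid, k = 500), "coastline")

  # GeoJSON round trip preserves the rings
  path <- tempfile(fileext = ".geojson")
  write_polygons_geojson(ez$polygons, path)
  back <- read_polygons_geojson(path)
  expect_equal(back, ez$polygons)
})
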