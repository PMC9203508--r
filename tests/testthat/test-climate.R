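target_grid <- make_env_grid(c(0, 2, 35, 37), cell_size = 0.1, seed = 2)

test_that("bilinear regridding reproduces linear fields exactly", {
  coarse <- list(lon = seq(-0.5, 2.5, 0.5), lat = seq(34.5, 37.5, 0.5))
  # constant field
  coarse$field <- matrix(4.2, length(coarse$lat), length(coarse$lon))
  out <- regrid_bilinear(coarse, target_grid)
  expect_equal(out, matrix(4.2, 20, 20))
  # field linear in lon and lat is reproduced at every target centre
  coarse$field <- outer(coarse$lat, coarse$lon,
                        function(la, lo) 2 * lo - 3 * la + 1)
  out <- regrid_bilinear(coarse, target_grid)
  truth <- outer(target_grid$lat, target_grid$lon,
                 function(la, lo) 2 * lo - 3 * la + 1)
  expect_equal(out, truth, tolerance = 1e-10)
  # convex-combination property on random fields
  set.seed(8)
  coarse$field <- matrix(rnorm(length(coarse$lat) * length(coarse$lon)),
                         length(coarse$lat))
  out <- regrid_bilinear(coarse, target_grid)
  expect_gte(min(out), min(coarse$field))
  expect_lte(max(out), max(coarse$field))
  # coverage error
  tiny <- list(lon = c(5, 6), lat = c(50, 51),
               field = matrix(1, 2, 2))
  expect_error(regrid_bilinear(tiny, target_grid), "coverage")
})

test_that("decade averaging is the per-cell mean of the ten years", {
  f <- matrix(2, 2, 2)
  yearly <- setNames(rep(list(f), 10), as.character(2030:2039))
  expect_equal(decade_average(yearly, "2030-2039"), f)
  # linear trend: the mean equals the value at the temporal midpoint
  yearly <- setNames(lapply(0:9, function(k) f + k), as.character(2030:2039))
  expect_equal(decade_average(yearly, "2030-2039"), f + 4.5)
  expect_error(decade_average(yearly[1:9], "2030-2039"), "2039")
})

test_that("Taylor statistics reproduce their closed forms", {
  set.seed(3)
  obs <- matrix(rnorm(100, 15, 2), 10)
  same <- taylor_stats(obs, obs)
  expect_equal(same$r, 1)
  expect_equal(same$rmsd, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$bias, 0)
  # constant offset: perfect pattern agreement, pure bias
  shifted <- taylor_stats(obs + 2, obs)
  expect_equal(shifted$r, 1)
  expect_equal(shifted$rmsd, 0, tolerance = 1e-12)
  expect_equal(shifted$bias, 2)
  # doubling a zero-mean field doubles the SD
  z <- obs - mean(obs)
  scaled <- taylor_stats(2 * z, z)
  expect_equal(scaled$sd_diff, sd(z))
  expect_error(taylor_stats(obs[1:2], obs[1:2]), "3 common cells")
})

test_that("delta correction is exact on the common period and preserves change", {
  gcm_common <- matrix(16, 3, 3); obs <- matrix(15, 3, 3)
  gcm_future <- matrix(18, 3, 3)
  corr <- bias_correct(gcm_common, gcm_future, obs)
  expect_equal(corr, matrix(17, 3, 3))
  # corrected common period is identically the observations
  set.seed(4)
  obs <- matrix(rnorm(400, 15, 2), 20)
  gcm <- obs + matrix(rnorm(400, 1, 0.5), 20)      # bias + noise
  cc <- bias_correct(gcm, gcm, obs)
  expect_lt(max(abs(cc - obs)), 1e-10)
  ts <- taylor_stats(cc, obs)
  expect_equal(ts$r, 1)
  expect_equal(ts$rmsd, 0)
  expect_equal(ts$sd_diff, 0)
  # change signal preserved: corrected_future - obs == gcm_future - gcm_common
  fut <- gcm + 3
  expect_equal(bias_correct(gcm, fut, obs) - obs, fut - gcm)
  expect_error(bias_correct(gcm, fut, obs[1:2, 1:2]), "match")
  # multiplicative variant clamps the ratio
  r <- bias_correct(matrix(1e-9, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2),
                    method = "multiplicative")
  expect_true(all(r <= 10))
})

test_that("averaging commutes with additive bias correction", {
  set.seed(5)
  obs <- matrix(rnorm(100), 10)
  gcm_common <- obs + 0.5
  yearly <- setNames(lapply(1:10, function(k)
    obs + 0.5 + 0.1 * k + matrix(rnorm(100, 0, 0.01), 10)),
    as.character(2090:2099))
  corr_then_avg <- decade_average(
    lapply(yearly, function(f) bias_correct(gcm_common, f, obs)),
    "2090-2099")
  avg_then_corr <- bias_correct(gcm_common,
                                decade_average(yearly, "2090-2099"), obs)
  expect_equal(corr_then_avg, avg_then_corr, tolerance = 1e-12)
})

test_that("future salinity is the contemporary field held constant", {
  w <- test_world()
  scen <- make_scenarios(w$grid, seed = 1)
  fit <- test_fit()
  corrected <- correct_scenarios(scen, w$grid)
  # projection builds SSS (absent from scenario fields) from the grid itself
  cells <- which(w$mask)
  fields <- corrected$fields$GCM1$`8.5`$`2090-2099`
  expect_false("SSS" %in% names(fields))
  e <- data.frame(cell_id = cells)
  for (v in c(fit$variables, "SSS"))
    e[[v]] <- if (v %in% names(fields)) fields[[v]][cells]
      else w$grid$layers[[v]][cells]
  expect_identical(e$SSS, w$grid$layers$SSS[cells])
})
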