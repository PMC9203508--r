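test_that("CBI calibration: informative, null and reversed predictions", {
  cbis <- sapply(1:20, function(s) {
    e <- cbi_experiment(1000, seed = s, mode = "true")
    continuous_boyce_index(e$p, e$bg)
  })
  expect_true(all(cbis >= 0.9))

  nulls <- sapply(1:20, function(s) {
    e <- cbi_experiment(1000, seed = s, mode = "random")
    continuous_boyce_index(e$p, e$bg)
  })
  expect_lt(mean(abs(nulls)), 0.3)
  expect_lt(abs(mean(nulls)), 0.2)

  revs <- sapply(1:20, function(s) {
    e <- cbi_experiment(1000, seed = s, mode = "reversed")
    continuous_boyce_index(e$p, e$bg)
  })
  expect_true(all(revs <= -0.9))
})

test_that("CBI is a rank statistic: invariant to monotone transforms", {
  e <- cbi_experiment(1000, seed = 3, mode = "true")
  base <- continuous_boyce_index(e$p, e$bg)
  # strictly monotone maps of [0,1] onto [0,1]; invariance is exact in the
  # continuum limit and holds up to window discretisation in practice
  for (squash in list(sqrt, function(x) x^1.5)) {
    shifted <- continuous_boyce_index(squash(e$p), squash(e$bg))
    expect_lt(abs(shifted - base), 0.05)
  }
  expect_true(base >= -1 && base <= 1)
})

test_that("CBI edge cases are handled explicitly", {
  expect_warning(v <- continuous_boyce_index(runif(50), rep(0.5, 50)),
                 "identical")
  expect_true(is.na(v))
  expect_error(continuous_boyce_index(numeric(0), runif(10)))
  expect_error(continuous_boyce_index(c(0.5, 1.2), runif(10)))
})

test_that("cross-validation splits are disjoint 70/30 partitions", {
  splits <- cv_splits(1000, runs = 10, seed = 4)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$train, 700)
    expect_length(sp$eval, 300)
    expect_length(intersect(sp$train, sp$eval), 0)
    expect_setequal(union(sp$train, sp$eval), 1:1000)
  }
  # different runs use different partitions
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))
  # different seeds differ
  expect_false(identical(cv_splits(1000, 1, seed = 1)[[1]]$train,
                         cv_splits(1000, 1, seed = 2)[[1]]$train))
  expect_error(cv_splits(10), "too small")
})

test_that("curve screening accepts unimodal/monotone and rejects bimodal", {
  x <- seq(0, 1, length.out = 100)
  gauss <- data.frame(value = x, esi = exp(-(x - 0.5)^2 / 0.02))
  expect_true(plausible_curve(gauss))
  mono <- data.frame(value = x, esi = x)
  expect_true(plausible_curve(mono))
  flat <- data.frame(value = x, esi = rep(0.4, 100))
  expect_true(plausible_curve(flat))
  bimodal <- data.frame(value = x,
                        esi = 0.8 * exp(-(x - 0.25)^2 / 0.005) +
                              0.7 * exp(-(x - 0.75)^2 / 0.005))
  expect_false(plausible_curve(bimodal))
  # sub-tolerance wiggles on a unimodal curve do not trigger rejection
  set.seed(1)
  wiggly <- data.frame(value = x,
                       esi = pmin(1, pmax(0, exp(-(x - 0.5)^2 / 0.02) +
                                               runif(100, 0, 0.005))))
  expect_true(plausible_curve(wiggly))
})

test_that("selection requires both the CBI threshold and plausible curves", {
  cbi <- c(NPPEN = 0.82, GLM = 0.45, GAM = 0.9, RF = 0.7)
  curves <- c(NPPEN = TRUE, GLM = TRUE, GAM = FALSE, RF = TRUE)
  rep <- select_algorithms(cbi, curves)
  expect_setequal(rep$retained, c("NPPEN", "RF"))  # 0.45 out, bimodal GAM out

  # monotone: raising a CBI never removes an algorithm
  cbi2 <- cbi; cbi2["GLM"] <- 0.6
  rep2 <- select_algorithms(cbi2, curves)
  expect_true(all(rep$retained %in% rep2$retained))

  expect_error(select_algorithms(c(a = 0.1), c(a = TRUE)), "no algorithm")
})

test_that("member SD is the population SD with its closed-form cases", {
  m1 <- matrix(0.2, 3, 3); m2 <- matrix(0.6, 3, 3)
  expect_equal(member_sd(list(m1, m2)), matrix(0.2, 3, 3))
  expect_equal(member_sd(list(m1, m1, m1)), matrix(0, 3, 3))
  # Popoviciu bound for [0,1]-valued members
  set.seed(2)
  ms <- lapply(1:5, function(i) matrix(runif(9), 3))
  expect_true(all(member_sd(ms) <= 0.5))
  expect_error(member_sd(list(m1)), "2")
  expect_error(member_sd(list(m1, matrix(0.1, 2, 2))), "common grid")
})
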