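test_that("correlation pruning keeps one variable per correlated cluster", {
  set.seed(3)
  n <- 200
  base <- rnorm(n)
  make_corr <- function(r) r * base + sqrt(1 - r^2) * rnorm(n)
  env <- data.frame(SBTr = base, SBTvar = make_corr(0.8),
                    Log_PP = rnorm(n))
  kept <- select_uncorrelated_variables(env, c("SBTr", "SBTvar", "Log_PP"))
  expect_equal(kept, c("SBTr", "Log_PP"))  # higher-priority of the r=0.8 pair

  # all pairwise below threshold: all kept
  env2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(select_uncorrelated_variables(env2, c("a", "b", "c")),
               c("a", "b", "c"))

  # three mutually correlated variables: exactly one survives
  env3 <- data.frame(a = base, b = make_corr(0.95), c = make_corr(0.93))
  env3$b <- 0.95 * base + sqrt(1 - 0.95^2) * (0.9 * rnorm(n))
  env3$c <- 0.95 * base + sqrt(1 - 0.95^2) * (0.9 * rnorm(n))
  expect_true(all(abs(cor(env3)[upper.tri(diag(3))]) > 0.7))
  expect_equal(select_uncorrelated_variables(env3, c("a", "b", "c")), "a")

  expect_warning(
    kept4 <- select_uncorrelated_variables(cbind(env2, k = 1), c("k", "a", "b", "c")),
    "constant")
  expect_false("k" %in% kept4)
})

test_that("environmental filtering keeps one presence per occupied bin", {
  w <- test_world()
  # constructed case: 10 points in 3 bins of width 0.5
  g <- env_grid(lon = seq(0.05, 0.95, 0.1), lat = 40.05,
                layers = list(SBT = matrix(c(14.1, 14.3, 14.4, 14.6, 14.9,
                                             15.1, 15.3, 14.2, 14.35, 14.45), 1),
                              bathymetry = matrix(-100, 1, 10),
                              dcoast = matrix(1, 1, 10)),
                cell_size = 0.1)
  pres <- grid_occurrences(
    data.frame(species = "sp", lon = seq(0.05, 0.95, 0.1), lat = 40.05,
               year = c(2001:2005, 2001:2003, 2010, 2011)), g)
  filt <- environmental_filter(pres, g, "SBT")
  # bins [14,14.5), [14.5,15), [15,15.5) -> 3 retained
  expect_equal(nrow(filt), 3)
  # deterministic pick: most recent year within each bin
  expect_setequal(filt$last_year, c(2011L, 2005L, 2002L))

  # idempotence and determinism on the full world
  again <- environmental_filter(w$filtered, w$grid, w$variables)
  expect_equal(as.data.frame(again)[names(again) != "env_bin"],
               as.data.frame(w$filtered)[names(w$filtered) != "env_bin"])
  # each occupied bin appears exactly once
  expect_false(any(duplicated(w$filtered$env_bin)))
})

test_that("percentile trimming removes extremes before hull construction", {
  sq <- data.frame(x = c(0, 1, 0, 1, 0.5), y = c(0, 0, 1, 1, 0.5))
  h <- build_trimmed_hull(sq, 0, 100)  # no trimming
  expect_true(all(in_hull(h, sq)))
  expect_true(in_hull(h, data.frame(x = 0.5, y = 0.5)))
  expect_false(in_hull(h, data.frame(x = 1.2, y = 0.5)))
  expect_false(in_hull(h, data.frame(x = -0.01, y = 0.5)))

  # a wild outlier is excluded by the 97.5 percentile trim
  set.seed(5)
  pts <- data.frame(x = rnorm(100), y = rnorm(100))
  outlier <- data.frame(x = 10 * diff(range(pts$x)), y = 0)
  h_clean <- build_trimmed_hull(pts)
  h_noisy <- build_trimmed_hull(rbind(pts, outlier))
  expect_false(in_hull(h_noisy, outlier))
  # the trimmed hull never reaches past the clean data's extent
  expect_lte(max(h_noisy$vertices[, "x"]), max(pts$x))
  probe <- data.frame(x = c(0, 0.5, 15, 25), y = 0.2)
  expect_equal(in_hull(h_noisy, probe), c(TRUE, TRUE, FALSE, FALSE))

  # trimming contracts: every trimmed-hull vertex is in the untrimmed hull
  h_full <- build_trimmed_hull(pts, 0, 100)
  expect_true(all(in_hull(h_full, h_clean$vertices)))

  # degenerate (collinear 2-D) set falls back to bounding box with warning
  line <- data.frame(x = 1:10, y = 2 * (1:10))
  expect_warning(hd <- build_trimmed_hull(line, 0, 100), "degenerate")
  expect_true(in_hull(hd, data.frame(x = 5, y = 10)))

  expect_error(build_trimmed_hull(sq[1:2, ], 0, 100), "d\\+1|points")
})

test_that("hull membership agrees with barycentric geometry in 3-D", {
  # random tetrahedron-cloud: membership must equal feasibility of the
  # convex-combination system solved by a reference least-squares check
  set.seed(9)
  P <- matrix(rnorm(45), ncol = 3)
  colnames(P) <- c("a", "b", "c")
  h <- build_trimmed_hull(P, 0, 100)
  # interior points constructed as convex combinations are inside
  for (i in 1:20) {
    lam <- rexp(nrow(P)); lam <- lam / sum(lam)
    q <- matrix(colSums(P * lam), 1, dimnames = list(NULL, c("a", "b", "c")))
    expect_true(in_hull(h, q))
  }
  # points beyond the furthest vertex along a random direction are outside
  ctr <- colMeans(P)
  for (i in 1:10) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    reach <- max((P %*% dir)) - sum(ctr * dir)
    q <- matrix(ctr + dir * (reach * 1.05), 1,
                dimnames = list(NULL, c("a", "b", "c")))
    expect_false(in_hull(h, q))
  }
})

test_that("pseudo-absences are balanced, outside the hull and reproducible", {
  w <- test_world()
  expect_equal(nrow(w$pa), nrow(w$filtered))           # equal numbers
  expect_true(all(!in_hull(w$hull, w$pa[w$variables]))) # all strictly outside
  again <- sample_pseudo_absences(w$hull, nrow(w$filtered), w$domain,
                                  seed = w$seed)
  expect_identical(again, w$pa)
  other <- sample_pseudo_absences(w$hull, nrow(w$filtered), w$domain, seed = 99)
  expect_false(identical(other, w$pa))

  n_out <- sum(!in_hull(w$hull, w$domain[w$variables]))
  expect_error(sample_pseudo_absences(w$hull, n_out + 1, w$domain),
               "shortfall 1")

  # PATable contract: exact class balance, hull exclusion for label 0
  tab <- w$table
  expect_equal(sum(tab$label == 0), sum(tab$label == 1))
  expect_true(all(!in_hull(w$hull, tab[tab$label == 0, w$variables])))
})
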