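#' Greedy correlation pruning of candidate variables
#'
#' Walks the candidates in priority order and keeps a variable iff its
#' absolute Pearson correlation with every already-kept variable is at most
#' `r_max`, so each cluster of intercorrelated factors contributes a single
#' variable. Constant variables (undefined correlation) are excluded with a
#' warning.
#'
#' @param env data frame of candidate variable values (rows = presence cells).
#' @param priority character vector ordering the candidates; defaults to the
#'   column order of `env`.
#' @param r_max correlation threshold (default 0.7).
#' @return character vector of retained variable names, in priority order.
#' @export
select_uncorrelated_variables <- function(env, priority = names(env), r_max = 0.7) {
  stopifnot(length(priority) >= 2, nrow(env) >= 3)
  kept <- character()
  for (v in priority) {
    x <- env[[v]]
    if (stats::sd(x) == 0) {
      warning("variable '", v, "' is constant; excluded")
      next
    }
    ok <- all(vapply(kept, function(k)
      abs(stats::cor(x, env[[k]])) <= r_max, TRUE))
    if (ok) kept <- c(kept, v)
  }
  kept
}

#' Environmental-space thinning of presences
#'
#' Partitions the selected environmental space into axis-aligned bins of the
#' stated widths (0.5 degrees C for temperature-type variables, 0.5 psu for
#' salinity, 0.5 log units for primary production) and retains exactly one
#' presence per occupied bin, damping spatially heterogeneous sampling
#' effort. The deterministic pick within a bin is the record with the most
#' recent year, ties broken by the lowest cell id, making the result
#' order-invariant and idempotent.
#'
#' @param presences an `occurrence_set` (from [grid_occurrences()]).
#' @param grid an [env_grid].
#' @param variables selected environmental variables.
#' @param resolutions named bin widths per variable (defaults to 0.5 for
#'   every selected variable).
#' @return the thinned `occurrence_set`, with the environmental covariates and
#'   bin index attached.
#' @export
environmental_filter <- function(presences, grid, variables,
                                 resolutions = NULL) {
  if (is.null(resolutions))
    resolutions <- stats::setNames(rep(0.5, length(variables)), variables)
  stopifnot(all(variables %in% names(resolutions)),
            all(resolutions[variables] > 0))
  env <- env_at_cells(grid, presences$cell_id, variables)
  x <- as.data.frame(presences)
  x <- cbind(x[setdiff(names(x), c(variables, "env_bin"))], env[variables])
  miss <- !stats::complete.cases(x[variables])
  if (any(miss)) {
    warning(sum(miss), " presence(s) with missing covariates excluded")
    x <- x[!miss, , drop = FALSE]
  }
  bin <- do.call(paste, c(lapply(variables, function(v)
    floor(x[[v]] / resolutions[[v]])), sep = "|"))
  # deterministic pick: most recent year first, then lowest cell id
  yr <- x$last_year
  yr[is.na(yr)] <- -Inf
  ord <- order(bin, -yr, x$cell_id)
  x <- x[ord, , drop = FALSE]
  keep <- !duplicated(bin[ord])
  out <- x[keep, , drop = FALSE]
  out$env_bin <- bin[ord][keep]
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species") <- attr(presences, "species")
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Percentile-trimmed convex hull in environmental space
#'
#' Removes points outside the per-variable `[p_lo, p_hi]` percentile interval
#' (damping the weight of environmental extremes), then takes the convex hull
#' of the survivors: the smallest convex hyper-volume containing the trimmed
#' presence environments. Membership is tested by linear-programming
#' feasibility (a point is inside iff it is a convex combination of the
#' retained points); boundary points count as inside. A rank-deficient
#' (degenerate) point set falls back to a bounding-box test with a warning.
#'
#' @param points data frame or matrix of presence environments (one column
#'   per selected variable).
#' @param p_lo,p_hi trimming percentiles (defaults 2.5 and 97.5).
#' @return an object of class `trimmed_hull`.
#' @export
build_trimmed_hull <- function(points, p_lo = 2.5, p_hi = 97.5) {
  pts <- as.matrix(points)
  d <- ncol(pts)
  lo <- apply(pts, 2, stats::quantile, probs = p_lo / 100, names = FALSE)
  hi <- apply(pts, 2, stats::quantile, probs = p_hi / 100, names = FALSE)
  inside_box <- rowSums(sweep(pts, 2, lo, ">=") & sweep(pts, 2, hi, "<=")) == d
  kept <- pts[inside_box, , drop = FALSE]
  if (nrow(kept) < d + 1)
    stop("fewer than d+1 points remain after percentile trimming")
  ctr <- colMeans(kept)
  scl <- apply(kept, 2, function(z) max(diff(range(z)) / 2, 1e-12))
  std <- sweep(sweep(kept, 2, ctr), 2, scl, "/")
  degenerate <- qr(sweep(std, 2, colMeans(std)))$rank < d
  if (degenerate)
    warning("degenerate (rank-deficient) point set; falling back to bounding-box membership")
  # 2-D vertex reduction keeps the LP small; higher dimensions keep all points.
  if (!degenerate && d == 2) {
    v <- grDevices::chull(std)
    std <- std[v, , drop = FALSE]
    kept <- kept[v, , drop = FALSE]
  }
  structure(list(vertices = kept, std = std, center = ctr, scale = scl,
                 bounds_lo = lo, bounds_hi = hi, dim = d,
                 degenerate = degenerate,
                 variables = colnames(pts)), class = "trimmed_hull")
}

#' Convex-hull membership test
#'
#' @param hull a [build_trimmed_hull()] result.
#' @param x data frame or matrix of query points (columns as the hull's
#'   variables).
#' @param tol feasibility tolerance in the standardised space (boundary
#'   points count as inside).
#' @return logical vector.
#' @export
in_hull <- function(hull, x, tol = 1e-9) {
  q <- as.matrix(x)[, hull$variables %||% colnames(hull$vertices), drop = FALSE]
  qs <- sweep(sweep(q, 2, hull$center), 2, hull$scale, "/")
  if (hull$degenerate) {
    lo <- (hull$bounds_lo - hull$center) / hull$scale
    hi <- (hull$bounds_hi - hull$center) / hull$scale
    return(rowSums(sweep(qs, 2, lo - tol, ">=") &
                   sweep(qs, 2, hi + tol, "<=")) == ncol(qs))
  }
  P <- t(hull$std)                       # d x n
  bbox_lo <- apply(hull$std, 2, min); bbox_hi <- apply(hull$std, 2, max)
  out <- logical(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    z <- qs[i, ]
    if (any(z < bbox_lo - tol | z > bbox_hi + tol)) { out[i] <- FALSE; next }
    out[i] <- lp_in_hull(P, z, tol)
  }
  out
}

# Phase-1 simplex feasibility: does lambda >= 0 with P lambda = z and
# sum(lambda) = 1 exist? Dense tableau with Bland's rule; m = d+1 rows.
lp_in_hull <- function(P, z, tol = 1e-9) {
  A <- rbind(P, rep(1, ncol(P)))
  b <- c(z, 1)
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # tableau: [A | I_m | b]; basis = artificials; minimise their sum
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost <- c(rep(0, n), rep(1, m))
  # reduced costs for basis of artificials: c_j - sum over rows of A
  red <- cost - colSums(Tb[, seq_len(n + m), drop = FALSE])
  obj <- sum(b)
  it <- 0L; maxit <- 500L * (n + m)
  while (it < maxit) {
    it <- it + 1L
    enter <- which(red < -1e-11)[1]           # Bland: lowest index
    if (is.na(enter)) break
    colv <- Tb[, enter]
    pos <- which(colv > 1e-11)
    if (!length(pos)) break                    # unbounded (cannot happen here)
    ratio <- Tb[pos, n + m + 1] / colv[pos]
    leave_candidates <- pos[ratio <= min(ratio) + 1e-12]
    leave <- leave_candidates[which.min(basis[leave_candidates])]
    piv <- Tb[leave, enter]
    Tb[leave, ] <- Tb[leave, ] / piv
    for (r in seq_len(m)) {
      if (r != leave && abs(Tb[r, enter]) > 0)
        Tb[r, ] <- Tb[r, ] - Tb[r, enter] * Tb[leave, ]
    }
    basis[leave] <- enter
    # recompute reduced costs from scratch (m is tiny, cost negligible)
    cb <- cost[basis]
    red <- cost - as.vector(cb %*% Tb[, seq_len(n + m), drop = FALSE])
    obj <- sum(cb * Tb[, n + m + 1])
  }
  obj <= tol
}

#' Sample pseudo-absences outside the trimmed hull
#'
#' Draws exactly `n` points uniformly at random without replacement from the
#' portion of the sampling domain (realised environments of candidate marine
#' cells) strictly outside the trimmed convex hull.
#'
#' @param hull a [trimmed_hull][build_trimmed_hull()].
#' @param n number of pseudo-absences (normally the filtered presence count).
#' @param domain data frame of candidate environments; extra columns (e.g.
#'   `cell_id`, `lon`, `lat`) are carried through.
#' @param seed integer seed.
#' @return the sampled rows of `domain`.
#' @export
sample_pseudo_absences <- function(hull, n, domain, seed = 1L) {
  inside <- in_hull(hull, domain[, hull$variables, drop = FALSE])
  outside <- which(!inside)
  if (length(outside) < n)
    stop("only ", length(outside), " candidate points outside the hull; ",
         n, " requested (shortfall ", n - length(outside), ")")
  pick <- with_seed(seed, sample(outside, n))
  out <- domain[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the model-ready presence/pseudo-absence table
#'
#' Binds filtered presences (label 1) and pseudo-absences (label 0) with their
#' environmental covariates; classes are exactly balanced by construction.
#'
#' @param presences filtered presences (from [environmental_filter()]).
#' @param absences pseudo-absences (from [sample_pseudo_absences()]).
#' @param variables model covariates.
#' @return a `pa_table` data frame with columns `label`, `cell_id`, `lon`,
#'   `lat` and one column per variable.
#' @export
make_pa_table <- function(presences, absences, variables) {
  cols <- c("cell_id", "lon", "lat", variables)
  p <- cbind(label = 1L, as.data.frame(presences)[, cols])
  a <- cbind(label = 0L, as.data.frame(absences)[, cols])
  out <- rbind(p, a)
  rownames(out) <- NULL
  attr(out, "variables") <- variables
  class(out) <- c("pa_table", "data.frame")
  out
}
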