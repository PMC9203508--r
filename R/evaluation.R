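#' Continuous Boyce Index
#'
#' Presence-only evaluation metric: overlapping windows of width `window`
#' slide across the `[0, 1]` suitability axis; in each window the
#' predicted-to-expected ratio `P/E` is the fraction of presence predictions
#' falling inside divided by the fraction of background predictions inside,
#' and the index is the Spearman rank correlation between window midpoints
#' and `P/E` over the windows where `E > 0` (windows with no background mass
#' are dropped, not imputed). 1 means predictions rank presences perfectly,
#' 0 is random, -1 inverted. Being a rank statistic, the index is invariant
#' to strictly monotone transforms of the predictions up to the window
#' discretisation (exactly so in the continuum limit).
#'
#' @param pred_presence predictions at presence sites, in `[0, 1]`.
#' @param pred_background predictions at background sites, in `[0, 1]`.
#' @param window window width as a fraction of the unit interval.
#' @param n_windows number of window positions.
#' @return the CBI in `[-1, 1]`, or `NA` (with a warning) when undefined.
#' @export
continuous_boyce_index <- function(pred_presence, pred_background,
                                   window = 0.1, n_windows = 101L) {
  stopifnot(length(pred_presence) > 0, length(pred_background) > 0,
            all(pred_presence >= 0 & pred_presence <= 1),
            all(pred_background >= 0 & pred_background <= 1))
  if (length(unique(pred_background)) == 1L) {
    warning("all background predictions identical; CBI undefined")
    return(NA_real_)
  }
  lo <- seq(0, 1 - window, length.out = n_windows)
  hi <- lo + window
  mid <- lo + window / 2
  np <- length(pred_presence); nb <- length(pred_background)
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    inside_p <- pred_presence >= lo[i] &
      (pred_presence < hi[i] | (hi[i] >= 1 & pred_presence <= 1))
    inside_b <- pred_background >= lo[i] &
      (pred_background < hi[i] | (hi[i] >= 1 & pred_background <= 1))
    P[i] <- sum(inside_p) / np
    E[i] <- sum(inside_b) / nb
  }
  keep <- E > 0
  fe <- P[keep] / E[keep]
  if (sum(keep) < 3 || stats::sd(fe) == 0) {
    warning("too few informative windows; CBI undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::cor(mid[keep], fe, method = "spearman"))
}

#' Random 70/30 cross-validation splits
#'
#' Draws `runs` independent random splits of the table rows, `round(0.7 n)`
#' for training and the remainder for evaluation only.
#'
#' @param n number of rows (or a `pa_table`, whose row count is used).
#' @param runs number of splits.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list of `runs` lists with integer `train` and `eval` indices.
#' @export
cv_splits <- function(n, runs = 10L, train_frac = 0.7, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n_train <- round(train_frac * n)
  if (n < 30 || n_train < 1 || n - n_train < 1)
    stop("table too small for a ", round(100 * (1 - train_frac)),
         "% evaluation set")
  lapply(seq_len(runs), function(r) {
    tr <- with_seed(derive_seed(seed, paste0("cv", r)), sample.int(n, n_train))
    list(run = r, train = sort(tr), eval = sort(setdiff(seq_len(n), tr)))
  })
}

#' Screen a response curve for ecological plausibility
#'
#' A curve passes iff, after light smoothing (3-point running mean), it has at
#' most one interior local maximum, maxima being counted only when they
#' exceed the neighbouring local minima by `tolerance` ESI units. Bimodal
#' responses — the canonical spurious shape — fail; monotone and flat curves
#' pass.
#'
#' @param curve data frame from [response_curve()] (`value`, `esi`).
#' @param tolerance minimum prominence of a counted maximum (ESI units).
#' @return logical verdict.
#' @export
plausible_curve <- function(curve, tolerance = 0.02) {
  y <- curve$esi
  n <- length(y)
  if (n < 5) return(TRUE)
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[1] <- y[1]; ys[n] <- y[n]
  ys <- as.numeric(ys)
  # Decompose into significant alternating extrema: direction only reverses
  # on a move exceeding the tolerance, so sub-tolerance wiggles are ignored.
  peaks <- 0L
  anchor <- ys[1]
  direction <- 0L  # +1 rising, -1 falling
  for (i in 2:n) {
    if (direction >= 0) {
      if (ys[i] > anchor) anchor <- ys[i]
      if (anchor - ys[i] > tolerance) {
        if (direction == 1L) peaks <- peaks + 1L  # interior maximum confirmed
        direction <- -1L
        anchor <- ys[i]
      } else if (direction == 0L && ys[i] - ys[1] > tolerance) direction <- 1L
    } else {
      if (ys[i] < anchor) anchor <- ys[i]
      if (ys[i] - anchor > tolerance) {
        direction <- 1L
        anchor <- ys[i]
      }
    }
  }
  peaks <= 1L
}

#' Check all response curves of a fitted model
#'
#' @param model a `niche_fit`.
#' @param tolerance passed to [plausible_curve()].
#' @return named logical vector, one verdict per covariate.
#' @export
check_response_curves <- function(model, tolerance = 0.02) {
  vapply(model$variables, function(v)
    plausible_curve(response_curve(model, v), tolerance), TRUE)
}

#' Ensemble member selection
#'
#' Retains the algorithms whose mean CBI across cross-validation runs exceeds
#' the threshold and whose response curves all pass the plausibility screen.
#'
#' @param mean_cbi named numeric vector of per-algorithm mean CBI.
#' @param curves_ok named logical vector of per-algorithm curve verdicts.
#' @param threshold CBI selection threshold (default 0.5).
#' @return a `selection_report`: list with `retained`, `mean_cbi`,
#'   `curves_ok`, `threshold`.
#' @export
select_algorithms <- function(mean_cbi, curves_ok, threshold = 0.5) {
  stopifnot(length(mean_cbi) >= 1, all(names(mean_cbi) %in% names(curves_ok)))
  retained <- names(mean_cbi)[!is.na(mean_cbi) & mean_cbi > threshold &
                                curves_ok[names(mean_cbi)]]
  if (length(retained) == 0)
    stop("no algorithm satisfies the selection rule; no ensemble possible")
  structure(list(retained = retained, mean_cbi = mean_cbi,
                 curves_ok = curves_ok, threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Ensemble selection (CBI >", x$threshold, "and plausible curves)\n")
  tab <- data.frame(algorithm = names(x$mean_cbi),
                    mean_cbi = round(x$mean_cbi, 3),
                    curves_ok = x$curves_ok[names(x$mean_cbi)],
                    retained = names(x$mean_cbi) %in% x$retained)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-cell standard deviation across ensemble members
#'
#' Population standard deviation across member maps (divisor `m`, not
#' `m - 1`), quantifying inter-member divergence.
#'
#' @param members list of numeric matrices (or vectors) on a common grid.
#' @return matrix (or vector) of per-cell standard deviations.
#' @export
member_sd <- function(members) {
  stopifnot(length(members) >= 2)
  dims <- lapply(members, dim)
  if (length(unique(vapply(members, length, 0L))) != 1 ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("member maps are not on a common grid")
  m <- length(members)
  mean_map <- Reduce(`+`, members) / m
  var_map <- Reduce(`+`, lapply(members, function(x) (x - mean_map)^2)) / m
  sqrt(var_map)
}
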