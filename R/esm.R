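#' Fit an ensemble species distribution model
#'
#' The package's central fitting function. Given a presence/pseudo-absence
#' table, `esm()` runs the full calibration-evaluation-selection procedure:
#' `runs` independent random 70/30 cross-validation splits; each candidate
#' algorithm fitted on every training split and scored on the held-out 30%
#' with the Continuous Boyce Index (presence predictions against the
#' evaluation background); response curves of full-data fits screened for
#' ecological plausibility; and the ensemble retained as the algorithms with
#' mean CBI above the threshold and plausible curves throughout.
#'
#' @param table a [pa_table][make_pa_table()].
#' @param background optional data frame of available environments (e.g. the
#'   covariates of every valid marine cell). The default (`NULL`) evaluates
#'   the Boyce index against the held-out presence/pseudo-absence rows — the
#'   usage the metric's presence/pseudo-absence formulation was designed for
#'   and the package's standard procedure. Supplying a background instead
#'   takes the expected distribution from environmental availability (the
#'   metric's habitat-suitability-map formulation); note that availability
#'   backgrounds penalise rank-calibrated models such as NPPEN, whose
#'   presence predictions are uniform rather than concentrated near 1.
#' @param algorithms candidate algorithm ids (see [niche_algorithms]).
#' @param runs number of cross-validation runs.
#' @param train_frac training fraction per run.
#' @param cbi_threshold selection threshold on mean CBI.
#' @param curve_tolerance prominence tolerance for the curve screen.
#' @param seed master seed; every stochastic step derives its own seed.
#' @return an object of class `esm`: cross-validated fits per (run,
#'   algorithm), full-data fits, the CBI matrix, curve verdicts and the
#'   selection report.
#' @seealso [predict.esm()], [project_ensemble()], [summary.esm()]
#' @export
esm <- function(table, background = NULL,
                algorithms = names(algorithm_defaults()), runs = 10L,
                train_frac = 0.7, cbi_threshold = 0.5, curve_tolerance = 0.02,
                seed = 1L) {
  stopifnot(inherits(table, "data.frame"), "label" %in% names(table))
  variables <- attr(table, "variables") %||%
    setdiff(names(table), c("label", "cell_id", "lon", "lat"))
  splits <- cv_splits(nrow(table), runs = runs, train_frac = train_frac,
                      seed = derive_seed(seed, "cv"))
  cbi <- matrix(NA_real_, length(algorithms), runs,
                dimnames = list(algorithms, paste0("run", seq_len(runs))))
  fits <- vector("list", runs)
  failures <- list()
  for (r in seq_len(runs)) {
    sp <- splits[[r]]
    train <- table[sp$train, , drop = FALSE]
    attr(train, "variables") <- variables
    eval_rows <- table[sp$eval, , drop = FALSE]
    if (length(unique(train$label)) < 2 || length(unique(eval_rows$label)) < 2)
      stop("cross-validation split lost a class; table too small")
    fits[[r]] <- list()
    for (a in algorithms) {
      f <- fit_algorithm(a, train, variables,
                         seed = derive_seed(seed, paste0("fit", r, a)))
      fits[[r]][[a]] <- f
      if (inherits(f, "niche_fit_failed")) {
        failures[[paste(a, "run", r)]] <- f$reason
        next
      }
      p <- predict(f, eval_rows)
      bg <- if (is.null(background)) p else predict(f, background)
      cbi[a, r] <- suppressWarnings(
        continuous_boyce_index(p[eval_rows$label == 1L], bg))
    }
  }
  full_fits <- list(); curves_ok <- stats::setNames(rep(NA, length(algorithms)),
                                                    algorithms)
  for (a in algorithms) {
    f <- fit_algorithm(a, table, variables,
                       seed = derive_seed(seed, paste0("full", a)))
    full_fits[[a]] <- f
    curves_ok[a] <- if (inherits(f, "niche_fit_failed")) FALSE
      else all(check_response_curves(f, curve_tolerance))
  }
  mean_cbi <- rowMeans(cbi, na.rm = TRUE)
  mean_cbi[is.nan(mean_cbi)] <- NA_real_
  selection <- select_algorithms(mean_cbi, curves_ok, cbi_threshold)
  structure(list(table = table, variables = variables, algorithms = algorithms,
                 runs = runs, splits = splits, fits = fits,
                 full_fits = full_fits, cbi = cbi, curves_ok = curves_ok,
                 selection = selection, failures = failures, seed = seed),
            class = "esm")
}

#' @export
print.esm <- function(x, ...) {
  cat("Ensemble SDM:", length(x$algorithms), "candidate algorithms,",
      x$runs, "cross-validation runs,", nrow(x$table), "rows (",
      sum(x$table$label == 1), "presences )\n")
  cat("Variables:", paste(x$variables, collapse = ", "), "\n")
  cat("Retained:", paste(x$selection$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise an ensemble SDM fit
#'
#' @param object an [esm] fit.
#' @param ... unused.
#' @return the selection report, invisibly; prints the per-algorithm CBI
#'   table.
#' @export
summary.esm <- function(object, ...) {
  print(object)
  cat("\nPer-algorithm CBI (mean over", object$runs, "runs):\n")
  print(object$selection)
  if (length(object$failures)) {
    cat("\nFailed fits:\n")
    for (nm in names(object$failures))
      cat("  ", nm, ":", object$failures[[nm]], "\n")
  }
  invisible(object$selection)
}

#' Predict ensemble ESI at new environmental points
#'
#' Members are the retained algorithms fitted on each cross-validation
#' training split; the ensemble prediction is the unweighted member mean,
#' with the per-point member standard deviation alongside.
#'
#' @param object an [esm] fit.
#' @param newdata data frame with the model covariates.
#' @param type `"ensemble"` (mean and member SD) or `"members"` (full member
#'   matrix, columns named `algorithm.run`).
#' @param ... unused.
#' @return for `"ensemble"`, a data frame with `esi` and `sd`; for
#'   `"members"`, a numeric matrix.
#' @export
predict.esm <- function(object, newdata, type = c("ensemble", "members"), ...) {
  type <- match.arg(type)
  preds <- list()
  for (a in object$selection$retained) {
    for (r in seq_len(object$runs)) {
      f <- object$fits[[r]][[a]]
      if (inherits(f, "niche_fit_failed")) next
      preds[[paste(a, r, sep = ".")]] <- predict(f, newdata)
    }
  }
  M <- do.call(cbind, preds)
  if (type == "members") return(M)
  data.frame(esi = rowMeans(M),
             sd = apply(M, 1, function(z) sqrt(mean((z - mean(z))^2))))
}

#' Plot response curves of the retained algorithms
#'
#' One panel per model covariate; each retained algorithm's full-data
#' response curve drawn with the remaining covariates at training medians.
#'
#' @param x an [esm] fit.
#' @param ... passed to [graphics::matplot].
#' @return invisible `NULL`.
#' @export
plot.esm <- function(x, ...) {
  vars <- x$variables
  ret <- x$selection$retained
  old <- graphics::par(mfrow = c(1, length(vars)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    curves <- lapply(ret, function(a) response_curve(x$full_fits[[a]], v))
    xs <- curves[[1]]$value
    ys <- vapply(curves, function(cv) cv$esi, numeric(length(xs)))
    graphics::matplot(xs, ys, type = "l", lty = 1, col = seq_along(ret),
                      xlab = v, ylab = "ESI", ylim = c(0, 1),
                      main = paste("Response:", v), ...)
    graphics::legend("topright", legend = ret, col = seq_along(ret),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(NULL)
}
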