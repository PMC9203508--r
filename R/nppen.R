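#' Non-Parametric Probabilistic Ecological Niche model (NPPEN)
#'
#' Presence-only niche model based on the Mahalanobis distance to a reference
#' matrix of presence environments. For a query point `x`,
#' `D2(x) = (x - mu)' Sigma^-1 (x - mu)` with `mu` and `Sigma` the mean and
#' covariance of the reference set, and the Environmental Suitability Index is
#' the rank-based probability of membership: the fraction of reference points
#' whose own `D2` exceeds `D2(x)`. A point at the niche centre scores 1, a
#' point more extreme than every reference point scores 0. The index is
#' invariant under invertible affine transforms of the environmental axes
#' (a property of the Mahalanobis form).
#'
#' @param reference matrix or data frame of presence environments (rows are
#'   filtered presences, columns the selected variables); needs at least
#'   `d + 2` rows.
#' @param ridge ridge added to a singular covariance (with a warning).
#' @return an object of class `nppen` with `predict` support.
#' @export
nppen <- function(reference, ridge = 1e-8) {
  X <- as.matrix(reference)
  d <- ncol(X)
  if (nrow(X) < d + 2) stop("NPPEN needs at least d + 2 reference points")
  mu <- colMeans(X)
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    warning("singular covariance; applying ridge regularisation")
    Sinv <- solve(S + diag(ridge, d))
  }
  ref_d2 <- sort(stats::mahalanobis(X, mu, Sinv, inverted = TRUE))
  structure(list(reference = X, mean = mu, cov = S, cov_inv = Sinv,
                 ref_d2 = ref_d2, variables = colnames(X)),
            class = "nppen")
}

#' @export
print.nppen <- function(x, ...) {
  cat("NPPEN reference:", nrow(x$reference), "points,",
      ncol(x$reference), "variables (",
      paste(x$variables, collapse = ", "), ")\n")
  invisible(x)
}

#' Predict ESI from an NPPEN model
#'
#' @param object an [nppen] model.
#' @param newdata data frame or matrix of environmental points.
#' @param ... unused.
#' @return numeric ESI in `[0, 1]`.
#' @export
predict.nppen <- function(object, newdata, ...) {
  q <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  d2 <- stats::mahalanobis(q, object$mean, object$cov_inv, inverted = TRUE)
  n <- length(object$ref_d2)
  # fraction of reference distances strictly greater than d2(x)
  (n - findInterval(d2, object$ref_d2)) / n
}
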