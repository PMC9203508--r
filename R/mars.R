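# Multivariate adaptive regression splines for presence/absence scores.
#
# Compact MARS: a forward pass grows reflected-pair hinge bases
# max(0, x - t) / max(0, t - x) (products up to `degree`), a backward pass
# prunes terms by generalised cross-validation, and the surviving basis is
# refitted as a binomial GLM so predictions are calibrated probabilities in
# [0, 1] (logistic link, clamped).

mars_fit <- function(x, y, degree = 2L, max_terms = 15L, n_knots = 10L,
                     penalty = 3) {
  X <- as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  knots <- lapply(seq_len(p), function(j)
    unique(stats::quantile(X[, j], probs = seq(0.05, 0.95, length.out = n_knots),
                           names = FALSE)))
  # basis described as list of factors: list(var, knot, sign); empty = intercept
  terms <- list(list())
  B <- matrix(1, n, 1)

  eval_term <- function(term, M) {
    b <- rep(1, nrow(M))
    for (f in term) {
      h <- if (f$sign > 0) pmax(0, M[, f$var] - f$knot) else pmax(0, f$knot - M[, f$var])
      b <- b * h
    }
    b
  }

  rss_of <- function(Bm) {
    fit <- stats::.lm.fit(Bm, y)
    sum(fit$residuals^2)
  }

  best_rss <- rss_of(B)
  while (ncol(B) < max_terms) {
    best <- NULL
    for (par in seq_along(terms)) {
      parent <- terms[[par]]
      if (length(parent) >= degree) next
      used <- vapply(parent, function(f) f$var, 0L)
      for (v in setdiff(seq_len(p), used)) {
        pb <- B[, par]
        for (t in knots[[v]]) {
          b1 <- pb * pmax(0, X[, v] - t)
          b2 <- pb * pmax(0, t - X[, v])
          if (stats::sd(b1) < 1e-12 || stats::sd(b2) < 1e-12) next
          r <- rss_of(cbind(B, b1, b2))
          if (is.null(best) || r < best$rss)
            best <- list(rss = r, par = par, var = v, knot = t)
        }
      }
    }
    if (is.null(best) || best$rss > best_rss * (1 - 1e-6)) break
    parent <- terms[[best$par]]
    t1 <- c(parent, list(list(var = best$var, knot = best$knot, sign = 1L)))
    t2 <- c(parent, list(list(var = best$var, knot = best$knot, sign = -1L)))
    B <- cbind(B, eval_term(t1, X), eval_term(t2, X))
    terms <- c(terms, list(t1), list(t2))
    best_rss <- best$rss
  }

  gcv <- function(Bm) {
    k <- ncol(Bm)
    cm <- k + penalty * (k - 1) / 2
    if (cm >= nrow(Bm)) return(Inf)
    (rss_of(Bm) / n) / (1 - cm / n)^2
  }
  keep <- seq_along(terms)
  best_keep <- keep; best_gcv <- gcv(B)
  while (length(keep) > 1) {
    cand <- setdiff(keep, 1L)  # never drop the intercept
    g <- vapply(cand, function(j) gcv(B[, setdiff(keep, j), drop = FALSE]), 0)
    j <- cand[which.min(g)]
    keep <- setdiff(keep, j)
    if (min(g) < best_gcv) { best_gcv <- min(g); best_keep <- keep }
  }
  terms <- terms[best_keep]
  Bk <- B[, best_keep, drop = FALSE]

  glm_fit <- suppressWarnings(
    stats::glm.fit(Bk, y, family = stats::binomial()))
  structure(list(terms = terms, coef = glm_fit$coefficients,
                 eval_term = eval_term, variables = colnames(X)),
            class = "mars_model")
}

predict_mars <- function(object, newdata) {
  M <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  B <- do.call(cbind, lapply(object$terms, function(tm) object$eval_term(tm, M)))
  co <- object$coef
  co[is.na(co)] <- 0
  eta <- as.vector(B %*% co)
  clamp(stats::plogis(eta), 0, 1)
}
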