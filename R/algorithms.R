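#' Candidate niche-modelling algorithms
#'
#' Eight candidate algorithms share a single fitting interface and a common
#' predict contract (ESI in `[0, 1]` for any finite environmental point):
#' `NPPEN` (presence-only Mahalanobis-rank model, fitted on label-1 rows
#' only), `GLM` (binomial logit with linear + quadratic terms), `GAM`
#' (binomial [mgcv::gam] with small spline bases), `GBM` (gradient-boosted
#' trees via xgboost), `ANN` (single-hidden-layer [nnet::nnet], best of three
#' restarts), `FDA` (discriminant analysis on a quadratic polynomial basis),
#' `MARS` (hinge-basis regression splines with GCV pruning and logistic
#' calibration) and `RF` ([randomForest::randomForest] class votes).
#' Parameters are frozen package defaults (see [algorithm_defaults()]), the
#' traditional presence/pseudo-absence settings: binomial family with logit
#' link for the regression-type learners.
#'
#' @name niche_algorithms
NULL

#' Frozen default parameters per algorithm
#'
#' @return named list of parameter lists.
#' @export
algorithm_defaults <- function() {
  list(
    NPPEN = list(),
    GLM = list(),
    GAM = list(k = 4),                                  # spline basis size
    GBM = list(nrounds = 2500, max_depth = 3, eta = 1e-3),
    ANN = list(size = 5, decay = 5e-4, maxit = 300, restarts = 3),
    FDA = list(),
    MARS = list(degree = 2, max_terms = 15),
    RF = list(ntree = 500)
  )
}

#' Fit one candidate algorithm on a presence/pseudo-absence table
#'
#' @param algorithm one of `"NPPEN"`, `"GLM"`, `"GAM"`, `"GBM"`, `"ANN"`,
#'   `"FDA"`, `"MARS"`, `"RF"`.
#' @param table a [pa_table][make_pa_table()] (or any data frame with a
#'   0/1 `label` and the covariates).
#' @param variables covariate names; defaults to the table's `variables`
#'   attribute.
#' @param seed integer seed (stochastic learners are seeded deterministically
#'   from it).
#' @return a `niche_fit` object with `predict` support, or a flagged failed
#'   fit (class `niche_fit_failed`) carrying the reason.
#' @export
fit_algorithm <- function(algorithm, table, variables = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, names(algorithm_defaults()))
  variables <- variables %||% attr(table, "variables") %||%
    setdiff(names(table), c("label", "cell_id", "lon", "lat"))
  if (length(unique(table$label)) < 2)
    stop("both classes must be present in the training table")
  if (min(table(table$label)) < 10)
    stop("need at least 10 rows per class")
  x <- as.data.frame(table)[, variables, drop = FALSE]
  y <- as.integer(table$label)
  defs <- algorithm_defaults()[[algorithm]]
  fit_seed <- derive_seed(seed, algorithm)

  fitted <- tryCatch(with_seed(fit_seed, switch(algorithm,
    NPPEN = nppen(x[y == 1L, , drop = FALSE]),
    GLM = {
      fml <- stats::as.formula(paste("y ~",
        paste(c(variables, sprintf("I(%s^2)", variables)), collapse = " + ")))
      stats::glm(fml, family = stats::binomial(), data = cbind(x, y = y))
    },
    GAM = {
      fml <- stats::as.formula(paste("y ~",
        paste(sprintf("s(%s, k = %d)", variables, defs$k), collapse = " + ")))
      mgcv::gam(fml, family = stats::binomial(), data = cbind(x, y = y),
                method = "REML")
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = defs$max_depth,
                                       eta = defs$eta, nthread = 1),
                         data = dtrain, nrounds = defs$nrounds, verbose = 0)
    },
    ANN = {
      xs <- scale(as.matrix(x))
      best <- NULL
      for (r in seq_len(defs$restarts)) {
        m <- nnet::nnet(xs, y, size = defs$size, decay = defs$decay,
                        maxit = defs$maxit, entropy = TRUE, trace = FALSE)
        if (is.null(best) || m$value < best$value) best <- m
      }
      list(net = best, center = attr(xs, "scaled:center"),
           scale = attr(xs, "scaled:scale"))
    },
    FDA = {
      basis <- fda_basis(x)
      list(lda = MASS::lda(basis, grouping = factor(y)), variables = variables)
    },
    MARS = mars_fit(x, y, degree = defs$degree, max_terms = defs$max_terms),
    RF = randomForest::randomForest(x, factor(y), ntree = defs$ntree)
  )), error = function(e) e)

  if (inherits(fitted, "error")) {
    return(structure(list(algorithm = algorithm, reason = conditionMessage(fitted),
                          variables = variables, seed = seed),
                     class = "niche_fit_failed"))
  }
  structure(list(algorithm = algorithm, model = fitted, variables = variables,
                 seed = seed,
                 medians = vapply(x, stats::median, 0),
                 ranges = vapply(x, range, numeric(2))),
            class = "niche_fit")
}

# quadratic polynomial basis for the flexible discriminant: linear terms,
# squares and pairwise products
fda_basis <- function(x) {
  X <- as.matrix(x)
  out <- X
  p <- ncol(X)
  for (i in seq_len(p)) for (j in i:p)
    out <- cbind(out, X[, i] * X[, j])
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("niche_fit:", x$algorithm, "on", length(x$variables), "variables (",
      paste(x$variables, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.niche_fit_failed <- function(x, ...) {
  cat("failed fit:", x$algorithm, "-", x$reason, "\n")
  invisible(x)
}

#' Predict ESI from a fitted algorithm
#'
#' @param object a `niche_fit`.
#' @param newdata data frame holding the model covariates.
#' @param ... unused.
#' @return numeric ESI in `[0, 1]`.
#' @export
predict.niche_fit <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$variables, drop = FALSE]
  m <- object$model
  p <- switch(object$algorithm,
    NPPEN = predict(m, nd),
    GLM = as.vector(stats::predict(m, nd, type = "response")),
    GAM = as.vector(mgcv::predict.gam(m, nd, type = "response")),
    GBM = as.vector(stats::predict(m, as.matrix(nd))),
    ANN = {
      xs <- sweep(sweep(as.matrix(nd), 2, m$center), 2, m$scale, "/")
      as.vector(stats::predict(m$net, xs))
    },
    FDA = {
      post <- stats::predict(m$lda, fda_basis(nd))$posterior
      as.vector(post[, "1"])
    },
    MARS = predict_mars(m, nd),
    RF = as.vector(stats::predict(m, nd, type = "prob")[, "1"])
  )
  clamp(p, 0, 1)
}

#' Response curve of a fitted algorithm along one variable
#'
#' Evaluates the model along a grid of values of one covariate with the
#' remaining covariates held at their training medians — the standard profile
#' used to screen for ecologically implausible (e.g. bimodal) responses.
#'
#' @param model a `niche_fit`.
#' @param variable covariate to vary.
#' @param values grid of values; defaults to 100 points spanning the training
#'   range extended by 10 percent either side.
#' @param others_at named values for the fixed covariates; defaults to the
#'   training medians.
#' @return data frame with columns `value` and `esi`.
#' @export
response_curve <- function(model, variable, values = NULL, others_at = NULL) {
  if (!variable %in% model$variables)
    stop("variable '", variable, "' is not a model covariate")
  fixed <- others_at %||% model$medians
  if (is.null(values)) {
    r <- model$ranges[, variable]
    pad <- 0.1 * diff(r)
    values <- seq(r[1] - pad, r[2] + pad, length.out = 100)
  }
  nd <- as.data.frame(as.list(fixed))[rep(1, length(values)), , drop = FALSE]
  nd[[variable]] <- values
  data.frame(value = values, esi = predict(model, nd))
}
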