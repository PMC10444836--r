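#' Fit a species distribution model
#'
#' Single front-end for the seven SDM algorithms compared by the package.
#' Three are presence-only profile models implemented here from first
#' principles, and four are presence/background learners backed by the
#' standard R implementations:
#'
#' \describe{
#'   \item{`bioclim`}{classic climate/terrain envelope. Each predictor is
#'     scored by how central the candidate value is within the training
#'     values, `2 * min(F, 1 - F)` with `F` the midpoint empirical CDF, and
#'     the overall score is the minimum across predictors: 1 at the
#'     per-variable medians, 0 outside any training min-max.}
#'   \item{`domain`}{Gower-similarity model: score is
#'     `S_A = max_j (1 - d(T_j, A))`, the complement of the range-
#'     standardized Gower distance ([gower_distance()]) to the nearest
#'     training site. 1 at any training site; may be negative outside the
#'     training ranges (use `clamp` at prediction time to truncate).}
#'   \item{`mahalanobis`}{squared Mahalanobis distance
#'     `D^2 = (x - mu)' S^{-1} (x - mu)` to the presence mean, with the
#'     sample covariance (denominator n-1, ridge-regularized only if its
#'     condition number exceeds 1e10). The suitability score is the
#'     chi-square survival function of `D^2` on Q degrees of freedom
#'     (1 at the mean, decreasing in `D^2`); raw `D^2` is available via
#'     `predict(..., type = "distance")`.}
#'   \item{`glm`}{generalized linear model `g(E(Y)) = alpha + X' beta` on
#'     the 0/1 labels via [stats::glm()]. Default `family = "gaussian"`
#'     (an identity-link linear probability fit, the convention this
#'     pipeline compares against); `"binomial"` gives ordinary logistic
#'     regression. Scores are on the response scale and may leave [0, 1]
#'     under the gaussian family.}
#'   \item{`gam`}{generalized additive model with one penalized spline
#'     smoother per predictor via [mgcv::gam()] (basis dimension
#'     `k_basis`, REML smoothness selection); predictors with fewer than
#'     10 unique values fall back to linear terms. Default binomial.}
#'   \item{`rf`}{classification random forest via
#'     [randomForest::randomForest()] with `ntree = 500` and `mtry = 10`
#'     (clamped with a warning when fewer predictors are available);
#'     score is the presence-class vote fraction.}
#'   \item{`svm`}{soft-margin support vector machine with Gaussian
#'     (radial) kernel via [e1071::svm()], predictors standardized
#'     internally; score is the signed decision value oriented so larger
#'     means more suitable.}
#' }
#'
#' All scores obey one contract: higher = more suitable, and prediction
#' matches predictors to training variables by name.
#'
#' @param x predictor matrix or data frame with named columns, or an
#'   [occurrence_set()] (in which case `y` is taken from it).
#' @param y 0/1 labels (1 = presence). May be `NULL` for profile methods,
#'   which then treat every row of `x` as a presence; when `y` is given,
#'   profile methods use only the rows with `y == 1`.
#' @param method one of `"bioclim"`, `"domain"`, `"mahalanobis"`, `"glm"`,
#'   `"gam"`, `"rf"`, `"svm"`.
#' @param family response family for `glm`/`gam`: `"gaussian"` or
#'   `"binomial"` (defaults: gaussian for `glm`, binomial for `gam`).
#' @param ntree,mtry random-forest size and per-split predictor count.
#' @param cost,gamma SVM cost and Gaussian-kernel width (default
#'   `1/n_predictors` on standardized predictors).
#' @param scale standardize predictors inside the SVM (default `TRUE`;
#'   disable when predictors are already on one scale).
#' @param k_basis GAM spline basis dimension per predictor.
#' @param seed integer seed for the stochastic learners; fitting is
#'   deterministic given it.
#' @return An object of class `c("sdm_<method>", "sdm")` supporting
#'   [predict()], [print()], [summary()] and (for `glm`) [coef()].
#' @examples
#' set.seed(1)
#' X <- cbind(a = rnorm(40), b = rnorm(40))
#' m <- sdm_fit(X, method = "bioclim")
#' predict(m, X[1:5, ])
#' @export
sdm_fit <- function(x, y = NULL,
                    method = c("bioclim", "domain", "mahalanobis",
                               "glm", "gam", "rf", "svm"),
                    family = NULL, ntree = 500, mtry = 10,
                    cost = 1, gamma = NULL, scale = TRUE, k_basis = 10,
                    seed = 1) {
  method <- match.arg(method)
  if (inherits(x, "occurrence_set")) {
    y <- x$y
    x <- x$X
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("v", seq_len(ncol(X)))
  if (anyNA(X)) stop("predictor matrix contains missing values",
                     call. = FALSE)
  profile <- method %in% c("bioclim", "domain", "mahalanobis")
  if (profile) {
    P <- if (is.null(y)) X else X[y == 1, , drop = FALSE]
    core <- switch(method,
                   bioclim = fit_bioclim(P),
                   domain = fit_domain(P),
                   mahalanobis = fit_mahalanobis(P))
  } else {
    if (is.null(y)) stop("'", method, "' needs 0/1 labels in 'y'",
                         call. = FALSE)
    stopifnot(length(y) == nrow(X))
    core <- switch(method,
      glm = fit_glm_sdm(X, y, family = family %||% "gaussian"),
      gam = fit_gam_sdm(X, y, family = family %||% "binomial",
                        k_basis = k_basis),
      rf = fit_rf_sdm(X, y, ntree = ntree, mtry = mtry, seed = seed),
      svm = fit_svm_sdm(X, y, cost = cost, gamma = gamma, seed = seed,
                        scale = scale))
  }
  structure(c(list(method = method, vars = colnames(X),
                   n_presence = if (profile) nrow(if (is.null(y)) X else
                     X[y == 1, , drop = FALSE]) else sum(y == 1),
                   n_background = if (profile) 0L else sum(y == 0)),
              core),
            class = c(paste0("sdm_", method), "sdm"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_newdata <- function(object, newdata) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$vars))
      stop("newdata has ", ncol(X), " columns; model expects ",
           length(object$vars), call. = FALSE)
    colnames(X) <- object$vars
  }
  miss <- setdiff(object$vars, colnames(X))
  if (length(miss))
    stop("newdata is missing predictor '", miss[1], "'", call. = FALSE)
  X[, object$vars, drop = FALSE]
}

#' Predict suitability scores from a fitted SDM
#'
#' @param object a fitted `"sdm"` model.
#' @param newdata predictor matrix/data frame (matched to training
#'   variables by name), or a `predictor_stack` — in which case a
#'   suitability [raster_grid()] is returned with nodata propagated.
#' @param type `"score"` (default; higher = more suitable) or, for
#'   Mahalanobis models, `"distance"` for raw `D^2`.
#' @param clamp for Domain models, truncate scores to [0, 1].
#' @param ... unused.
#' @return Numeric vector of scores, or a [raster_grid()] when `newdata`
#'   is a `predictor_stack`.
#' @export
predict.sdm <- function(object, newdata, type = c("score", "distance"),
                        clamp = FALSE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "predictor_stack"))
    return(predict_map(object, newdata, type = type, clamp = clamp))
  X <- check_newdata(object, newdata)
  score_sdm(object, X, type = type, clamp = clamp)
}

score_sdm <- function(object, X, type = "score", clamp = FALSE) {
  if (type == "distance" && object$method != "mahalanobis")
    stop("type = \"distance\" is only available for Mahalanobis models",
         call. = FALSE)
  switch(object$method,
    bioclim = score_bioclim(object, X),
    domain = score_domain(object, X, clamp = clamp),
    mahalanobis = score_mahalanobis(object, X, type = type),
    glm = ,
    gam = as.numeric(stats::predict(object$fit,
                                    newdata = as.data.frame(X),
                                    type = "response")),
    rf = as.numeric(stats::predict(object$fit, as.data.frame(X),
                                   type = "prob")[, "1"]),
    svm = {
      dv <- attr(stats::predict(object$fit, as.data.frame(X),
                                decision.values = TRUE),
                 "decision.values")
      object$sign * as.numeric(dv[, 1])
    })
}

#' @export
print.sdm <- function(x, ...) {
  kind <- if (x$method %in% c("bioclim", "domain", "mahalanobis"))
    "presence-only profile" else "presence/background"
  cat(sprintf("sdm: %s (%s)\n", x$method, kind))
  cat(sprintf("  predictors: %s\n", paste(x$vars, collapse = ", ")))
  cat(sprintf("  training: %d presences", x$n_presence))
  if (x$n_background > 0) cat(sprintf(", %d background", x$n_background))
  cat("\n")
  invisible(x)
}

#' @export
summary.sdm <- function(object, ...) {
  print(object)
  switch(object$method,
    glm = , gam = print(summary(object$fit)),
    rf = print(object$fit),
    svm = cat(sprintf("  SVM: cost %g, gamma %g, %d support vectors\n",
                      object$cost, object$gamma, object$fit$tot.nSV)),
    mahalanobis = {
      cat("  presence mean:\n")
      print(signif(object$mean, 5))
    },
    domain = cat(sprintf("  %d training sites; ranges: %s\n",
                         nrow(object$train),
                         paste(signif(object$ranges, 4), collapse = ", "))),
    bioclim = cat(sprintf("  envelope over %d presence rows\n", object$n)))
  invisible(object)
}

#' @export
coef.sdm <- function(object, ...) {
  if (object$method %in% c("glm", "gam")) stats::coef(object$fit)
  else stop("coefficients are only defined for glm/gam models",
            call. = FALSE)
}

#' Serialize explicit-parameter SDMs to JSON
#'
#' BIOCLIM, Domain, Mahalanobis and GLM models have explicit parameters and
#' round-trip through a versioned JSON document; the opaque fitted states of
#' GAM/RF/SVM do not and are rejected.
#'
#' @param object a fitted `"sdm"` model.
#' @param path output file path.
#' @return `path`, invisibly (`write_sdm`); a fitted `"sdm"` (`read_sdm`).
#' @export
write_sdm <- function(object, path) {
  stopifnot(inherits(object, "sdm"))
  doc <- switch(object$method,
    bioclim = list(tables = object$tables, n = object$n),
    domain = list(train = object$train, ranges = as.list(object$ranges)),
    mahalanobis = list(mean = as.list(object$mean), cov = object$cov,
                       df = object$df),
    glm = list(coef = as.list(stats::coef(object$fit)),
               family = object$family),
    stop("only bioclim/domain/mahalanobis/glm models serialize to JSON",
         call. = FALSE))
  doc <- c(list(format = "toposdm-sdm", version = 1L,
                method = object$method, vars = as.list(object$vars),
                n_presence = object$n_presence), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sdm
#' @export
read_sdm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "toposdm-sdm"))
    stop("not a serialized sdm document: ", path, call. = FALSE)
  vars <- as.character(unlist(doc$vars))
  num <- function(x) as.numeric(unlist(x))
  rowmat <- function(x) {
    m <- do.call(rbind, lapply(x, num))
    colnames(m) <- vars
    m
  }
  if (identical(doc$method, "glm")) {
    # rebuild a minimal linear scorer rather than a glm object
    cf <- stats::setNames(num(doc$coef), names(doc$coef))
    return(structure(list(method = "glm", vars = vars,
                          n_presence = doc$n_presence, n_background = NA,
                          coefs = cf, family = doc$family, fit = NULL),
                     class = c("sdm_glm_json", "sdm_glm", "sdm")))
  }
  core <- switch(doc$method,
    bioclim = list(tables = lapply(doc$tables, num), n = doc$n),
    domain = list(train = rowmat(doc$train),
                  ranges = stats::setNames(num(doc$ranges), vars)),
    mahalanobis = {
      S <- rowmat(doc$cov); rownames(S) <- vars
      list(mean = stats::setNames(num(doc$mean), vars), cov = S,
           inv = solve(S), df = doc$df)
    },
    stop("unknown serialized method '", doc$method, "'", call. = FALSE))
  structure(c(list(method = doc$method, vars = vars,
                   n_presence = doc$n_presence, n_background = 0L),
              core),
            class = c(paste0("sdm_", doc$method), "sdm"))
}

#' @export
predict.sdm_glm_json <- function(object, newdata, ...) {
  if (inherits(newdata, "predictor_stack"))
    return(predict_map(object, newdata))
  X <- check_newdata(object, newdata)
  eta <- drop(cbind(1, X) %*% object$coefs[c("(Intercept)", object$vars)])
  if (object$family == "binomial") stats::plogis(eta) else eta
}
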