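# Supervised presence/background learners behind sdm_fit(): GLM, GAM, RF,
# SVM. Each returns the fields stored in the "sdm" object and a scorer used
# by predict.sdm(); higher score = more suitable everywhere.

fit_glm_sdm <- function(X, y, family = "gaussian") {
  check_two_classes(y)
  d <- data.frame(.y = y, X, check.names = FALSE)
  fam <- switch(family, gaussian = stats::gaussian(),
                binomial = stats::binomial(),
                stop("unsupported family '", family, "'", call. = FALSE))
  fit <- stats::glm(.y ~ ., data = d, family = fam)
  if (anyNA(stats::coef(fit)))
    warning("rank-deficient design: aliased column(s) dropped from the fit",
            call. = FALSE)
  list(fit = fit, family = family)
}

fit_gam_sdm <- function(X, y, family = "binomial", k_basis = 10) {
  check_two_classes(y)
  d <- data.frame(.y = y, X, check.names = FALSE)
  fam <- switch(family, gaussian = stats::gaussian(),
                binomial = stats::binomial(),
                stop("unsupported family '", family, "'", call. = FALSE))
  terms <- vapply(colnames(X), function(v) {
    nu <- length(unique(X[, v]))
    if (nu >= 10) {
      sprintf("s(`%s`, k = %d)", v, min(k_basis, nu - 1L))
    } else {
      warning("predictor '", v, "' has only ", nu,
              " unique values; using a linear term", call. = FALSE)
      sprintf("`%s`", v)
    }
  }, character(1))
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = d, family = fam, method = "REML")
  list(fit = fit, family = family)
}

fit_rf_sdm <- function(X, y, ntree = 500, mtry = 10, seed = 1) {
  check_two_classes(y)
  if (mtry > ncol(X)) {
    warning("mtry = ", mtry, " exceeds the ", ncol(X),
            " available predictors; clamped to ", ncol(X), call. = FALSE)
    mtry <- ncol(X)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
    ntree = ntree, mtry = mtry)
  list(fit = fit, ntree = ntree, mtry = mtry, seed = seed)
}

fit_svm_sdm <- function(X, y, cost = 1, gamma = NULL, seed = 1,
                        scale = TRUE) {
  if (length(unique(y)) < 2L)
    stop("SVM requires both classes in the training labels", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(X)  # on internally standardized X
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = scale)
  # orient the decision value so that higher = presence class "1"
  dv <- attr(stats::predict(fit, as.data.frame(X), decision.values = TRUE),
             "decision.values")
  lab <- colnames(dv)[1]
  sign <- if (grepl("^1/", lab)) 1 else -1
  list(fit = fit, cost = cost, gamma = gamma, sign = sign, seed = seed)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop("degenerate labels: need both presence (1) and background (0) rows",
         call. = FALSE)
  invisible(y)
}
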