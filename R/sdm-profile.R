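#' Gower distance between predictor vectors
#'
#' Range-standardized mean absolute difference across the Q predictors:
#' `d(a, b) = (1/Q) * sum_K |a_K - b_K| / range_K`. Range standardization
#' equalizes the contribution of each predictor; the absolute value keeps
#' the quantity a metric (nonnegative, symmetric, zero only for identical
#' standardized profiles). This is the distance underlying the Domain
#' model's similarity.
#'
#' @param a,b numeric vectors of equal length Q.
#' @param ranges strictly positive per-variable ranges (length Q).
#' @return A single nonnegative number.
#' @examples
#' gower_distance(c(1, 2), c(3, 6), ranges = c(2, 4))  # 1
#' @export
gower_distance <- function(a, b, ranges) {
  if (length(a) != length(b) || length(a) != length(ranges))
    stop("'a', 'b' and 'ranges' must have equal length", call. = FALSE)
  if (any(!is.finite(ranges)) || any(ranges <= 0))
    stop("all 'ranges' must be strictly positive; drop or jitter ",
         "zero-range variables upstream", call. = FALSE)
  mean(abs(a - b) / ranges)
}

# ---- BIOCLIM -------------------------------------------------------------

fit_bioclim <- function(X) {
  if (nrow(X) < 3L) stop("BIOCLIM needs at least 3 presence rows",
                         call. = FALSE)
  list(tables = lapply(seq_len(ncol(X)), function(j) sort(X[, j])),
       vars = colnames(X), n = nrow(X))
}

# Midpoint empirical CDF: F(x) = (#{v < x} + 0.5 #{v == x}) / n
bioclim_cdf <- function(sorted, x) {
  n_le <- findInterval(x, sorted)
  n_lt <- findInterval(x, sorted, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / length(sorted)
}

score_bioclim <- function(model, X) {
  p <- matrix(NA_real_, nrow(X), length(model$vars))
  for (j in seq_along(model$vars)) {
    F <- bioclim_cdf(model$tables[[j]], X[, j])
    p[, j] <- 2 * pmin(F, 1 - F)
  }
  out <- do.call(pmin, as.data.frame(p))
  as.numeric(out)
}

# ---- Domain (Gower similarity) ------------------------------------------

fit_domain <- function(X) {
  rng <- apply(X, 2, function(v) diff(range(v)))
  if (any(rng <= 0))
    stop("zero range in presence data for variable '",
         colnames(X)[which(rng <= 0)[1]],
         "'; Domain requires strictly positive ranges", call. = FALSE)
  list(train = X, ranges = rng, vars = colnames(X))
}

# S_A = max_j (1 - d(T_j, A)); similarity to any training site itself is 1.
score_domain <- function(model, X, clamp = FALSE) {
  Tm <- model$train
  Q <- length(model$vars)
  D <- matrix(0, nrow(X), nrow(Tm))
  for (k in seq_len(Q))
    D <- D + abs(outer(X[, k], Tm[, k], "-")) / model$ranges[k]
  D <- D / Q
  s <- 1 - apply(D, 1L, min)
  if (clamp) s <- pmin(pmax(s, 0), 1)
  s
}

# ---- Mahalanobis ---------------------------------------------------------

fit_mahalanobis <- function(X, cond_max = 1e10) {
  if (nrow(X) < 2L) stop("Mahalanobis needs at least 2 presence rows",
                         call. = FALSE)
  mu <- colMeans(X)
  S <- stats::cov(X)  # n - 1 denominator
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_max) {
    lambda <- max(ev) / cond_max
    S <- S + diag(lambda, ncol(S))
    warning("near-singular presence covariance; ridge-regularized with ",
            "lambda = ", signif(lambda, 3), call. = FALSE)
  }
  list(mean = mu, cov = S, inv = solve(S), df = ncol(X), vars = colnames(X))
}

score_mahalanobis <- function(model, X, type = c("score", "distance")) {
  type <- match.arg(type)
  Xc <- sweep(X, 2, model$mean)
  d2 <- rowSums((Xc %*% model$inv) * Xc)
  d2 <- pmax(d2, 0)
  if (type == "distance") return(d2)
  # chi-square survival function: probabilistic calibration of D^2
  stats::pchisq(d2, df = model$df, lower.tail = FALSE)
}
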