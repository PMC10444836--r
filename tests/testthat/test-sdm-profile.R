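test_that("gower distance matches hand evaluation and is a metric", {
  expect_equal(gower_distance(c(1, 2), c(3, 6), ranges = c(2, 4)), 1.0)
  expect_equal(gower_distance(c(5, 5), c(5, 5), ranges = c(1, 2)), 0)
  set.seed(2)
  for (i in 1:100) {
    q <- sample(2:6, 1)
    a <- runif(q); b <- runif(q); r <- runif(q, 0.5, 2)
    expect_equal(gower_distance(a, b, r), oracle_gower(a, b, r),
                 tolerance = 1e-12)
    expect_identical(gower_distance(a, b, r), gower_distance(b, a, r))
    expect_gte(gower_distance(a, b, r), 0)
  }
  expect_error(gower_distance(1:2, 1:2, c(1, 0)), "positive")
  expect_error(gower_distance(1:2, 1:3, c(1, 1)), "equal length")
})

test_that("bioclim scores are percentile envelopes", {
  set.seed(4)
  X <- cbind(a = rnorm(25), b = runif(25))
  m <- sdm_fit(X, method = "bioclim")
  # every training point is inside its own envelope
  expect_true(all(predict(m, X) > 0))
  med <- apply(X, 2, stats::median)
  expect_equal(predict(m, rbind(med)), 1.0)
  low <- apply(X, 2, min) - 1
  expect_equal(predict(m, rbind(low)), 0)
  one_out <- rbind(c(a = min(X[, "a"]) - 1, b = unname(med["b"])))
  expect_equal(unname(predict(m, one_out)), 0)
})

test_that("bioclim equals brute-force percentile computation", {
  set.seed(5)
  Xt <- cbind(u = runif(5), v = runif(5))
  m <- sdm_fit(Xt, method = "bioclim")
  cdf <- function(vals, x) (sum(vals < x) + 0.5 * sum(vals == x)) /
    length(vals)
  for (i in 1:100) {
    x <- c(u = runif(1, -0.2, 1.2), v = runif(1, -0.2, 1.2))
    want <- min(vapply(names(x), function(nm) {
      F <- cdf(Xt[, nm], x[nm]); 2 * min(F, 1 - F)
    }, numeric(1)))
    expect_equal(unname(predict(m, rbind(x))), want, tolerance = 1e-12)
  }
})

test_that("domain similarity is the max Gower complement over sites", {
  set.seed(6)
  Tm <- cbind(p = runif(4), q = runif(4, 10, 20), r = runif(4))
  m <- sdm_fit(Tm, method = "domain")
  expect_equal(unname(predict(m, Tm[2, , drop = FALSE])), 1.0)
  # brute-force double loop over candidates and training sites
  rng <- apply(Tm, 2, function(v) diff(range(v)))
  for (i in 1:100) {
    x <- c(p = runif(1), q = runif(1, 8, 22), r = runif(1))
    want <- max(vapply(1:4, function(j) 1 - oracle_gower(Tm[j, ], x, rng),
                       numeric(1)))
    expect_equal(unname(predict(m, rbind(x))), want, tolerance = 1e-9)
  }
  # far outside the training range the raw similarity goes negative
  far <- rbind(c(p = 50, q = 15, r = 0.5))
  expect_lt(predict(m, far), 0)
  expect_gte(predict(m, far, clamp = TRUE), 0)
  Tc <- Tm; Tc[, "r"] <- 1
  expect_error(sdm_fit(Tc, method = "domain"), "zero range")
})

test_that("mahalanobis scores reduce to the classic quadratic form", {
  set.seed(7)
  X <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- sdm_fit(X, method = "mahalanobis")
  expect_equal(m$mean, colMeans(X))
  expect_equal(m$cov, stats::cov(X))
  # D^2 at the mean is 0 and suitability 1
  expect_equal(unname(predict(m, rbind(colMeans(X)), type = "distance")), 0)
  expect_equal(unname(predict(m, rbind(colMeans(X)))), 1.0)
  # independent oracle: stats::mahalanobis
  cand <- matrix(rnorm(150), ncol = 3, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(m, cand, type = "distance")),
               unname(stats::mahalanobis(cand, colMeans(X), stats::cov(X))),
               tolerance = 1e-9)
  # identity covariance: D^2 equals squared Euclidean distance
  set.seed(8)
  Z <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  mz <- sdm_fit(Z, method = "mahalanobis")
  x0 <- rbind(c(a = 1, b = -2))
  d2 <- unname(predict(mz, x0, type = "distance"))
  expect_equal(d2, sum((x0 - mz$mean) %*% solve(mz$cov) * (x0 - mz$mean)))
  expect_equal(d2, sum((x0 - colMeans(Z))^2), tolerance = 0.2)
})

test_that("mahalanobis D^2 is invariant under invertible linear maps", {
  set.seed(9)
  X <- matrix(rnorm(240), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  cand <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, colnames(X)))
  A <- matrix(c(2, 0.5, 0, -1, 1, 0.3, 0.2, 0, 1.5), 3, 3)
  b <- c(5, -3, 100)
  Xt <- sweep(X %*% A, 2, b, `+`); colnames(Xt) <- colnames(X)
  ct <- sweep(cand %*% A, 2, b, `+`); colnames(ct) <- colnames(X)
  d1 <- predict(sdm_fit(X, method = "mahalanobis"), cand, type = "distance")
  d2 <- predict(sdm_fit(Xt, method = "mahalanobis"), ct, type = "distance")
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("singular presence covariance is ridge-regularized with a warning", {
  set.seed(10)
  z <- rnorm(20)
  X <- cbind(a = z, b = z, c = rnorm(20))
  expect_warning(m <- sdm_fit(X, method = "mahalanobis"), "ridge")
  s <- predict(m, X)
  expect_true(all(is.finite(s) & s >= 0 & s <= 1))
})

test_that("profile scores ignore training-row order and affine rescaling", {
  set.seed(11)
  X <- cbind(a = rnorm(30), b = runif(30, 5, 9))
  cand <- cbind(a = rnorm(10), b = runif(10, 4, 10))
  perm <- sample(30)
  for (meth in c("bioclim", "domain", "mahalanobis")) {
    s1 <- predict(sdm_fit(X, method = meth), cand)
    s2 <- predict(sdm_fit(X[perm, ], method = meth), cand)
    expect_equal(s1, s2, tolerance = 1e-12)
  }
  # per-variable affine rescaling: bioclim and domain scores are unchanged
  resc <- function(M) cbind(a = 3 * M[, "a"] - 7, b = -2 * M[, "b"] + 1)
  for (meth in c("bioclim", "domain")) {
    s1 <- predict(sdm_fit(X, method = meth), cand)
    s2 <- predict(sdm_fit(resc(X), method = meth), resc(cand))
    if (meth == "bioclim") {
      expect_equal(s1, s2, tolerance = 1e-12)
    } else {
      expect_equal(s1, s2, tolerance = 1e-9)
    }
  }
})

test_that("scores never increase along rays away from an isotropic centroid", {
  set.seed(12)
  X <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  mu <- colMeans(X)
  dir <- c(1, 0.6) / sqrt(1.36)
  steps <- seq(0, 4, by = 0.25)
  for (meth in c("bioclim", "domain", "mahalanobis")) {
    m <- sdm_fit(X, method = meth)
    pts <- t(vapply(steps, function(s) mu + s * dir, numeric(2)))
    colnames(pts) <- colnames(X)
    sc <- predict(m, pts)
    # the nearest-site similarity of Domain is locally rough at the scale
    # of the sample spacing; allow wiggle of that order there
    tol <- if (meth == "domain") 0.02 else 1e-9
    expect_true(all(diff(sc) <= tol))
  }
})
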