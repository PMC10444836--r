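test_that("gaussian GLM reproduces exact least squares", {
  set.seed(1)
  x <- runif(30)
  X <- cbind(x1 = x, x2 = rnorm(30))
  y <- 2 + 3 * x  # exactly linear, no noise
  m <- sdm_fit(X, y, method = "glm", family = "gaussian")
  cf <- coef(m)
  expect_equal(unname(cf["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(cf["x1"]), 3, tolerance = 1e-8)
  expect_equal(unname(abs(cf["x2"])) < 1e-8, TRUE)
  # scores equal the closed-form normal-equations prediction
  Xn <- cbind(x1 = runif(10), x2 = rnorm(10))
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(predict(m, Xn)), drop(cbind(1, Xn) %*% beta),
               tolerance = 1e-8)
  expect_error(sdm_fit(X, rep(1, 30), method = "glm"), "degenerate")
  expect_warning(sdm_fit(cbind(a = x, b = 2 * x), y, method = "glm"),
                 "aliased")
})

test_that("GAM recovers a smooth unimodal optimum and degrades to linear", {
  set.seed(2)
  n <- 300
  x <- runif(n, 0, 10)
  z <- rnorm(n)
  f <- exp(-0.5 * ((x - 6.2) / 1.5)^2)
  y <- f + rnorm(n, 0, 0.05)
  m <- sdm_fit(cbind(x = x, z = z), y, method = "gam", family = "gaussian")
  xs <- seq(0, 10, length.out = 500)
  sc <- predict(m, cbind(x = xs, z = 0))
  expect_lt(abs(xs[which.max(sc)] - 6.2), 1)  # within 10% of the range
  # all-linear truth: GAM and GLM scores agree closely
  y2 <- 1 + 0.5 * x - 0.8 * z + rnorm(n, 0, 0.05)
  X <- cbind(x = x, z = z)
  g1 <- predict(sdm_fit(X, y2, method = "gam", family = "gaussian"), X)
  g2 <- predict(sdm_fit(X, y2, method = "glm", family = "gaussian"), X)
  expect_gt(stats::cor(g1, g2), 0.99)
  # permuting sample order leaves fitted scores unchanged
  p <- sample(n)
  g3 <- predict(sdm_fit(X[p, ], y2[p], method = "gam",
                        family = "gaussian"), X)
  expect_equal(g1, g3, tolerance = 1e-6)
  # few unique values fall back to a linear term with a warning
  Xq <- cbind(x = x, q = sample(0:3, n, replace = TRUE))
  expect_warning(sdm_fit(Xq, y2, method = "gam", family = "gaussian"),
                 "linear term")
})

test_that("random forest separates separable data deterministically", {
  set.seed(3)
  X <- rbind(cbind(a = rnorm(40, 0), b = rnorm(40, 0)),
             cbind(a = rnorm(40, 6), b = rnorm(40, 6)))
  y <- rep(c(0, 1), each = 40)
  m <- sdm_fit(X, y, method = "rf", mtry = 2, seed = 9)
  s <- predict(m, X)
  expect_gt(min(s[y == 1]), max(s[y == 0]))
  m2 <- sdm_fit(X, y, method = "rf", mtry = 2, seed = 9)
  expect_identical(predict(m2, X), s)
  expect_equal(m$fit$ntree, 500)
  # the default mtry = 10 clamps to the predictor count with a warning
  expect_warning(m3 <- sdm_fit(X, y, method = "rf", seed = 9),
                 "clamped to 2")
  expect_equal(m3$mtry, 2)
})

test_that("the SVM depends only on its support vectors", {
  set.seed(4)
  X <- rbind(cbind(a = rnorm(30, 0, 0.5), b = rnorm(30, 0, 0.5)),
             cbind(a = rnorm(30, 5, 0.5), b = rnorm(30, 5, 0.5)))
  y <- rep(c(0, 1), each = 30)
  m <- sdm_fit(X, y, method = "svm", seed = 1)
  s <- predict(m, X)
  # separable blobs: the sign threshold classifies the training set exactly
  expect_true(all((s > 0) == (y == 1)))
  # removing a non-support point changes no score beyond numerics; fit on
  # pre-standardized data with internal scaling off, so the kernel is not
  # perturbed by the refit's slightly different standardization constants
  Z <- scale(X); colnames(Z) <- colnames(X)
  mz <- sdm_fit(Z, y, method = "svm", seed = 1, scale = FALSE)
  sv <- mz$fit$index
  drop <- setdiff(seq_len(60), sv)[1]
  mz2 <- sdm_fit(Z[-drop, ], y[-drop], method = "svm", seed = 1,
                 scale = FALSE)
  cand <- cbind(a = seq(-2, 2, length.out = 20),
                b = seq(-2, 2, length.out = 20))
  expect_lt(max(abs(predict(mz, cand) - predict(mz2, cand))), 1e-6)
  expect_error(sdm_fit(X, rep(1, 60), method = "svm"), "both classes")
})

test_that("SVM scores are invariant to shifting a predictor", {
  set.seed(5)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  y <- as.integer(X[, "a"] + X[, "b"] + rnorm(50, 0, 0.3) > 0)
  m1 <- sdm_fit(X, y, method = "svm", seed = 2)
  Xs <- X; Xs[, "a"] <- Xs[, "a"] + 1000
  m2 <- sdm_fit(Xs, y, method = "svm", seed = 2)
  cand <- cbind(a = rnorm(15), b = rnorm(15))
  cands <- cand; cands[, "a"] <- cands[, "a"] + 1000
  expect_equal(predict(m1, cand), predict(m2, cands), tolerance = 1e-6)
})

test_that("prediction matches variables by name, not position", {
  set.seed(6)
  X <- cbind(a = rnorm(40), b = rnorm(40, 10))
  y <- as.integer(X[, "a"] > 0)
  for (meth in c("bioclim", "glm", "rf")) {
    m <- suppressWarnings(sdm_fit(X, y, method = meth, mtry = 2, seed = 1))
    s1 <- predict(m, X)
    s2 <- predict(m, X[, c("b", "a")])
    expect_equal(s1, s2)
    expect_error(predict(m, X[, "a", drop = FALSE]), "missing predictor")
  }
})

test_that("explicit-parameter models round-trip through JSON", {
  set.seed(7)
  X <- cbind(a = rnorm(25), b = runif(25, 3, 9))
  y <- as.integer(X[, "a"] + rnorm(25, 0, 0.5) > 0)
  cand <- cbind(a = rnorm(8), b = runif(8, 3, 9))
  for (meth in c("bioclim", "domain", "mahalanobis", "glm")) {
    m <- sdm_fit(X, y, method = meth)
    f <- tempfile(fileext = ".json")
    write_sdm(m, f)
    m2 <- read_sdm(f)
    expect_equal(predict(m2, cand), predict(m, cand), tolerance = 1e-8)
  }
  m <- sdm_fit(X, y, method = "rf", mtry = 2, seed = 1)
  expect_error(write_sdm(m, tempfile()), "serialize")
})
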