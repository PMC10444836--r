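test_that("confusion counts match a brute-force loop", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  for (t in c(-1, 0.05, 0.35, 0.5, 0.65, 0.85, 2)) {
    cm <- confusion_at_threshold(scores, labels, t)
    want <- oracle_confusion(scores, labels, t)
    expect_equal(cm[c("A", "B", "C", "D")], want)
  }
  set.seed(1)
  for (i in 1:100) {
    s <- runif(12); y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    t <- runif(1)
    expect_equal(confusion_at_threshold(s, y, t)[c("A", "B", "C", "D")],
                 oracle_confusion(s, y, t))
  }
  # perfect separation with a threshold between the groups
  cm <- confusion_at_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(cm$B + cm$C, 0L)
  # threshold below every score predicts everything positive
  cm2 <- confusion_at_threshold(scores, labels, -10)
  expect_equal(cm2$C, 3L); expect_equal(cm2$B, 0L)
  expect_error(confusion_at_threshold(1:3, c(1, 1, 1), 0.5), "at least one")
})

test_that("confusion rates follow the 2x2 formulas", {
  mk <- function(A, B, C, D) structure(list(A = A, B = B, C = C, D = D),
                                       class = "sdm_confusion")
  expect_equal(confusion_rates(mk(5, 0, 0, 5)),
               c(tpr = 1, fpr = 0, tnr = 1, acc = 1))
  expect_equal(confusion_rates(mk(0, 5, 5, 0)),
               c(tpr = 0, fpr = 1, tnr = 0, acc = 0))
  expect_equal(confusion_rates(mk(3, 1, 2, 4)),
               c(tpr = 0.75, fpr = 1 / 3, tnr = 2 / 3, acc = 0.7))
})

test_that("AUC equals the exhaustive pair count, with tie handling", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(2)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    # label inversion flips the AUC
    expect_equal(roc_auc(s, 1 - y), 1 - roc_auc(s, y), tolerance = 1e-12)
    # strictly increasing transforms leave the AUC unchanged
    expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(rank(s, ties.method = "average"), y),
                 roc_auc(s, y), tolerance = 1e-12)
  }
})

test_that("pair-count AUC equals the trapezoidal ROC area", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_auc(s, y), want, tolerance = 1e-10)
  }
})

test_that("threshold search equals full enumeration", {
  set.seed(4)
  for (i in 1:30) {
    s <- round(runif(10), 1)
    y <- rbinom(10, 1, 0.5)
    if (length(unique(y)) < 2) next
    bt <- best_threshold(s, y, criterion = "youden")
    # brute force over a dense threshold sweep
    cand <- sort(unique(c(s - 1e-6, s + 1e-6, min(s) - 1, max(s) + 1)))
    vals <- vapply(cand, function(t) {
      r <- confusion_rates(confusion_at_threshold(s, y, t))
      unname(r["tpr"] + r["tnr"] - 1)
    }, numeric(1))
    expect_equal(bt$youden, max(vals), tolerance = 1e-12)
  }
  # perfectly separated: Youden 1 anywhere between the classes
  bt <- best_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(bt$youden, 1)
  expect_true(bt$threshold > 0.2 && bt$threshold < 0.8)
  # the paper-literal criterion maximizes TPR + FPR, which peaks at
  # the all-positive classifier
  bt2 <- best_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                        criterion = "paper_literal")
  expect_equal(bt2$paper_style_sum, 2)
})

test_that("random labels give a Youden index near zero", {
  set.seed(5)
  n <- 400
  s <- runif(n)
  perm <- replicate(200, {
    y <- sample(rep(c(0, 1), each = n / 2))
    best_threshold(s, y)$youden
  })
  # with no signal the optimized index collapses toward 0 (small positive
  # optimism bias only): every permutation draw stays within 3 SD of the
  # permutation mean, and the mean itself is near zero
  obs <- best_threshold(s, sample(rep(c(0, 1), each = n / 2)))$youden
  expect_lt(abs(obs - mean(perm)), 3 * stats::sd(perm))
  expect_lt(mean(perm), 0.2)
})

test_that("AUC ratings band as printed, boundaries to the lower band", {
  expect_equal(rate_auc(0.95), "excellent")
  expect_equal(rate_auc(0.80), "fair")
  expect_equal(rate_auc(0.65), "poor")
  expect_equal(rate_auc(0.9), "fair")
  expect_equal(rate_auc(0.7), "poor")
  expect_error(rate_auc(1.2), "\\[0, 1\\]")
})

test_that("repeated evaluation has the Table-1 shape and is deterministic", {
  sc <- paper_scenario()
  pres <- scenario_presence(sc)
  tab <- suppressWarnings(
    repeated_evaluation(sc$stack, pres, methods = c("bioclim", "glm"),
                        n_runs = 3, seed = 77))
  expect_s3_class(tab, "sdm_eval")
  expect_equal(nrow(tab), 3 * 2 + 2)
  expect_equal(sum(tab$run == "mean"), 2L)
  means <- tab[tab$run == "mean", ]
  runs <- tab[tab$run != "mean", ]
  for (m in c("bioclim", "glm"))
    expect_equal(means$auc[means$model == m],
                 mean(runs$auc[runs$model == m]), tolerance = 1e-12)
  tab2 <- suppressWarnings(
    repeated_evaluation(sc$stack, pres, methods = c("bioclim", "glm"),
                        n_runs = 3, seed = 77))
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  f <- tempfile(fileext = ".csv")
  write_eval(tab, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(tab))
})
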