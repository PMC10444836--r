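#' Confusion matrix at a score threshold
#'
#' Predicted presence iff `score >= t`. Counts follow the usual 2x2 layout:
#' A = true positives, B = false negatives, C = false positives, D = true
#' negatives.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 observed labels (1 = presence).
#' @param t threshold.
#' @return An object of class `sdm_confusion`: list with integer fields
#'   `A`, `B`, `C`, `D`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  check_labels(labels)
  pred <- scores >= t
  structure(list(A = sum(pred & labels == 1),
                 B = sum(!pred & labels == 1),
                 C = sum(pred & labels == 0),
                 D = sum(!pred & labels == 0)),
            class = "sdm_confusion")
}

#' @export
print.sdm_confusion <- function(x, ...) {
  cat(sprintf("confusion: TP %d, FN %d, FP %d, TN %d\n", x$A, x$B, x$C, x$D))
  invisible(x)
}

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("need at least one presence and one background label",
         call. = FALSE)
  invisible(labels)
}

#' Rates from a confusion matrix
#'
#' TPR (sensitivity) = A/(A+B); FPR = C/(C+D); TNR (specificity) = 1 - FPR;
#' ACC = (A+D)/(A+B+C+D).
#'
#' @param cm an `sdm_confusion` from [confusion_at_threshold()].
#' @return Named numeric vector `tpr`, `fpr`, `tnr`, `acc`.
#' @export
confusion_rates <- function(cm) {
  stopifnot(inherits(cm, "sdm_confusion"))
  P <- cm$A + cm$B; N <- cm$C + cm$D
  if (P == 0 || N == 0)
    stop("both classes must be present", call. = FALSE)
  tpr <- cm$A / P; fpr <- cm$C / N
  c(tpr = tpr, fpr = fpr, tnr = 1 - fpr,
    acc = (cm$A + cm$D) / (P + N))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (presence, background) pairs in
#' which the presence scores higher, ties counted one half. Computed from
#' midranks, so it is exact under ties and invariant to any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 observed labels.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  check_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pick the best classification threshold
#'
#' Scans every midpoint between consecutive distinct scores, plus one
#' candidate below all scores and one above, and returns the threshold
#' maximizing the chosen criterion:
#' \describe{
#'   \item{`youden`}{Youden's J = TPR + TNR - 1, the standard reading of
#'     "maximize sensitivity plus specificity".}
#'   \item{`paper_literal`}{TPR + FPR, i.e. the sum with the second term
#'     taken literally from the false-positive-rate formula `C/(C+D)` that
#'     some studies print under the name TNR; provided for comparability.}
#' }
#' Ties in the criterion resolve to the lowest threshold (the more
#' sensitive classifier).
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 observed labels.
#' @param criterion `"youden"` (default) or `"paper_literal"`.
#' @return A list: `threshold`, `tpr`, `fpr`, `tnr`, `youden`
#'   (TPR + TNR - 1), `paper_style_sum` (TPR + FPR), `criterion`.
#' @export
best_threshold <- function(scores, labels,
                           criterion = c("youden", "paper_literal")) {
  criterion <- match.arg(criterion)
  check_labels(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL; best_val <- -Inf
  for (t in cand) {
    r <- confusion_rates(confusion_at_threshold(scores, labels, t))
    val <- if (criterion == "youden") r["tpr"] + r["tnr"] - 1
           else r["tpr"] + r["fpr"]
    if (val > best_val + 1e-12) {
      best_val <- val
      best <- list(threshold = t, tpr = unname(r["tpr"]),
                   fpr = unname(r["fpr"]), tnr = unname(r["tnr"]),
                   youden = unname(r["tpr"] + r["tnr"] - 1),
                   paper_style_sum = unname(r["tpr"] + r["fpr"]))
    }
  }
  c(best, list(criterion = criterion))
}

#' Verbal accuracy rating of an AUC
#'
#' The conventional bands: excellent for AUC > 0.9, fair for
#' 0.7 < AUC < 0.9, poor for AUC < 0.7 (strict inequalities; the boundary
#' values 0.9 and 0.7 fall into the lower band).
#'
#' @param auc AUC value in [0, 1].
#' @return `"excellent"`, `"fair"` or `"poor"`.
#' @export
rate_auc <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1L || is.na(auc) ||
      auc < 0 || auc > 1)
    stop("'auc' must be a single value in [0, 1]", call. = FALSE)
  if (auc > 0.9) "excellent" else if (auc > 0.7) "fair" else "poor"
}

all_sdm_methods <- function() c("bioclim", "domain", "mahalanobis",
                                "glm", "gam", "rf", "svm")

# Per-stage seed derivation: offsets by run number and by the method's index
# in the canonical list, so adding/removing a method never shifts the
# randomness of the others.
derive_seed <- function(master, run, stage = 0L) {
  (as.integer(master) + 1009L * as.integer(run) + 17L * as.integer(stage)) %%
    .Machine$integer.max
}

#' Repeated cross-validated model comparison
#'
#' The evaluation protocol for comparing the seven algorithms on one
#' presence set: for each of `n_runs` runs, draw a fresh background sample
#' of `n_background` cells, split presences + background into `k`
#' stratified folds, and for each fold train on the remaining folds and
#' score the held-out rows. Profile models train on the training-fold
#' presences only; supervised models on training-fold presences plus
#' background. AUC and the optimal-threshold rates are computed on each
#' held-out fold and averaged within the run, giving one record per model
#' and run plus a per-model mean row.
#'
#' A model failure in a run is recorded as `NA` with the reason attached
#' (attribute `failures`), never silently dropped.
#'
#' @param stack a `predictor_stack`.
#' @param presence data frame of presence cells (`row`, `col`).
#' @param methods character vector of model names (default all seven).
#' @param n_background background cells per run.
#' @param k number of cross-validation folds.
#' @param n_runs number of repeated runs.
#' @param seed master seed; every random draw derives from it.
#' @param criterion threshold criterion passed to [best_threshold()].
#' @param stratified stratify folds by label (default) or not.
#' @return An object of class `sdm_eval`: a data frame with columns `run`
#'   (1..n_runs, then `"mean"`), `model`, `auc`, `tpr`, `fpr`, `tnr`,
#'   `youden`, `paper_style_sum`, `threshold`.
#' @export
repeated_evaluation <- function(stack, presence,
                                methods = all_sdm_methods(),
                                n_background = 100, k = 5, n_runs = 10,
                                seed = 1, criterion = "youden",
                                stratified = TRUE) {
  stopifnot(inherits(stack, "predictor_stack"))
  methods <- match.arg(methods, all_sdm_methods(), several.ok = TRUE)
  canon <- all_sdm_methods()
  grid <- stack[[1L]]
  rows <- list(); failures <- list()
  for (run in seq_len(n_runs)) {
    bg <- sample_background(grid, presence, n = n_background,
                            seed = derive_seed(seed, run, 1L))
    os <- occurrence_set(presence, bg, stack)
    folds <- kfold_partition(length(os$y), k = k,
                             seed = derive_seed(seed, run, 2L),
                             labels = if (stratified) os$y else NULL)
    for (m in methods) {
      mseed <- derive_seed(seed, run, 10L + match(m, canon))
      fold_metrics <- matrix(NA_real_, k, 7L)
      err <- NULL
      for (f in seq_len(k)) {
        res <- tryCatch({
          tr <- folds != f; te <- folds == f
          fit <- sdm_fit(os$X[tr, , drop = FALSE], os$y[tr], method = m,
                         mtry = min(10, ncol(os$X)), seed = mseed)
          sc <- predict(fit, os$X[te, , drop = FALSE])
          bt <- best_threshold(sc, os$y[te], criterion = criterion)
          c(roc_auc(sc, os$y[te]), bt$tpr, bt$fpr, bt$tnr, bt$youden,
            bt$paper_style_sum, bt$threshold)
        }, error = function(e) e)
        if (inherits(res, "error")) { err <- conditionMessage(res); break }
        fold_metrics[f, ] <- res
      }
      if (is.null(err)) {
        v <- colMeans(fold_metrics)
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, model = m, auc = v[1], tpr = v[2], fpr = v[3],
          tnr = v[4], youden = v[5], paper_style_sum = v[6],
          threshold = v[7], stringsAsFactors = FALSE)
      } else {
        failures[[length(failures) + 1L]] <-
          list(run = run, model = m, reason = err)
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, model = m, auc = NA_real_, tpr = NA_real_,
          fpr = NA_real_, tnr = NA_real_, youden = NA_real_,
          paper_style_sum = NA_real_, threshold = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(methods, function(m) {
    sub <- tab[tab$model == m, ]
    data.frame(run = "mean", model = m,
               auc = mean(sub$auc, na.rm = TRUE),
               tpr = mean(sub$tpr, na.rm = TRUE),
               fpr = mean(sub$fpr, na.rm = TRUE),
               tnr = mean(sub$tnr, na.rm = TRUE),
               youden = mean(sub$youden, na.rm = TRUE),
               paper_style_sum = mean(sub$paper_style_sum, na.rm = TRUE),
               threshold = NA_real_, stringsAsFactors = FALSE)
  }))
  tab$run <- as.character(tab$run)
  out <- rbind(tab, means)
  rownames(out) <- NULL
  structure(out, failures = failures, seed = seed,
            class = c("sdm_eval", "data.frame"))
}

#' @export
print.sdm_eval <- function(x, ...) {
  means <- x[x$run == "mean", c("model", "auc", "tpr", "tnr", "youden")]
  n_runs <- sum(x$run != "mean") / max(1L, nrow(means))
  cat(sprintf("sdm_eval: %d models x %d runs\n", nrow(means), n_runs))
  means$rating <- vapply(means$auc, rate_auc, character(1))
  print.data.frame(means[order(-means$auc), ], row.names = FALSE, digits = 4)
  fl <- attr(x, "failures")
  if (length(fl)) cat(length(fl), "model-run failure(s); see attr(x, 'failures')\n")
  invisible(x)
}

#' @export
plot.sdm_eval <- function(x, ...) {
  runs <- x[x$run != "mean" & !is.na(x$auc), ]
  graphics::boxplot(auc ~ model, data = runs, ylab = "AUC",
                    xlab = "", las = 2, ...)
  graphics::abline(h = 0.7, lty = 3)
  invisible(x)
}

#' Write an evaluation table to delimited text
#'
#' @param x an `sdm_eval` table.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_eval <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
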