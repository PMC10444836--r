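#' Run the full fine-scale SDM workflow
#'
#' End-to-end pipeline from a DEM and an occurrence table to evaluated
#' models and habitat maps: (1) optionally block-aggregate the DEM to the
#' analysis resolution; (2) derive the aspect/dem/profile/slope predictor
#' stack; (3) screen predictors by VIF; (4) clean occurrences onto the
#' grid; (5) run the repeated cross-validated model comparison; (6) refit
#' every requested model on the full design, map suitability (min-max
#' rescaled to [0, 1]), classify habitat bands and summarize areas; (7)
#' compute per-predictor response curves for every model. Every random
#' draw derives from `seed`.
#'
#' @param dem a [raster_grid()] of elevations, or a path to an ESRI ASCII
#'   file.
#' @param occurrences data frame with `x`, `y` columns, or a path to a
#'   delimited file readable by [read_occurrences()].
#' @param boundary optional polygon ring (two-column matrix) bounding the
#'   study area.
#' @param methods model names to run (default all seven).
#' @param resample_factor block-aggregation factor applied to the DEM
#'   before analysis (1 = none).
#' @param vif_threshold collinearity threshold for [vif_screen()]; screened
#'   predictors are dropped from modelling.
#' @param n_background,k,n_runs,criterion evaluation settings, see
#'   [repeated_evaluation()].
#' @param shi_thresholds habitat-classification bands for [classify_shi()].
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, writes predictor rasters,
#'   the VIF report, the evaluation table, per-model suitability and class
#'   maps, response curves and a JSON run log there.
#' @return An object of class `sdm_pipeline`: list with `stack`, `vif`,
#'   `presence`, `evaluation`, `models`, `maps` (per-model suitability
#'   rasters), `shi` (per-model `shi_class`), `curves` (per-model list of
#'   `sdm_response`), `best_model` (name with highest mean AUC), `seed`.
#' @examples
#' \donttest{
#' sc <- simulate_scenario(rows = 40, cols = 40, n_presence = 30, seed = 2)
#' res <- run_pipeline(sc$dem, sc$occurrences, methods = c("bioclim", "glm"),
#'                     n_background = 50, n_runs = 2, seed = 2)
#' res$evaluation
#' }
#' @export
run_pipeline <- function(dem, occurrences, boundary = NULL,
                         methods = all_sdm_methods(),
                         resample_factor = 1, vif_threshold = 10,
                         n_background = 100, k = 5, n_runs = 10,
                         criterion = "youden",
                         shi_thresholds = c(0.3, 0.5),
                         seed = 1, out_dir = NULL) {
  if (is.character(dem)) dem <- read_raster(dem)
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  methods <- match.arg(methods, all_sdm_methods(), several.ok = TRUE)
  if (resample_factor > 1)
    dem <- aggregate_raster(dem, resample_factor, "mean")
  stack <- terrain_stack(dem)

  M <- stack_matrix(stack)
  M <- M[rowSums(is.na(M)) == 0, , drop = FALSE]
  vif <- vif_screen(M, threshold = vif_threshold)
  kept <- vif$predictor[vif$kept]
  if (length(kept) < ncol(M))
    message("VIF screening dropped: ",
            paste(setdiff(colnames(M), kept), collapse = ", "))
  stack_model <- stack[kept]

  presence <- clean_occurrences(occurrences, stack_model[[1L]], boundary)
  if (nrow(presence) < 3L)
    stop("fewer than 3 presence cells after cleaning", call. = FALSE)

  evaluation <- repeated_evaluation(stack_model, presence, methods = methods,
                                    n_background = n_background, k = k,
                                    n_runs = n_runs, seed = seed,
                                    criterion = criterion)
  means <- evaluation[evaluation$run == "mean", ]
  best_model <- means$model[which.max(means$auc)]

  bg <- sample_background(stack_model[[1L]], presence, n = n_background,
                          seed = derive_seed(seed, 0L, 99L))
  os <- occurrence_set(presence, bg, stack_model)
  models <- list(); maps <- list(); shi <- list(); curves <- list()
  for (m in methods) {
    fit <- sdm_fit(os$X, os$y, method = m,
                   mtry = min(10, ncol(os$X)),
                   seed = derive_seed(seed, 0L, match(m, all_sdm_methods())))
    models[[m]] <- fit
    maps[[m]] <- predict_map(fit, stack_model, rescale = "minmax")
    shi[[m]] <- classify_shi(maps[[m]], shi_thresholds[1], shi_thresholds[2],
                             clamp = TRUE)
    curves[[m]] <- lapply(stats::setNames(nm = names(stack_model)),
                          function(p) response_curve(fit, stack_model, p))
  }

  res <- structure(list(stack = stack, vif = vif, presence = presence,
                        evaluation = evaluation, models = models,
                        maps = maps, shi = shi, curves = curves,
                        best_model = best_model, seed = seed),
                   class = "sdm_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$stack))
    write_raster(res$stack[[nm]], file.path(out_dir, paste0(nm, ".asc")))
  utils::write.csv(as.data.frame(res$vif),
                   file.path(out_dir, "vif_report.csv"), row.names = FALSE)
  utils::write.csv(res$presence, file.path(out_dir, "presence_cells.csv"),
                   row.names = FALSE)
  write_eval(res$evaluation, file.path(out_dir, "evaluation.csv"))
  for (m in names(res$maps)) {
    write_raster(res$maps[[m]],
                 file.path(out_dir, paste0("suitability_", m, ".asc")))
    write_raster(res$shi[[m]]$classes,
                 file.path(out_dir, paste0("shi_", m, ".asc")))
    for (p in names(res$curves[[m]]))
      utils::write.table(res$curves[[m]][[p]],
                         file.path(out_dir,
                                   paste0("response_", m, "_", p, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  areas <- lapply(res$shi, function(s) s$areas)
  jsonlite::write_json(
    list(seed = res$seed, best_model = res$best_model,
         class_codes = list(unsuitable = 0, low_suitable = 1, suitable = 2),
         areas = areas),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.sdm_pipeline <- function(x, ...) {
  cat("sdm_pipeline (seed ", x$seed, ")\n", sep = "")
  cat("  presences: ", nrow(x$presence), "\n", sep = "")
  cat("  best model by mean AUC: ", x$best_model, "\n", sep = "")
  print(x$evaluation)
  invisible(x)
}
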