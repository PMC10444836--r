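#' Map a fitted SDM over a predictor stack
#'
#' Scores every valid cell of the stack with the model, propagating nodata.
#' `rescale = "minmax"` linearly maps the valid scores to [0, 1], which is
#' required before habitat classification for scorers that are not
#' probabilities (gaussian-family GLM, raw Domain similarity, SVM decision
#' values); rank-based metrics such as AUC are unaffected by the choice.
#'
#' @param model a fitted `"sdm"`.
#' @param stack a `predictor_stack` covering the model's training variables
#'   (matched by name).
#' @param rescale `"none"` (default) or `"minmax"`.
#' @param type,clamp passed to [predict.sdm()].
#' @return A suitability [raster_grid()].
#' @export
predict_map <- function(model, stack, rescale = c("none", "minmax"),
                        type = "score", clamp = FALSE) {
  stopifnot(inherits(model, "sdm"), inherits(stack, "predictor_stack"))
  rescale <- match.arg(rescale)
  miss <- setdiff(model$vars, names(stack))
  if (length(miss))
    stop("stack is missing model variable '", miss[1], "'", call. = FALSE)
  ref <- stack[[1L]]
  M <- stack_matrix(stack)[, model$vars, drop = FALSE]
  ok <- rowSums(is.na(M)) == 0
  out <- rep(NA_real_, nrow(M))
  if (any(ok))
    out[ok] <- predict(model, M[ok, , drop = FALSE], type = type,
                       clamp = clamp)
  if (rescale == "minmax" && any(ok)) {
    rng <- range(out[ok])
    out[ok] <- if (rng[2] > rng[1]) (out[ok] - rng[1]) / (rng[2] - rng[1])
               else 0
  }
  raster_grid(matrix(out, nrow(ref$values), ncol(ref$values)),
              xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              crs = ref$crs)
}

#' Classify a suitability map into habitat bands
#'
#' Three-band suitable-habitat-index classification: unsuitable for values
#' at or below `t_low`, low suitable above `t_low` up to and including
#' `t_high`, suitable above `t_high` (default bands 0.3 and 0.5, boundary
#' values falling into the lower band as the inequalities state).
#'
#' @param suitability a [raster_grid()] with values in [0, 1].
#' @param t_low,t_high band thresholds, `t_low < t_high`.
#' @param clamp truncate values outside [0, 1] (numerical dust) instead of
#'   erroring.
#' @return An object of class `shi_class`: list with `classes` (a
#'   [raster_grid()] coded 0 = unsuitable, 1 = low suitable, 2 = suitable),
#'   `thresholds`, and `areas` (the [area_summary()] data frame).
#' @export
classify_shi <- function(suitability, t_low = 0.3, t_high = 0.5,
                         clamp = FALSE) {
  stop_if_not_grid(suitability)
  if (t_low >= t_high) stop("'t_low' must be below 't_high'", call. = FALSE)
  v <- suitability$values
  if (clamp) v <- pmin(pmax(v, 0), 1)
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("suitability values outside [0, 1]; rescale first or use clamp",
         call. = FALSE)
  cls <- ifelse(v > t_high, 2, ifelse(v > t_low, 1, 0))
  cls[!ok] <- NA_real_
  grid <- raster_grid(cls, xll = suitability$xll, yll = suitability$yll,
                      cellsize = suitability$cellsize, crs = suitability$crs)
  out <- structure(list(classes = grid,
                        thresholds = c(t_low = t_low, t_high = t_high)),
                   class = "shi_class")
  out$areas <- area_summary(out)
  out
}

#' Habitat areas per suitability class
#'
#' Cell counts and areas (cell count times cell size squared) per class,
#' with percentages of the total valid area.
#'
#' @param classification a `shi_class` from [classify_shi()].
#' @return Data frame with columns `class`, `code`, `cells`, `area_m2`,
#'   `pct`.
#' @export
area_summary <- function(classification) {
  stopifnot(inherits(classification, "shi_class"))
  g <- classification$classes
  cell_area <- g$cellsize^2
  codes <- c(unsuitable = 0, low_suitable = 1, suitable = 2)
  cells <- vapply(codes, function(k) sum(g$values == k, na.rm = TRUE),
                  numeric(1))
  total <- sum(cells)
  data.frame(class = names(codes), code = unname(codes),
             cells = unname(cells), area_m2 = unname(cells) * cell_area,
             pct = if (total > 0) unname(cells) / total * 100 else
               rep(NA_real_, 3),
             stringsAsFactors = FALSE)
}

#' @export
print.shi_class <- function(x, ...) {
  cat(sprintf("shi_class (thresholds %g / %g):\n", x$thresholds[1],
              x$thresholds[2]))
  print.data.frame(x$areas, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Single-predictor response curve of a fitted SDM
#'
#' Sweeps one predictor across its observed range (or `from`/`to`) while
#' holding the others fixed — at their valid-cell medians by default, or at
#' the presence means — and records the model score at each value. This is
#' the "driven factor" analysis: the curve's argmax locates the modelled
#' optimum of that predictor.
#'
#' @param model a fitted `"sdm"`.
#' @param stack a `predictor_stack`.
#' @param predictor name of the predictor to sweep.
#' @param n_points number of evaluation points (strictly increasing grid).
#' @param fixing `"median"` (default) or `"presence_mean"`.
#' @param presence presence cells (`row`, `col`), required for
#'   `fixing = "presence_mean"`.
#' @param from,to optional sweep limits overriding the observed range.
#' @return An object of class `sdm_response`: data frame with columns
#'   `value` and `score`, attributes `predictor` and `fixed`.
#' @export
response_curve <- function(model, stack, predictor, n_points = 100,
                           fixing = c("median", "presence_mean"),
                           presence = NULL, from = NULL, to = NULL) {
  stopifnot(inherits(model, "sdm"), inherits(stack, "predictor_stack"))
  fixing <- match.arg(fixing)
  if (!predictor %in% names(stack))
    stop("unknown predictor '", predictor, "'", call. = FALSE)
  M <- stack_matrix(stack)
  M <- M[rowSums(is.na(M)) == 0, , drop = FALSE]
  if (fixing == "median") {
    fixed <- apply(M, 2, stats::median)
  } else {
    if (is.null(presence))
      stop("fixing = \"presence_mean\" needs presence cells", call. = FALSE)
    P <- extract_predictors(presence, stack)
    fixed <- colMeans(P)
  }
  rng <- range(M[, predictor])
  xs <- seq(from %||% rng[1], to %||% rng[2], length.out = n_points)
  X <- matrix(rep(fixed, each = n_points), n_points,
              dimnames = list(NULL, colnames(M)))
  X[, predictor] <- xs
  sc <- predict(model, X[, model$vars, drop = FALSE])
  structure(data.frame(value = xs, score = sc),
            predictor = predictor, fixed = fixed[setdiff(colnames(M),
                                                         predictor)],
            class = c("sdm_response", "data.frame"))
}

#' Location of a response curve's maximum
#'
#' The predictor value at which the curve peaks; across a plateau of tied
#' maxima (piecewise-constant learners) the plateau midpoint is returned.
#'
#' @param curve an `sdm_response` from [response_curve()].
#' @param tol scores within `tol` of the maximum count as tied.
#' @return A single predictor value.
#' @export
curve_argmax <- function(curve, tol = 1e-9) {
  stopifnot(inherits(curve, "sdm_response"))
  top <- curve$value[curve$score >= max(curve$score) - tol]
  mean(range(top))
}

#' @export
plot.sdm_response <- function(x, ...) {
  graphics::plot(x$value, x$score, type = "l",
                 xlab = attr(x, "predictor"), ylab = "score", ...)
  invisible(x)
}
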