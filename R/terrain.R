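#' Topographic derivatives of a DEM
#'
#' Slope and aspect use Horn's (1981) 3x3 finite-difference gradients, the
#' algorithm implemented by mainstream GIS software; profile curvature uses
#' the Zevenbergen & Thorne (1987) quadratic fit. Border cells and any cell
#' with a nodata neighbour in its 3x3 window are set to nodata, since the
#' kernels are undefined there.
#'
#' Conventions:
#' \itemize{
#'   \item `terrain_slope`: degrees from horizontal, 0 = flat.
#'   \item `terrain_aspect`: downslope azimuth in degrees clockwise from
#'     north (0 = north, 90 = east). Flat cells, where the azimuth is
#'     undefined, get the sentinel value `flat_value` (default -1, the
#'     common GIS convention); pass `flat_value = NA` to mask them instead.
#'   \item `profile_curvature`: curvature of the surface along the direction
#'     of maximum slope, expressed per 100 m. Positive values are concave
#'     (upward-curving along the slope line, decelerating flow), negative
#'     values convex; every planar surface has profile curvature exactly 0.
#'     Cells with zero gradient have no slope direction and are reported
#'     as 0.
#' }
#'
#' @param dem a [raster_grid()] of elevations in metres, cell size in metres.
#' @param flat_value value assigned to flat cells by `terrain_aspect`.
#' @return A [raster_grid()] with the same geometry as `dem`.
#' @references Horn, B.K.P. (1981) Hill shading and the reflectance map.
#'   Proceedings of the IEEE 69(1), 14-47. Zevenbergen, L.W. & Thorne, C.R.
#'   (1987) Quantitative analysis of land surface topography. Earth Surface
#'   Processes and Landforms 12, 47-56.
#' @name terrain
NULL

# 3x3 neighbour matrices of the interior; z[[k]] follows the keypad layout
#   z1 z2 z3     (z1 = NW, z2 = N, ..., row 1 of the grid is north)
#   z4 z5 z6
#   z7 z8 z9
neighbourhood <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L)
    stop("DEM must be at least 3 x 3", call. = FALSE)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  list(z1 = m[ri - 1L, ci - 1L], z2 = m[ri - 1L, ci], z3 = m[ri - 1L, ci + 1L],
       z4 = m[ri, ci - 1L],      z5 = m[ri, ci],      z6 = m[ri, ci + 1L],
       z7 = m[ri + 1L, ci - 1L], z8 = m[ri + 1L, ci], z9 = m[ri + 1L, ci + 1L])
}

horn_gradients <- function(dem) {
  z <- neighbourhood(dem$values)
  L <- dem$cellsize
  # dz/dx: east minus west; dz/dy: north minus south (y increases north)
  p <- ((z$z3 + 2 * z$z6 + z$z9) - (z$z1 + 2 * z$z4 + z$z7)) / (8 * L)
  q <- ((z$z1 + 2 * z$z2 + z$z3) - (z$z7 + 2 * z$z8 + z$z9)) / (8 * L)
  list(p = p, q = q)
}

pad_interior <- function(dem, inner) {
  out <- matrix(NA_real_, nrow(dem$values), ncol(dem$values))
  out[2:(nrow(out) - 1L), 2:(ncol(out) - 1L)] <- inner
  raster_grid(out, xll = dem$xll, yll = dem$yll, cellsize = dem$cellsize,
              crs = dem$crs)
}

#' @rdname terrain
#' @export
terrain_slope <- function(dem) {
  stop_if_not_grid(dem)
  g <- horn_gradients(dem)
  pad_interior(dem, atan(sqrt(g$p^2 + g$q^2)) * 180 / pi)
}

#' @rdname terrain
#' @export
terrain_aspect <- function(dem, flat_value = -1) {
  stop_if_not_grid(dem)
  g <- horn_gradients(dem)
  # downslope direction is -(p, q) in (east, north); azimuth clockwise from N
  az <- atan2(-g$p, -g$q) * 180 / pi
  az <- (az + 360) %% 360
  flat <- !is.na(g$p) & g$p == 0 & g$q == 0
  az[flat] <- flat_value
  pad_interior(dem, az)
}

#' @rdname terrain
#' @export
profile_curvature <- function(dem) {
  stop_if_not_grid(dem)
  z <- neighbourhood(dem$values)
  L <- dem$cellsize
  # Zevenbergen-Thorne quadratic coefficients
  D <- ((z$z4 + z$z6) / 2 - z$z5) / L^2
  E <- ((z$z2 + z$z8) / 2 - z$z5) / L^2
  F <- (-z$z1 + z$z3 + z$z7 - z$z9) / (4 * L^2)
  G <- (-z$z4 + z$z6) / (2 * L)
  H <- (z$z2 - z$z8) / (2 * L)
  g2 <- G^2 + H^2
  prof <- 200 * (D * G^2 + E * H^2 + F * G * H) / g2
  prof[!is.na(g2) & g2 == 0] <- 0
  pad_interior(dem, prof)
}

#' Derive the standard predictor stack from a DEM
#'
#' Convenience wrapper producing the four-layer predictor stack used by the
#' modelling pipeline: `aspect`, `dem`, `profile`, `slope`. Aspect sentinel
#' cells (flat terrain) are masked to nodata by default, since a downslope
#' azimuth is undefined there and the models treat aspect as a numeric
#' covariate.
#'
#' @param dem a [raster_grid()] of elevations.
#' @param aspect_flat how flat cells enter the stack: `"na"` masks them,
#'   `"sentinel"` keeps the -1 sentinel as a value.
#' @return A `predictor_stack` with layers aspect, dem, profile, slope.
#' @export
terrain_stack <- function(dem, aspect_flat = c("na", "sentinel")) {
  aspect_flat <- match.arg(aspect_flat)
  fv <- if (aspect_flat == "na") NA_real_ else -1
  align_stack(list(aspect = terrain_aspect(dem, flat_value = fv),
                   dem = dem,
                   profile = profile_curvature(dem),
                   slope = terrain_slope(dem)))
}

#' Screen predictors for collinearity by variance inflation factors
#'
#' The VIF of predictor j is `1 / (1 - R^2_j)` where `R^2_j` comes from the
#' least-squares regression of predictor j on all the others. Predictors are
#' dropped one at a time — the largest VIF above the threshold first, ties
#' broken by dropping the alphabetically later name — until every remaining
#' VIF is at or below the threshold. Constant (zero-variance) predictors have
#' infinite VIF and are removed first.
#'
#' @param samples numeric matrix or data frame, one column per predictor.
#' @param threshold VIF above which a predictor is considered collinear;
#'   10 is the customary cut-off.
#' @return An object of class `vif_report`: a data frame with one row per
#'   predictor (`predictor`, `vif` at the iteration it was last evaluated,
#'   `kept`, `drop_order`), plus attributes `threshold` and `history`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' vif_screen(x)
#' @export
vif_screen <- function(samples, threshold = 10) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (nrow(x) < ncol(x) + 2L)
    stop("need at least n_predictors + 2 samples", call. = FALSE)
  vif_one <- function(j, cols) {
    xj <- x[, cols[j]]
    if (stats::var(xj) == 0) return(Inf)
    others <- x[, cols[-j], drop = FALSE]
    if (ncol(others) == 0L) return(1)
    fit <- stats::lm.fit(cbind(1, others), xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1) Inf else 1 / (1 - r2)
  }
  kept <- sort(colnames(x))
  dropped <- character(0)
  history <- list()
  last_vif <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  repeat {
    v <- vapply(seq_along(kept), vif_one, numeric(1), cols = kept)
    names(v) <- kept
    history[[length(history) + 1L]] <- v
    last_vif[kept] <- v
    if (length(kept) <= 1L || all(v <= threshold)) break
    worst <- v[v > threshold]
    # largest VIF first; on ties, the alphabetically later name
    cand <- names(worst)[worst == max(worst)]
    drop <- sort(cand, decreasing = TRUE)[1L]
    if (is.infinite(max(worst)))
      warning("predictor '", drop,
              "' is constant or exactly collinear (infinite VIF); dropped",
              call. = FALSE)
    kept <- setdiff(kept, drop)
    dropped <- c(dropped, drop)
  }
  out <- data.frame(predictor = colnames(x),
                    vif = unname(last_vif[colnames(x)]),
                    kept = colnames(x) %in% kept,
                    drop_order = match(colnames(x), dropped),
                    stringsAsFactors = FALSE)
  structure(out, threshold = threshold, history = history,
            class = c("vif_report", "data.frame"))
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screening (threshold ", attr(x, "threshold"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
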