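#' Virtual species niche specification
#'
#' Describes how occurrence probability responds to the four topographic
#' predictors. Each response maps its predictor to [0, 1]; the combined
#' suitability is their product times `base_rate` (limiting-factor logic:
#' any unsuitable factor suppresses the cell).
#'
#' Response forms:
#' \itemize{
#'   \item elevation: Gaussian, `exp(-0.5 ((z - elev_opt)/elev_sd)^2)`.
#'   \item aspect: cosine southness,
#'     `(((1 + cos(aspect - aspect_pref)) / 2)^aspect_strength`; flat-cell
#'     sentinel values (< 0) get the neutral response 0.5.
#'   \item slope: logistic plateau-decay,
#'     `1 / (1 + exp(slope_decay * (s - slope_max)))` — near 1 on gentle
#'     slopes, 0.5 at `slope_max`, decaying beyond.
#'   \item profile curvature: Gaussian centred at `profile_opt`.
#' }
#'
#' The defaults encode a shrub of gently sloping, south-facing dune flats
#' with a steep elevation response: optimum 1010 m (sd 0.5 m), preferred
#' azimuth 180 degrees (sharpness 2, a clear southern preference), suitable slopes up to 20 degrees, and near-zero
#' profile curvature.
#'
#' @param elev_opt,elev_sd optimum and breadth of the elevation response (m).
#' @param aspect_pref,aspect_strength preferred downslope azimuth (degrees)
#'   and sharpness exponent of the aspect response.
#' @param slope_max,slope_decay slope (degrees) at which suitability has
#'   dropped to one half, and logistic decay rate (per degree).
#' @param profile_opt,profile_sd optimum and breadth of the profile-curvature
#'   response (per 100 m).
#' @param base_rate overall probability scaling in (0, 1].
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(elev_opt = 1010, elev_sd = 0.5,
                       aspect_pref = 180, aspect_strength = 2,
                       slope_max = 20, slope_decay = 0.5,
                       profile_opt = 0, profile_sd = 0.5,
                       base_rate = 1) {
  if (elev_sd <= 0 || profile_sd <= 0 || slope_decay <= 0)
    stop("response breadths and decay rates must be positive", call. = FALSE)
  if (base_rate < 0 || base_rate > 1)
    stop("'base_rate' must be in [0, 1]", call. = FALSE)
  structure(list(elev_opt = elev_opt, elev_sd = elev_sd,
                 aspect_pref = aspect_pref, aspect_strength = aspect_strength,
                 slope_max = slope_max, slope_decay = slope_decay,
                 profile_opt = profile_opt, profile_sd = profile_sd,
                 base_rate = base_rate),
            class = "niche_spec")
}

#' @export
print.niche_spec <- function(x, ...) {
  cat("niche_spec:\n")
  cat(sprintf("  elevation: Gaussian(opt %g m, sd %g m)\n", x$elev_opt, x$elev_sd))
  cat(sprintf("  aspect:    southness(pref %g deg, power %g)\n",
              x$aspect_pref, x$aspect_strength))
  cat(sprintf("  slope:     plateau to %g deg, decay %g/deg\n",
              x$slope_max, x$slope_decay))
  cat(sprintf("  profile:   Gaussian(opt %g, sd %g)\n",
              x$profile_opt, x$profile_sd))
  cat(sprintf("  base rate: %g\n", x$base_rate))
  invisible(x)
}

#' Evaluate one niche response
#'
#' @param niche a [niche_spec()].
#' @param predictor one of `"aspect"`, `"dem"`, `"profile"`, `"slope"`.
#' @param values numeric vector of predictor values.
#' @return Numeric vector in [0, 1].
#' @export
niche_response <- function(niche, predictor, values) {
  stopifnot(inherits(niche, "niche_spec"))
  switch(match.arg(predictor, c("aspect", "dem", "profile", "slope")),
    dem = exp(-0.5 * ((values - niche$elev_opt) / niche$elev_sd)^2),
    aspect = {
      r <- ((1 + cos((values - niche$aspect_pref) * pi / 180)) / 2) ^
        niche$aspect_strength
      r[!is.na(values) & values < 0] <- 0.5  # flat-cell sentinel: neutral
      r
    },
    slope = 1 / (1 + exp(niche$slope_decay * (values - niche$slope_max))),
    profile = exp(-0.5 * ((values - niche$profile_opt) / niche$profile_sd)^2))
}

#' Generate a dune-like synthetic DEM
#'
#' Spectral synthesis of a smooth, spatially autocorrelated random surface:
#' complex white noise is shaped by a power-law amplitude spectrum
#' `f^(-roughness/2)` and inverted by FFT, then affinely rescaled so that the
#' minimum and maximum elevations hit `elev_range` exactly. Larger
#' `roughness` exponents give smoother, longer-wavelength terrain.
#'
#' @param rows,cols grid dimensions.
#' @param cellsize cell size in metres.
#' @param elev_range length-2 numeric, output (min, max) elevation in metres.
#' @param roughness spectral exponent (power of the amplitude decay);
#'   2.5-3.5 produces dune-like rolling surfaces.
#' @param hypsometry distribution of area over the elevation band:
#'   `"uniform"` (default) applies a monotone histogram-flattening
#'   transform so every elevation in the band holds similar area, as on a
#'   dune plain; `"gaussian"` keeps the raw spectral field's bell-shaped
#'   hypsometry, which concentrates area mid-band. The transform is
#'   monotone, so spatial structure and autocorrelation are preserved.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @param xll,yll world coordinates of the lower-left corner.
#' @return A [raster_grid()] of elevations.
#' @examples
#' dem <- generate_dune_dem(50, 50, seed = 1)
#' range(dem$values)
#' @export
generate_dune_dem <- function(rows = 100, cols = 100, cellsize = 10,
                              elev_range = c(1009, 1016), roughness = 3,
                              hypsometry = c("uniform", "gaussian"),
                              seed = 1, xll = 0, yll = 0) {
  hypsometry <- match.arg(hypsometry)
  if (length(elev_range) != 2L || !all(is.finite(elev_range)) ||
      elev_range[1] >= elev_range[2])
    stop("'elev_range' must be (low, high) with low < high", call. = FALSE)
  if (rows < 2 || cols < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  # frequency grid (cycles per cell) for an rows x cols DFT
  fr <- c(0:floor(rows / 2), -(ceiling(rows / 2) - 1):-1) / rows
  fc <- c(0:floor(cols / 2), -(ceiling(cols / 2) - 1):-1) / cols
  f <- sqrt(outer(fr^2, fc^2, `+`))
  amp <- f ^ (-roughness / 2)
  amp[1, 1] <- 0  # no DC component; mean is set by rescaling
  phase <- matrix(stats::runif(rows * cols, 0, 2 * pi), rows, cols)
  mag <- matrix(stats::rnorm(rows * cols), rows, cols)
  spec <- amp * mag * exp(1i * phase)
  z <- Re(stats::fft(spec, inverse = TRUE)) / (rows * cols)
  if (hypsometry == "uniform")
    z[] <- (rank(z, ties.method = "first") - 1) / (length(z) - 1)
  z <- elev_range[1] + (z - min(z)) / (max(z) - min(z)) * diff(elev_range)
  raster_grid(z, xll = xll, yll = yll, cellsize = cellsize)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' True occurrence-probability surface of a virtual species
#'
#' Evaluates the niche on every cell of the predictor stack: the cellwise
#' product of the four responses times the base rate, a value in [0, 1].
#' Nodata propagates from any layer.
#'
#' @param stack a `predictor_stack` containing layers `aspect`, `dem`,
#'   `profile`, `slope`.
#' @param niche a [niche_spec()].
#' @return A [raster_grid()] of occurrence probabilities.
#' @export
suitability_surface <- function(stack, niche) {
  stopifnot(inherits(stack, "predictor_stack"))
  need <- c("aspect", "dem", "profile", "slope")
  miss <- setdiff(need, names(stack))
  if (length(miss))
    stop("stack is missing layer '", miss[1], "'", call. = FALSE)
  ref <- stack[[1L]]
  s <- niche$base_rate
  for (nm in need)
    s <- s * niche_response(niche, nm, stack[[nm]]$values)
  raster_grid(matrix(s, nrow(ref$values), ncol(ref$values)),
              xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              crs = ref$crs)
}

#' Draw virtual-species occurrences from a probability surface
#'
#' One independent Bernoulli draw per valid cell with that cell's
#' probability. Presences are reported at cell centres.
#'
#' @param prob a [raster_grid()] with values in [0, 1].
#' @param seed integer RNG seed.
#' @param full if `TRUE`, return every valid cell with its 0/1 outcome;
#'   otherwise only the presences.
#' @return A data frame with columns `x`, `y`, `observed` (all 1 unless
#'   `full = TRUE`).
#' @export
simulate_occurrences <- function(prob, seed = 1, full = FALSE) {
  stop_if_not_grid(prob)
  p <- prob$values
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("'prob' values must lie in [0, 1]", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  draw <- matrix(0L, nrow(p), ncol(p))
  draw[ok] <- stats::rbinom(sum(ok), 1L, p[ok])
  idx <- which(if (full) ok else ok & draw == 1L, arr.ind = TRUE)
  xy <- cell_xy(prob, idx[, 1], idx[, 2])
  data.frame(x = xy$x, y = xy$y, observed = draw[idx])
}

#' Simulate a complete virtual-species study scenario
#'
#' Builds the full synthetic analogue of a fine-scale topographic SDM study:
#' a dune DEM, its derived predictor stack, the species' true suitability
#' surface, and a field-like occurrence table. The niche's base rate is
#' calibrated so the expected number of occupied cells equals
#' `n_presence`, and the Bernoulli draw is repeated over derived sub-seeds
#' until the deduplicated presence count matches `n_presence` exactly, so
#' the design has the intended sample size.
#'
#' @param rows,cols,cellsize,elev_range,roughness passed to
#'   [generate_dune_dem()].
#' @param niche a [niche_spec()]; its `base_rate` is treated as an upper
#'   bound during calibration.
#' @param n_presence target number of presence cells.
#' @param seed master integer seed controlling every random draw.
#' @param max_tries maximum rejection-sampling attempts for the exact count.
#' @param out_dir optional directory; if given, writes `dem.asc`,
#'   `true_suitability.asc`, `occurrences.csv` and `niche.json` there.
#' @return A list of class `sdm_scenario`: `dem`, `stack`
#'   (aspect/dem/profile/slope), `suitability` (true probability surface),
#'   `occurrences` (data frame x, y, observed = 1), `niche`, `seed`.
#' @examples
#' sc <- simulate_scenario(rows = 40, cols = 40, n_presence = 30, seed = 7)
#' nrow(sc$occurrences)
#' @export
simulate_scenario <- function(rows = 100, cols = 100, cellsize = 10,
                              elev_range = c(1009, 1016), roughness = 2,
                              niche = niche_spec(), n_presence = 67,
                              seed = 1, max_tries = 2000, out_dir = NULL) {
  dem <- generate_dune_dem(rows, cols, cellsize, elev_range, roughness,
                           seed = seed)
  stack <- terrain_stack(dem)
  suit <- suitability_surface(stack, niche)
  ok <- !is.na(suit$values)
  s <- suit$values[ok]
  if (sum(s) <= 0) stop("suitability surface is identically zero",
                        call. = FALSE)
  if (sum(s > 0) < n_presence)
    stop("fewer cells with positive suitability than the presence target",
         call. = FALSE)
  # calibrate the probability scale so the expected occupied-cell count hits
  # the design target; expectation is monotone in the scale (cells saturate
  # at probability 1), so a root always exists
  expected <- function(lc) sum(pmin(exp(lc) * s, 1))
  if (sum(s) >= n_presence) {
    scale <- n_presence / sum(s)
  } else {
    lc <- stats::uniroot(function(lc) expected(lc) - n_presence,
                         lower = 0, upper = 60, tol = 1e-12)$root
    scale <- exp(lc)
  }
  prob <- suit
  prob$values <- pmin(prob$values * scale, 1)
  occ <- NULL
  for (try in seq_len(max_tries)) {
    cand <- simulate_occurrences(prob, seed = (seed + 7919L * try) %% .Machine$integer.max)
    if (nrow(cand) == n_presence) { occ <- cand; break }
  }
  if (is.null(occ))
    stop("could not hit the presence target of ", n_presence, " in ",
         max_tries, " attempts; adjust the niche or grid size",
         call. = FALSE)
  sc <- structure(list(dem = dem, stack = stack, suitability = suit,
                       sampling_probability = prob, occurrences = occ,
                       niche = niche, seed = seed),
                  class = "sdm_scenario")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raster(dem, file.path(out_dir, "dem.asc"))
    write_raster(suit, file.path(out_dir, "true_suitability.asc"))
    utils::write.csv(occ, file.path(out_dir, "occurrences.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(niche), file.path(out_dir, "niche.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  sc
}

#' @export
print.sdm_scenario <- function(x, ...) {
  d <- dim(x$dem$values)
  cat(sprintf("sdm_scenario: %d x %d cells of %g m, elevations [%g, %g] m\n",
              d[1], d[2], x$dem$cellsize, min(x$dem$values),
              max(x$dem$values)))
  cat(sprintf("  %d presence cells (seed %d)\n", nrow(x$occurrences), x$seed))
  invisible(x)
}
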