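#' Georeferenced raster grid
#'
#' Light-weight single-band raster container used throughout the package:
#' a numeric matrix in north-up orientation (row 1 is the northernmost row)
#' together with an affine transform given by the lower-left corner of the
#' grid and a square cell size. Nodata cells are stored as `NA`.
#' World coordinates refer to cell centers; a point at (x, y) falls in the
#' cell whose half-open interval `[x0, x0 + cellsize)` contains it.
#'
#' @param values numeric matrix, row 1 = northernmost row. `NA` marks nodata.
#' @param xll,yll x and y world coordinate of the lower-left *corner* of the
#'   grid, in the same length unit as `cellsize` (metres throughout the
#'   package).
#' @param cellsize side length of the (square) cells, strictly positive.
#' @param crs optional free-text coordinate reference system label.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), xll = 0, yll = 0, cellsize = 10)
#' dim(g)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1, crs = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("'cellsize' must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = crs),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g\n", d[1], d[2],
              x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + d[2] * x$cellsize,
              x$yll, x$yll + d[1] * x$cellsize))
  if (length(v))
    cat(sprintf("  values: min %.6g, mean %.6g, max %.6g (%d nodata)\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, main = NULL, col = grDevices::hcl.colors(64),
                             ...) {
  d <- dim(x$values)
  # image() draws column-major with y increasing; flip rows so north is up
  z <- t(x$values[d[1]:1, , drop = FALSE])
  xs <- x$xll + (seq_len(d[2]) - 0.5) * x$cellsize
  ys <- x$yll + (seq_len(d[1]) - 0.5) * x$cellsize
  graphics::image(xs, ys, z, asp = 1, col = col, xlab = "x", ylab = "y",
                  main = main, ...)
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

stop_if_not_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_raster_grid(x))
    stop(sprintf("'%s' must be a raster_grid", arg), call. = FALSE)
  invisible(x)
}

#' Cell centre coordinates and point-to-cell lookup
#'
#' `cell_xy()` returns world coordinates of cell centres for (row, col)
#' indices; `xy_cell()` maps world points to (row, col) indices using
#' half-open cell intervals, returning `NA` for points off the grid.
#'
#' @param grid a [raster_grid()].
#' @param row,col integer cell indices (1-based, row 1 = north).
#' @param x,y world coordinates.
#' @return A data frame with columns `x`, `y` (for `cell_xy`) or
#'   `row`, `col` (for `xy_cell`).
#' @export
cell_xy <- function(grid, row, col) {
  stop_if_not_grid(grid)
  nr <- nrow(grid$values)
  data.frame(x = grid$xll + (col - 0.5) * grid$cellsize,
             y = grid$yll + (nr - row + 0.5) * grid$cellsize)
}

#' @rdname cell_xy
#' @export
xy_cell <- function(grid, x, y) {
  stop_if_not_grid(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xll) / grid$cellsize) + 1L
  row <- nr - floor((y - grid$yll) / grid$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) <= tol && abs(a$yll - b$yll) <= tol &&
    abs(a$cellsize - b$cellsize) <= tol
}

#' Read a raster from disk
#'
#' Reads single-band rasters stored as ESRI ASCII Grid (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by whitespace-separated cell
#' values in north-up row order. Cells equal to the declared nodata value are
#' masked to `NA`.
#'
#' @param path path to the file.
#' @param format raster format; only `"esri_ascii"` is supported.
#' @return A [raster_grid()].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF support is not available in this build; ",
         "use format = \"esri_ascii\"", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header: missing key '", miss[1], "'",
         call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - cs / 2
  else stop("malformed ESRI ASCII header: missing key 'xllcorner'",
            call. = FALSE)
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - cs / 2
  else stop("malformed ESRI ASCII header: missing key 'yllcorner'",
            call. = FALSE)
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != nr * nc || anyNA(vals))
    stop("malformed ESRI ASCII body: expected ", nr * nc,
         " numeric cells, found ", sum(!is.na(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xll = xll, yll = yll, cellsize = cs)
}

#' Write a raster to disk
#'
#' Writes ESRI ASCII Grid with an `xllcorner`/`yllcorner` header; `NA` cells
#' are written as the `nodata` value (default -9999).
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @param format raster format; only `"esri_ascii"` is supported.
#' @param nodata numeric value standing for nodata cells in the file.
#' @param digits significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("esri_ascii", "geotiff"),
                         nodata = -9999, digits = 10) {
  format <- match.arg(format)
  stop_if_not_grid(grid)
  if (format == "geotiff")
    stop("GeoTIFF support is not available in this build; ",
         "use format = \"esri_ascii\"", call. = FALSE)
  m <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  m[is.na(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits,
                                                 format = "g"),
                                         collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write raster to ", path, call. = FALSE)
  invisible(path)
}

#' Block-aggregate a raster to a coarser resolution
#'
#' Aggregates `factor` x `factor` blocks of cells into single output cells
#' (e.g. resampling a fine elevation model onto a 10 m analysis grid). The
#' output cell size is `factor` times the input cell size. Trailing partial
#' blocks use the cells available; nodata cells are ignored within a block
#' and an all-nodata block yields nodata.
#'
#' @param grid a [raster_grid()].
#' @param factor positive integer block size.
#' @param stat aggregation statistic, one of `"mean"`, `"min"`, `"max"`.
#' @return A [raster_grid()] with the coarser geometry.
#' @export
aggregate_raster <- function(grid, factor, stat = c("mean", "min", "max")) {
  stop_if_not_grid(grid)
  stat <- match.arg(stat)
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  f <- switch(stat, mean = mean, min = min, max = max)
  m <- grid$values
  nr <- nrow(m); nc <- ncol(m)
  onr <- ceiling(nr / factor); onc <- ceiling(nc / factor)
  out <- matrix(NA_real_, onr, onc)
  for (i in seq_len(onr)) {
    ri <- ((i - 1L) * factor + 1L):min(i * factor, nr)
    for (j in seq_len(onc)) {
      cj <- ((j - 1L) * factor + 1L):min(j * factor, nc)
      v <- m[ri, cj]
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- f(v)
    }
  }
  # keep the north-west corner anchored: top of the grid stays put
  new_cs <- grid$cellsize * factor
  ytop <- grid$yll + nr * grid$cellsize
  raster_grid(out, xll = grid$xll, yll = ytop - onr * new_cs,
              cellsize = new_cs, crs = grid$crs)
}

#' Stack aligned predictor rasters
#'
#' Combines named rasters sharing one geometry into a predictor stack, the
#' multi-layer carrier used for model fitting and mapping. The union of the
#' layers' nodata masks is applied to every layer, so a cell is either valid
#' in all layers or in none.
#'
#' @param layers a named list of [raster_grid()]s with identical shape,
#'   origin and cell size.
#' @return An object of class `predictor_stack`: a named list of aligned
#'   `raster_grid`s with attribute `geometry`.
#' @examples
#' g <- raster_grid(matrix(runif(9), 3), cellsize = 10)
#' s <- align_stack(list(dem = g, slope = g))
#' names(s)
#' @export
align_stack <- function(layers) {
  if (!is.list(layers) || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("'layers' must be a fully named list of raster_grid objects",
         call. = FALSE)
  if (anyDuplicated(names(layers)))
    stop("layer names must be unique", call. = FALSE)
  for (nm in names(layers)) stop_if_not_grid(layers[[nm]], nm)
  ref <- layers[[1L]]
  for (nm in names(layers))
    if (!same_geometry(ref, layers[[nm]]))
      stop("layer '", nm, "' does not share the stack geometry ",
           "(shape, origin and cell size must match)", call. = FALSE)
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  layers <- lapply(layers, function(g) {
    g$values[mask] <- NA_real_
    g
  })
  structure(layers, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  d <- dim(x[[1L]]$values)
  cat(sprintf("predictor_stack: %d layers (%s), %d x %d cells of %g\n",
              length(x), paste(names(x), collapse = ", "), d[1], d[2],
              x[[1L]]$cellsize))
  invisible(x)
}

#' @export
`[.predictor_stack` <- function(x, i) {
  align_stack(unclass(x)[i])
}

stack_matrix <- function(stack) {
  # cells in column-major matrix order; one column per layer
  vapply(stack, function(g) as.vector(g$values), numeric(length(stack[[1L]]$values)))
}
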