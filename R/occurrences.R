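#' Read an occurrence table
#'
#' Delimited text with a header containing at least `x` and `y` columns
#' (and optionally `observed`).
#'
#' @param path path to the file.
#' @param sep field separator (default comma).
#' @return A data frame with numeric `x`, `y` columns.
#' @export
read_occurrences <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(d)))
    stop("occurrence file must have 'x' and 'y' columns", call. = FALSE)
  d$x <- as.numeric(d$x); d$y <- as.numeric(d$y)
  d
}

# Even-odd ray casting; points exactly on an edge count as inside.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # edge membership: collinear and within the segment's bounding box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_seg <- abs(cross) < 1e-12 * (1 + abs(xj - xi) + abs(yj - yi)) &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside | on_edge
}

#' Clean raw occurrence points onto the analysis grid
#'
#' Removes points outside the study boundary, snaps the remainder to the
#' grid cell containing them (half-open cell intervals, so each point maps
#' to exactly one cell), and deduplicates so every occupied cell appears
#' once. Points falling on nodata cells are dropped.
#'
#' @param points data frame with numeric `x`, `y` columns.
#' @param grid a [raster_grid()] defining the analysis resolution.
#' @param boundary optional polygon ring as a two-column matrix of x, y
#'   vertices; defaults to the grid's rectangular extent. Points exactly on
#'   the boundary count as inside.
#' @return A data frame of presence cells: `row`, `col`, `x`, `y` (cell
#'   centres), one row per occupied cell. Zero rows triggers a warning, not
#'   an error.
#' @export
clean_occurrences <- function(points, grid, boundary = NULL) {
  stop_if_not_grid(grid)
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    keep <- keep & point_in_polygon(x, y, boundary)
  }
  x <- x[keep]; y <- y[keep]
  rc <- xy_cell(grid, x, y)
  ok <- !is.na(rc$row)
  rc <- rc[ok, , drop = FALSE]
  if (nrow(rc)) {
    valid <- !is.na(grid$values[cbind(rc$row, rc$col)])
    rc <- rc[valid, , drop = FALSE]
  }
  rc <- unique(rc)
  if (nrow(rc) == 0L)
    warning("no occurrence points remain after cleaning", call. = FALSE)
  ctr <- cell_xy(grid, rc$row, rc$col)
  out <- data.frame(row = rc$row, col = rc$col, x = ctr$x, y = ctr$y)
  rownames(out) <- NULL
  out
}

#' Sample background (pseudo-absence) cells
#'
#' Draws `n` distinct valid cells uniformly at random, excluding presence
#' cells (the presence/absence framing keeps the two sets disjoint;
#' set `exclude_presence = FALSE` to allow overlap) and optionally
#' restricted to a rectangular extent.
#'
#' @param grid a [raster_grid()].
#' @param presence data frame of presence cells with `row`, `col` columns
#'   (as returned by [clean_occurrences()]), or `NULL`.
#' @param n number of background cells.
#' @param seed integer RNG seed.
#' @param extent optional `c(xmin, xmax, ymin, ymax)` restriction on cell
#'   centres.
#' @param exclude_presence logical; drop presence cells from the eligible
#'   pool (default `TRUE`).
#' @return A data frame of background cells: `row`, `col`, `x`, `y`.
#' @export
sample_background <- function(grid, presence = NULL, n = 100, seed = 1,
                              extent = NULL, exclude_presence = TRUE) {
  stop_if_not_grid(grid)
  nr <- nrow(grid$values)
  idx <- which(!is.na(grid$values), arr.ind = TRUE)
  elig <- data.frame(row = idx[, 1], col = idx[, 2])
  if (!is.null(extent)) {
    ctr <- cell_xy(grid, elig$row, elig$col)
    keep <- ctr$x >= extent[1] & ctr$x <= extent[2] &
      ctr$y >= extent[3] & ctr$y <= extent[4]
    elig <- elig[keep, , drop = FALSE]
  }
  if (exclude_presence && !is.null(presence) && nrow(presence)) {
    key <- paste(elig$row, elig$col)
    pkey <- paste(presence$row, presence$col)
    elig <- elig[!(key %in% pkey), , drop = FALSE]
  }
  if (n > nrow(elig))
    stop("requested ", n, " background cells but only ", nrow(elig),
         " are eligible", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  pick <- sample.int(nrow(elig), n)
  sel <- elig[pick, , drop = FALSE]
  ctr <- cell_xy(grid, sel$row, sel$col)
  out <- data.frame(row = sel$row, col = sel$col, x = ctr$x, y = ctr$y)
  rownames(out) <- NULL
  out
}

#' Extract predictor values at cells
#'
#' Returns the matrix of predictor values at the given cells, columns named
#' by stack layer. Cells where any layer is nodata are removed with a
#' message; row order is otherwise preserved.
#'
#' @param cells data frame with `row`, `col` columns.
#' @param stack a `predictor_stack`.
#' @return A numeric matrix, one row per retained cell, with attribute
#'   `kept` giving the retained row indices of `cells`.
#' @export
extract_predictors <- function(cells, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  ij <- cbind(cells$row, cells$col)
  m <- vapply(stack, function(g) g$values[ij], numeric(nrow(ij)))
  if (nrow(ij) == 1L) m <- matrix(m, nrow = 1L,
                                  dimnames = list(NULL, names(stack)))
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    message(sum(bad), " cell(s) dropped: nodata in at least one layer")
    m <- m[!bad, , drop = FALSE]
  }
  attr(m, "kept") <- which(!bad)
  m
}

#' Assign rows to cross-validation folds
#'
#' Random balanced partition of `n_rows` rows into `k` groups whose sizes
#' differ by at most one. With `labels` given, the partition is stratified:
#' each class is partitioned separately so every fold preserves the
#' presence:background ratio (pass `labels = NULL` for plain random folds).
#'
#' @param n_rows number of rows to partition.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @param labels optional 0/1 vector of length `n_rows` for stratification.
#' @return Integer vector of fold indices in `1..k`.
#' @export
kfold_partition <- function(n_rows, k = 5, seed = 1, labels = NULL) {
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  if (k > n_rows)
    stop("'k' (", k, ") exceeds the number of rows (", n_rows, ")",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  assign_one <- function(idx) {
    g <- rep_len(seq_len(k), length(idx))
    stats::setNames(sample(g), idx)
  }
  out <- integer(n_rows)
  if (is.null(labels)) {
    out <- unname(assign_one(seq_len(n_rows)))
  } else {
    stopifnot(length(labels) == n_rows)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      out[idx] <- unname(assign_one(idx))
    }
  }
  out
}

#' Assemble a presence/background training set
#'
#' Binds cleaned presence cells and sampled background cells, extracts their
#' predictor vectors from the stack, and labels rows 1 (presence) or 0
#' (background).
#'
#' @param presence,background data frames of cells (`row`, `col`, `x`, `y`).
#' @param stack a `predictor_stack`.
#' @return An object of class `occurrence_set`: list with `cells` (data
#'   frame incl. `label`), `X` (predictor matrix) and `y` (0/1 labels).
#' @export
occurrence_set <- function(presence, background, stack) {
  pk <- paste(presence$row, presence$col)
  bk <- paste(background$row, background$col)
  if (any(bk %in% pk))
    stop("presence and background cells overlap", call. = FALSE)
  if (anyDuplicated(pk) || anyDuplicated(bk))
    stop("duplicate cells within presence or background", call. = FALSE)
  cells <- rbind(cbind(presence, label = 1L), cbind(background, label = 0L))
  X <- extract_predictors(cells, stack)
  kept <- attr(X, "kept")
  cells <- cells[kept, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, X = X, y = cells$label),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d presences, %d background, %d predictors (%s)\n",
              sum(x$y == 1), sum(x$y == 0), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}
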