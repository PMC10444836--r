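# Shared fixtures, all built in code.

# Planar DEM z = a*x + b*y + c evaluated at cell centres (x east, y north).
planar_dem <- function(n = 10, a = 0, b = 0, c = 0, cellsize = 1) {
  g <- raster_grid(matrix(0, n, n), cellsize = cellsize)
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  xy <- cell_xy(g, idx$row, idx$col)
  g$values[cbind(idx$row, idx$col)] <- a * xy$x + b * xy$y + c
  g
}

random_dem <- function(n = 30, seed = 1, cellsize = 2) {
  set.seed(seed)
  raster_grid(matrix(runif(n * n, 100, 110), n, n), cellsize = cellsize)
}

# A small stack with independent-ish layers for model tests.
toy_stack <- function(n = 20, seed = 42, cellsize = 10) {
  set.seed(seed)
  mk <- function() raster_grid(matrix(runif(n * n), n, n),
                               cellsize = cellsize)
  align_stack(list(aspect = raster_grid(matrix(runif(n * n, 0, 360), n, n),
                                        cellsize = cellsize),
                   dem = raster_grid(matrix(runif(n * n, 1009, 1016), n, n),
                                     cellsize = cellsize),
                   profile = mk(), slope = mk()))
}

# The paper-shaped synthetic study design, generated once per test run.
paper_scenario <- local({
  cache <- new.env()
  function(seed = 20240901) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_scenario(seed = seed)
    cache[[key]]
  }
})

scenario_presence <- function(sc) clean_occurrences(sc$occurrences,
                                                    sc$stack$dem)

# Independent brute-force oracles (kept deliberately naive).
oracle_gower <- function(a, b, ranges) {
  s <- 0
  for (k in seq_along(a)) s <- s + abs(a[k] - b[k]) / ranges[k]
  s / length(a)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_confusion <- function(scores, labels, t) {
  A <- B <- C <- D <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= t
    if (labels[i] == 1) { if (pred) A <- A + 1L else B <- B + 1L }
    else { if (pred) C <- C + 1L else D <- D + 1L }
  }
  list(A = A, B = B, C = C, D = D)
}
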