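# Fixed-radius neighbor search.  Point counts per candidate use a
# spatial-grid bucket index (cell side = r): for each query only the 3x3
# block of cells around it is scanned, giving near-linear behaviour on the
# localization densities seen in SMLM fields.  All comparisons are strict
# (d < r), matching the neighborhood definition of the detection statistics.

# Build a grid index over points; cell ids are encoded as one integer key.
grid_index <- function(x, y, cell) {
  cx <- as.integer(floor(x / cell))
  cy <- as.integer(floor(y / cell))
  key <- paste(cx, cy)
  list(cx = cx, cy = cy, buckets = split(seq_along(x), key), cell = cell)
}

# Indices of points within strict distance r of (qx, qy).
grid_query <- function(idx, px, py, qx, qy, r) {
  cqx <- as.integer(floor(qx / idx$cell))
  cqy <- as.integer(floor(qy / idx$cell))
  keys <- as.vector(outer(cqx + (-1:1), cqy + (-1:1),
                          function(a, b) paste(a, b)))
  cand <- unlist(idx$buckets[keys], use.names = FALSE)
  if (is.null(cand) || !length(cand)) return(integer(0))
  d2 <- (px[cand] - qx)^2 + (py[cand] - qy)^2
  cand[d2 < r * r]
}

# For each of m query points, indices of table points within strict
# distance r.  Returns a list of integer vectors.
radius_neighbors <- function(px, py, qx, qy, r) {
  stopifnot(r > 0)
  idx <- grid_index(px, py, r)
  lapply(seq_along(qx), function(i)
    grid_query(idx, px, py, qx[i], qy[i], r))
}
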