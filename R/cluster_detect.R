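# Cluster mode: fiducial-free landmark detection.  Multi-labeled
# nanoparticles (e.g. cargo-loaded LNPs) produce dense localization
# clusters in every channel; the densest clusters serve as registration
# landmarks when no beads are present.  No MT/VL criteria here: neighbor
# counts are pooled over all frames.

#' Detect dense localization clusters as registration landmarks
#'
#' For every localization, counts the neighboring localizations within
#' strict Euclidean distance `r_c`, pooled across all frames, then retains
#' the `k` localizations with the largest counts.  By default candidates
#' within `r_c` of an already-selected, higher-ranked candidate are
#' suppressed, so the landmarks spread over distinct physical clusters
#' rather than all falling inside the single densest one
#' (`suppress = FALSE` gives the literal unsuppressed top-`k`).
#'
#' @param table a non-empty [loc_table].
#' @param r_c cluster neighborhood radius in nm (default 750, suited to
#'   ~100 nm nanoparticle clusters rendered at typical densities).
#' @param k maximum number of landmarks retained (default 25).
#' @param suppress suppress lower-ranked candidates within `r_c` of a
#'   selected one (default `TRUE`).
#' @return A `landmark_set` with `support` = pooled neighbor count (the
#'   candidate localization counts itself), `source = "cluster"`; `mt` and
#'   `vl` are `NA`.
#' @export
detect_clusters <- function(table, r_c = 750, k = 25, suppress = TRUE) {
  stopifnot(inherits(table, "loc_table"), r_c > 0, k >= 1)
  if (nrow(table) == 0L) stop("cannot detect clusters in an empty table")
  counts <- cluster_neighbor_counts(table$x, table$y, r_c)
  ord <- order(-counts, seq_along(counts))  # ties: earlier row wins
  if (suppress) {
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel) ||
          all((table$x[sel] - table$x[i])^2 +
              (table$y[sel] - table$y[i])^2 >= r_c^2))
        sel <- c(sel, i)
      if (length(sel) == k) break
    }
  } else {
    sel <- ord[seq_len(min(k, length(ord)))]
  }
  if (length(sel) < 2L)
    stop("cluster detection yielded ", length(sel),
         " landmark(s); at least 2 are needed for a rigid fit ",
         "(try a smaller r_c or check the input)")
  new_landmark_set(table$x[sel], table$y[sel], support = counts[sel],
                   source = "cluster", channel_id = channel_id(table),
                   params = list(r_c = r_c, k = k, suppress = suppress))
}

# Pooled neighbor count (strict < r) for every point, via the grid index;
# each point counts itself (distance 0).
cluster_neighbor_counts <- function(x, y, r) {
  idx <- grid_index(x, y, r)
  counts <- integer(length(x))
  cxs <- idx$cx
  cys <- idx$cy
  for (b in idx$buckets) {
    # all points sharing one cell query the same 3x3 block
    keys <- as.vector(outer(cxs[b[1]] + (-1:1), cys[b[1]] + (-1:1),
                            function(a, d) paste(a, d)))
    cand <- unlist(idx$buckets[keys], use.names = FALSE)
    dx <- outer(x[b], x[cand], "-")
    dy <- outer(y[b], y[cand], "-")
    counts[b] <- as.integer(rowSums(dx * dx + dy * dy < r * r))
  }
  counts
}
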