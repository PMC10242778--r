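# Fiducial-marker detection.  Fiducial beads (e.g. 100 nm TetraSpeck) emit
# constantly, unlike blinking fluorophores, so a bead produces roughly one
# localization in (almost) every frame at a fixed position.  Candidates are
# seeded from the densest frame and scored by two per-frame neighborhood
# statistics: the mean tolerance MT (mean neighbor count per frame) must be
# high, and the variance limit VL (population variance of that count) must
# be low.

#' Fiducial-detection parameters
#'
#' @param r neighborhood tolerance in nm; set to the fiducial diameter
#'   (default 100 nm for standard TetraSpeck beads).  A localization belongs
#'   to a candidate's neighborhood when its Euclidean distance is strictly
#'   below `r`.
#' @param mt_min minimum acceptable mean tolerance MT (mean per-frame
#'   neighbor count).  Default 0.5: the bead must be localized in at least
#'   half of the analyzed frames.
#' @param vl_max maximum acceptable variance limit VL (population variance
#'   of the per-frame neighbor count).  Default 0.25: rejects blinking
#'   structures, whose count fluctuates strongly between frames.
#' @param frame_first,frame_last optional frame range analyzed for
#'   detection (both inclusive); useful when fiducial emission bleaches
#'   late in the acquisition.  `NULL` analyzes all frames.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(r = 100, mt_min = 0.5, vl_max = 0.25,
                             frame_first = NULL, frame_last = NULL) {
  stopifnot(r > 0, mt_min >= 0, vl_max >= 0)
  if (!is.null(frame_first) != !is.null(frame_last))
    stop("frame_first and frame_last must be given together")
  structure(list(r = r, mt_min = mt_min, vl_max = vl_max,
                 frame_first = frame_first, frame_last = frame_last),
            class = "detection_params")
}

# Landmark sets: a data.frame of landmark positions with their detection
# statistics (NA where a statistic does not apply to the detection mode).
new_landmark_set <- function(x, y, mt = NA_real_, vl = NA_real_,
                             support = NA_integer_, source = "fiducial",
                             channel_id = "ch", params = NULL) {
  n <- length(x)
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       mt = rep_len(mt, n), vl = rep_len(vl, n),
                       support = rep_len(as.integer(support), n),
                       source = rep_len(source, n)),
            channel_id = as.character(channel_id), params = params,
            class = c("landmark_set", "data.frame"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: channel '%s', %d landmark(s)\n",
              attr(x, "channel_id"), nrow(x)))
  NextMethod()
}

#' Coordinates of a landmark set as a matrix
#'
#' @param landmarks a `landmark_set`.
#' @return A numeric matrix with columns `x`, `y`.
#' @export
landmark_coords <- function(landmarks) {
  cbind(x = landmarks$x, y = landmarks$y)
}

#' Seed candidate fiducials from the densest frame
#'
#' Finds the frame with the most localizations (ties broken toward the
#' lowest frame index) and returns every localization of that frame as a
#' candidate fiducial position.  Fiducials emit in every frame, so each
#' bead is guaranteed to appear in the densest frame.
#'
#' @param table a non-empty [loc_table].
#' @return A data.frame with columns `frame`, `x`, `y`, one row per
#'   candidate.
#' @export
seed_candidates <- function(table) {
  stopifnot(inherits(table, "loc_table"))
  if (nrow(table) == 0L) stop("cannot seed candidates from an empty table")
  counts <- tabulate(table$frame, nbins = n_frames(table))
  densest <- which.max(counts)  # which.max takes the first (lowest) maximum
  rows <- table$frame == densest
  data.frame(frame = densest, x = table$x[rows], y = table$y[rows])
}

#' Per-frame neighbor counts around a candidate
#'
#' For each analyzed frame `f`, counts the localizations of that frame
#' within strict Euclidean distance `r` of the candidate position; frames
#' with no localizations contribute 0.  These counts feed the MT/VL
#' statistics of [score_candidate()].
#'
#' @param table a [loc_table]; its `n_frames` attribute defines the number
#'   of analyzed frames.
#' @param candidate numeric vector `c(x, y)` in nm.
#' @param r tolerance radius in nm.
#' @return Integer vector of length `n_frames(table)`.
#' @export
neighbor_counts_per_frame <- function(table, candidate, r) {
  stopifnot(inherits(table, "loc_table"), r > 0, length(candidate) >= 2)
  nb <- radius_neighbors(table$x, table$y, candidate[1], candidate[2], r)[[1]]
  tabulate(table$frame[nb], nbins = n_frames(table))
}

#' Detection statistics of a candidate fiducial
#'
#' Computes the mean tolerance `mt = mean(counts)` and the variance limit
#' `vl = mean((counts - mt)^2)` (population variance, divisor `n`) from the
#' per-frame neighbor counts.  A stable constant emitter has `mt = 1`,
#' `vl = 0`; blinking structures have high `vl`.
#'
#' @param counts integer vector of per-frame neighbor counts, length `n`
#'   (zeros included for frames without neighbors).
#' @param n number of analyzed frames; defaults to `length(counts)`.
#' @return Named numeric vector `c(mt, vl)`.
#' @export
score_candidate <- function(counts, n = length(counts)) {
  stopifnot(n >= 1)
  if (length(counts) < n) counts <- c(counts, rep(0L, n - length(counts)))
  mt <- sum(counts) / n
  vl <- sum((counts - mt)^2) / n
  c(mt = mt, vl = vl)
}

#' Detect fiducial markers in a localization table
#'
#' Full detection pipeline: restrict to the analyzed frame range, seed one
#' candidate per localization of the densest frame, score every candidate
#' by MT and VL, keep candidates with `mt >= mt_min` and `vl <= vl_max`,
#' refine each kept candidate to the centroid of its in-radius
#' localizations pooled over all analyzed frames, and merge duplicates
#' closer than `r` (one physical bead seeds several candidates; the one
#' with highest MT survives, ties broken by lowest VL then lowest x).
#'
#' @param table a non-empty [loc_table].
#' @param params a [detection_params()] object.
#' @return A `landmark_set` with one row per detected fiducial and columns
#'   `x`, `y`, `mt`, `vl`, `support` (total in-radius localizations).
#' @examples
#' sim <- simulate_channel(simulation_config(n_fiducials = 3, n_frames = 200,
#'                                           seed = 7))
#' fids <- detect_fiducials(sim$table, detection_params())
#' nrow(fids)
#' @export
detect_fiducials <- function(table, params = detection_params()) {
  stopifnot(inherits(table, "loc_table"), inherits(params, "detection_params"))
  if (nrow(table) == 0L) stop("cannot detect fiducials in an empty table")
  if (!is.null(params$frame_first))
    table <- restrict_frames(table, params$frame_first, params$frame_last)
  cand <- seed_candidates(table)
  n <- n_frames(table)
  nb <- radius_neighbors(table$x, table$y, cand$x, cand$y, params$r)
  support <- lengths(nb)
  frame_of <- table$frame
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    counts <- tabulate(frame_of[nb[[i]]], nbins = n)
    score_candidate(counts, n)
  }, numeric(2))
  mt <- scores["mt", ]
  vl <- scores["vl", ]
  keep <- mt >= params$mt_min & vl <= params$vl_max
  if (!any(keep))
    stop("no fiducials found: no candidate met MT >= ", params$mt_min,
         " and VL <= ", params$vl_max,
         "; consider adjusting r, mt_min, vl_max or the frame range")
  kept <- which(keep)
  # refine to the centroid of in-radius localizations (averages frame jitter)
  cx <- vapply(kept, function(i) mean(table$x[nb[[i]]]), numeric(1))
  cy <- vapply(kept, function(i) mean(table$y[nb[[i]]]), numeric(1))
  lm <- data.frame(x = cx, y = cy, mt = mt[kept], vl = vl[kept],
                   support = support[kept])
  # deduplicate: best candidate first, suppress others within r
  ord <- order(-lm$mt, lm$vl, lm$x)
  lm <- lm[ord, , drop = FALSE]
  sel <- integer(0)
  for (i in seq_len(nrow(lm))) {
    if (!length(sel) ||
        all((lm$x[sel] - lm$x[i])^2 + (lm$y[sel] - lm$y[i])^2 >= params$r^2))
      sel <- c(sel, i)
  }
  lm <- lm[sel, , drop = FALSE]
  new_landmark_set(lm$x, lm$y, mt = lm$mt, vl = lm$vl, support = lm$support,
                   source = "fiducial", channel_id = channel_id(table),
                   params = params)
}
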