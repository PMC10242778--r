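# Iterative Closest Point over landmark sets.  Alternates nearest-neighbor
# correspondence (moving -> reference), outlier rejection on the pair
# distances, and a closed-form rigid fit on the inliers, until the mean
# inlier distance stops changing.  Landmarks present in only one channel
# (spurious detections, undetected beads) are absorbed by the outlier rule.

#' ICP configuration
#'
#' @param convergence_tol convergence tolerance in nm: iteration stops when
#'   the mean inlier distance changes by less than this between two
#'   consecutive iterations (default 1 nm).
#' @param max_iterations iteration cap (default 100); reaching it without
#'   convergence returns a result flagged `converged = FALSE` with a
#'   warning.
#' @param outlier_sd outlier multiplier: pairs with distance greater than
#'   `mean + outlier_sd * sd` of the current pair distances are discarded
#'   before the fit (default 1).  The rule is re-applied on the surviving
#'   pairs until no pair is removed, but never trims below half the pairs.
#' @param init initial transform: `"vote"` (default) estimates a starting
#'   translation as the mode of all pairwise reference-minus-moving
#'   displacement vectors, which keeps the first nearest-neighbor
#'   correspondences correct even when the misalignment approaches the
#'   landmark spacing; `"identity"` starts from no transform (sufficient
#'   when the misalignment is well below half the landmark spacing).
#' @param vote_tol clustering tolerance in nm for the displacement-vector
#'   vote (default 750; should exceed the displacement spread the rotation
#'   causes across the field).
#' @return A list of class `icp_config`.
#' @export
icp_config <- function(convergence_tol = 1, max_iterations = 100,
                       outlier_sd = 1, init = c("vote", "identity"),
                       vote_tol = 750) {
  stopifnot(convergence_tol > 0, max_iterations >= 1, outlier_sd >= 0,
            vote_tol > 0)
  structure(list(convergence_tol = convergence_tol,
                 max_iterations = max_iterations,
                 outlier_sd = outlier_sd,
                 init = match.arg(init),
                 vote_tol = vote_tol),
            class = "icp_config")
}

# Mode of the pairwise displacement vectors ref_j - mov_i.  The true
# translation is voted for once per landmark common to both sets, while
# unrelated pairs scatter over the field; the densest cluster (within tol)
# wins and its supporting vectors are averaged.
vote_translation <- function(mov, ref, tol) {
  dx <- as.vector(outer(mov[, 1], ref[, 1], function(m, r) r - m))
  dy <- as.vector(outer(mov[, 2], ref[, 2], function(m, r) r - m))
  d2 <- outer(dx, dx, "-")^2 + outer(dy, dy, "-")^2
  votes <- rowSums(d2 < tol^2)
  supp <- d2[which.max(votes), ] < tol^2
  c(mean(dx[supp]), mean(dy[supp]))
}

# Nearest reference index for each moving point (small landmark sets:
# direct distance matrix).
nearest_reference <- function(moving, reference) {
  d2 <- outer(moving[, 1], reference[, 1], "-")^2 +
        outer(moving[, 2], reference[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Register landmark sets by Iterative Closest Point
#'
#' Estimates the rigid transformation mapping the moving channel's
#' landmarks onto the reference channel's.  Each iteration matches every
#' moving landmark to its nearest reference landmark, computes the pair
#' distances, discards pairs farther than `mean + outlier_sd * sd`
#' (recomputed every iteration from the current distances), fits the
#' least-squares rigid transform on the inliers, and accumulates it into
#' the overall transform.  Convergence is declared when the mean inlier
#' distance changes by less than `convergence_tol` between iterations.
#'
#' @param moving,reference `landmark_set`s (or 2-column coordinate
#'   matrices) with at least 2 landmarks each.
#' @param config an [icp_config()].
#' @return An object of class `registration_result`: a list with
#'   `transform` (the [rigid_transform()] mapping original moving
#'   coordinates into reference space), `n_iterations`,
#'   `final_mean_distance` (mean inlier distance, nm), `matched_pairs`
#'   (two-column matrix of inlier moving/reference indices at the last
#'   iteration), `mean_distance_history` and `converged`.
#' @examples
#' ref <- cbind(x = c(0, 1000, 0, 1500), y = c(0, 0, 1200, 900))
#' mov <- transform_points(rigid_transform(0.01, 300, -200), ref)
#' res <- icp(mov, ref)
#' res$transform
#' @export
icp <- function(moving, reference, config = icp_config()) {
  stopifnot(inherits(config, "icp_config"))
  mov0 <- landmark_matrix(moving)
  ref <- landmark_matrix(reference)
  if (nrow(mov0) < 2L || nrow(ref) < 2L)
    stop("ICP needs at least 2 landmarks in each set (got ",
         nrow(mov0), " moving, ", nrow(ref), " reference)")
  transform <- if (config$init == "vote") {
    t0 <- vote_translation(mov0, ref, config$vote_tol)
    rigid_transform(0, t0[1], t0[2])
  } else rigid_transform(0, 0, 0)
  prev_mean <- Inf
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  pairs <- NULL
  mean_d <- NA_real_
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    cur <- transform_points(transform, mov0)
    match_idx <- nearest_reference(cur, ref)
    d <- sqrt(rowSums((cur - ref[match_idx, , drop = FALSE])^2))
    # trimmed outlier rejection: the mean + k*SD rule is re-applied on the
    # surviving pairs until stable (a single pass can leave heavily
    # contaminated sets in a compromise state); never trims below half the
    # pairs, so <= 50% spurious landmarks cannot exhaust the inliers
    inlier <- rep(TRUE, length(d))
    repeat {
      cutoff <- mean(d[inlier]) + config$outlier_sd * stats::sd(d[inlier])
      if (is.na(cutoff)) break
      new_in <- inlier & d <= cutoff
      if (sum(new_in) < max(2L, ceiling(length(d) / 2)) ||
          identical(new_in, inlier)) break
      inlier <- new_in
    }
    if (sum(inlier) < 2L)
      stop("outlier rejection left ", sum(inlier), " of ", length(d),
           " pairs; cannot fit a rigid transform ",
           "(mean distance ", signif(mean(d), 4), " nm)")
    mean_d <- mean(d[inlier])
    history <- c(history, mean_d)
    pairs <- cbind(moving = which(inlier), reference = match_idx[inlier])
    if (abs(prev_mean - mean_d) < config$convergence_tol) {
      converged <- TRUE
      break
    }
    prev_mean <- mean_d
    step <- estimate_rigid(cur[inlier, , drop = FALSE],
                           ref[match_idx[inlier], , drop = FALSE])
    transform <- compose_transforms(step, transform)
  }
  if (!converged)
    warning("ICP did not converge within ", config$max_iterations,
            " iterations (last mean-distance change ",
            signif(abs(prev_mean - mean_d), 4), " nm)")
  structure(list(transform = transform,
                 n_iterations = iter,
                 final_mean_distance = mean_d,
                 matched_pairs = pairs,
                 mean_distance_history = history,
                 converged = converged),
            class = "registration_result")
}

landmark_matrix <- function(x) {
  if (inherits(x, "landmark_set")) landmark_coords(x)
  else {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 2)
    colnames(m) <- c("x", "y")
    m
  }
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("ICP registration: %d iteration(s), %s, ",
                     "mean inlier distance %.3g nm, %d matched pair(s)\n"),
              x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              x$final_mean_distance, nrow(x$matched_pairs)))
  print(x$transform)
  invisible(x)
}
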