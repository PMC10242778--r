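# Synthetic multi-channel SMLM data with known ground truth.  Emulates the
# ingredients registration depends on: stable fiducial emitters (one
# jittered localization per frame while "on"), blinking structured signal
# (filaments, clusters), a rigid inter-channel misalignment, and Gaussian
# localization jitter.  Photophysics (dye state kinetics, camera noise,
# PSF-fit bias) is deliberately not modeled.

#' Simulation configuration
#'
#' Defaults emulate a typical STORM acquisition geometry: a 256-pixel
#' square field at 130 nm/pixel (33 280 nm) and 2000 analyzed frames.
#' Fiducials are placed by dart-throwing (Poisson-disc) sampling with a
#' minimum spacing of `min_spacing` so ICP correspondences are
#' unambiguous.
#'
#' @param field_size side of the square field of view in nm (default
#'   33280).
#' @param n_frames number of acquisition frames (default 2000).
#' @param n_fiducials number of fiducial beads (default 8).
#' @param fiducial_on_prob per-frame Bernoulli probability that a bead is
#'   localized (default 0.95: beads emit near-constantly).
#' @param fiducial_jitter localization precision sigma in nm (default 10).
#' @param structures list of structured-signal specs, each a list with
#'   `type = "filament"` (`from`, `to` endpoints in nm, `rate` expected
#'   blinks per frame, `jitter` nm) or `type = "cluster"` (`center`,
#'   `sigma` nm, `n_points` total blinks).
#' @param min_spacing minimum fiducial spacing in nm (default 1000, ten
#'   bead diameters).
#' @param margin keep-out border for bead placement in nm (default 500).
#' @param fiducial_intensity,signal_intensity median photon-scale
#'   intensities for bead and structure localizations (log-normal spread);
#'   beads are much brighter than single-fluorophore blinks.
#' @param seed integer RNG seed; a fixed seed makes [simulate_channel()]
#'   fully reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(field_size = 33280, n_frames = 2000,
                              n_fiducials = 8, fiducial_on_prob = 0.95,
                              fiducial_jitter = 10, structures = list(),
                              min_spacing = 1000, margin = 500,
                              fiducial_intensity = 20000,
                              signal_intensity = 5000, seed = NULL) {
  stopifnot(field_size > 0, n_frames >= 1, n_fiducials >= 0,
            fiducial_on_prob >= 0, fiducial_on_prob <= 1,
            fiducial_jitter >= 0, min_spacing > 0)
  structure(list(field_size = field_size, n_frames = as.integer(n_frames),
                 n_fiducials = as.integer(n_fiducials),
                 fiducial_on_prob = fiducial_on_prob,
                 fiducial_jitter = fiducial_jitter,
                 structures = structures, min_spacing = min_spacing,
                 margin = margin,
                 fiducial_intensity = fiducial_intensity,
                 signal_intensity = signal_intensity, seed = seed),
            class = "simulation_config")
}

# Dart-throwing Poisson-disc sampling inside the margin-inset field.
poisson_disc <- function(n, field, spacing, margin, max_tries = 10000L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  lo <- margin; hi <- field - margin
  if (hi <= lo) stop("field too small for the requested margin")
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    p <- stats::runif(2, lo, hi)
    if (placed == 0L ||
        all((pts[seq_len(placed), 1] - p[1])^2 +
            (pts[seq_len(placed), 2] - p[2])^2 >= spacing^2)) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  if (placed < n)
    stop("could not place ", n, " fiducials with spacing ", spacing,
         " nm in a ", field, " nm field")
  colnames(pts) <- c("x", "y")
  pts
}

#' Simulate one channel of localizations with ground truth
#'
#' Generates fiducial and structured-signal localizations in the reference
#' coordinate frame, then maps every coordinate through the channel's true
#' rigid transform (the misalignment a registration run should recover by
#' estimating its inverse).
#'
#' Fiducials: in each frame a bead is localized with probability
#' `fiducial_on_prob` at its true position plus isotropic Gaussian jitter.
#' Filaments blink Poisson-distributed counts per frame uniformly along
#' the segment; clusters scatter a fixed number of blinks (Gaussian around
#' the centre) over random frames.
#'
#' @param config a [simulation_config()].
#' @param channel_id channel label.
#' @param transform the channel's true misalignment as a
#'   [rigid_transform()] (identity for the reference channel).
#' @param fiducial_positions optional n x 2 matrix of true bead positions
#'   (reference frame); shared across channels of one simulated sample.
#'   `NULL` draws new Poisson-disc positions.
#' @param seed RNG seed; defaults to `config$seed`.  `NULL` uses the
#'   current RNG state.
#' @return A list: `table` (a [loc_table]), `truth` with `fiducials`
#'   (true positions, reference frame), `fiducials_mapped` (after the
#'   channel transform), `structure_points` (mapped), `transform`.
#' @export
simulate_channel <- function(config, channel_id = "ch",
                             transform = rigid_transform(0, 0, 0),
                             fiducial_positions = NULL, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(transform, "rigid_transform"))
  run <- function() {
    if (is.null(fiducial_positions) && config$n_fiducials > 0)
      fiducial_positions <- poisson_disc(config$n_fiducials,
                                         config$field_size,
                                         config$min_spacing, config$margin)
    frame <- integer(0); x <- numeric(0); y <- numeric(0)
    intensity <- numeric(0)
    nf <- config$n_frames
    if (config$n_fiducials > 0) {
      for (i in seq_len(config$n_fiducials)) {
        on <- which(stats::runif(nf) < config$fiducial_on_prob)
        k <- length(on)
        if (!k) next
        frame <- c(frame, on)
        x <- c(x, fiducial_positions[i, 1] +
                 stats::rnorm(k, 0, config$fiducial_jitter))
        y <- c(y, fiducial_positions[i, 2] +
                 stats::rnorm(k, 0, config$fiducial_jitter))
        intensity <- c(intensity,
                       stats::rlnorm(k, log(config$fiducial_intensity), 0.2))
      }
    }
    for (s in config$structures) {
      if (identical(s$type, "filament")) {
        jit <- if (is.null(s$jitter)) 10 else s$jitter
        k_per_frame <- stats::rpois(nf, s$rate)
        k <- sum(k_per_frame)
        if (!k) next
        u <- stats::runif(k)
        frame <- c(frame, rep(seq_len(nf), k_per_frame))
        x <- c(x, s$from[1] + u * (s$to[1] - s$from[1]) +
                 stats::rnorm(k, 0, jit))
        y <- c(y, s$from[2] + u * (s$to[2] - s$from[2]) +
                 stats::rnorm(k, 0, jit))
        intensity <- c(intensity,
                       stats::rlnorm(k, log(config$signal_intensity), 0.3))
      } else if (identical(s$type, "cluster")) {
        k <- s$n_points
        if (!k) next
        frame <- c(frame, sample.int(nf, k, replace = TRUE))
        x <- c(x, stats::rnorm(k, s$center[1], s$sigma))
        y <- c(y, stats::rnorm(k, s$center[2], s$sigma))
        intensity <- c(intensity,
                       stats::rlnorm(k, log(config$signal_intensity), 0.3))
      } else stop("unknown structure type: ", s$type)
    }
    if (!length(frame)) stop("simulation produced no localizations")
    ord <- order(frame)
    xy <- transform_points(transform, cbind(x, y))[ord, , drop = FALSE]
    tab <- loc_table(frame[ord], xy[, 1], xy[, 2],
                     intensity = intensity[ord], channel_id = channel_id,
                     n_frames = nf)
    struct_pts <- if (length(config$structures)) {
      centers <- do.call(rbind, lapply(config$structures, function(s)
        if (identical(s$type, "cluster")) s$center
        else rbind(s$from, s$to)))
      transform_points(transform, centers)
    }
    list(table = tab,
         truth = list(fiducials = fiducial_positions,
                      fiducials_mapped = if (!is.null(fiducial_positions))
                        transform_points(transform, fiducial_positions),
                      structure_points = struct_pts,
                      transform = transform))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Thin a table by exponential photobleaching
#'
#' Retains each localization independently with probability
#' `2^(-frame / half_life)`: emission decays with a half-life expressed in
#' frames, emulating fiducials that bleach during the acquisition.  Used
#' to study the benefit of restricting detection to early frames.
#'
#' @param table a [loc_table].
#' @param half_life bleaching half-life in frames (> 0); `Inf` keeps
#'   everything.
#' @return A thinned [loc_table] (same `n_frames`).
#' @export
emulate_bleaching <- function(table, half_life) {
  stopifnot(inherits(table, "loc_table"), half_life > 0)
  p_keep <- 2^(-table$frame / half_life)
  keep <- stats::runif(nrow(table)) < p_keep
  relabel_table(as.data.frame(table)[keep, , drop = FALSE], table)
}
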