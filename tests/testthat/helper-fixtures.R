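# Shared fixture builders.  Everything is generated in code; no data files.

# Brute-force per-frame neighbor counts: the O(n*m) double loop the grid
# index must agree with (strict d < r).
brute_counts_per_frame <- function(table, cx, cy, r) {
  counts <- integer(n_frames(table))
  for (i in seq_len(nrow(table))) {
    d <- sqrt((table$x[i] - cx)^2 + (table$y[i] - cy)^2)
    if (d < r) counts[table$frame[i]] <- counts[table$frame[i]] + 1L
  }
  counts
}

# A random localization table with no structure.
random_table <- function(n, n_frames = 50, field = 5000, intensity = TRUE) {
  loc_table(frame = sample.int(n_frames, n, replace = TRUE),
            x = runif(n, 0, field), y = runif(n, 0, field),
            intensity = if (intensity) runif(n, 100, 5000),
            channel_id = "test", n_frames = n_frames)
}

# Table with stable emitters + blinkers, returning ground truth.
emitter_field <- function(n_emitters = 5, n_blinkers = 50, n_frames = 500,
                          on_prob = 0.95, blink_prob = 0.05, jitter = 10,
                          field = 20000, spacing = 1000) {
  cfg <- simulation_config(field_size = field, n_frames = n_frames,
                           n_fiducials = n_emitters,
                           fiducial_on_prob = on_prob,
                           fiducial_jitter = jitter, min_spacing = spacing)
  pos <- stormreg:::poisson_disc(n_emitters + n_blinkers, field, spacing, 500)
  fid_pos <- pos[seq_len(n_emitters), , drop = FALSE]
  sim <- simulate_channel(cfg, "em", fiducial_positions = fid_pos, seed = NULL)
  tab <- sim$table
  # blinkers: rare single blinks at fixed positions
  for (i in seq_len(n_blinkers)) {
    on <- which(runif(n_frames) < blink_prob)
    if (!length(on)) next
    extra <- loc_table(on,
                       pos[n_emitters + i, 1] + rnorm(length(on), 0, jitter),
                       pos[n_emitters + i, 2] + rnorm(length(on), 0, jitter),
                       intensity = rep(1000, length(on)),
                       n_frames = n_frames)
    df <- rbind(as.data.frame(tab), as.data.frame(extra))
    tab <- loc_table(df$frame, df$x, df$y, intensity = df$intensity,
                     channel_id = "em", n_frames = n_frames)
  }
  list(table = tab, emitters = fid_pos,
       blinkers = pos[-seq_len(n_emitters), , drop = FALSE])
}

# Write a small ThunderSTORM-style CSV, return its path.
write_ts_csv <- function(df, path = tempfile(fileext = ".csv")) {
  header <- '"frame","x [nm]","y [nm]","intensity [photon]"'
  rows <- sprintf("%d,%.4f,%.4f,%.1f", df$frame, df$x, df$y, df$intensity)
  writeLines(c(header, rows), path)
  path
}
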