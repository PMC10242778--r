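# High-level registration pipeline and the batch job runner.  A job is one
# set of registrations: a reference channel, one or more moving channels,
# and the detection/ICP parameters.  Jobs run sequentially; a failure in
# one job is logged and does not stop the remaining jobs.

#' Register moving channels onto a reference channel
#'
#' Runs the full pipeline on in-memory tables: detect landmarks in every
#' channel (fiducial or cluster mode), estimate one rigid transform per
#' moving channel by ICP against the reference landmarks, apply it to all
#' localizations of that channel, and optionally strip the fiducial
#' localizations from the corrected tables.
#'
#' @param reference a [loc_table]: the fixed channel.
#' @param moving a [loc_table] or list of them: the channels to correct.
#' @param mode `"fiducial"` (MT/VL bead detection) or `"cluster"`
#'   (fiducial-free densest-cluster landmarks).
#' @param params a [detection_params()] (fiducial mode).
#' @param r_c,k cluster-mode radius (nm) and landmark count.
#' @param config an [icp_config()].
#' @param strip_fiducials remove bead localizations (within
#'   `strip_diameter` of each detected landmark) from the corrected
#'   tables and the reference copy.
#' @param strip_diameter removal radius in nm (default 100).
#' @return A list of class `registration_run`: `reference` (possibly
#'   stripped), `reference_landmarks`, and `channels`, a named list per
#'   moving channel with `table` (corrected), `landmarks`, `result`
#'   (the `registration_result`).
#' @export
register_channels <- function(reference, moving, mode = c("fiducial", "cluster"),
                              params = detection_params(), r_c = 750, k = 25,
                              config = icp_config(), strip_fiducials = FALSE,
                              strip_diameter = 100) {
  mode <- match.arg(mode)
  if (inherits(moving, "loc_table")) moving <- list(moving)
  if (is.null(names(moving)))
    names(moving) <- vapply(moving, channel_id, character(1))
  detect <- function(tab) {
    if (mode == "fiducial") detect_fiducials(tab, params)
    else detect_clusters(tab, r_c = r_c, k = k)
  }
  ref_lm <- detect(reference)
  channels <- lapply(moving, function(tab) {
    lm <- detect(tab)
    res <- icp(lm, ref_lm, config)
    corrected <- apply_transform(tab, res$transform)
    if (strip_fiducials) {
      lm_corr <- lm
      xy <- transform_points(res$transform, landmark_coords(lm))
      lm_corr$x <- xy[, 1]; lm_corr$y <- xy[, 2]
      corrected <- remove_fiducials(corrected, lm_corr, strip_diameter)
    }
    list(table = corrected, landmarks = lm, result = res)
  })
  ref_out <- if (strip_fiducials)
    remove_fiducials(reference, ref_lm, strip_diameter) else reference
  structure(list(reference = ref_out, reference_landmarks = ref_lm,
                 channels = channels),
            class = "registration_run")
}

#' Run a batch of registration jobs from a YAML job file
#'
#' The job file is a YAML document with an optional `defaults` mapping and
#' a `jobs` list; each job names a `reference` CSV, one or more `moving`
#' CSVs, and may override any default.  Recognized keys per job:
#' `name`, `mode` ("fiducial"/"cluster"), `r`, `mt_min`, `vl_max`,
#' `frame_range` (two-element list, applied at detection time), `r_c`,
#' `k`, `min_intensity`, `convergence_tol`, `max_iterations`,
#' `outlier_sd`, `remove_fiducials` (logical), `diameter`, `out_dir`.
#'
#' Each job writes one corrected CSV per moving channel
#' (`<input>_registered.csv`) plus a JSON sidecar with the transform and
#' ICP diagnostics.  A failing job is reported and skipped; the remaining
#' jobs still run.
#'
#' @param jobfile path to the YAML job file.
#' @param out_dir default output directory (overridable per job).
#' @param quiet suppress per-job progress messages.
#' @return Invisibly, a data.frame with one row per job: `name`, `ok`,
#'   `message`, `n_outputs`.
#' @export
run_jobs <- function(jobfile, out_dir = ".", quiet = FALSE) {
  spec <- yaml::read_yaml(jobfile)
  if (is.null(spec$jobs) || !length(spec$jobs))
    stop("job file has no 'jobs' list: ", jobfile)
  defaults <- spec$defaults %||% list()
  say <- function(...) if (!quiet) message(...)
  rows <- lapply(seq_along(spec$jobs), function(j) {
    job <- utils::modifyList(defaults, spec$jobs[[j]])
    name <- job$name %||% paste0("job", j)
    out <- tryCatch({
      n_out <- run_one_job(job, out_dir, say)
      data.frame(name = name, ok = TRUE, message = "ok", n_outputs = n_out)
    }, error = function(e) {
      say("job '", name, "' FAILED: ", conditionMessage(e))
      data.frame(name = name, ok = FALSE, message = conditionMessage(e),
                 n_outputs = 0L)
    })
    out
  })
  invisible(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_job_channel <- function(path, job) {
  tab <- read_localizations(path)
  min_int <- job[["min_intensity"]] %||% 0
  if (min_int > 0) tab <- filter_by_intensity(tab, min_int)
  tab
}

run_one_job <- function(job, out_dir, say) {
  if (is.null(job$reference) || is.null(job$moving))
    stop("job needs 'reference' and 'moving' entries")
  paths <- c(job$reference, unlist(job$moving))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir <- job$out_dir %||% out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mode <- job[["mode"]] %||% "fiducial"
  fr <- job[["frame_range"]]
  params <- detection_params(r = job[["r"]] %||% 100,  # [[ ]]: no partial match
                             mt_min = job[["mt_min"]] %||% 0.5,
                             vl_max = job[["vl_max"]] %||% 0.25,
                             frame_first = if (!is.null(fr)) fr[[1]],
                             frame_last = if (!is.null(fr)) fr[[2]])
  config <- icp_config(convergence_tol = job[["convergence_tol"]] %||% 1,
                       max_iterations = job[["max_iterations"]] %||% 100,
                       outlier_sd = job[["outlier_sd"]] %||% 1)
  reference <- load_job_channel(job$reference, job)
  moving <- lapply(unlist(job$moving), load_job_channel, job = job)
  names(moving) <- vapply(moving, channel_id, character(1))
  run <- register_channels(reference, moving, mode = mode, params = params,
                           r_c = job[["r_c"]] %||% 750, k = job[["k"]] %||% 25,
                           config = config,
                           strip_fiducials = isTRUE(job[["remove_fiducials"]]),
                           strip_diameter = job[["diameter"]] %||% 100)
  n_out <- 0L
  for (i in seq_along(run$channels)) {
    ch <- run$channels[[i]]
    in_path <- unlist(job$moving)[i]
    stem <- sub("\\.[^.]*$", "", basename(in_path))
    csv_path <- file.path(dir, paste0(stem, "_registered.csv"))
    write_localizations(ch$table, csv_path)
    sidecar <- list(theta = ch$result$transform$theta,
                    tx = ch$result$transform$tx,
                    ty = ch$result$transform$ty,
                    n_iterations = ch$result$n_iterations,
                    converged = ch$result$converged,
                    final_mean_distance = ch$result$final_mean_distance,
                    n_landmarks_moving = nrow(ch$landmarks),
                    n_landmarks_reference = nrow(run$reference_landmarks),
                    n_matched_pairs = nrow(ch$result$matched_pairs))
    jsonlite::write_json(sidecar, paste0(csv_path, ".transform.json"),
                         auto_unbox = TRUE, digits = NA)
    say(sprintf(
      "  %s: %d/%d landmarks, %d iteration(s), mean distance %.2f nm -> %s",
      names(run$channels)[i], nrow(ch$landmarks),
      nrow(run$reference_landmarks), ch$result$n_iterations,
      ch$result$final_mean_distance, basename(csv_path)))
    n_out <- n_out + 1L
  }
  n_out
}
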