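# Localization tables: the native data unit of SMLM.  One row per detected
# blink: frame index, x/y in nanometres, optional photon-scale intensity and
# localization uncertainty.  Stored as a plain data.frame with attributes so
# all of base R keeps working on them.

#' Construct a localization table
#'
#' A localization table holds every localization of one channel: one row per
#' single-molecule blink with its acquisition frame and coordinates in
#' nanometres.  It is a plain `data.frame` carrying the channel label and the
#' number of acquisition frames as attributes, so standard data-frame
#' operations apply.
#'
#' @param frame integer vector of 1-based acquisition frame indices.
#' @param x,y numeric vectors of coordinates in nanometres.
#' @param intensity optional numeric vector of photon-scale intensities
#'   (non-negative).  `NULL` means the channel carries no intensity column.
#' @param uncertainty optional numeric vector of localization uncertainties
#'   in nanometres.
#' @param channel_id free-form channel label, e.g. `"642"`.
#' @param n_frames number of acquisition frames.  Defaults to the largest
#'   frame index present; may be declared larger (frames with zero
#'   localizations still count in per-frame statistics).
#'
#' @return An object of class `loc_table`: a `data.frame` with columns
#'   `frame`, `x`, `y` and optionally `intensity`, `uncertainty`, plus
#'   attributes `channel_id` and `n_frames`.
#' @examples
#' tab <- loc_table(frame = c(1, 1, 2), x = c(0, 50, 10), y = c(0, 0, 5))
#' n_frames(tab)
#' @export
loc_table <- function(frame, x, y, intensity = NULL, uncertainty = NULL,
                      channel_id = "ch", n_frames = NULL) {
  frame <- as.integer(frame)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(frame) != length(x) || length(x) != length(y))
    stop("frame, x and y must have equal length")
  if (length(frame) && any(frame < 1L))
    stop("frame indices must be >= 1 (1-based)")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("coordinates must be finite")
  df <- data.frame(frame = frame, x = x, y = y)
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != nrow(df))
      stop("intensity length mismatch")
    if (length(intensity) && any(intensity < 0, na.rm = TRUE))
      stop("intensity must be non-negative")
    df$intensity <- intensity
  }
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (length(uncertainty) != nrow(df))
      stop("uncertainty length mismatch")
    df$uncertainty <- uncertainty
  }
  max_frame <- if (nrow(df)) max(df$frame) else 0L
  if (is.null(n_frames)) n_frames <- max_frame
  n_frames <- as.integer(n_frames)
  if (n_frames < max_frame)
    stop("n_frames (", n_frames, ") is smaller than the largest frame index (",
         max_frame, ")")
  structure(df,
            channel_id = as.character(channel_id),
            n_frames = n_frames,
            class = c("loc_table", "data.frame"))
}

#' @rdname loc_table
#' @param table a `loc_table`.
#' @export
n_frames <- function(table) attr(table, "n_frames")

#' @rdname loc_table
#' @export
channel_id <- function(table) attr(table, "channel_id")

# Rebuild a loc_table from a subset of rows, keeping metadata.
relabel_table <- function(df, template, n_frames = attr(template, "n_frames")) {
  rownames(df) <- NULL
  structure(df,
            channel_id = attr(template, "channel_id"),
            n_frames = as.integer(n_frames),
            dialect = attr(template, "dialect"),
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: channel '%s', %d localizations, %d frames\n",
              channel_id(x), nrow(x), n_frames(x)))
  NextMethod()
}

#' Default column-name aliases for localization CSV files
#'
#' Maps the internal column names to the header names accepted on import.
#' The first alias of each entry is also the header written on export when
#' the input dialect is unknown.  Defaults cover the ThunderSTORM export
#' dialect (`"x [nm]"`) and bare names (`"x"`) used by other reconstruction
#' software.
#'
#' @return Named list of character vectors of accepted header names.
#' @export
default_aliases <- function() {
  list(frame = c("frame", "frame_ix", "t"),
       x = c("x [nm]", "x", "x_nm", "xnm"),
       y = c("y [nm]", "y", "y_nm", "ynm"),
       intensity = c("intensity [photon]", "intensity", "intensity_photon"),
       uncertainty = c("uncertainty [nm]", "uncertainty",
                       "uncertainty_xy [nm]"))
}

match_alias <- function(headers, aliases) {
  hit <- match(tolower(aliases), tolower(trimws(headers)))
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a localization table from CSV
#'
#' Reads a ThunderSTORM-style comma-separated localization file: a header
#' row naming at least the frame, x and y columns, then one row per
#' localization with coordinates in nanometres.  Header names are matched
#' case-insensitively against a configurable alias map, so both
#' `"x [nm]"` and plain `"x"` dialects import.  Rows whose frame or
#' coordinate fields are not numeric are dropped with a warning.
#'
#' @param path path to a CSV file.
#' @param aliases alias map as returned by [default_aliases()]; entries may
#'   be overridden to match other export dialects.
#' @param channel_id channel label stored on the result; defaults to the
#'   file name without extension.
#' @param n_frames optional declared number of acquisition frames (defaults
#'   to the maximum frame index found).
#'
#' @return A [loc_table]. The original header spellings are kept in the
#'   `dialect` attribute so [write_localizations()] reproduces them.
#' @seealso [write_localizations()]
#' @export
read_localizations <- function(path, aliases = default_aliases(),
                               channel_id = NULL, n_frames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    stop("empty localization file (no data rows): ", path)
  headers <- names(raw)
  cols <- vapply(names(aliases), function(nm) match_alias(headers, aliases[[nm]]),
                 integer(1))
  for (mandatory in c("frame", "x", "y")) {
    if (is.na(cols[[mandatory]]))
      stop("missing mandatory column '", mandatory, "'; accepted header names: ",
           paste(sQuote(aliases[[mandatory]]), collapse = ", "))
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  frame <- num(raw[[cols[["frame"]]]])
  x <- num(raw[[cols[["x"]]]])
  y <- num(raw[[cols[["y"]]]])
  ok <- is.finite(frame) & is.finite(x) & is.finite(y)
  if (any(!ok))
    warning(sum(!ok), " row(s) with non-numeric frame/x/y rejected")
  if (!any(ok))
    stop("no valid localization rows in ", path)
  intensity <- if (!is.na(cols[["intensity"]])) num(raw[[cols[["intensity"]]]])[ok]
  uncertainty <- if (!is.na(cols[["uncertainty"]])) num(raw[[cols[["uncertainty"]]]])[ok]
  if (is.null(channel_id))
    channel_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- loc_table(frame[ok], x[ok], y[ok], intensity = intensity,
                   uncertainty = uncertainty, channel_id = channel_id,
                   n_frames = n_frames)
  dialect <- vapply(names(cols), function(nm) {
    i <- cols[[nm]]
    if (is.na(i)) NA_character_ else headers[i]
  }, character(1))
  attr(tab, "dialect") <- dialect
  tab
}

#' Write a localization table to CSV
#'
#' Writes the table back in the dialect it was read with (ThunderSTORM
#' headers by default), so the output re-imports both here and in
#' ThunderSTORM/Fiji.  Coordinates are written with ten decimal places
#' (1e-10 nm), which round-trips exactly under repeated write/read.
#'
#' @param table a non-empty [loc_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "loc_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty localization table")
  dialect <- attr(table, "dialect")
  hdr_for <- function(nm) {
    if (!is.null(dialect) && !is.na(dialect[[nm]])) dialect[[nm]]
    else default_aliases()[[nm]][1]
  }
  cols <- c("frame", "x", "y")
  if (!is.null(table$intensity)) cols <- c(cols, "intensity")
  if (!is.null(table$uncertainty)) cols <- c(cols, "uncertainty")
  header <- paste(sprintf('"%s"', vapply(cols, hdr_for, character(1))),
                  collapse = ",")
  fmt <- list(frame = function(v) sprintf("%d", as.integer(v)),
              x = function(v) sprintf("%.10f", v),
              y = function(v) sprintf("%.10f", v),
              intensity = function(v) sprintf("%.4f", v),
              uncertainty = function(v) sprintf("%.4f", v))
  body <- do.call(paste, c(lapply(cols, function(nm) fmt[[nm]](table[[nm]])),
                           sep = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Filter localizations by intensity
#'
#' Drops localizations with intensity strictly below `min_intensity`
#' (values equal to the threshold are kept), the background/noise filter
#' applied at import for dim channels.
#'
#' @param table a [loc_table].
#' @param min_intensity non-negative intensity threshold; `0` is the
#'   identity.
#' @return A [loc_table] with the surviving rows, metadata unchanged.
#' @export
filter_by_intensity <- function(table, min_intensity) {
  stopifnot(inherits(table, "loc_table"), min_intensity >= 0)
  if (min_intensity == 0) return(table)
  if (is.null(table$intensity))
    stop("table has no intensity column but min_intensity > 0; ",
         "refusing to silently pass all rows")
  keep <- table$intensity >= min_intensity
  relabel_table(as.data.frame(table)[keep, , drop = FALSE], table)
}

#' Restrict a localization table to a frame range
#'
#' Keeps localizations with `first <= frame <= last` (both ends inclusive)
#' and re-indexes the surviving frames to `1..(last - first + 1)`, so that
#' the per-frame detection statistics normalize over the included frames
#' only.  Used to exclude late frames where fiducial emission has bleached.
#'
#' @param table a [loc_table].
#' @param first,last 1-based frame range, `1 <= first <= last`.
#' @return A [loc_table] with `n_frames = last - first + 1`.
#' @export
restrict_frames <- function(table, first, last) {
  stopifnot(inherits(table, "loc_table"))
  first <- as.integer(first); last <- as.integer(last)
  if (first < 1L || last < first)
    stop("invalid frame range: need 1 <= first <= last")
  keep <- table$frame >= first & table$frame <= last
  if (!any(keep))
    warning("frame restriction [", first, ", ", last, "] leaves no localizations")
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out$frame <- out$frame - first + 1L
  relabel_table(out, table, n_frames = last - first + 1L)
}
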