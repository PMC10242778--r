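# Post-registration cleanup: strip the fiducial-bead localizations so the
# final visualization shows only the sample signal.

#' Remove fiducial localizations from a table
#'
#' Drops every localization with Euclidean distance strictly below
#' `diameter` from any landmark.  The removal radius is one full fiducial
#' diameter (not a radius of diameter/2): bead localizations scatter by
#' the localization precision around the bead surface, so a one-diameter
#' clearance removes the bead signal cleanly.
#'
#' @param table a [loc_table].
#' @param landmarks a `landmark_set` (typically from [detect_fiducials()]);
#'   an empty set returns the table unchanged with a warning.
#' @param diameter removal radius in nm (default 100, the fiducial
#'   diameter).
#' @return A [loc_table] with the surviving localizations in their
#'   original order.
#' @export
remove_fiducials <- function(table, landmarks, diameter = 100) {
  stopifnot(inherits(table, "loc_table"), diameter > 0)
  if (is.null(landmarks) || nrow(landmarks) == 0L) {
    warning("empty landmark set: nothing to remove")
    return(table)
  }
  nb <- radius_neighbors(table$x, table$y,
                         landmarks$x, landmarks$y, diameter)
  drop <- unique(unlist(nb, use.names = FALSE))
  keep <- rep(TRUE, nrow(table))
  if (length(drop)) keep[drop] <- FALSE
  relabel_table(as.data.frame(table)[keep, , drop = FALSE], table)
}
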