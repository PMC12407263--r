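# Post-processing of binary masks into discrete, role-labeled peak
# segments.

#' Peak segment
#'
#' A half-open index range \code{[start, end)} on the 512-sample profile
#' axis, with the apex (index of the profile extremum inside the run) and
#' an assigned line role.
#'
#' @param start,end half-open bounds, \code{1 <= start < end <= 513}.
#' @param apex extremum index, \code{start <= apex < end}.
#' @param role \code{"test"}, \code{"antigen"}, \code{"control"} or
#'   \code{"unassigned"}.
#' @return object of class \code{peak_segment}.
#' @export
peak_segment <- function(start, end, apex,
                         role = c("unassigned", "test", "antigen",
                                  "control")) {
  role <- match.arg(role)
  stopifnot(start >= 1, start < end, end <= 513, apex >= start, apex < end)
  structure(list(start = as.integer(start), end = as.integer(end),
                 apex = as.integer(apex), role = role),
            class = "peak_segment")
}

#' @export
print.peak_segment <- function(x, ...) {
  cat(sprintf("Peak segment [%d, %d), apex %d, role %s\n",
              x$start, x$end, x$apex, x$role))
  invisible(x)
}

#' Extract peak segments from a binary mask
#'
#' Maximal runs of 1s in the mask become segments; runs shorter than
#' \code{min_width} samples are discarded as noise (at the 512-sample
#' resolution 4 samples correspond to roughly the physical floor of a
#' printed line width). The apex of each segment is the index of the
#' profile maximum within the run. Segments are returned ordered by
#' start; an empty list is allowed.
#'
#' @param mask integer/logical vector of length 512.
#' @param profile an [intensity_profile()] or numeric length-512 vector
#'   (used for apex location).
#' @param min_width minimum run width in samples.
#' @return list of [peak_segment()] objects.
#' @export
segments_from_mask <- function(mask, profile, min_width = 4L) {
  if (length(mask) != 512)
    stop_domain("mask must have length 512 (contract error)")
  v <- if (inherits(profile, "intensity_profile")) profile$values else profile
  stopifnot(length(v) == 512)
  r <- rle(as.integer(mask) == 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_width)
  lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k] + 1L
    apex <- s - 1L + which.max(v[s:(e - 1L)])
    peak_segment(s, e, apex)
  })
}

# Expected number of segments per readout class.
class_expected_count <- function(readout_class) {
  switch(readout_class,
         control_only = 1L,
         test_and_control = 2L,
         test_antigen_and_control = 3L,
         stop_domain(paste("unknown readout class:", readout_class)))
}

#' Assign line roles to peak segments
#'
#' Checks that the number of segments matches the readout class
#' (otherwise raises an \code{lfa_invalid_test} error prompting
#' re-classification), then assigns each segment the role of the nearest
#' expected line position from the layout, each role used at most once.
#' A valid assignment must include the control line.
#'
#' @param segments list of [peak_segment()]s ordered by start.
#' @param readout_class a readout class string (see [classify_readout()]).
#' @param layout a [strip_layout()] giving expected line positions as
#'   fractions of the readout-zone length.
#' @return the segments with roles filled in.
#' @export
assign_roles <- function(segments, readout_class, layout) {
  n <- length(segments)
  expected <- class_expected_count(readout_class)
  if (n != expected)
    stop(structure(class = c("lfa_invalid_test", "error", "condition"),
                   list(message = sprintf(
                     "segment count %d inconsistent with readout class %s (expected %d)",
                     n, readout_class, expected), call = NULL)))
  roles <- layout$lines$role
  centers <- layout$lines$center * 512
  used <- rep(FALSE, length(roles))
  out <- segments
  for (i in seq_along(segments)) {
    apex <- segments[[i]]$apex
    d <- abs(centers - apex)
    d[used] <- Inf
    k <- which.min(d)
    used[k] <- TRUE
    out[[i]]$role <- roles[k]
  }
  if (!"control" %in% vapply(out, `[[`, "", "role"))
    stop(structure(class = c("lfa_invalid_test", "error", "condition"),
                   list(message = "no segment assignable to the control line: invalid test",
                        call = NULL)))
  out
}
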