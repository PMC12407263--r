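# Strip geometry: line placement and readout-zone location.

#' Construct a strip layout
#'
#' Geometry of a lateral-flow strip: overall pixel dimensions, the readout
#' zone (the region where the colored lines appear, as a fractional
#' axis-aligned box), and the ordered lines inside it. The flow direction
#' is left to right in canonical crops; the control line is always the
#' last (rightmost) line.
#'
#' @param strip_length_px,strip_width_px integer strip dimensions in pixels
#'   (length is along the flow direction).
#' @param readout_zone numeric length-4 \code{c(x0, y0, x1, y1)} in
#'   fractions of strip length/width; must lie inside \code{[0,1]}.
#' @param lines data.frame with columns \code{role} (one of \code{"test"},
#'   \code{"antigen"}, \code{"control"}), \code{center} (fraction of
#'   readout-zone length, strictly increasing) and \code{width_px}
#'   (nominal full line width in strip pixels).
#' @param format \code{"line_based"} or \code{"dot_based"} (dot-based
#'   multiplex designs print the same roles as short dashes; the profile
#'   geometry along the flow axis is identical).
#' @return an object of class \code{strip_layout}.
#' @export
strip_layout <- function(strip_length_px = 400L, strip_width_px = 80L,
                         readout_zone = c(0.30, 0.12, 0.80, 0.88),
                         lines,
                         format = c("line_based", "dot_based")) {
  format <- match.arg(format)
  stopifnot(strip_length_px >= 32, strip_width_px >= 16,
            length(readout_zone) == 4L,
            all(readout_zone >= 0), all(readout_zone <= 1),
            readout_zone[1] < readout_zone[3],
            readout_zone[2] < readout_zone[4])
  stopifnot(is.data.frame(lines),
            all(c("role", "center", "width_px") %in% names(lines)))
  lines$role <- as.character(lines$role)
  if (!all(lines$role %in% c("test", "antigen", "control")))
    stop_domain("line roles must be test, antigen or control")
  if (sum(lines$role == "control") != 1L)
    stop_domain("layout must contain exactly one control line")
  if (any(diff(lines$center) <= 0))
    stop_domain("line centers must be strictly increasing along the flow direction")
  if (any(lines$center <= 0 | lines$center >= 1))
    stop_domain("line centers must lie strictly inside the readout zone")
  if ("antigen" %in% lines$role && nrow(lines) != 3L)
    stop_domain("antigen lines occur only in three-line layouts")
  structure(list(strip_length_px = as.integer(strip_length_px),
                 strip_width_px = as.integer(strip_width_px),
                 readout_zone = as.numeric(readout_zone),
                 lines = lines, format = format),
            class = "strip_layout")
}

#' Default two- and three-line layouts
#'
#' Both place the outermost lines at the same fractions of the readout
#' zone (0.25 and 0.80), so zone extent can be inferred from the line span
#' alone; the three-line design adds the competitive antigen line between
#' them. Line width defaults to 7 px on a 400 px strip.
#'
#' @param n_lines 2 (test + control) or 3 (test + antigen + control).
#' @param ... passed on to [strip_layout()].
#' @return a \code{strip_layout}.
#' @export
default_layout <- function(n_lines = 2, ...) {
  lines <- if (n_lines == 2) {
    data.frame(role = c("test", "control"),
               center = c(0.25, 0.80), width_px = 7)
  } else if (n_lines == 3) {
    data.frame(role = c("test", "antigen", "control"),
               center = c(0.25, 0.525, 0.80), width_px = 7)
  } else stop_domain("n_lines must be 2 or 3")
  strip_layout(lines = lines, ...)
}

#' @export
print.strip_layout <- function(x, ...) {
  cat(sprintf("Strip layout (%s): %d x %d px, readout zone [%.2f,%.2f]x[%.2f,%.2f]\n",
              x$format, x$strip_length_px, x$strip_width_px,
              x$readout_zone[1], x$readout_zone[3],
              x$readout_zone[2], x$readout_zone[4]))
  print(x$lines, row.names = FALSE)
  invisible(x)
}

# Line centers in absolute strip-x pixels.
line_centers_px <- function(layout) {
  z <- layout$readout_zone
  x0 <- z[1] * layout$strip_length_px
  x1 <- z[3] * layout$strip_length_px
  x0 + layout$lines$center * (x1 - x0)
}

# Readout zone as an absolute pixel box c(x0, y0, x1, y1) in strip coords.
zone_box_px <- function(layout) {
  z <- layout$readout_zone
  c(z[1] * layout$strip_length_px, z[2] * layout$strip_width_px,
    z[3] * layout$strip_length_px, z[4] * layout$strip_width_px)
}
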