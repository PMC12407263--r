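# Deterministic readout-zone detection, profile extraction, classification.

#' Intensity profile of a readout zone
#'
#' A positionally indexed 1-D line scan: intensities are inverted channel
#' values (darker lines become peaks), resampled to exactly 512 samples
#' (the segmentation model's input contract). The background level is a
#' robust low quantile of the profile, so line intensities measured
#' against it are invariant to adding a constant to the whole profile.
#'
#' @param values numeric vector of inverted intensities (any length >= 8;
#'   resampled to 512).
#' @param channel colour channel the values came from.
#' @return an object of class \code{intensity_profile} with fields
#'   \code{values} (length 512), \code{axis} (normalized position in
#'   \code{[0,1]}), \code{channel}, \code{background_level}.
#' @export
intensity_profile <- function(values, channel = "green") {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 8) stop_domain("profile needs at least 8 samples")
  v <- if (length(values) == 512) values else resample_linear(values, 512)
  structure(list(values = v,
                 axis = seq(0, 1, length.out = 512),
                 channel = channel,
                 background_level = unname(stats::quantile(v, 0.10))),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile: 512 samples (%s channel), background %.4f, max %.4f\n",
              x$channel, x$background_level, max(x$values)))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(x$axis, x$values, type = "l", xlab = "position",
                 ylab = "inverted intensity", ...)
  graphics::abline(h = x$background_level, lty = 2)
  invisible(x)
}

# Crop an axis-aligned pixel box c(x0, y0, x1, y1) from an image array.
crop_box <- function(image, box) {
  H <- dim(image)[1]; W <- dim(image)[2]
  j0 <- max(1L, round(box[1]) + 1L); j1 <- min(W, round(box[3]))
  i0 <- max(1L, round(box[2]) + 1L); i1 <- min(H, round(box[4]))
  if (j1 <= j0 || i1 <= i0) stop_domain("empty crop box")
  image[i0:i1, j0:j1, , drop = FALSE]
}

#' Extract the intensity profile of a cropped readout zone
#'
#' Implements the standard strip-reader measurement: take one colour
#' channel of the rectified zone crop, aggregate each column with a
#' trimmed mean across the transverse direction (trimming suppresses
#' specular highlights and stray fibres), invert so that darker lines
#' become peaks, and resample to 512 positions.
#'
#' @param zone_image RGB array (values in \code{[0,1]}), the cropped
#'   readout zone with the flow direction along columns.
#' @param channel \code{"green"} (default: red-dominant lines absorb green
#'   most strongly), \code{"red"} or \code{"blue"}.
#' @param trim trim fraction of the transverse trimmed mean.
#' @return an [intensity_profile()].
#' @export
extract_intensity_profile <- function(zone_image, channel = "green",
                                      trim = 0.1) {
  channel <- match.arg(channel, c("red", "green", "blue"))
  stopifnot(length(dim(zone_image)) == 3)
  if (dim(zone_image)[2] < 8)
    stop_domain("readout zone narrower than 8 px (geometry error)")
  ch <- match(channel, c("red", "green", "blue"))
  plane <- zone_image[, , ch]
  col_mean <- apply(plane, 2, mean, trim = trim)
  intensity_profile(1 - col_mean, channel = channel)
}

#' Background-subtracted intensity of a line
#'
#' The line intensity is the absolute contrast of the segment's extremum
#' against the profile background level: peak value minus background,
#' reported non-negative.
#'
#' @param profile an [intensity_profile()].
#' @param segment a \code{peak_segment} (see [segments_from_mask()]) or a
#'   length-2 integer \code{c(start, end)} half-open index range.
#' @return non-negative scalar intensity.
#' @export
line_intensity <- function(profile, segment) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (inherits(segment, "peak_segment")) segment <- c(segment$start, segment$end)
  s <- as.integer(segment[1]); e <- as.integer(segment[2])
  if (e <= s || s < 1 || e > 513)
    stop_domain("segment must be a non-empty range within the profile")
  v <- profile$values[s:(e - 1)]
  max(abs(v - profile$background_level))
}

# Robust per-sample noise SD of a profile (from first differences, which
# cancel the slowly varying line shapes and illumination trend).
profile_noise_sd <- function(values) {
  stats::mad(diff(values)) / sqrt(2)
}

# Sub-pixel peak apexes of a profile: local maxima above a noise-scaled
# prominence threshold, refined by quadratic interpolation. Returns a
# data.frame(position, height) in profile sample units, ordered by
# position. Used by both classification and zone inference.
find_profile_peaks <- function(values, min_height = NULL,
                               min_distance = 60) {
  ns <- profile_noise_sd(values)
  base <- stats::median(values)
  if (is.null(min_height)) min_height <- base + max(6 * ns, 0.04)
  pk <- pracma::findpeaks(values, minpeakheight = min_height,
                          minpeakdistance = min_distance)
  if (is.null(pk)) return(data.frame(position = numeric(0),
                                     height = numeric(0)))
  pos <- pk[, 2]
  # quadratic apex refinement
  ref <- vapply(pos, function(i) {
    if (i <= 1 || i >= length(values)) return(as.numeric(i))
    y0 <- values[i - 1]; y1 <- values[i]; y2 <- values[i + 1]
    d <- y0 - 2 * y1 + y2
    if (d >= 0) as.numeric(i) else i + 0.5 * (y0 - y2) / d
  }, numeric(1))
  o <- order(ref)
  data.frame(position = ref[o], height = pk[o, 1])
}

#' Classify the readout type of a profile
#'
#' Counts candidate peaks exceeding a noise-scaled prominence threshold
#' and maps the count to the three readout categories used for
#' gold-nanoparticle strips: one visible line (the control), two lines
#' (test and control) or three lines (test, antigen and control). A
#' profile with no candidate peaks has no control line, which by standard
#' LFA validity rules is a failed test and raises an error of class
#' \code{lfa_invalid_test}.
#'
#' @param profile an [intensity_profile()].
#' @return one of \code{"control_only"}, \code{"test_and_control"},
#'   \code{"test_antigen_and_control"}.
#' @export
classify_readout <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  pk <- find_profile_peaks(profile$values)
  n <- nrow(pk)
  if (n == 0)
    stop(structure(class = c("lfa_invalid_test", "error", "condition"),
                   list(message = "no visible lines: invalid (failed) test",
                        call = NULL)))
  class_from_visible(min(n, 3L))
}

#' Detection result for a readout zone
#' @param bbox pixel box \code{c(x0, y0, x1, y1)} in image coordinates.
#' @param confidence detection confidence in \code{[0,1]}.
#' @param extra internal fields (rectification parameters).
#' @return object of class \code{detection_result}; \code{accepted} is
#'   \code{TRUE} iff \code{confidence >= 0.8}.
#' @keywords internal
detection_result <- function(bbox, confidence, extra = list()) {
  structure(c(list(bbox = bbox, confidence = confidence,
                   accepted = confidence >= 0.8), extra),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (is.null(x$bbox)) cat("Readout zone: not found (confidence 0)\n")
  else cat(sprintf(
    "Readout zone: [%.1f, %.1f, %.1f, %.1f], confidence %.3f (%s)\n",
    x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], x$confidence,
    if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Locate the readout zone in a strip or pad image
#'
#' Deterministic detector: (1) segment the pale membrane from the darker
#' pad by thresholding the per-pixel channel minimum; (2) estimate the
#' strip's in-plane angle from the mask's second moments and derotate;
#' (3) find the strip box from marginal runs of the mask; (4) locate line
#' peaks in the strip's column profile and infer the readout-zone extent
#' from the outermost peak positions (the layout convention places the
#' outer lines at fixed fractions 0.25 and 0.80 of the zone length);
#' (5) map the zone box back to image coordinates and report the
#' axis-aligned bounding box. The confidence is a saturating map of the
#' strongest peak's signal-to-noise ratio into \code{[0,1]}; the zone is
#' accepted iff confidence >= 0.8. Never raises on feature-less images:
#' returns confidence 0 instead.
#'
#' @param image RGB array in \code{[0,1]} (at least 64 x 64 px).
#' @param pale_threshold membrane segmentation threshold on
#'   \code{min(R,G,B)}.
#' @return a \code{detection_result}; when accepted, carries internal
#'   rectification fields (\code{angle_deg}, \code{center},
#'   \code{bbox_rect}, \code{rectified}) used by the analysis pipeline to
#'   crop a rectified zone.
#' @export
detect_readout_zone <- function(image, pale_threshold = 0.62) {
  stopifnot(length(dim(image)) == 3)
  if (dim(image)[1] < 64 || dim(image)[2] < 64)
    stop_domain("image must be at least 64 x 64 px")
  none <- detection_result(NULL, 0)
  mask <- pmin(image[, , 1], image[, , 2], image[, , 3]) > pale_threshold
  if (sum(mask) < 800) return(none)

  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  sxx <- stats::var(idx[, 2]); syy <- stats::var(idx[, 1])
  sxy <- stats::cov(idx[, 2], idx[, 1])
  angle <- 0.5 * atan2(2 * sxy, sxx - syy)       # radians, principal axis
  if (abs(angle) > 20 * pi / 180) angle <- 0     # outside supported range

  rect <- rotate_about(image, -angle, c(cx, cy))
  rmask <- pmin(rect[, , 1], rect[, , 2], rect[, , 3]) > pale_threshold
  cs <- colSums(rmask); rs <- rowSums(rmask)
  # dark lines punch holes in the membrane mask: close short gaps before
  # taking the longest run, so the strip is not split at a strong line
  xr <- largest_run(close_gaps(cs > 0.5 * max(cs), 40))
  yr <- largest_run(close_gaps(rs > 0.5 * max(rs), 10))
  if (is.null(xr) || is.null(yr) || diff(xr) < 32 || diff(yr) < 8)
    return(none)

  strip <- rect[yr[1]:yr[2], xr[1]:xr[2], , drop = FALSE]
  inner <- round(nrow(strip) * c(0.15, 0.85))
  plane <- strip[max(1, inner[1]):min(nrow(strip), inner[2]), , 2]
  prof <- 1 - apply(plane, 2, mean, trim = 0.1)
  ns <- profile_noise_sd(prof)
  pk <- find_profile_peaks(prof, min_height = stats::median(prof) +
                             max(6 * ns, 0.04),
                           min_distance = 20)
  if (nrow(pk) == 0) {
    snr <- (max(prof) - stats::median(prof)) / max(ns, 1e-6)
    return(detection_result(NULL, snr^2 / (snr^2 + 400)))
  }
  snr <- (max(pk$height) - stats::median(prof)) / max(ns, 1e-6)
  confidence <- snr^2 / (snr^2 + 400)

  # infer zone extent from outer peak positions (layout convention:
  # outer lines at fractions 0.25 / 0.80 of the zone length)
  x_first <- xr[1] - 1 + min(pk$position)
  x_last <- xr[1] - 1 + max(pk$position)
  if (nrow(pk) >= 2) {
    zone_len <- (x_last - x_first) / 0.55
    zx0 <- x_first - 0.25 * zone_len
  } else {
    # a single visible line is the control, which sits at 0.80 of the
    # zone by the layout convention
    zone_len <- (xr[2] - xr[1]) * 0.5
    zx0 <- x_first - 0.80 * zone_len
  }
  zx1 <- zx0 + zone_len
  zx0 <- max(zx0, xr[1] - 1); zx1 <- min(zx1, xr[2])
  sh <- yr[2] - yr[1] + 1
  zy0 <- yr[1] - 1 + 0.12 * sh
  zy1 <- yr[1] - 1 + 0.88 * sh
  bbox_rect <- c(zx0, zy0, zx1, zy1)

  # map back to original image coordinates
  th <- angle
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  corners <- matrix(c(zx0, zy0, zx1, zy0, zx0, zy1, zx1, zy1),
                    ncol = 2, byrow = TRUE)
  tc <- sweep(sweep(corners, 2, c(cx, cy)) %*% t(R), 2, c(cx, cy), "+")
  bbox <- c(min(tc[, 1]), min(tc[, 2]), max(tc[, 1]), max(tc[, 2]))
  detection_result(bbox, confidence,
                   extra = list(angle_deg = angle * 180 / pi,
                                center = c(cx, cy),
                                bbox_rect = bbox_rect,
                                rectified = rect))
}

# Rotate an image by `angle` radians about `center` (x, y), bilinear.
rotate_about <- function(image, angle, center) {
  if (abs(angle) < 1e-9) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  R <- matrix(c(cos(-angle), sin(-angle), -sin(-angle), cos(-angle)), 2, 2)
  grid <- cbind(rep(seq_len(W), each = H) - 0.5,
                rep(seq_len(H), times = W) - 0.5)
  src <- sweep(sweep(grid, 2, center) %*% t(R), 2, center, "+")
  out <- array(0, dim(image))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image[, , ch], src[, 1], src[, 2]),
                          H, W)
  out
}

# Fill FALSE gaps of length <= maxgap that are flanked by TRUE runs.
close_gaps <- function(x, maxgap) {
  r <- rle(x)
  n <- length(r$values)
  if (n >= 3) {
    fill <- !r$values & r$lengths <= maxgap &
      seq_len(n) > 1 & seq_len(n) < n
    r$values[fill] <- TRUE
  }
  inverse.rle(r)
}

# Bounds (first, last index) of the longest TRUE run of a logical vector.
largest_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[k], ends[k])
}

#' Intersection-over-union of two pixel boxes
#' @param a,b boxes \code{c(x0, y0, x1, y1)}.
#' @return IoU in \code{[0,1]}.
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}
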