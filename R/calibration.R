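# Calibration fitting, detection limits and intensity-to-concentration
# inversion.

#' Fit a calibration curve
#'
#' Ordinary least squares of mean replicate intensity on concentration
#' (\code{form = "linear_c"}) or on log10 concentration
#' (\code{form = "linear_log10c"}, the usual choice when the calibrated
#' window spans several decades). Replicate intensities are averaged per
#' concentration before fitting (uniform weights). Blank replicate
#' statistics are stored for limit-of-detection estimation.
#'
#' @param points data.frame with columns \code{concentration} and
#'   \code{intensity}; replicate measurements are additional rows with
#'   the same concentration.
#' @param form \code{"linear_c"} or \code{"linear_log10c"}.
#' @param blanks numeric vector of blank (zero-analyte) replicate
#'   intensities, length >= 2.
#' @param analyte label stored on the curve.
#' @param line_role \code{"test"} (sandwich, increasing) or
#'   \code{"antigen"} (competitive, decreasing).
#' @return object of class \code{lfa_calibration} with slope, intercept,
#'   \code{r_squared}, \code{residual_sd}, blank statistics,
#'   \code{valid_range} (concentration range of the data) and
#'   \code{direction}.
#' @seealso [lod()], [invert_calibration()], [quantify_crp()]
#' @export
fit_calibration <- function(points, form = c("linear_c", "linear_log10c"),
                            blanks, analyte = NA_character_,
                            line_role = c("test", "antigen")) {
  form <- match.arg(form)
  line_role <- match.arg(line_role)
  stopifnot(is.data.frame(points),
            all(c("concentration", "intensity") %in% names(points)))
  if (length(blanks) < 2) stop_domain("need at least 2 blank replicates")
  agg <- stats::aggregate(intensity ~ concentration, points, mean)
  if (nrow(agg) < 4)
    stop_domain("need at least 4 distinct concentrations")
  if (form == "linear_log10c" && any(agg$concentration <= 0))
    stop_domain("log10 form requires strictly positive concentrations")
  x <- if (form == "linear_c") agg$concentration else log10(agg$concentration)
  if (stats::sd(x) == 0) stop_domain("all concentrations identical: cannot fit")
  fit <- stats::lm(agg$intensity ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((agg$intensity - mean(agg$intensity))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot
  sigma <- sqrt(sum(res^2) / stats::df.residual(fit))
  slope <- unname(stats::coef(fit)[2])
  direction <- if (slope >= 0) "increasing" else "decreasing"
  if (direction == "decreasing" && line_role != "antigen")
    warning("decreasing calibration on a test (sandwich) line; ",
            "check the line_role", call. = FALSE)
  structure(list(analyte = analyte, line_role = line_role, form = form,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residual_sd = sigma,
                 blank_mean = mean(blanks), blank_sd = stats::sd(blanks),
                 valid_range = range(agg$concentration),
                 direction = direction,
                 data = agg),
            class = "lfa_calibration")
}

#' @export
print.lfa_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %s (%s line, %s, %s)\n",
              x$analyte, x$line_role, x$form, x$direction))
  cat(sprintf("  intensity = %.5g %+.5g * %s,  R^2 = %.4f, residual SD = %.4g\n",
              x$intercept, x$slope,
              if (x$form == "linear_c") "c" else "log10(c)",
              x$r_squared, x$residual_sd))
  cat(sprintf("  valid range [%g, %g]; blanks: mean %.4g, SD %.4g\n",
              x$valid_range[1], x$valid_range[2], x$blank_mean, x$blank_sd))
  invisible(x)
}

#' @export
coef.lfa_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.lfa_calibration <- function(object, newdata, ...) {
  c_conc <- if (is.data.frame(newdata)) newdata$concentration else newdata
  x <- if (object$form == "linear_c") c_conc else log10(c_conc)
  object$intercept + object$slope * x
}

#' @export
plot.lfa_calibration <- function(x, ...) {
  xs <- if (x$form == "linear_c") x$data$concentration
        else log10(x$data$concentration)
  graphics::plot(xs, x$data$intensity,
                 xlab = if (x$form == "linear_c") "concentration"
                        else "log10 concentration",
                 ylab = "intensity", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Limit of detection from the limit of the blank
#'
#' The limit of the blank is \eqn{\mu_{blank} + 3\sigma_{blank}}; the LOD
#' is its inverse image under the calibration, floored at zero. Defined
#' for increasing (sandwich-line) calibrations only.
#'
#' @param curve an [fit_calibration()] result.
#' @return concentration at the limit of the blank.
#' @examples
#' pts <- data.frame(concentration = 0:5, intensity = 10 + 4 * (0:5))
#' curve <- fit_calibration(pts, "linear_c", blanks = c(8, 10, 12))
#' lod(curve)  # (blank_mean + 3 * blank_sd - 10) / 4
#' @export
lod <- function(curve) {
  stopifnot(inherits(curve, "lfa_calibration"))
  if (curve$direction != "increasing")
    stop_domain("LOD is defined for increasing (sandwich-line) calibrations only")
  if (curve$slope == 0) stop_domain("zero slope: LOD undefined")
  lob <- curve$blank_mean + 3 * curve$blank_sd
  x <- (lob - curve$intercept) / curve$slope
  c_lod <- if (curve$form == "linear_c") x else 10^x
  max(c_lod, 0)
}

#' Signal-to-noise ratio
#'
#' Mean signal intensity divided by the standard deviation of the noise.
#'
#' @param signal_intensities numeric vector of signal measurements.
#' @param noise_intensities numeric vector of noise measurements
#'   (SD must be positive).
#' @return scalar ratio.
#' @export
snr <- function(signal_intensities, noise_intensities) {
  s <- stats::sd(noise_intensities)
  if (!is.finite(s) || s == 0)
    stop_domain("noise standard deviation is zero: SNR undefined")
  mean(signal_intensities) / s
}

#' Coefficient of variation in percent
#'
#' \code{100 * sd(values) / mean(values)}, using the sample (n-1)
#' standard deviation.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' cv(c(8, 10, 12))  # 20
#' @export
cv <- function(values) {
  if (length(values) < 2) stop_domain("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop_domain("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' Invert a calibration curve
#'
#' Maps an intensity back to concentration,
#' \eqn{c = (I - intercept)/slope} (with the log10 transform undone for
#' \code{linear_log10c} curves). The result is clamped to the curve's
#' valid range with an out-of-range flag; concentrations that fall below
#' the curve's limit of detection are flagged \code{below_lod} and should
#' be reported as "< LOD" rather than as a numeric value.
#'
#' @param curve an [fit_calibration()] result.
#' @param intensity finite scalar intensity.
#' @return list with \code{concentration}, \code{below_lod},
#'   \code{out_of_range}.
#' @export
invert_calibration <- function(curve, intensity) {
  stopifnot(inherits(curve, "lfa_calibration"))
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity))
    stop_domain("intensity must be a single finite number")
  if (curve$slope == 0) stop_domain("zero slope: inversion undefined")
  x <- (intensity - curve$intercept) / curve$slope
  c_est <- if (curve$form == "linear_c") x else 10^x
  below <- if (curve$direction == "increasing") c_est < lod(curve) else FALSE
  out <- c_est < curve$valid_range[1] || c_est > curve$valid_range[2]
  list(concentration = min(max(c_est, curve$valid_range[1]),
                           curve$valid_range[2]),
       below_lod = below, out_of_range = out)
}

#' Hook-effect aware CRP quantification
#'
#' The three-line CRP design pairs a sandwich line calibrated on the low
#' window (0-10 ug/mL) with a competitive antigen line calibrated on the
#' high window (10-500 ug/mL), where the sandwich line hooks. The branch
#' is chosen from the antigen line, which is monotone and therefore
#' well-posed at high concentration: if the antigen intensity is at or
#' above its expected value at the 10 ug/mL crossover, the sample is in
#' the low regime and the sandwich line is inverted; otherwise the
#' antigen line is inverted on the high curve.
#'
#' @param test_intensity,antigen_intensity background-subtracted line
#'   intensities.
#' @param low_curve increasing calibration of the sandwich line on the
#'   low window.
#' @param high_curve decreasing calibration of the antigen line on the
#'   high window.
#' @param noise_floor intensity below which a line is considered absent.
#' @return list with \code{concentration}, \code{branch}
#'   (\code{"low"}/\code{"high"}), \code{below_lod}, \code{out_of_range}.
#' @export
quantify_crp <- function(test_intensity, antigen_intensity,
                         low_curve, high_curve, noise_floor = 0.01) {
  stopifnot(inherits(low_curve, "lfa_calibration"),
            inherits(high_curve, "lfa_calibration"))
  if (low_curve$direction != "increasing" ||
      high_curve$direction != "decreasing")
    stop_domain("low curve must be increasing and high curve decreasing")
  if (test_intensity < noise_floor && antigen_intensity < noise_floor)
    stop(structure(class = c("lfa_invalid_test", "error", "condition"),
                   list(message = "both CRP lines below the noise floor: invalid test",
                        call = NULL)))
  crossover <- predict(high_curve, 10)
  if (antigen_intensity >= crossover) {
    r <- invert_calibration(low_curve, test_intensity)
    c(r, branch = "low")
  } else {
    r <- invert_calibration(high_curve, antigen_intensity)
    c(r, branch = "high")
  }
}
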