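# Seeded rendering of synthetic gold-nanoparticle strips.

#' Noise specification for the synthetic renderer
#'
#' Three noise sources act on a rendered strip: a multiplicative Gaussian
#' perturbation of each line's amplitude (relative SD, the dominant source
#' of replicate-to-replicate variation), additive per-pixel Gaussian noise,
#' and a smooth multiplicative illumination gradient across the strip. The
#' defaults reproduce replicate coefficients of variation under 10% for
#' extracted line intensities while still exercising background
#' subtraction.
#'
#' In addition, line placement and width vary slightly from strip to
#' strip (striping-machine tolerance), so peak extents are not a fixed
#' position set and segmentation must be learned from profile shape.
#'
#' @param amplitude_rel_sd relative SD of per-line amplitude noise.
#' @param pixel_sd SD of additive pixel noise (image units, image in
#'   \code{[0,1]}).
#' @param gradient_amp peak-to-centre amplitude of the illumination
#'   gradient (fraction of base brightness).
#' @param center_jitter_px SD of per-line centre placement jitter
#'   (strip pixels).
#' @param width_jitter_rel relative SD of per-line width jitter.
#' @param mottle_sd SD of the smooth low-frequency absorbance mottle
#'   along the flow axis (residual staining of the membrane, e.g. lysed
#'   cells in whole-blood samples); absorbance units.
#' @return a list of class \code{noise_spec}.
#' @export
noise_spec <- function(amplitude_rel_sd = 0.05, pixel_sd = 0.008,
                       gradient_amp = 0.02, center_jitter_px = 1,
                       width_jitter_rel = 0.08, mottle_sd = 0.01) {
  stopifnot(amplitude_rel_sd >= 0, pixel_sd >= 0, gradient_amp >= 0,
            center_jitter_px >= 0, width_jitter_rel >= 0, mottle_sd >= 0)
  structure(list(amplitude_rel_sd = amplitude_rel_sd, pixel_sd = pixel_sd,
                 gradient_amp = gradient_amp,
                 center_jitter_px = center_jitter_px,
                 width_jitter_rel = width_jitter_rel,
                 mottle_sd = mottle_sd),
            class = "noise_spec")
}

# Rendering constants: membrane colour and per-channel absorbance of the
# red-dominant (gold-nanoparticle hue) line pigment. Green absorbs most,
# so the green channel carries maximal line contrast.
.membrane_rgb <- c(0.94, 0.92, 0.89)
.absorbance_k <- c(red = 0.15, green = 0.90, blue = 0.70)

# Minimum nominal signal for a line to count as "visible" in ground truth.
.visible_signal <- 0.05

#' Expected line contrast for a nominal signal
#'
#' The renderer attenuates the green channel of a line with nominal signal
#' \eqn{s} by \eqn{exp(-k_g s)}; after inversion of the profile the
#' expected peak height above background is therefore
#' \eqn{G_0 (1 - e^{-k_g s})} with \eqn{G_0} the membrane green level.
#' Useful for comparing extracted intensities against generator truth.
#'
#' @param signal nominal line signal(s).
#' @param channel colour channel, default \code{"green"}.
#' @return expected inverted-profile peak height above background.
#' @export
render_transfer <- function(signal, channel = "green") {
  ch <- match(match.arg(channel, c("red", "green", "blue")),
              c("red", "green", "blue"))
  .membrane_rgb[ch] * (1 - exp(-.absorbance_k[[ch]] * signal))
}

#' Render a synthetic LFA strip image
#'
#' Draws reddish lines on a pale nitrocellulose-like membrane: each line is
#' a Gaussian absorbance band across the flow direction whose per-channel
#' attenuation follows Beer-Lambert decay with red-dominant pigment
#' constants, so darker lines correspond to larger signals. Dot-based
#' layouts restrict the bands to a central dash. Rendering is a pure
#' function of (inputs, seed).
#'
#' @param layout a [strip_layout()].
#' @param signals named numeric vector of nominal signals, one entry per
#'   line role present in the layout (e.g.
#'   \code{c(test = 0.4, control = 0.8)}).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param concentrations optional named list recorded as ground truth.
#' @return an object of class \code{lfa_sample}: list with \code{image}
#'   (height x width x 3 array in \code{[0,1]}), \code{truth_bbox}
#'   (readout-zone pixel box \code{c(x0, y0, x1, y1)}), \code{truth_class},
#'   \code{truth_mask} (length-512 0/1 labels on the resampled profile
#'   axis), \code{truth_signals}, \code{truth_concentrations},
#'   \code{layout}, \code{seed}.
#' @export
render_strip <- function(layout, signals, noise = noise_spec(), seed = 1L,
                         concentrations = NULL) {
  stopifnot(inherits(layout, "strip_layout"), inherits(noise, "noise_spec"))
  roles <- layout$lines$role
  if (!all(roles %in% names(signals)))
    stop_domain("signals must cover every line role in the layout")
  if (!all(names(signals) %in% roles))
    stop_domain(paste("signal given for role absent from layout:",
                      paste(setdiff(names(signals), roles), collapse = ", ")))
  if (any(signals < 0)) stop_domain("line signals must be non-negative")

  H <- layout$strip_width_px
  W <- layout$strip_length_px
  centers <- line_centers_px(layout)
  sigma <- layout$lines$width_px / 2.355  # width is the FWHM

  with_seed(seed, {
    amp <- signals[roles] * (1 + stats::rnorm(length(roles), 0,
                                              noise$amplitude_rel_sd))
    amp <- pmax(amp, 0)
    # striping tolerance: small per-line placement and width variation
    centers <- centers + stats::rnorm(length(centers), 0,
                                      noise$center_jitter_px)
    sigma <- sigma * pmax(1 + stats::rnorm(length(sigma), 0,
                                           noise$width_jitter_rel), 0.5)
    # absorbance per column (flow axis); dot-based designs confine lines
    # to the central third of the strip width.
    xs <- seq_len(W)
    absorb <- rep(0, W)
    for (i in seq_along(centers))
      absorb <- absorb + amp[i] * exp(-(xs - centers[i])^2 / (2 * sigma[i]^2))
    if (noise$mottle_sd > 0) {
      # smooth residual-staining mottle, correlation length ~12 px
      knots <- stats::rnorm(ceiling(W / 12) + 2, 0, noise$mottle_sd)
      mottle <- stats::approx(seq(0, W + 12, length.out = length(knots)),
                              knots, xout = xs)$y
      absorb <- pmax(absorb + mottle, 0)
    }
    rowmask <- rep(1, H)
    if (layout$format == "dot_based") {
      rowmask <- rep(0, H)
      rowmask[seq(round(H / 3), round(2 * H / 3))] <- 1
    }
    gx <- stats::runif(1, -noise$gradient_amp, noise$gradient_amp)
    gy <- stats::runif(1, -noise$gradient_amp, noise$gradient_amp)
    gain <- outer(1 + gy * (seq_len(H) / H - 0.5),
                  1 + gx * (xs / W - 0.5))
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      att <- exp(-.absorbance_k[ch] * absorb)       # length W
      plane <- .membrane_rgb[ch] * gain *
        (1 + outer(rowmask, att - 1))               # rowmask blends in lines
      plane <- plane + stats::rnorm(H * W, 0, noise$pixel_sd)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }

    visible <- signals[roles] >= .visible_signal
    structure(list(
      image = img,
      truth_bbox = zone_box_px(layout),
      truth_class = class_from_visible(sum(visible)),
      truth_mask = truth_mask_for(layout, visible, centers, sigma),
      truth_signals = signals[roles],
      truth_concentrations = concentrations,
      layout = layout,
      seed = as.integer(seed)
    ), class = "lfa_sample")
  })
}

# Map a count of visible lines to the readout class taxonomy.
class_from_visible <- function(n_visible) {
  if (n_visible <= 0) return("none")
  c("control_only", "test_and_control", "test_antigen_and_control")[
    min(n_visible, 3L)]
}

# Analytic per-pixel peak labels on the 512-sample profile axis: a pixel is
# labelled 1 when it lies within +-2 SD of a visible line centre (at the
# line's rendered, jittered position). Uses the same integer crop
# convention as crop_box()/extract_intensity_profile so labels and
# rendered extents agree after resampling.
truth_mask_for <- function(layout, visible, centers, sigma) {
  box <- zone_box_px(layout)
  j0 <- max(1L, round(box[1]) + 1L)
  j1 <- min(layout$strip_length_px, round(box[3]))
  xp <- j0 + (0:511) * (j1 - j0) / 511          # absolute column per sample
  mask <- rep(0L, 512)
  for (i in seq_along(centers)) {
    if (!visible[i]) next
    mask[abs(xp - centers[i]) <= 2 * sigma[i]] <- 1L
  }
  mask
}

#' @export
print.lfa_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic LFA sample: %d x %d px, class %s, seed %d\n",
              d[2], d[1], x$truth_class, x$seed))
  if (!is.null(x$truth_concentrations))
    cat("  concentrations:",
        paste(names(x$truth_concentrations),
              unlist(x$truth_concentrations), sep = " = ", collapse = ", "),
        "\n")
  cat(sprintf("  zone bbox: [%.0f, %.0f, %.0f, %.0f]\n",
              x$truth_bbox[1], x$truth_bbox[2], x$truth_bbox[3],
              x$truth_bbox[4]))
  invisible(x)
}

#' Render a strip for an analyte at a given concentration
#'
#' Convenience wrapper: evaluates the response model, picks the matching
#' default layout (three lines for hook-effect assays), and renders.
#'
#' @param response an [analyte_response()].
#' @param c_conc concentration.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param layout optional [strip_layout()] override.
#' @return an \code{lfa_sample}.
#' @export
render_assay_strip <- function(response, c_conc, noise = noise_spec(),
                               seed = 1L, layout = NULL) {
  sig <- signal_from_concentration(response, c_conc)
  if (is.null(layout))
    layout <- default_layout(if (is.na(sig[["antigen"]])) 2 else 3)
  signals <- if (nrow(layout$lines) == 3)
    c(test = sig[["test"]], antigen = sig[["antigen"]],
      control = sig[["control"]])
  else c(test = sig[["test"]], control = sig[["control"]])
  conc <- stats::setNames(list(c_conc), response$analyte)
  render_strip(layout, signals, noise, seed, concentrations = conc)
}
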