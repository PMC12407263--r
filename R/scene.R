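# Compositing rendered strips onto textured pad backgrounds.

#' Scene specification for pad compositing
#'
#' Describes how a strip is placed on a textured hygiene-pad background:
#' in-plane rotation (small angles only, as in handheld smartphone
#' capture), a global brightness gain emulating lighting, and a placement
#' offset from the scene centre.
#'
#' @param rotation_deg rotation in degrees, must be within ±15.
#' @param gain brightness gain in \code{[0.7, 1.3]}.
#' @param offset_px length-2 \code{c(dx, dy)} offset of the strip centre
#'   from the scene centre, pixels.
#' @param pad_size_px length-2 \code{c(height, width)} of the scene.
#' @return a list of class \code{scene_spec}.
#' @export
scene_spec <- function(rotation_deg = 0, gain = 1,
                       offset_px = c(0, 0), pad_size_px = c(260, 560)) {
  if (abs(rotation_deg) > 15)
    stop_domain("rotation outside ±15 degrees is not supported (layout error)")
  if (gain < 0.7 || gain > 1.3)
    stop_domain("brightness gain must lie in [0.7, 1.3]")
  stopifnot(length(offset_px) == 2L, length(pad_size_px) == 2L,
            all(pad_size_px >= 16))
  structure(list(rotation_deg = rotation_deg, gain = gain,
                 offset_px = as.numeric(offset_px),
                 pad_size_px = as.integer(pad_size_px)),
            class = "scene_spec")
}

# Forward affine map of the scene: rotate about the strip centre, then
# translate the strip centre to scene centre + offset. Points are (x, y)
# continuous pixel coordinates. Returns a function of an n x 2 matrix.
scene_affine <- function(strip_dim_hw, scene, inverse = FALSE) {
  th <- scene$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sc <- c(strip_dim_hw[2] / 2, strip_dim_hw[1] / 2)          # strip centre
  cc <- c(scene$pad_size_px[2] / 2, scene$pad_size_px[1] / 2) +
    scene$offset_px                                           # scene centre
  if (!inverse) {
    function(p) sweep(sweep(p, 2, sc) %*% t(R), 2, cc, "+")
  } else {
    function(p) sweep(sweep(p, 2, cc) %*% R, 2, sc, "+")
  }
}

# Bilinear lookup of image plane values at continuous (x, y) points.
bilinear_sample <- function(plane, x, y) {
  H <- nrow(plane); W <- ncol(plane)
  # continuous coords: pixel (r, c) is centred at (c - 0.5, r - 0.5)
  cx <- pmin(pmax(x - 0.5, 0), W - 1)
  cy <- pmin(pmax(y - 0.5, 0), H - 1)
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  x0 <- pmin(x0, W - 2); y0 <- pmin(y0, H - 2)
  i00 <- y0 + 1 + x0 * H
  v00 <- plane[i00];       v10 <- plane[i00 + H]
  v01 <- plane[i00 + 1];   v11 <- plane[i00 + H + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Composite a strip onto a textured pad scene
#'
#' Places the sample's strip image onto a fibrous, darker pad background
#' with the rotation, offset and brightness of \code{scene}, and
#' transforms the ground-truth readout-zone box consistently (the stored
#' \code{truth_bbox} becomes the axis-aligned bounding box of the
#' transformed zone corners).
#'
#' @param sample an \code{lfa_sample} from [render_strip()].
#' @param scene a [scene_spec()].
#' @param seed integer seed (pad texture and pixel noise).
#' @return a new \code{lfa_sample} whose \code{image} is the scene.
#' @export
render_pad_scene <- function(sample, scene = scene_spec(), seed = 1L) {
  stopifnot(inherits(sample, "lfa_sample"), inherits(scene, "scene_spec"))
  sdim <- dim(sample$image)[1:2]
  H <- scene$pad_size_px[1]; W <- scene$pad_size_px[2]
  fwd <- scene_affine(sdim, scene)
  inv <- scene_affine(sdim, scene, inverse = TRUE)

  corners <- matrix(c(0, 0, sdim[2], 0, 0, sdim[1], sdim[2], sdim[1]),
                    ncol = 2, byrow = TRUE)
  tc <- fwd(corners)
  if (any(tc[, 1] < 0) || any(tc[, 1] > W) ||
      any(tc[, 2] < 0) || any(tc[, 2] > H))
    stop_domain("strip falls outside the scene bounds (layout error)")

  with_seed(seed, {
    img <- pad_texture(H, W)
    # restrict inverse mapping to the strip's bounding region
    xr <- max(1L, floor(min(tc[, 1]))):min(W, ceiling(max(tc[, 1])))
    yr <- max(1L, floor(min(tc[, 2]))):min(H, ceiling(max(tc[, 2])))
    grid <- cbind(x = rep(xr, each = length(yr)) - 0.5,
                  y = rep(yr, times = length(xr)) - 0.5)
    sp <- inv(grid)
    inside <- sp[, 1] >= 0 & sp[, 1] <= sdim[2] &
      sp[, 2] >= 0 & sp[, 2] <= sdim[1]
    rows <- rep(yr, times = length(xr))[inside]
    cols <- rep(xr, each = length(yr))[inside]
    for (ch in 1:3) {
      v <- bilinear_sample(sample$image[, , ch], sp[inside, 1], sp[inside, 2])
      plane <- img[, , ch]
      plane[cbind(rows, cols)] <- v
      img[, , ch] <- plane
    }
    img <- pmin(pmax(img * scene$gain +
                       stats::rnorm(H * W * 3, 0, 0.004), 0), 1)

    zb <- sample$truth_bbox
    zq <- fwd(matrix(c(zb[1], zb[2], zb[3], zb[2],
                       zb[1], zb[4], zb[3], zb[4]), ncol = 2, byrow = TRUE))
    out <- sample
    out$image <- img
    out$truth_bbox <- c(min(zq[, 1]), min(zq[, 2]), max(zq[, 1]), max(zq[, 2]))
    out$scene <- scene
    out$seed <- as.integer(seed)
    out
  })
}

# Fibrous bluish-grey pad background: coarse smooth mottling plus fine
# grain, kept dark enough that the pale membrane separates cleanly.
pad_texture <- function(H, W, base = 0.40) {
  coarse <- matrix(stats::rnorm(ceiling(H / 16) * ceiling(W / 16), 0, 0.05),
                   ceiling(H / 16))
  up <- upscale_bilinear(coarse, H, W)
  tint <- c(0.95, 0.98, 1.05)
  img <- array(0, c(H, W, 3))
  grain <- matrix(stats::rnorm(H * W, 0, 0.015), H, W)
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base * tint[ch] + up + grain, 0), 1)
  img
}

upscale_bilinear <- function(m, H, W) {
  ry <- seq(1, nrow(m), length.out = H)
  rx <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(ry), nrow(m) - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1); fx <- rx - x0
  a <- m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0 + 1, x0] * outer(fy, 1 - fx) +
    m[y0, x0 + 1] * outer(1 - fy, fx) + m[y0 + 1, x0 + 1] * outer(fy, fx)
  a
}
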