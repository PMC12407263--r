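# Capillary-fluidics design equations for passive volume-control devices.
#
# All quantities are SI internally (m, s, Pa, N/m, Pa.s); use the
# ul_to_m3()/mm_to_m() helpers at the boundary. Blood is treated as a
# Newtonian fluid with a configurable effective viscosity.

#' Channel geometry
#'
#' Rectangular channels are described by width \code{w}, height \code{h}
#' and length \code{L}; cylindrical capillaries by radius \code{r} and
#' length \code{L}. All dimensions in metres. The derived volume is
#' \code{w*h*L} or \code{pi*r^2*L}.
#'
#' @param shape \code{"rectangular"} or \code{"cylindrical"}.
#' @param w,h,r,L dimensions in metres.
#' @return object of class \code{channel_geometry} with a \code{volume}
#'   field (m^3).
#' @export
channel_geometry <- function(shape = c("rectangular", "cylindrical"),
                             w = NA_real_, h = NA_real_, r = NA_real_,
                             L) {
  shape <- match.arg(shape)
  stopifnot(L > 0)
  if (shape == "rectangular") {
    stopifnot(w > 0, h > 0)
    vol <- w * h * L
  } else {
    stopifnot(r > 0)
    vol <- pi * r^2 * L
  }
  structure(list(shape = shape, w = w, h = h, r = r, L = L, volume = vol),
            class = "channel_geometry")
}

#' Fluid specification
#'
#' @param gamma surface tension (N/m), > 0.
#' @param theta contact angle (radians); wetting flow requires
#'   \code{theta} in \code{[0, pi/2]}.
#' @param mu dynamic viscosity (Pa.s), > 0. For whole blood an effective
#'   Newtonian viscosity of 3-4 mPa.s is conventional.
#' @return object of class \code{fluid_spec}.
#' @export
fluid_spec <- function(gamma, theta, mu) {
  stopifnot(gamma > 0, mu > 0, theta >= 0, theta <= pi)
  structure(list(gamma = gamma, theta = theta, mu = mu),
            class = "fluid_spec")
}

#' Laplace driving pressure of a rectangular channel
#'
#' The capillary pressure at the liquid/air meniscus,
#' \deqn{\Delta P = 2\gamma\cos\theta\,(1/w + 1/h),}
#' is the driving force of passive flow in the microchannel. Symmetric in
#' \code{w} and \code{h}.
#'
#' @param fluid a [fluid_spec()].
#' @param geom a rectangular [channel_geometry()].
#' @return pressure in Pa.
#' @export
laplace_pressure <- function(fluid, geom) {
  stopifnot(inherits(fluid, "fluid_spec"),
            inherits(geom, "channel_geometry"))
  if (geom$shape != "rectangular")
    stop_domain("Laplace pressure formula applies to rectangular channels (shape error)")
  2 * fluid$gamma * cos(fluid$theta) * (1 / geom$w + 1 / geom$h)
}

#' Hagen-Poiseuille volumetric flow in a cylindrical capillary
#'
#' \deqn{Q = \pi r^4 \Delta P / (8 \mu L)} under laminar flow of an
#' incompressible fluid.
#'
#' @param fluid a [fluid_spec()].
#' @param geom a cylindrical [channel_geometry()].
#' @param delta_p pressure difference in Pa, >= 0 (no backflow
#'   modelling).
#' @return volumetric flow rate in m^3/s.
#' @export
poiseuille_flow <- function(fluid, geom, delta_p) {
  stopifnot(inherits(fluid, "fluid_spec"),
            inherits(geom, "channel_geometry"))
  if (geom$shape != "cylindrical")
    stop_domain("Hagen-Poiseuille applies to cylindrical capillaries (shape error)")
  if (delta_p < 0) stop_domain("negative pressure difference: no backflow modelling")
  pi * geom$r^4 * delta_p / (8 * fluid$mu * geom$L)
}

#' Washburn capillary filling
#'
#' Filled length of a channel under constant capillary pressure,
#' \deqn{L^2 = \gamma D \cos\theta \, t / (4\mu),} so \eqn{L \propto
#' \sqrt t}. \code{washburn_time} is the exact inverse.
#'
#' @param fluid a [fluid_spec()]; filling requires a wetting contact
#'   angle (\code{theta < pi/2}).
#' @param diameter channel diameter in metres.
#' @param t time in seconds (>= 0).
#' @param L filled length in metres (>= 0), for the inverse.
#' @return \code{washburn_fill}: length in metres; \code{washburn_time}:
#'   time in seconds.
#' @export
washburn_fill <- function(fluid, diameter, t) {
  stopifnot(inherits(fluid, "fluid_spec"), diameter > 0)
  if (any(t < 0)) stop_domain("time must be non-negative")
  if (fluid$theta >= pi / 2 && any(t > 0))
    stop_domain("non-wetting fluid (theta >= 90 deg): no capillary filling")
  sqrt(fluid$gamma * diameter * cos(fluid$theta) * t / (4 * fluid$mu))
}

#' @rdname washburn_fill
#' @export
washburn_time <- function(fluid, diameter, L) {
  stopifnot(inherits(fluid, "fluid_spec"), diameter > 0)
  if (any(L < 0)) stop_domain("length must be non-negative")
  if (fluid$theta >= pi / 2 && any(L > 0))
    stop_domain("non-wetting fluid (theta >= 90 deg): no capillary filling")
  4 * fluid$mu * L^2 / (fluid$gamma * diameter * cos(fluid$theta))
}

#' Time to fill a reservoir at a given flow rate
#'
#' @param reservoir_volume volume in m^3.
#' @param q volumetric flow rate in m^3/s, > 0.
#' @return time in seconds.
#' @export
reservoir_fill_time <- function(reservoir_volume, q) {
  stopifnot(reservoir_volume >= 0)
  if (q <= 0) stop_domain("flow rate must be positive")
  reservoir_volume / q
}

#' Reference volumes of the two wearable prototypes
#'
#' Prototype 1 retains blood behind a dissolvable membrane in a 150 uL
#' reservoir; prototype 2 uses a 60 uL capillary inlet reservoir feeding
#' a 25 uL microfluidic channel.
#'
#' @return named list of volumes in microlitres.
#' @export
prototype_volumes <- function() {
  list(prototype1_reservoir_ul = 150,
       prototype2_inlet_ul = 60,
       prototype2_channel_ul = 25)
}
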