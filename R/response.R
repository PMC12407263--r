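# Concentration -> line-signal models for the simulated assays.

#' Construct an analyte response model
#'
#' Describes how the nominal optical signal of each line on a strip depends
#' on analyte concentration. The test line follows simple saturating
#' (sandwich) binding with an optional high-dose hook term,
#' \deqn{S(c) = s_{max} \frac{c}{k_d + c} \cdot \frac{1}{1 + c/c_{hook}},}
#' and the competitive antigen line (three-line designs only) decays as
#' \deqn{A(c) = a_{max} / (1 + c/k_c).}
#' The control line signal is concentration-independent. These are the
#' simplest forms with the qualitative behaviour of gold-nanoparticle
#' sandwich/competitive assays: zero test signal at zero analyte,
#' saturation near \code{k_d}, signal loss above the hook onset, and a
#' strictly decreasing antigen line.
#'
#' @param analyte one of \code{"CEA"}, \code{"CA125"}, \code{"CRP"} (or any
#'   label for custom assays).
#' @param units concentration units string (e.g. \code{"ng/mL"}).
#' @param s_max maximal test-line signal (arbitrary intensity units).
#' @param k_d half-saturation concentration of the sandwich line.
#' @param hook_c hook-onset concentration; \code{Inf} disables the hook.
#'   When finite, the test-line response peaks at
#'   \code{sqrt(k_d * hook_c)}, so choosing \code{k_d == hook_c} places the
#'   maximum exactly at the hook onset.
#' @param a_max maximal antigen-line signal; \code{NA} for two-line assays.
#' @param k_c competitive half-decay concentration of the antigen line.
#' @param control_signal fixed control-line signal.
#' @param valid_range length-2 numeric, calibrated concentration window.
#' @return an object of class \code{analyte_response}.
#' @seealso [signal_from_concentration()], [default_responses()]
#' @export
analyte_response <- function(analyte, units, s_max, k_d, hook_c = Inf,
                             a_max = NA_real_, k_c = NA_real_,
                             control_signal = 0.8,
                             valid_range = c(0, Inf)) {
  stopifnot(is.character(analyte), length(analyte) == 1L,
            s_max >= 0, k_d > 0, hook_c > 0,
            control_signal >= 0, length(valid_range) == 2L,
            valid_range[1] < valid_range[2])
  if (!is.na(a_max)) stopifnot(a_max >= 0, k_c > 0)
  structure(list(analyte = analyte, units = units, s_max = s_max,
                 k_d = k_d, hook_c = hook_c, a_max = a_max, k_c = k_c,
                 control_signal = control_signal,
                 valid_range = as.numeric(valid_range)),
            class = "analyte_response")
}

#' @export
print.analyte_response <- function(x, ...) {
  cat("Analyte response model:", x$analyte, sprintf("(%s)\n", x$units))
  cat(sprintf("  sandwich line: s_max = %g, k_d = %g, hook onset = %g\n",
              x$s_max, x$k_d, x$hook_c))
  if (!is.na(x$a_max))
    cat(sprintf("  antigen line (competitive): a_max = %g, k_c = %g\n",
                x$a_max, x$k_c))
  cat(sprintf("  control line: %g; valid range: [%g, %g]\n",
              x$control_signal, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Default response models for the three-biomarker panel
#'
#' CEA (carcinoembryonic antigen, ng/mL) and CA-125 (U/mL) are plain
#' sandwich assays with \code{k_d} far above the calibrated window so the
#' response is close to linear across it. CRP (ug/mL) is the three-line
#' hook-effect design: its sandwich line is calibrated on 0-10 ug/mL and
#' hooks above 10, while the competitive antigen line covers 10-500 ug/mL.
#' \code{k_d = hook_c = 10} places the sandwich maximum at the hook onset.
#'
#' @return named list of [analyte_response] objects.
#' @export
default_responses <- function() {
  list(
    CEA = analyte_response("CEA", "ng/mL", s_max = 8, k_d = 400,
                           valid_range = c(0, 50)),
    CA125 = analyte_response("CA125", "U/mL", s_max = 8, k_d = 8000,
                             valid_range = c(0, 1000)),
    CRP = analyte_response("CRP", "ug/mL", s_max = 3.2, k_d = 10,
                           hook_c = 10, a_max = 0.85, k_c = 30,
                           valid_range = c(0.1, 500))
  )
}

#' Nominal line signals at a given concentration
#'
#' Evaluates the response model: returns the nominal (noise-free) signals
#' of the test, antigen and control lines. The antigen signal is \code{NA}
#' for two-line assays.
#'
#' @param response an [analyte_response].
#' @param c_conc non-negative concentration in the model's units.
#' @return named numeric vector \code{c(test, antigen, control)}.
#' @examples
#' r <- default_responses()$CRP
#' signal_from_concentration(r, 5)["test"] <
#'   signal_from_concentration(r, 10)["test"]   # below the hook onset
#' @export
signal_from_concentration <- function(response, c_conc) {
  stopifnot(inherits(response, "analyte_response"))
  if (!is.numeric(c_conc) || length(c_conc) != 1L || !is.finite(c_conc) ||
      c_conc < 0)
    stop_domain("concentration must be a single finite non-negative number")
  test <- response$s_max * c_conc / (response$k_d + c_conc) /
    (1 + c_conc / response$hook_c)
  antigen <- if (is.na(response$a_max)) NA_real_
             else response$a_max / (1 + c_conc / response$k_c)
  c(test = test, antigen = antigen, control = response$control_signal)
}
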