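# Clinical-range interpretation of the multiplexed panel.

#' Clinical interpretation thresholds
#'
#' Reads the fixed thresholds table shipped with the package (a YAML
#' file under \code{extdata}): CEA normal below 5 ng/mL and elevated
#' above 20 ng/mL; CA-125 normal up to 35 U/mL and strongly elevated
#' above 100 U/mL; CRP reported against the 10 ug/mL low/high branch
#' boundary. Interpretation bands derive only from this table.
#'
#' @param path optional path to an alternative YAML thresholds file.
#' @return nested list of thresholds.
#' @export
clinical_thresholds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "clinical_thresholds.yaml",
                        package = "lfaquant")
  yaml::read_yaml(path)
}

#' Interpret a panel of biomarker concentrations
#'
#' Maps each concentration to an advisory band from the fixed clinical
#' thresholds table. CEA: \code{normal} (< 5 ng/mL), \code{intermediate}
#' (5-20), \code{elevated} (> 20). CA-125: \code{normal} (<= 35 U/mL),
#' \code{elevated} (> 35), \code{strongly_elevated} (> 100). CRP:
#' \code{low_range} (<= 10 ug/mL, the sandwich-line regime) or
#' \code{high_range} (> 10, the competitive regime). The wording is
#' advisory, never diagnostic.
#'
#' @param concentrations named numeric vector or list
#'   (names among \code{CEA}, \code{CA125}, \code{CRP}), non-negative.
#' @param thresholds thresholds table, see [clinical_thresholds()].
#' @return object of class \code{lfa_panel}: data.frame with analyte,
#'   concentration, units and band, plus a \code{validity} attribute.
#' @export
interpret_panel <- function(concentrations,
                            thresholds = clinical_thresholds()) {
  conc <- unlist(concentrations)
  if (any(conc < 0)) stop_domain("concentrations must be non-negative")
  unknown <- setdiff(names(conc), names(thresholds))
  if (length(unknown))
    stop_domain(paste("no thresholds configured for analyte:",
                      paste(unknown, collapse = ", ")))
  band_of <- function(analyte, x) {
    th <- thresholds[[analyte]]
    switch(analyte,
      CEA = if (x < th$normal_below) "normal"
            else if (x <= th$elevated_above) "intermediate"
            else "elevated",
      CA125 = if (x <= th$normal_upper) "normal"
              else if (x <= th$strongly_elevated_above) "elevated"
              else "strongly_elevated",
      CRP = if (x <= th$low_high_boundary) "low_range" else "high_range")
  }
  out <- data.frame(
    analyte = names(conc),
    concentration = unname(conc),
    units = vapply(names(conc), function(a) thresholds[[a]]$units, ""),
    band = vapply(names(conc), function(a) band_of(a, conc[[a]]), ""),
    row.names = NULL)
  structure(out, class = c("lfa_panel", "data.frame"), validity = TRUE)
}

#' @export
print.lfa_panel <- function(x, ...) {
  cat("Biomarker panel (advisory interpretation, not a diagnosis):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
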