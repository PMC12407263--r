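# End-to-end orchestration: image -> detection -> classification ->
# segmentation -> intensities -> concentrations -> panel report.

#' Analyze a strip or pad image end to end
#'
#' Runs the full readout pipeline in order: readout-zone detection,
#' rectified zone crop, profile extraction, readout classification, FCL
#' peak segmentation, role assignment, background-subtracted line
#' intensities, calibration inversion (hook-effect aware for CRP) and
#' clinical interpretation. Any stage failure yields a structured
#' invalid-test report with a \code{status} field; a partial silent
#' result is never returned. Inference is fully deterministic: re-running
#' on the same inputs and config yields an identical report.
#'
#' @param image RGB array or path to an image file.
#' @param curves calibration curves: for one-curve assays a single
#'   [fit_calibration()] object (or \code{list(curve)}); for CRP a
#'   \code{list(low = ..., high = ...)}.
#' @param models named list of \code{fcl_model}s with entries
#'   \code{two_peak} and \code{three_peak}.
#' @param config list: \code{analyte} (which assay the strip carries,
#'   required), \code{channel} (default \code{"green"}), \code{layout}
#'   (a [strip_layout()]; default chosen from the analyte).
#' @return object of class \code{lfa_report}: detection result, readout
#'   class, role-labeled segments with intensities, per-analyte
#'   concentration with branch and flags, panel interpretation, and a
#'   provenance block (config hash, model seeds, package version).
#' @export
analyze_image <- function(image, curves, models, config = list()) {
  if (is.character(image)) image <- read_image(image)
  analyte <- config$analyte
  if (is.null(analyte)) stop_domain("config$analyte is required")
  channel <- config$channel %||% "green"
  is_crp <- identical(analyte, "CRP")
  layout <- config$layout %||% default_layout(if (is_crp) 3 else 2)
  if (is_crp) {
    if (!all(c("low", "high") %in% names(curves)))
      stop_domain("CRP requires curves = list(low = ..., high = ...)")
  } else if (inherits(curves, "lfa_calibration")) {
    curves <- list(curves)
  }
  if (!all(c("two_peak", "three_peak") %in% names(models)))
    stop_domain("models must contain two_peak and three_peak entries")

  provenance <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("lfaquant")),
    config_hash = hash_config(list(analyte = analyte, channel = channel,
                                   layout = unclass(layout)[
                                     c("readout_zone", "format")],
                                   lines = layout$lines)),
    model_seeds = lapply(models, `[[`, "seed"))

  report <- function(status, ...) {
    structure(c(list(status = status, analyte = analyte,
                     provenance = provenance), list(...)),
              class = "lfa_report")
  }

  det <- detect_readout_zone(image)
  if (!det$accepted)
    return(report("zone_not_found", detection = det[c("bbox", "confidence",
                                                      "accepted")]))
  zone <- crop_box(det$rectified, det$bbox_rect)
  profile <- extract_intensity_profile(zone, channel = channel)

  readout_class <- tryCatch(classify_readout(profile),
                            lfa_invalid_test = function(e) NULL)
  if (is.null(readout_class))
    return(report("invalid_test",
                  detection = det[c("bbox", "confidence", "accepted")],
                  reason = "no visible lines (missing control line)"))

  variant <- if (readout_class == "test_antigen_and_control") "three_peak"
             else "two_peak"
  pm <- predict_mask(models[[variant]], profile)
  segments <- segments_from_mask(pm$mask, profile)
  segments <- tryCatch(assign_roles(segments, readout_class, layout),
                       lfa_invalid_test = function(e) e)
  if (inherits(segments, "error"))
    return(report("invalid_test",
                  detection = det[c("bbox", "confidence", "accepted")],
                  readout_class = readout_class,
                  reason = conditionMessage(segments)))
  roles <- vapply(segments, `[[`, "", "role")
  if (!"control" %in% roles)
    return(report("invalid_test",
                  detection = det[c("bbox", "confidence", "accepted")],
                  readout_class = readout_class,
                  reason = "control line absent"))

  intensities <- stats::setNames(
    vapply(segments, function(s) line_intensity(profile, s), numeric(1)),
    roles)
  test_int <- if ("test" %in% roles) intensities[["test"]] else 0
  antigen_int <- if ("antigen" %in% roles) intensities[["antigen"]] else 0

  quant <- if (is_crp) {
    if (readout_class == "control_only" ||
        (test_int < 0.01 && antigen_int < 0.01)) {
      list(concentration = 0, below_lod = TRUE, out_of_range = FALSE,
           branch = NA_character_)
    } else if (antigen_int < 0.01 && readout_class == "test_and_control") {
      # two visible lines on a hook design with no antigen signal means
      # the antigen line has been fully competed away: high branch
      r <- invert_calibration(curves$high,
                              max(antigen_int, .Machine$double.eps))
      c(r, branch = "high")
    } else {
      tryCatch(quantify_crp(test_int, antigen_int, curves$low, curves$high),
               lfa_invalid_test = function(e) e)
    }
  } else {
    if (readout_class == "control_only") {
      list(concentration = 0, below_lod = TRUE, out_of_range = FALSE,
           branch = NA_character_)
    } else {
      c(invert_calibration(curves[[1]], test_int), branch = NA_character_)
    }
  }
  if (inherits(quant, "error"))
    return(report("invalid_test",
                  detection = det[c("bbox", "confidence", "accepted")],
                  readout_class = readout_class,
                  reason = conditionMessage(quant)))

  conc <- stats::setNames(quant$concentration, analyte)
  panel <- interpret_panel(conc)

  report("ok",
         detection = det[c("bbox", "confidence", "accepted")],
         readout_class = readout_class,
         segments = lapply(seq_along(segments), function(i)
           c(unclass(segments[[i]]), intensity = intensities[[i]])),
         intensities = as.list(intensities),
         concentration = list(
           analyte = analyte, value = quant$concentration,
           below_lod = isTRUE(quant$below_lod),
           out_of_range = isTRUE(quant$out_of_range),
           branch = quant$branch,
           display = if (isTRUE(quant$below_lod)) "< LOD"
                     else format(quant$concentration, digits = 4)),
         panel = panel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lfa_report <- function(x, ...) {
  cat("LFA analysis report — status:", x$status, "\n")
  if (!is.null(x$detection) && !is.null(x$detection$bbox))
    cat(sprintf("  readout zone confidence %.3f\n", x$detection$confidence))
  if (!is.null(x$readout_class)) cat("  readout class:", x$readout_class, "\n")
  if (identical(x$status, "ok")) {
    cat(sprintf("  %s = %s (%s)%s\n", x$analyte, x$concentration$display,
                x$panel$band[1],
                if (!is.na(x$concentration$branch %||% NA))
                  paste0(", branch ", x$concentration$branch) else ""))
  } else if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#' @param report an \code{lfa_report}.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string or (invisibly) \code{path}.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "lfa_report"))
  obj <- unclass(report)
  if (!is.null(obj$panel)) obj$panel <- as.data.frame(obj$panel)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = 8, na = "null")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8,
                       na = "null")
  invisible(path)
}

#' Analyze a batch of images and summarize replicate precision
#'
#' Applies [analyze_image()] to each entry; unreadable or failing entries
#' are logged, skipped and counted. The summary reports, per analyte and
#' concentration group, the coefficient of variation of the extracted
#' test-line intensities across valid replicates (invalid strips are
#' excluded from the CV and counted separately).
#'
#' @param images list of RGB arrays, \code{lfa_sample}s or file paths.
#' @param curves,models,config as in [analyze_image()]; \code{config} may
#'   be a single list shared by all images or a list of per-image
#'   configs.
#' @param groups optional vector labelling replicate groups (e.g. the
#'   true concentration); CVs are computed within groups.
#' @return list of class \code{lfa_batch}: \code{reports}, \code{summary}
#'   (data.frame with group, n_valid, n_invalid, mean_intensity,
#'   cv_percent), \code{n_failed}.
#' @export
batch_analyze <- function(images, curves, models, config = list(),
                          groups = NULL) {
  n <- length(images)
  shared_config <- !is.null(config$analyte) || n == 0
  reports <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (inherits(img, "lfa_sample")) img <- img$image
    cfg <- if (shared_config) config else config[[i]]
    reports[[i]] <- tryCatch(analyze_image(img, curves, models, cfg),
                             error = function(e) {
                               message("entry ", i, " failed: ",
                                       conditionMessage(e))
                               NULL
                             })
    if (is.null(reports[[i]])) n_failed <- n_failed + 1L
  }
  if (is.null(groups)) groups <- rep("all", n)
  ok <- vapply(reports, function(r) !is.null(r) &&
                 identical(r$status, "ok"), logical(1))
  test_int <- vapply(reports, function(r) {
    if (is.null(r) || !identical(r$status, "ok")) return(NA_real_)
    r$intensities$test %||% NA_real_
  }, numeric(1))
  summ <- do.call(rbind, lapply(split(seq_len(n), groups), function(ix) {
    v <- test_int[ix][ok[ix] & !is.na(test_int[ix])]
    data.frame(group = as.character(groups[ix[1]]),
               n_valid = length(v),
               n_invalid = sum(!ok[ix]),
               mean_intensity = if (length(v)) mean(v) else NA_real_,
               cv_percent = if (length(v) >= 2 && mean(v) != 0) cv(v)
                            else NA_real_)
  }))
  if (is.null(summ))
    summ <- data.frame(group = character(0), n_valid = integer(0),
                       n_invalid = integer(0), mean_intensity = numeric(0),
                       cv_percent = numeric(0))
  rownames(summ) <- NULL
  structure(list(reports = reports, summary = summ, n_failed = n_failed),
            class = "lfa_batch")
}

#' @export
print.lfa_batch <- function(x, ...) {
  cat(sprintf("Batch analysis: %d reports, %d failed entries\n",
              length(x$reports), x$n_failed))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
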