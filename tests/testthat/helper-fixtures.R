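# Shared fixtures: cached small trained models and calibration corpora.
# Everything is generated in code under fixed seeds; nothing is stored on
# disk.

.fixture_env <- new.env(parent = emptyenv())

# Small FCL models for pipeline tests: trained lazily once per run on a
# compact corpus (enough to saturate the easy regime at reduced epochs).
fixture_model <- function(variant) {
  key <- paste0("model_", variant)
  if (is.null(.fixture_env[[key]])) {
    data <- generate_labeled_profiles(60, variant, seed = 424,
                                      acquisition = "truth_crop")
    .fixture_env[[key]] <- train_fcl(data, variant, seed = 424,
                                     epochs = 30)
  }
  .fixture_env[[key]]
}

fixture_models <- function() {
  list(two_peak = fixture_model("two_peak"),
       three_peak = fixture_model("three_peak"))
}

# Calibration curve for an analyte built from rendered replicate strips,
# measuring intensities through the imaging module with ground-truth
# zone crops and ground-truth mask segments (no NN involvement).
measure_line_intensity <- function(sample, role) {
  zone <- lfaquant:::crop_box(sample$image, sample$truth_bbox)
  profile <- extract_intensity_profile(zone)
  segs <- segments_from_mask(sample$truth_mask, profile)
  segs <- assign_roles(segs, sample$truth_class, sample$layout)
  roles <- vapply(segs, `[[`, "", "role")
  if (!role %in% roles) return(NA_real_)
  line_intensity(profile, segs[[match(role, roles)]])
}

fixture_calibration <- function(analyte = "CEA", levels = NULL,
                                reps = 3, seed = 99, role = "test",
                                form = "linear_c") {
  key <- paste("cal", analyte, role, form, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  resp <- default_responses()[[analyte]]
  if (is.null(levels))
    levels <- seq(resp$valid_range[1] + 1, resp$valid_range[2],
                  length.out = 8)
  pts <- list(); blanks <- numeric(0)
  k <- 0
  for (c_i in levels) for (r in seq_len(reps)) {
    k <- k + 1
    s <- render_assay_strip(resp, c_i, seed = seed + k)
    pts[[k]] <- data.frame(concentration = c_i,
                           intensity = measure_line_intensity(s, role))
  }
  for (r in 1:4) {
    s <- render_assay_strip(resp, 0, seed = seed + 1000 + r)
    zone <- lfaquant:::crop_box(s$image, s$truth_bbox)
    profile <- extract_intensity_profile(zone)
    # blank intensity at the nominal test-line window
    blanks <- c(blanks,
                line_intensity(profile, c(100, 160)))
  }
  curve <- fit_calibration(stats::na.omit(do.call(rbind, pts)), form,
                           blanks, analyte = analyte,
                           line_role = if (role == "antigen") "antigen"
                                       else "test")
  .fixture_env[[key]] <- curve
  curve
}

# CRP low (sandwich, 0.1-10) and high (antigen, 10-500) curve pair.
fixture_crp_curves <- function(seed = 77) {
  if (!is.null(.fixture_env$crp_curves)) return(.fixture_env$crp_curves)
  resp <- default_responses()$CRP
  low_levels <- 10^seq(log10(0.3), 1, length.out = 6)
  high_levels <- 10^seq(1, log10(500), length.out = 6)
  measure <- function(levels, role) {
    out <- list(); k <- 0
    for (c_i in levels) for (r in 1:3) {
      k <- k + 1
      s <- render_assay_strip(resp, c_i, seed = seed + k +
                                1000 * (role == "antigen"))
      out[[k]] <- data.frame(concentration = c_i,
                             intensity = measure_line_intensity(s, role))
    }
    stats::na.omit(do.call(rbind, out))
  }
  blanks <- vapply(1:4, function(r) {
    s <- render_assay_strip(resp, 0.1, seed = seed + 5000 + r)
    zone <- lfaquant:::crop_box(s$image, s$truth_bbox)
    line_intensity(extract_intensity_profile(zone), c(100, 160))
  }, numeric(1))
  curves <- list(
    low = fit_calibration(measure(low_levels, "test"), "linear_log10c",
                          blanks, analyte = "CRP", line_role = "test"),
    high = fit_calibration(measure(high_levels, "antigen"),
                           "linear_log10c", blanks, analyte = "CRP",
                           line_role = "antigen"))
  .fixture_env$crp_curves <- curves
  curves
}
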