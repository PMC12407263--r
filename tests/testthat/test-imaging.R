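# Zone detection, profile extraction, line intensity, classification.

test_that("profile extraction is flat for a blank zone and peaked for lines", {
  lay <- default_layout(2)
  blank <- render_strip(lay, c(test = 0, control = 0),
                        noise = noise_spec(amplitude_rel_sd = 0,
                                           gradient_amp = 0,
                                           mottle_sd = 0),
                        seed = 5)
  zone <- lfaquant:::crop_box(blank$image, blank$truth_bbox)
  p <- extract_intensity_profile(zone)
  expect_lt(max(p$values) - p$background_level, 0.01)
  expect_error(extract_intensity_profile(zone[, 1:4, , drop = FALSE]),
               "narrower than 8")
})

test_that("line intensity is the contrast of the segment extremum against background", {
  # flat profile -> 0; rectangular peak of height h over baseline b -> h
  flat <- intensity_profile(rep(0.2, 512))
  expect_equal(line_intensity(flat, c(100, 200)), 0)
  v <- rep(0.1, 512); v[200:230] <- 0.1 + 0.35
  rect <- intensity_profile(v)
  expect_equal(line_intensity(rect, c(190, 240)), 0.35, tolerance = 1e-12)
  expect_error(line_intensity(rect, c(200, 200)), "non-empty")
})

test_that("line intensity is invariant to adding a constant to the profile", {
  s <- render_assay_strip(default_responses()$CEA, 30, seed = 12)
  zone <- lfaquant:::crop_box(s$image, s$truth_bbox)
  p <- extract_intensity_profile(zone)
  p_shift <- intensity_profile(p$values + 0.17, channel = p$channel)
  segs <- segments_from_mask(s$truth_mask, p)
  for (g in segs)
    expect_equal(line_intensity(p, g), line_intensity(p_shift, g),
                 tolerance = 1e-10)
})

test_that("extracted intensity tracks the generator's nominal signal", {
  # within 10% of the transfer-mapped nominal, averaged over 20 seeds
  resp <- default_responses()$CEA
  ratios <- vapply(1:20, function(sd) {
    s <- render_assay_strip(resp, 30, seed = 700 + sd)
    nominal <- render_transfer(s$truth_signals[["test"]])
    measure_line_intensity(s, "test") / nominal
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("uniform blank images are rejected with confidence below 0.8", {
  dark <- array(0.3, c(128, 256, 3))
  d <- detect_readout_zone(dark)
  expect_false(d$accepted)
  pale <- array(0.9, c(128, 256, 3))
  d2 <- detect_readout_zone(pale)
  expect_false(d2$accepted)
  expect_lt(d2$confidence, 0.8)
  expect_error(detect_readout_zone(array(0.5, c(32, 32, 3))), "64 x 64")
})

test_that("detection on strip-only images accepts and stays inside the strip", {
  s <- render_assay_strip(default_responses()$CA125, 600, seed = 9)
  d <- detect_readout_zone(s$image)
  expect_true(d$accepted)
  expect_gte(bbox_iou(d$bbox, s$truth_bbox), 0.7)
  dd <- dim(s$image)
  expect_true(d$bbox[1] >= 0 && d$bbox[3] <= dd[2] &&
                d$bbox[2] >= 0 && d$bbox[4] <= dd[1])
})

test_that("detection recovers the readout zone on seeded pad scenes (IoU >= 0.7)", {
  ds <- generate_dataset(50, class_mix = c(test_and_control = 0.5,
                                           test_antigen_and_control = 0.5),
                         seed = 1234, scenes = TRUE)
  ious <- vapply(ds$samples, function(s) {
    d <- detect_readout_zone(s$image)
    if (!d$accepted) return(0)
    bbox_iou(d$bbox, s$truth_bbox)
  }, numeric(1))
  expect_true(all(ious >= 0.7))
})

test_that("detect -> crop -> extract aligns with the ground-truth crop within 1 px", {
  # apex positions mapped back to strip pixels must agree within 1 px
  for (sd in c(41, 42)) {
    s <- render_assay_strip(default_responses()$CRP, 30, seed = sd)
    d <- detect_readout_zone(s$image)
    expect_true(d$accepted)
    p_det <- extract_intensity_profile(
      lfaquant:::crop_box(d$rectified, d$bbox_rect))
    p_true <- extract_intensity_profile(
      lfaquant:::crop_box(s$image, s$truth_bbox))
    pk_det <- lfaquant:::find_profile_peaks(p_det$values)
    pk_true <- lfaquant:::find_profile_peaks(p_true$values)
    expect_equal(nrow(pk_det), nrow(pk_true))
    # map profile sample index -> absolute strip x
    to_x <- function(pos, box) {
      j0 <- round(box[1]) + 1; j1 <- round(box[3])
      j0 + (pos - 1) * (j1 - j0) / 511
    }
    expect_equal(to_x(pk_det$position, d$bbox_rect),
                 to_x(pk_true$position, s$truth_bbox), tolerance = 1)
  }
})

test_that("readout classification matches generator truth on 200 seeded samples", {
  ds <- generate_dataset(200, seed = 77, scenes = FALSE)
  pred <- vapply(ds$samples, function(s) {
    zone <- lfaquant:::crop_box(s$image, s$truth_bbox)
    classify_readout(extract_intensity_profile(zone))
  }, character(1))
  expect_identical(unname(pred), ds$manifest$class)
})

test_that("classification handles the degenerate cases of the taxonomy", {
  lay3 <- default_layout(3)
  one <- render_strip(lay3, c(test = 0, antigen = 0, control = 0.8),
                      seed = 3)
  p1 <- extract_intensity_profile(lfaquant:::crop_box(one$image,
                                                      one$truth_bbox))
  expect_identical(classify_readout(p1), "control_only")
  three <- render_strip(lay3, c(test = 0.5, antigen = 0.5, control = 0.8),
                        seed = 3)
  p3 <- extract_intensity_profile(lfaquant:::crop_box(three$image,
                                                      three$truth_bbox))
  expect_identical(classify_readout(p3), "test_antigen_and_control")
  flat <- intensity_profile(rep(0.1, 512) + rnorm(512, 0, 1e-4))
  expect_error(classify_readout(flat), class = "lfa_invalid_test")
})
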