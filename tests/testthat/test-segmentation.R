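# FCL peak segmentation: contracts, training behaviour, post-processing.

test_that("predict_mask enforces the 512-sample contract and the tie rule", {
  m <- fixture_model("two_peak")
  expect_error(predict_mask(m, rnorm(100)), "512")
  # threshold semantics: probability >= threshold is a peak, so exactly
  # 0.5 counts as peak and 0.49 does not
  expect_identical(as.integer(0.49 >= m$threshold), 0L)
  expect_identical(as.integer(0.50 >= m$threshold), 1L)
  s <- render_assay_strip(default_responses()$CEA, 30, seed = 15)
  p <- extract_intensity_profile(lfaquant:::crop_box(s$image, s$truth_bbox))
  pm <- predict_mask(m, p)
  expect_length(pm$probabilities, 512)
  expect_true(all(pm$probabilities > 0 & pm$probabilities < 1))
  expect_identical(pm$mask, as.integer(pm$probabilities >= 0.5))
})

test_that("raising the binarization threshold never adds positive pixels", {
  m <- fixture_model("three_peak")
  s <- render_assay_strip(default_responses()$CRP, 50, seed = 16)
  p <- extract_intensity_profile(lfaquant:::crop_box(s$image, s$truth_bbox))
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    sum(predict_mask(m, p, threshold = th)$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trained model reproduces generator truth on in-regime profiles", {
  m <- fixture_model("two_peak")
  data <- generate_labeled_profiles(12, "two_peak", seed = 550,
                                    acquisition = "truth_crop")
  agree <- vapply(1:12, function(i) {
    pm <- predict_mask(m, data$profiles[i, ])
    mean(pm$mask == data$masks[i, ])
  }, numeric(1))
  expect_true(all(agree >= 0.95))
  # oracle equivalence: predicted segment bounds within +-3 px of truth
  for (i in 1:5) {
    p <- intensity_profile(data$profiles[i, ])
    pred <- segments_from_mask(predict_mask(m, p)$mask, p)
    truth <- segments_from_mask(data$masks[i, ], p)
    expect_length(pred, length(truth))
    for (k in seq_along(pred)) {
      expect_lte(abs(pred[[k]]$start - truth[[k]]$start), 3)
      expect_lte(abs(pred[[k]]$end - truth[[k]]$end), 3)
    }
  }
})

test_that("training is deterministic and rejects mismatched variants", {
  data <- generate_labeled_profiles(52, "two_peak", seed = 31,
                                    acquisition = "truth_crop")
  m1 <- train_fcl(data, "two_peak", seed = 5, epochs = 4)
  m2 <- train_fcl(data, "two_peak", seed = 5, epochs = 4)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$W1, m2$W1)
  expect_error(train_fcl(data, "three_peak", seed = 1), "variant")
  expect_error(train_fcl(list(profiles = data$profiles[1:10, ],
                              masks = data$masks[1:10, ],
                              variant = "two_peak"), "two_peak"),
               "at least 50")
})

test_that("all-background labels drive predictions below threshold everywhere", {
  data <- generate_labeled_profiles(52, "two_peak", seed = 32,
                                    acquisition = "truth_crop")
  data$masks[] <- 0L
  m <- train_fcl(data, "two_peak", seed = 2, epochs = 10)
  for (i in c(1, 25)) {
    pm <- predict_mask(m, data$profiles[i, ])
    expect_true(all(pm$probabilities < 0.5))
  }
})

test_that("segments_from_mask extracts maximal runs and drops slivers", {
  v <- rep(0.1, 512); v[100:119] <- 0.5; v[300:329] <- 0.4
  p <- intensity_profile(v)
  mask <- rep(0L, 512); mask[100:119] <- 1L; mask[300:329] <- 1L
  segs <- segments_from_mask(mask, p)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$start, 100); expect_equal(segs[[1]]$end, 120)
  expect_equal(segs[[2]]$start, 300); expect_equal(segs[[2]]$end, 330)
  expect_true(segs[[1]]$apex >= 100 && segs[[1]]$apex < 120)
  # empty mask -> empty list; 2-px run -> discarded
  expect_length(segments_from_mask(rep(0L, 512), p), 0)
  sliver <- rep(0L, 512); sliver[10:11] <- 1L
  expect_length(segments_from_mask(sliver, p), 0)
  expect_error(segments_from_mask(rep(0L, 100), p), "512")
})

test_that("roles are assigned by expected position with the control mandatory", {
  lay <- default_layout(3)
  v <- rep(0.1, 512)
  p <- intensity_profile(v)
  seg_at <- function(center) {
    s <- center - 10; peak_segment(s, s + 21, center)
  }
  segs <- assign_roles(list(seg_at(128), seg_at(269), seg_at(410)),
                       "test_antigen_and_control", lay)
  expect_identical(vapply(segs, `[[`, "", "role"),
                   c("test", "antigen", "control"))
  one <- assign_roles(list(seg_at(410)), "control_only", default_layout(2))
  expect_identical(one[[1]]$role, "control")
  # count mismatch -> invalid test; no control assignable -> invalid test
  expect_error(assign_roles(list(seg_at(128), seg_at(410)),
                            "test_antigen_and_control", lay),
               class = "lfa_invalid_test")
  expect_error(assign_roles(list(seg_at(128)), "control_only",
                            default_layout(2)),
               class = "lfa_invalid_test")
})

test_that("segmentation metrics reproduce the hand confusion table", {
  expect_equal(evaluate_segmentation(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               list(accuracy = 0.5, precision = 0.5, recall = 0.5))
  expect_equal(evaluate_segmentation(c(1, 0, 1), c(1, 0, 1)),
               list(accuracy = 1, precision = 1, recall = 1))
  # undefined-denominator conventions
  expect_equal(evaluate_segmentation(c(0, 0), c(1, 0))$recall, 0)
  expect_equal(evaluate_segmentation(c(0, 0), c(1, 1))$precision, 0)
  expect_error(evaluate_segmentation(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("models round-trip through the portable JSON serialization", {
  m <- fixture_model("two_peak")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fcl(m, path)
  m2 <- read_fcl(path)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12)
  s <- render_assay_strip(default_responses()$CEA, 30, seed = 18)
  p <- extract_intensity_profile(lfaquant:::crop_box(s$image, s$truth_bbox))
  expect_identical(predict_mask(m2, p)$mask, predict_mask(m, p)$mask)
})
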