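# Calibration fitting, LOD, SNR, CV, inversion, hook-effect branching,
# panel interpretation.

test_that("noiseless linear data is fitted exactly and inverted exactly", {
  pts <- data.frame(concentration = rep(c(1, 5, 10, 20, 40), each = 2),
                    intensity = rep(2 * c(1, 5, 10, 20, 40) + 1, each = 2))
  curve <- fit_calibration(pts, "linear_c", blanks = c(1, 1, 1))
  expect_equal(coef(curve), c(intercept = 1, slope = 2), tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$residual_sd, 0, tolerance = 1e-10)
  expect_equal(invert_calibration(curve, 5)$concentration, 2,
               tolerance = 1e-12)
  # round trip over the valid range, both forms
  for (c0 in c(1, 7, 33)) {
    expect_equal(invert_calibration(curve, predict(curve, c0))$concentration,
                 c0, tolerance = 1e-10)
  }
  ptsl <- data.frame(concentration = 10^(0:3),
                     intensity = 5 - 1.2 * (0:3))
  curvel <- fit_calibration(ptsl, "linear_log10c", blanks = c(5, 5),
                            line_role = "antigen")
  expect_identical(curvel$direction, "decreasing")
  expect_lt(coef(curvel)[["slope"]], 0)
  for (c0 in c(1, 50, 800))
    expect_equal(invert_calibration(curvel, predict(curvel, c0))$concentration,
                 c0, tolerance = 1e-9)
})

test_that("calibration fit preconditions are enforced", {
  pts <- data.frame(concentration = c(1, 1, 1, 1), intensity = 1:4)
  expect_error(fit_calibration(pts, "linear_c", blanks = c(1, 2)),
               "4 distinct")
  pts2 <- data.frame(concentration = 1:5, intensity = 1:5)
  expect_error(fit_calibration(pts2, "linear_c", blanks = 1), "2 blank")
  pts3 <- data.frame(concentration = 0:4, intensity = 1:5)
  expect_error(fit_calibration(pts3, "linear_log10c", blanks = c(1, 2)),
               "positive")
})

test_that("calibration on generated CEA data recovers the transfer slope", {
  curve <- fixture_calibration("CEA")
  expect_identical(curve$direction, "increasing")
  expect_gt(curve$r_squared, 0.9)
  # local linear slope of the generator chain at mid-range
  resp <- default_responses()$CEA
  chain <- function(c_) render_transfer(
    signal_from_concentration(resp, c_)[["test"]])
  slope_true <- (chain(30) - chain(20)) / 10
  expect_equal(curve$slope, slope_true, tolerance = 0.1)
})

test_that("LOD follows the limit-of-the-blank hand computation", {
  pts <- data.frame(concentration = 0:5, intensity = 10 + 4 * (0:5))
  curve <- fit_calibration(pts, "linear_c",
                           blanks = c(8, 10, 12))  # mean 10, sd 2
  expect_equal(lod(curve), (10 + 3 * sd(c(8, 10, 12)) - 10) / 4,
               tolerance = 1e-12)
  expect_equal(lod(curve), 1.5, tolerance = 1e-12)
  # perfect blank with intercept at blank mean -> LOD 0
  curve0 <- fit_calibration(pts, "linear_c", blanks = c(10, 10, 10))
  expect_equal(lod(curve0), 0, tolerance = 1e-12)
  # doubling the blank SD strictly increases the LOD
  curve2 <- fit_calibration(pts, "linear_c", blanks = c(6, 10, 14))
  expect_gt(lod(curve2), lod(curve))
  # unsupported for decreasing (antigen) curves
  dec <- fit_calibration(data.frame(concentration = 1:5,
                                    intensity = 10 - (1:5)),
                         "linear_c", blanks = c(1, 2),
                         line_role = "antigen")
  expect_error(lod(dec), "increasing")
})

test_that("snr and cv follow their definitions", {
  expect_equal(snr(c(18, 20, 22), c(1, 5, 9)), 20 / 4)
  expect_equal(snr(2 * c(18, 20, 22), c(1, 5, 9)), 10)
  expect_error(snr(1:3, c(2, 2, 2)), "zero")
  expect_equal(cv(c(10, 10, 10)), 0)
  expect_equal(cv(c(8, 10, 12)), 20, tolerance = 1e-12)
  expect_equal(cv(3 * c(8, 10, 12)), cv(c(8, 10, 12)), tolerance = 1e-12)
  expect_error(cv(c(-1, 1)), "zero mean")
  expect_error(cv(5), "at least 2")
})

test_that("intensities below the limit of the blank are flagged below LOD", {
  pts <- data.frame(concentration = 0:5, intensity = 10 + 4 * (0:5))
  curve <- fit_calibration(pts, "linear_c", blanks = c(8, 10, 12))
  r <- invert_calibration(curve, 9)   # below the blank mean
  expect_true(r$below_lod)
  r2 <- invert_calibration(curve, 30)
  expect_false(r2$below_lod)
  expect_error(invert_calibration(curve, Inf), "finite")
})

test_that("hook-effect branching picks the regime from the antigen line", {
  curves <- fixture_crp_curves()
  resp <- default_responses()$CRP
  line_int <- function(c_) {
    sig <- signal_from_concentration(resp, c_)
    c(test = render_transfer(sig[["test"]]),
      antigen = render_transfer(sig[["antigen"]]))
  }
  # antigen near maximum, test mid-range -> low branch in [0, 10]
  li <- line_int(3)
  r <- quantify_crp(li[["test"]], li[["antigen"]], curves$low, curves$high)
  expect_identical(r$branch, "low")
  expect_true(r$concentration >= 0 && r$concentration <= 10)
  # antigen almost competed away -> high branch near the top of the range
  hi <- line_int(400)
  r2 <- quantify_crp(hi[["test"]], hi[["antigen"]], curves$low, curves$high)
  expect_identical(r2$branch, "high")
  expect_gt(r2$concentration, 100)
  # both lines dead -> invalid test
  expect_error(quantify_crp(0.001, 0.001, curves$low, curves$high),
               class = "lfa_invalid_test")
})

test_that("the two CRP branches agree near the 10 ug/mL crossover", {
  curves <- fixture_crp_curves()
  resp <- default_responses()$CRP
  sig <- signal_from_concentration(resp, 10)
  r <- quantify_crp(render_transfer(sig[["test"]]),
                    render_transfer(sig[["antigen"]]),
                    curves$low, curves$high)
  # recovered concentration close to 10 regardless of branch: tolerance
  # from the curves' own residual scatter mapped through their slopes
  tol <- max(curves$low$residual_sd / abs(curves$low$slope),
             curves$high$residual_sd / abs(curves$high$slope))
  expect_lt(abs(log10(r$concentration) - 1), max(tol, 0.15))
})

test_that("panel interpretation follows the fixed clinical thresholds", {
  p <- interpret_panel(c(CEA = 3, CA125 = 120, CRP = 2))
  expect_identical(p$band, c("normal", "strongly_elevated", "low_range"))
  p2 <- interpret_panel(c(CEA = 12, CA125 = 50, CRP = 40))
  expect_identical(p2$band, c("intermediate", "elevated", "high_range"))
  p3 <- interpret_panel(c(CEA = 0, CA125 = 0, CRP = 0))
  expect_true(all(p3$band %in% c("normal", "low_range")))
  expect_true(attr(p3, "validity"))
  expect_error(interpret_panel(c(TROPONIN = 1)), "thresholds")
  expect_error(interpret_panel(c(CEA = -1)), "non-negative")
  # boundary semantics pinned to the shipped table
  th <- clinical_thresholds()
  expect_identical(interpret_panel(c(CEA = th$CEA$normal_below))$band,
                   "intermediate")
  expect_identical(interpret_panel(c(CA125 = th$CA125$normal_upper))$band,
                   "normal")
})
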