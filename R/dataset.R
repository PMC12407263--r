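# Seeded generation of labeled datasets: pad scenes for detection and
# classification, labeled profiles for segmentation training.

#' Partition sizes for dataset splits
#'
#' Rounding rule: nearest integer (half up) for every partition except the
#' last, which receives the remainder; sizes always sum to \code{n}.
#'
#' @param n total count.
#' @param splits numeric proportions summing to 1.
#' @return integer vector of sizes, same names as \code{splits}.
#' @export
split_sizes <- function(n, splits) {
  if (abs(sum(splits) - 1) > 1e-8)
    stop_domain("split proportions must sum to 1")
  if (any(splits < 0)) stop_domain("split proportions must be non-negative")
  k <- length(splits)
  sizes <- floor(n * splits[-k] + 0.5)
  sizes <- c(sizes, n - sum(sizes))
  if (any(sizes < 0)) stop_domain("degenerate split proportions for this n")
  stats::setNames(as.integer(sizes), names(splits))
}

# Class-conditional concentration sampler used by the default dataset
# generator. Concentrations are drawn so that every line that should be
# visible clears the renderer's visibility threshold comfortably.
default_conc_sampler <- function(class, responses = default_responses()) {
  switch(class,
    control_only = {
      analyte <- sample(c("CEA", "CA125"), 1)
      list(analyte = analyte, concentration = 0)
    },
    test_and_control = {
      analyte <- sample(c("CEA", "CA125"), 1)
      conc <- if (analyte == "CEA") stats::runif(1, 10, 50)
              else stats::runif(1, 200, 1000)
      list(analyte = analyte, concentration = conc)
    },
    test_antigen_and_control = {
      list(analyte = "CRP", concentration = 10^stats::runif(1, 0, 2.3))
    },
    stop_domain(paste("unknown readout class:", class)))
}

#' Generate a labeled synthetic dataset of pad scenes
#'
#' Draws readout classes from \code{class_mix}, samples concentrations
#' per class, renders each strip, composites it onto a pad scene with
#' random rotation (within ±10 degrees), placement and lighting, and
#' partitions the samples into splits by the documented rounding rule.
#' Every sample carries complete ground truth (zone box, class, pixel
#' mask, concentrations, seed); partitions are disjoint and the whole
#' procedure is deterministic given \code{seed}.
#'
#' @param n number of samples, >= 10.
#' @param class_mix named proportions over the readout classes.
#' @param conc_sampler function(class) returning
#'   \code{list(analyte, concentration)}; default draws analytes and
#'   concentrations spanning the calibrated windows.
#' @param splits named proportions over partitions, summing to 1.
#' @param seed integer seed.
#' @param noise a [noise_spec()].
#' @param scenes logical: composite onto pad scenes (\code{TRUE}) or keep
#'   plain strip images.
#' @return list of class \code{lfa_dataset}: \code{samples} (list of
#'   \code{lfa_sample}), \code{manifest} (data.frame with id, class,
#'   analyte, concentration, partition, seed), \code{seed}.
#' @export
generate_dataset <- function(n,
                             class_mix = c(control_only = 1/3,
                                           test_and_control = 1/3,
                                           test_antigen_and_control = 1/3),
                             conc_sampler = NULL,
                             splits = c(train = 0.7, test = 0.2, val = 0.1),
                             seed = 1L, noise = noise_spec(),
                             scenes = TRUE) {
  if (n < 10) stop_domain("n must be at least 10")
  known <- c("control_only", "test_and_control", "test_antigen_and_control")
  if (!all(names(class_mix) %in% known))
    stop_domain("class_mix contains an unknown readout class (config error)")
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop_domain("class_mix proportions must sum to 1")
  sizes <- split_sizes(n, splits)
  if (is.null(conc_sampler)) conc_sampler <- default_conc_sampler
  responses <- default_responses()

  with_seed(seed, {
    classes <- sample(names(class_mix), n, replace = TRUE,
                      prob = class_mix)
    sample_seeds <- sample.int(.Machine$integer.max - 1, 2 * n)
    partition <- rep(names(sizes), sizes)[sample.int(n)]

    samples <- vector("list", n)
    man <- vector("list", n)
    for (i in seq_len(n)) {
      drawn <- conc_sampler(classes[i])
      resp <- responses[[drawn$analyte]]
      s <- render_assay_strip(resp, drawn$concentration, noise,
                              seed = sample_seeds[2 * i - 1])
      if (scenes) {
        sc <- scene_spec(rotation_deg = stats::runif(1, -10, 10),
                         gain = stats::runif(1, 0.85, 1.15),
                         offset_px = round(stats::runif(2, -20, 20)))
        s <- render_pad_scene(s, sc, seed = sample_seeds[2 * i])
      }
      samples[[i]] <- s
      man[[i]] <- data.frame(id = i, class = s$truth_class,
                             analyte = drawn$analyte,
                             concentration = drawn$concentration,
                             partition = partition[i],
                             seed = s$seed)
    }
    structure(list(samples = samples, manifest = do.call(rbind, man),
                   seed = as.integer(seed)),
              class = "lfa_dataset")
  })
}

#' @export
print.lfa_dataset <- function(x, ...) {
  cat(sprintf("Synthetic LFA dataset: %d samples, seed %d\n",
              nrow(x$manifest), x$seed))
  print(table(x$manifest$partition, x$manifest$class))
  invisible(x)
}

#' Generate labeled intensity profiles for segmentation training
#'
#' Renders strips of the requested variant (\code{two_peak}: two-line
#' assays at quantifiable concentrations; \code{three_peak}: three-line
#' hook-design assays; \code{pooled}: an even mix) and pairs each
#' 512-sample profile with the generator's per-pixel line labels.
#'
#' With the default \code{acquisition = "detected"} each strip is
#' composited onto a pad scene under varied lighting and small rotations,
#' the readout zone is located by [detect_readout_zone()] and the profile
#' is extracted from the rectified detected crop — the same acquisition
#' path as real smartphone captures. The ground-truth mask lives on the
#' true zone grid, so the small residual registration error of detection
#' is part of the learning task (labels are still generated, never
#' hand-annotated). \code{acquisition = "truth_crop"} bypasses scenes and
#' detection and yields perfectly registered, noise-free-geometry
#' profiles.
#'
#' @param n number of profiles.
#' @param variant \code{"two_peak"}, \code{"three_peak"} or
#'   \code{"pooled"}.
#' @param seed integer seed.
#' @param noise a [noise_spec()].
#' @param acquisition \code{"detected"} (scene + detector, default) or
#'   \code{"truth_crop"}.
#' @return list with \code{profiles} (n x 512 matrix), \code{masks}
#'   (n x 512), \code{variant}, \code{seed}.
#' @export
generate_labeled_profiles <- function(n, variant = c("two_peak",
                                                     "three_peak",
                                                     "pooled"),
                                      seed = 1L, noise = noise_spec(),
                                      acquisition = c("detected",
                                                      "truth_crop")) {
  variant <- match.arg(variant)
  acquisition <- match.arg(acquisition)
  responses <- default_responses()
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1, 2 * n)
    kinds <- switch(variant,
                    two_peak = rep("two", n),
                    three_peak = rep("three", n),
                    pooled = sample(rep(c("two", "three"), length.out = n)))
    profiles <- matrix(0, n, 512)
    masks <- matrix(0L, n, 512)
    for (i in seq_len(n)) {
      # profiles span each assay type's full range, including blanks and
      # faint lines, so the models learn absent as well as present peaks
      drawn <- if (kinds[i] == "two") {
        if (stats::runif(1) < 0.15) {
          list(analyte = sample(c("CEA", "CA125"), 1), concentration = 0)
        } else default_conc_sampler("test_and_control", responses)
      } else {
        list(analyte = "CRP", concentration = 10^stats::runif(1, -1, 2.3))
      }
      s <- render_assay_strip(responses[[drawn$analyte]],
                              drawn$concentration, noise,
                              seed = seeds[2 * i - 1])
      zone <- NULL
      if (acquisition == "detected") {
        sc <- scene_spec(rotation_deg = stats::runif(1, -10, 10),
                         gain = stats::runif(1, 0.85, 1.15),
                         offset_px = round(stats::runif(2, -20, 20)))
        ps <- render_pad_scene(s, sc, seed = seeds[2 * i])
        det <- detect_readout_zone(ps$image)
        if (det$accepted)
          zone <- crop_box(det$rectified, det$bbox_rect)
      }
      if (is.null(zone)) zone <- crop_box(s$image, s$truth_bbox)
      profiles[i, ] <- extract_intensity_profile(zone)$values
      masks[i, ] <- s$truth_mask
    }
    list(profiles = profiles, masks = masks, variant = variant,
         seed = as.integer(seed))
  })
}

#' Write a dataset to disk as PNG images with JSON ground truth
#'
#' Each sample becomes \code{sample_<id>.png} (8-bit RGB) with a JSON
#' sidecar holding the zone box, class, mask run-lengths, concentrations
#' and seed; a \code{manifest.csv} indexes the directory.
#'
#' @param dataset an \code{lfa_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lfa_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    png::writePNG(s$image, file.path(dir, sprintf("sample_%04d.png", i)))
    r <- rle(s$truth_mask)
    jsonlite::write_json(
      list(bbox = s$truth_bbox, class = s$truth_class,
           mask_rle = list(lengths = r$lengths, values = r$values),
           concentrations = s$truth_concentrations, seed = s$seed),
      file.path(dir, sprintf("sample_%04d.json", i)),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a PNG/TIFF/JPEG image as a numeric RGB array
#'
#' @param path image file (PNG via the png package; TIFF via the tiff
#'   package if installed).
#' @return height x width x 3 array in \code{[0,1]}.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop_domain("reading TIFF requires the tiff package")
                  tiff::readTIFF(path)
                },
                stop_domain(paste("unsupported image format:", ext)))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
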