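# Conditioning: turn a high-contrast raster into the canonical white-on-black
# silhouette (single homogeneous component) and enforce the acquisition
# quality-control rules. General-photo background removal is out of scope:
# inputs are assumed separable by a global threshold.

#' Rescale an image to the standard pixel count
#'
#' Scales both dimensions by `sqrt(target_pixels / current_pixels)` so the
#' aspect ratio is preserved and the output pixel count equals the standard
#' (up to the rounding needed to keep integer dimensions). Images already at
#' the target are returned unchanged.
#'
#' @param image Numeric raster matrix in `[0, 1]`.
#' @param target_pixels Standard resolution in pixels (default 5 megapixels,
#'   the acquisition standard).
#' @return Numeric raster matrix.
#' @export
standardize_resolution <- function(image, target_pixels = 5e6) {
  assert_that(is.matrix(image) && is.numeric(image) && length(image) > 0,
              "image must be a non-empty numeric matrix", "silfat_invalid_input")
  assert_that(is_scalar(target_pixels) && target_pixels >= 1,
              "target_pixels must be positive")
  h <- nrow(image); w <- ncol(image)
  s <- sqrt(target_pixels / (h * w))
  nh <- max(1L, as.integer(round(h * s)))
  nw <- max(1L, as.integer(round(w * s)))
  if (nh == h && nw == w) return(image)
  resize_raster(image, nh, nw)
}

#' Binarize a raster into a conditioned silhouette
#'
#' Thresholds the image, keeps the largest 8-connected foreground component,
#' fills interior holes, and validates the silhouette invariants. Values
#' above the threshold are foreground when `foreground = "light"`; setting
#' `foreground = "dark"` makes the result invariant to inverting the image.
#'
#' @param image Numeric raster in `[0, 1]` (8-bit matrices in `[0, 255]` are
#'   accepted and rescaled).
#' @param threshold `"otsu"` or a numeric cut in `[0, 1]` (values > 1 are
#'   taken on the 8-bit scale).
#' @param foreground Which side of the threshold is the body.
#' @param fill_holes Fill interior holes after component selection.
#' @param strict Enforce the left/right/top border-clearance invariant
#'   (framing error when violated). Use `strict = FALSE` to obtain a lenient
#'   silhouette for [quality_check()].
#' @param allow_bottom_contact Permit foreground on the bottom image row
#'   when `strict`.
#' @return A [binary_silhouette()].
#' @export
binarize <- function(image, threshold = "otsu",
                     foreground = c("light", "dark"), fill_holes = TRUE,
                     strict = TRUE, allow_bottom_contact = FALSE) {
  foreground <- match.arg(foreground)
  assert_that(is.matrix(image) && is.numeric(image) && length(image) > 0,
              "image must be a non-empty numeric matrix", "silfat_invalid_input")
  if (max(image) > 1) image <- image / 255
  if (identical(threshold, "otsu")) {
    thr <- EBImage::otsu(EBImage::Image(image))
  } else {
    assert_that(is_scalar(threshold), "threshold must be 'otsu' or a number")
    thr <- if (threshold > 1) threshold / 255 else threshold
  }
  mask <- if (foreground == "light") image > thr else image < thr
  runs <- mask_runs(mask)
  if (nrow(runs) == 0L) {
    stop_silfat("no foreground pixels after thresholding", "silfat_no_subject")
  }
  comp <- run_labels(runs)
  kept <- seq_len(nrow(runs))
  if (max(comp) > 1L) {
    lens <- runs$end - runs$start + 1L
    sizes <- as.integer(tapply(lens, comp, sum))
    kept <- which(comp == which.max(sizes))
    mask <- runs_to_mask(runs, kept, nrow(mask), ncol(mask))
  }
  if (fill_holes && anyDuplicated(runs$row[kept]) > 0L) {
    mask <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask), ncol(mask))) > 0
  }
  if (strict) {
    # single component is guaranteed above; only the framing invariant can fail
    assert_that(!any(mask[1L, ]) && !any(mask[, 1L]) && !any(mask[, ncol(mask)]),
                "foreground touches the top, left, or right border",
                "silfat_framing_error")
    if (!allow_bottom_contact) {
      assert_that(!any(mask[nrow(mask), ]),
                  "foreground touches the bottom border",
                  "silfat_framing_error")
    }
  }
  binary_silhouette(mask, check = FALSE)
}

#' Quality-control thresholds
#'
#' Operational tolerances for the acquisition rules. The named checks come
#' from the acquisition protocol; the numeric defaults are package choices
#' (the protocol names the rules but not their thresholds).
#'
#' @param head_tilt_deg Maximum deviation (degrees) of the head principal
#'   axis from vertical.
#' @param min_height_fraction Minimum eye-malleolus span as a fraction of
#'   image height (guards against coarse pixel size).
#' @param protrusion_fraction Maximum torso-row protrusion
#'   (`(max - median)` row width over span) before an arm is judged not
#'   alongside the body.
#' @param leg_split_fraction Maximum fraction of lower-body rows allowed to
#'   split into multiple runs.
#' @param allow_bottom_contact Permit foreground on the bottom image row.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(head_tilt_deg = 8, min_height_fraction = 0.5,
                      protrusion_fraction = 0.15, leg_split_fraction = 0.1,
                      allow_bottom_contact = FALSE) {
  structure(list(head_tilt_deg = head_tilt_deg,
                 min_height_fraction = min_height_fraction,
                 protrusion_fraction = protrusion_fraction,
                 leg_split_fraction = leg_split_fraction,
                 allow_bottom_contact = allow_bottom_contact),
            class = "qc_config")
}

# Angle (degrees) of the principal axis of a pixel region from vertical.
principal_axis_deg <- function(mask_region) {
  px <- which(mask_region, arr.ind = TRUE)
  if (nrow(px) < 10L) return(0)
  cv <- stats::cov(px)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  atan2(abs(ev[2L]), abs(ev[1L])) * 180 / pi
}

#' Acquisition quality control on a conditioned silhouette
#'
#' Runs every check and reports all failures (no short-circuit): head not
#' horizontal, arm not alongside, legs not aligned, subject too small,
#' touching border, multiple bodies. Degenerate silhouettes yield failures,
#' never exceptions.
#'
#' @param sil A [binary_silhouette()] (possibly leniently constructed).
#' @param config A [qc_config()].
#' @return An object of class `qc_report`: `passed`, `failures`, `metrics`.
#' @export
quality_check <- function(sil, config = qc_config()) {
  assert_that(inherits(sil, "binary_silhouette"), "sil must be a binary_silhouette")
  mask <- sil$mask
  failures <- character(0)
  metrics <- list()

  ncomp <- count_components(mask)
  metrics$n_components <- ncomp
  if (ncomp > 1L) {
    failures <- c(failures, "multiple_bodies")
    mask <- largest_component(mask)
  }

  border <- any(mask[1L, ]) || any(mask[, 1L]) || any(mask[, ncol(mask)]) ||
    (!config$allow_bottom_contact && any(mask[nrow(mask), ]))
  metrics$touching_border <- border
  if (border) failures <- c(failures, "touching_border")

  prof <- sil_profile(mask)
  if (is.null(prof) || prof$body_height < 20L) {
    failures <- unique(c(failures, "subject_too_small"))
    return(structure(list(passed = length(failures) == 0L,
                          failures = failures, metrics = metrics),
                     class = "qc_report"))
  }
  top <- prof$top; bottom <- prof$bottom; counts <- prof$counts
  bh <- prof$body_height

  # approximate eye and malleolus lines (same conventions as the detector)
  k <- max(5L, 2L * as.integer(round(bh / 500)) + 1L)
  nwin <- (top + as.integer(round(0.08 * bh))):(top + as.integer(round(0.22 * bh)))
  nwin <- nwin[nwin >= top & nwin <= bottom]
  neck_row <- nwin[which.min(run_mean(counts[nwin], k))]
  eye <- top + as.integer(round(0.4 * (neck_row - top)))
  malleolus <- bottom - as.integer(round(0.02 * bh))
  span <- malleolus - eye

  metrics$span_fraction <- span / nrow(mask)
  if (metrics$span_fraction < config$min_height_fraction) {
    failures <- c(failures, "subject_too_small")
  }

  head_rows <- top:neck_row
  metrics$head_tilt_deg <- principal_axis_deg(mask[head_rows, , drop = FALSE])
  if (metrics$head_tilt_deg > config$head_tilt_deg) {
    failures <- c(failures, "head_not_horizontal")
  }

  torso_rows <- (top + as.integer(round(0.18 * bh))):(top + as.integer(round(0.50 * bh)))
  tw <- counts[torso_rows]
  metrics$protrusion_fraction <- (max(tw) - stats::median(tw)) / span
  if (metrics$protrusion_fraction > config$protrusion_fraction) {
    failures <- c(failures, "arm_not_alongside")
  }

  leg_rows <- (top + as.integer(round(0.58 * bh))):(top + as.integer(round(0.90 * bh)))
  w <- ncol(mask)
  starts <- mask[leg_rows, , drop = FALSE] &
    !cbind(FALSE, mask[leg_rows, -w, drop = FALSE])
  nrun <- rowSums(starts)
  metrics$leg_split_fraction <- mean(nrun > 1L)
  if (metrics$leg_split_fraction > config$leg_split_fraction) {
    failures <- c(failures, "legs_not_aligned")
  }

  structure(list(passed = length(failures) == 0L, failures = failures,
                 metrics = metrics), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", if (x$passed) "PASSED" else
    paste("FAILED:", paste(x$failures, collapse = ", "))))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %s = %s\n", nm, format(x$metrics[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Condition an image file into a silhouette with a QC report
#'
#' Reads a raster, standardizes its resolution, binarizes it and runs
#' quality control; optionally writes the conditioned silhouette and the QC
#' report.
#'
#' @param input Path to a PNG/PGM image.
#' @param output Optional path for the conditioned silhouette image.
#' @param qc_report_path Optional path for the QC report JSON.
#' @param threshold See [binarize()].
#' @param target_pixels See [standardize_resolution()].
#' @param qc A [qc_config()].
#' @return A list with `silhouette` and `qc`.
#' @export
condition_image <- function(input, output = NULL, qc_report_path = NULL,
                            threshold = "otsu", target_pixels = 5e6,
                            qc = qc_config()) {
  img <- read_raster(input)
  img <- standardize_resolution(img, target_pixels)
  sil <- binarize(img, threshold = threshold, strict = FALSE)
  report <- quality_check(sil, qc)
  if (!is.null(output)) write_silhouette(sil, output)
  if (!is.null(qc_report_path)) {
    jsonlite::write_json(list(passed = report$passed, failures = report$failures,
                              metrics = report$metrics),
                         qc_report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(silhouette = sil, qc = report)
}
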