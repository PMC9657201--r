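# Landmark detection, virtual frame and occupancy features on a conditioned
# silhouette. All features are normalized by the eye-malleolus span, which is
# what makes them invariant to camera distance and image resolution.

#' Geometry configuration
#'
#' @param frame_fraction Virtual-frame width as a fraction of the
#'   eye-malleolus span (the "preset standard fraction").
#' @param site_fractions Named fractions of the eye-malleolus span at which
#'   the chest, belly, thigh and calf lines are placed before refinement.
#' @param malleolus_offset Malleolus line offset above the lowest foreground
#'   row, as a fraction of body height.
#' @param eye_head_fraction Eye line position as a fraction of head height
#'   (crown to neck minimum) below the crown.
#' @param refine_window Half-width (fraction of span) of the search window in
#'   which a site line snaps to the nearest local width extremum; if the
#'   window contains none, the proportional placement is kept.
#' @param neck_search Fractions of body height bounding the neck-minimum
#'   search.
#' @param min_rows Minimum body height in rows below which landmark
#'   detection refuses the input.
#' @param occupancy_mode `"ratio"` (foreground / background pixels inside
#'   the frame) or `"fraction"` (foreground / all frame pixels).
#' @param width_band Half-width of the site-width averaging band as a
#'   fraction of span (at least 3 rows); 0 measures the single site row.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(frame_fraction = 0.4,
                            site_fractions = c(chest = 0.22, belly = 0.38,
                                               thigh = 0.60, calf = 0.82),
                            malleolus_offset = 0.02,
                            eye_head_fraction = 0.4,
                            refine_window = 0.03,
                            neck_search = c(0.08, 0.22),
                            min_rows = 50L,
                            occupancy_mode = c("ratio", "fraction"),
                            width_band = 0.005) {
  occupancy_mode <- match.arg(occupancy_mode)
  assert_that(is_scalar(frame_fraction) && frame_fraction > 0 && frame_fraction <= 1,
              "frame_fraction must be in (0, 1]")
  assert_that(length(site_fractions) == 4L &&
                all(c("chest", "belly", "thigh", "calf") %in% names(site_fractions)) &&
                all(site_fractions > 0 & site_fractions < 1) &&
                !is.unsorted(site_fractions[c("chest", "belly", "thigh", "calf")]),
              "site_fractions must be four increasing fractions in (0, 1)")
  structure(list(frame_fraction = frame_fraction,
                 site_fractions = site_fractions[c("chest", "belly", "thigh", "calf")],
                 malleolus_offset = malleolus_offset,
                 eye_head_fraction = eye_head_fraction,
                 refine_window = refine_window,
                 neck_search = neck_search,
                 min_rows = as.integer(min_rows),
                 occupancy_mode = occupancy_mode,
                 width_band = width_band),
            class = "geometry_config")
}

#' Transverse landmark line rows
#'
#' @param eye_row,chest_row,belly_row,thigh_row,calf_row,malleolus_row
#'   Row indices (1-based, row 1 = top), strictly increasing.
#' @param image_height Image height used for bounds checking.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(eye_row, chest_row, belly_row, thigh_row,
                         calf_row, malleolus_row, image_height) {
  rows <- c(eye_row = eye_row, chest_row = chest_row, belly_row = belly_row,
            thigh_row = thigh_row, calf_row = calf_row,
            malleolus_row = malleolus_row)
  assert_that(all(rows >= 1) && all(rows <= image_height),
              "landmark rows out of image bounds", "silfat_landmark_failure")
  assert_that(all(diff(rows) > 0),
              "landmark rows must be strictly ordered top to bottom",
              "silfat_landmark_failure")
  vals <- as.integer(round(rows))
  names(vals) <- names(rows)
  structure(as.list(vals), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>", paste(names(unclass(x)),
                              unlist(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Detect anatomical landmark lines on a silhouette
#'
#' The malleolus line sits a configured offset above the lowest foreground
#' row; the eye line a configured fraction of head height below the crown
#' (head height is estimated from the neck minimum-width row, since eyes are
#' invisible on a binary mask); the chest, belly, thigh and calf lines are
#' placed at configured fractions of the eye-malleolus span and refined to
#' the nearest local width extremum within `refine_window` of span.
#'
#' @param sil A [binary_silhouette()].
#' @param config A [geometry_config()].
#' @return A [landmark_set()].
#' @export
detect_landmarks <- function(sil, config = geometry_config()) {
  assert_that(inherits(sil, "binary_silhouette"), "sil must be a binary_silhouette")
  prof <- sil_profile(sil$mask)
  assert_that(!is.null(prof), "silhouette has no foreground", "silfat_no_subject")
  if (prof$body_height < config$min_rows) {
    stop_silfat(sprintf("silhouette of %d rows is below the %d-row minimum",
                        prof$body_height, config$min_rows),
                "silfat_degenerate_input")
  }
  top <- prof$top; bottom <- prof$bottom; counts <- prof$counts
  bh <- prof$body_height
  malleolus <- bottom - as.integer(round(config$malleolus_offset * bh))

  k <- max(5L, 2L * as.integer(round(bh / 500)) + 1L)
  nwin <- top + as.integer(round(config$neck_search * bh))
  nwin <- max(nwin[1], top):min(nwin[2], bottom)
  sm <- run_mean(counts[nwin], k)
  neck_row <- nwin[which.min(sm)]
  # the neck minimum is a kink of the width profile; localize it subrow-
  # accurately the same way as the site lines
  neck_row <- refine_site(counts, neck_row,
                          max(3L, as.integer(round(0.015 * bh))), top, bottom)
  eye <- top + as.integer(round(config$eye_head_fraction * (neck_row - top)))

  span <- malleolus - eye
  assert_that(span > 0, "eye-malleolus span is degenerate", "silfat_landmark_failure")
  sites <- eye + as.integer(round(config$site_fractions * span))
  win <- max(3L, as.integer(round(config$refine_window * span)))
  refined <- vapply(sites, function(s) refine_site(counts, s, win, top, bottom),
                    integer(1))

  landmark_set(eye, refined[1L], refined[2L], refined[3L], refined[4L],
               malleolus, image_height = sil$height)
}

# Refine a site row to the local kink of the width profile. The outline is
# piecewise linear, so the anatomical line (width extremum or slope break)
# is the breakpoint of a continuous two-segment least-squares fit over the
# search window; this localizes the kink to about a row even where
# quantized widths plateau. Windows without a clear slope break keep the
# proportional placement.
refine_site <- function(counts, s, win, top, bottom) {
  a <- max(top, s - win)
  b <- min(bottom, s + win)
  rows <- a:b
  n <- length(rows)
  if (n < 12L) return(as.integer(s))
  v <- counts[rows]
  # candidate breakpoints in the middle half of the window (the kink is
  # near the proportional row by convention)
  lo <- a + as.integer(ceiling(n / 4)); hi <- b - as.integer(ceiling(n / 4))
  if (lo >= hi) return(as.integer(s))
  best <- c(rss = Inf, row = s, dslope = 0)
  for (cp in lo:hi) {
    x1 <- rows - cp
    X <- cbind(1, x1, pmax(x1, 0))
    cf <- tryCatch(qr.coef(qr(X), v), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    rss <- sum((v - X %*% cf)^2)
    if (rss < best[["rss"]]) best <- c(rss = rss, row = cp, dslope = cf[3L])
  }
  # require a slope break of at least ~0.02 px/row to accept the refinement
  if (abs(best[["dslope"]]) < 0.02) return(as.integer(s))
  as.integer(best[["row"]])
}

#' Virtual frame bounded by the eye and malleolus lines
#'
#' The frame's vertical span is the eye-malleolus pixel distance; its width
#' is `frame_fraction` of that span, centered on the silhouette centroid
#' column and clipped to the image.
#'
#' @param lm A [landmark_set()].
#' @param sil The [binary_silhouette()] the landmarks belong to.
#' @param frame_fraction Frame width as a fraction of the span.
#' @return An object of class `virtual_frame` with `top_row`, `bottom_row`,
#'   `left_col`, `right_col`, `span`.
#' @export
build_virtual_frame <- function(lm, sil, frame_fraction = 0.4) {
  assert_that(inherits(lm, "landmark_set"), "lm must be a landmark_set")
  assert_that(inherits(sil, "binary_silhouette"), "sil must be a binary_silhouette")
  assert_that(is_scalar(frame_fraction) && frame_fraction > 0 && frame_fraction <= 1,
              "frame_fraction must be in (0, 1]")
  span <- lm$malleolus_row - lm$eye_row
  width <- as.integer(round(frame_fraction * span))
  rows <- lm$eye_row:(lm$malleolus_row - 1L)
  cols_in <- which(colSums(sil$mask[rows, , drop = FALSE]) > 0)
  centroid <- sum(sil$mask[rows, , drop = FALSE] %*% seq_len(sil$width)) /
    sum(sil$mask[rows, , drop = FALSE])
  left <- as.integer(round(centroid - width / 2))
  left <- max(1L, min(left, sil$width - width + 1L))
  right <- min(sil$width, left + width - 1L)
  if (length(cols_in) && (min(cols_in) < left || max(cols_in) > right)) {
    stop_silfat(sprintf(
      "silhouette (cols %d..%d) overflows the virtual frame (cols %d..%d); raise frame_fraction",
      min(cols_in), max(cols_in), left, right), "silfat_frame_overflow")
  }
  structure(list(top_row = lm$eye_row, bottom_row = lm$malleolus_row,
                 left_col = left, right_col = right, span = span),
            class = "virtual_frame")
}

#' @export
print.virtual_frame <- function(x, ...) {
  cat(sprintf("<virtual_frame> rows %d..%d (span %d), cols %d..%d (width %d)\n",
              x$top_row, x$bottom_row, x$span, x$left_col, x$right_col,
              x$right_col - x$left_col + 1L))
  invisible(x)
}

#' Pixel occupancy inside the virtual frame
#'
#' The method's core shape feature: the count of foreground pixels inside
#' the frame divided by the count of background pixels inside it
#' (`mode = "ratio"`), or by all frame pixels (`mode = "fraction"`). Rows
#' are counted half-open, `[top_row, bottom_row)`.
#'
#' @param sil A [binary_silhouette()].
#' @param frame A [virtual_frame()].
#' @param mode `"ratio"` or `"fraction"`.
#' @return A positive scalar.
#' @export
occupancy_ratio <- function(sil, frame, mode = c("ratio", "fraction")) {
  mode <- match.arg(mode)
  assert_that(inherits(frame, "virtual_frame"), "frame must be a virtual_frame")
  assert_that(frame$bottom_row <= sil$height && frame$right_col <= sil$width,
              "frame exceeds silhouette bounds")
  rows <- frame$top_row:(frame$bottom_row - 1L)
  cols <- frame$left_col:frame$right_col
  fg <- sum(sil$mask[rows, cols])
  total <- length(rows) * length(cols)
  assert_that(fg > 0, "no foreground pixels inside the frame", "silfat_no_subject")
  if (mode == "fraction") return(fg / total)
  bg <- total - fg
  assert_that(bg > 0, "frame contains no background pixels",
              "silfat_degenerate_frame")
  fg / bg
}

#' Normalized transverse widths at the landmark sites
#'
#' Foreground run length at each site row, divided by the eye-malleolus
#' span. The run length is averaged over a narrow band of rows
#' (`width_band` of span, at least +-3 rows) centered on the site line;
#' `width_band = 0` measures the single row.
#'
#' @param sil A [binary_silhouette()].
#' @param lm A [landmark_set()].
#' @param width_band Band half-width as a fraction of span.
#' @return Named numeric vector `chest`, `belly`, `thigh`, `calf`, each in
#'   `(0, 1)`.
#' @export
site_widths <- function(sil, lm, width_band = 0.005) {
  assert_that(inherits(lm, "landmark_set"), "lm must be a landmark_set")
  span <- lm$malleolus_row - lm$eye_row
  counts <- rowSums(sil$mask)
  hw <- if (width_band > 0) max(3L, as.integer(round(width_band * span))) else 0L
  sites <- c(chest = lm$chest_row, belly = lm$belly_row,
             thigh = lm$thigh_row, calf = lm$calf_row)
  w <- vapply(sites, function(s) {
    rows <- max(1L, s - hw):min(sil$height, s + hw)
    mean(counts[rows])
  }, numeric(1))
  if (any(w <= 0)) {
    stop_silfat("no foreground pixels on a site row", "silfat_landmark_failure")
  }
  w / span
}

#' Assemble the model feature vector
#'
#' Combines the occupancy ratio and the four site widths with the span and
#' subject metadata. Body weight is deliberately not representable here:
#' the prediction models are trained exclusive of body weight.
#'
#' @param sil A [binary_silhouette()].
#' @param lm A [landmark_set()].
#' @param frame A [virtual_frame()].
#' @param gender `"female"` or `"male"`.
#' @param subject_id Identifier.
#' @param stature Optional stature in cm, carried for the optional model
#'   covariate.
#' @param metadata Optional named list of extra fields; any field matching
#'   `weight` is rejected.
#' @param config A [geometry_config()] (occupancy mode and width band).
#' @return An object of class `feature_vector`.
#' @export
extract_features <- function(sil, lm, frame, gender,
                             subject_id = NA_character_, stature = NULL,
                             metadata = NULL, config = geometry_config()) {
  gender <- match.arg(gender, c("female", "male"))
  if (!is.null(metadata) && any(grepl("weight", names(metadata), ignore.case = TRUE))) {
    stop_silfat("body weight must not enter the feature vector",
                "silfat_contract_error")
  }
  w <- site_widths(sil, lm, width_band = config$width_band)
  structure(list(subject_id = subject_id,
                 occupancy_ratio = occupancy_ratio(sil, frame,
                                                   mode = config$occupancy_mode),
                 width_chest = w[["chest"]], width_belly = w[["belly"]],
                 width_thigh = w[["thigh"]], width_calf = w[["calf"]],
                 span_px = frame$span, gender = gender,
                 stature = stature %||% NA_real_),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%s): occupancy %.4f, widths C %.4f B %.4f T %.4f Cf %.4f, span %d px\n",
              x$subject_id, x$gender, x$occupancy_ratio, x$width_chest,
              x$width_belly, x$width_thigh, x$width_calf, x$span_px))
  invisible(x)
}

#' One-shot feature extraction from a silhouette
#'
#' Runs landmark detection, frame construction and feature assembly.
#'
#' @inheritParams extract_features
#' @param config A [geometry_config()].
#' @return A `feature_vector`.
#' @export
silhouette_features <- function(sil, gender, subject_id = NA_character_,
                                stature = NULL, config = geometry_config()) {
  lm <- detect_landmarks(sil, config)
  frame <- build_virtual_frame(lm, sil, frame_fraction = config$frame_fraction)
  extract_features(sil, lm, frame, gender, subject_id = subject_id,
                   stature = stature, config = config)
}

#' Tabulate feature vectors
#'
#' @param fvs List of `feature_vector` objects.
#' @return Data frame with columns `subject_id, occupancy_ratio,
#'   width_chest, width_belly, width_thigh, width_calf, span_px, gender,
#'   stature_cm`.
#' @export
features_table <- function(fvs) {
  assert_that(length(fvs) > 0 && all(vapply(fvs, inherits, logical(1), "feature_vector")),
              "fvs must be a non-empty list of feature_vector")
  data.frame(
    subject_id = vapply(fvs, function(f) as.character(f$subject_id), character(1)),
    occupancy_ratio = vapply(fvs, `[[`, numeric(1), "occupancy_ratio"),
    width_chest = vapply(fvs, `[[`, numeric(1), "width_chest"),
    width_belly = vapply(fvs, `[[`, numeric(1), "width_belly"),
    width_thigh = vapply(fvs, `[[`, numeric(1), "width_thigh"),
    width_calf = vapply(fvs, `[[`, numeric(1), "width_calf"),
    span_px = vapply(fvs, `[[`, numeric(1), "span_px"),
    gender = vapply(fvs, `[[`, character(1), "gender"),
    stature_cm = vapply(fvs, `[[`, numeric(1), "stature"),
    stringsAsFactors = FALSE
  )
}
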