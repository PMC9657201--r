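# Parametric lateral-silhouette renderer. The body is a vertical stack of
# piecewise-linear width segments (sagittal depths); in the lateral view the
# arm hangs within the torso profile, the legs merge into a single column,
# and only transverse widths matter downstream, so no limb detail is drawn.

WIDTH_JITTER_SD <- 5e-4   # multiplicative width noise per knot, per jitter unit
LEAN_JITTER_SD_DEG <- 0.25 # lean-angle SD (degrees) per jitter unit
NECK_MIN_T <- 0.155        # neck minimum as fraction of stature from crown

#' Rendering specification
#'
#' @param megapixels Target image size in megapixels (used when
#'   `image_width`/`image_height` are not given). The standard acquisition
#'   resolution is 5 MP.
#' @param aspect_ratio Width / height of the image.
#' @param image_width,image_height Explicit pixel dimensions (override
#'   `megapixels`).
#' @param pixels_per_cm Scale factor; `NULL` picks the scale at which the
#'   body spans `fill_fraction` of the image height (emulating the 1.8-2.1 m
#'   camera distance).
#' @param fill_fraction Body height as a fraction of image height when
#'   `pixels_per_cm` is `NULL`.
#' @param pose_jitter Dimensionless repositioning perturbation scale: 1 unit
#'   = 0.05% multiplicative width noise per profile knot and a 0.25 degree
#'   SD lean. 0 disables all randomness.
#' @param foreground_value,background_value 8-bit intensities of body and
#'   background in the rendered raster.
#' @param seed Integer seed for the jitter draws.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(megapixels = 5, aspect_ratio = 0.5,
                        image_width = NULL, image_height = NULL,
                        pixels_per_cm = NULL, fill_fraction = 0.9,
                        pose_jitter = 1, foreground_value = 255,
                        background_value = 0, seed = 1L) {
  if (is.null(image_width) || is.null(image_height)) {
    assert_that(is_scalar(megapixels) && megapixels > 0.009 && megapixels <= 64,
                "megapixels must be in (0.01, 64]")
    image_width <- as.integer(round(sqrt(megapixels * 1e6 * aspect_ratio)))
    image_height <- as.integer(round(image_width / aspect_ratio))
  }
  assert_that(is_count(image_width) && is_count(image_height),
              "image dimensions must be positive integers")
  assert_that(is_scalar(pose_jitter) && pose_jitter >= 0,
              "pose_jitter must be nonnegative")
  assert_that(is_scalar(foreground_value) && is_scalar(background_value) &&
                foreground_value != background_value,
              "foreground_value must differ from background_value")
  assert_that(is.null(pixels_per_cm) ||
                (is_scalar(pixels_per_cm) && pixels_per_cm > 0),
              "pixels_per_cm must be positive")
  assert_that(is_scalar(fill_fraction) && fill_fraction > 0 && fill_fraction < 1,
              "fill_fraction must be in (0, 1)")
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 pixels_per_cm = pixels_per_cm, fill_fraction = fill_fraction,
                 pose_jitter = pose_jitter,
                 foreground_value = foreground_value,
                 background_value = background_value,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' @export
print.render_spec <- function(x, ...) {
  cat(sprintf("<render_spec> %d x %d px (%.1f MP), jitter %.2f, seed %d\n",
              x$image_width, x$image_height,
              x$image_width * x$image_height / 1e6, x$pose_jitter, x$seed))
  invisible(x)
}

# Profile knots (t = fraction of stature from the crown, width in cm).
# The chest/belly/calf knots sit exactly at the default proportional site
# positions, so the generator and the landmark detector share one anatomical
# convention: refined and proportional placements coincide by construction.
body_profile_knots <- function(params, geometry = geometry_config()) {
  d <- params$segment_thicknesses
  t_eye <- geometry$eye_head_fraction * NECK_MIN_T
  t_mall <- 1 - geometry$malleolus_offset
  ts <- t_eye + geometry$site_fractions * (t_mall - t_eye)
  k <- rbind(
    c(0.000, 0.25 * d[["head"]]),
    c(0.020, 0.72 * d[["head"]]),
    c(0.045, 0.95 * d[["head"]]),
    c(0.075, 1.00 * d[["head"]]),
    c(0.105, 0.92 * d[["head"]]),
    c(0.130, 1.08 * d[["neck"]]),
    c(NECK_MIN_T, 1.00 * d[["neck"]]),
    c(0.185, 0.85 * d[["chest"]]),
    c(ts[["chest"]], d[["chest"]]),
    c(0.330, 0.88 * d[["chest"]]),
    c(ts[["belly"]], d[["belly"]]),
    c(0.470, d[["hip"]]),
    c(0.530, 0.85 * d[["hip"]]),
    c(ts[["thigh"]], d[["thigh"]]),
    c(0.740, 0.95 * d[["calf"]]),
    c(ts[["calf"]], d[["calf"]]),
    c(0.930, d[["ankle"]]),
    c(0.965, 0.98 * d[["ankle"]]),
    c(0.975, d[["ankle"]]),
    c(1.000, d[["ankle"]] + 8)
  )
  assert_that(all(diff(k[, 1]) > 0),
              "landmark fractions incompatible with the body profile")
  list(t = k[, 1], w = k[, 2], t_eye = t_eye, t_mall = t_mall, t_sites = ts)
}

# Exact trapezoid integral of the piecewise-linear profile over [a, b] in t.
integrate_profile <- function(t, w, a, b) {
  xs <- sort(unique(c(t[t > a & t < b], a, b)))
  ws <- stats::approx(t, w, xout = xs, rule = 2)$y
  sum((ws[-1] + ws[-length(ws)]) / 2 * diff(xs))
}

# Features implied by the continuous outline (pixel-free oracle). Site
# widths are band means over the same span-relative band the pixel
# measurement uses, so the two agree in the infinite-resolution limit.
profile_true_features <- function(knots, stature, ppc,
                                  geometry = geometry_config()) {
  span_t <- knots$t_mall - knots$t_eye
  span_cm <- span_t * stature
  area_cm2 <- integrate_profile(knots$t, knots$w, knots$t_eye, knots$t_mall) * stature
  frame_cm2 <- geometry$frame_fraction * span_cm * span_cm
  hb <- geometry$width_band * span_t
  wsite <- if (hb > 0) {
    vapply(knots$t_sites, function(ts) {
      integrate_profile(knots$t, knots$w, ts - hb, ts + hb) / (2 * hb)
    }, numeric(1)) / span_cm
  } else {
    stats::approx(knots$t, knots$w, xout = knots$t_sites, rule = 2)$y / span_cm
  }
  occ <- switch(geometry$occupancy_mode,
                ratio = area_cm2 / (frame_cm2 - area_cm2),
                fraction = area_cm2 / frame_cm2)
  list(occupancy_ratio = occ,
       width_chest = wsite[[1]], width_belly = wsite[[2]],
       width_thigh = wsite[[3]], width_calf = wsite[[4]],
       span_px = span_cm * ppc)
}

#' Render a lateral silhouette image
#'
#' Draws the standing lateral profile of one subject as a single connected
#' foreground region, together with the exact ground truth (landmark rows
#' and the features implied by the continuous outline). With
#' `pose_jitter = 0` the output is a pure function of `(params, spec)`;
#' otherwise jitter draws are seeded by `spec$seed`.
#'
#' @param params A [body_params()] subject.
#' @param spec A [render_spec()].
#' @param geometry A [geometry_config()]; fixes the shared landmark
#'   conventions (and the frame fraction used for the ground-truth
#'   occupancy).
#' @return A list of class `silhouette_render` with `image` (numeric raster
#'   in `[0, 1]`), `mask` (logical), `ground_truth` (`landmarks`,
#'   `true_features`), and `pixels_per_cm`.
#' @export
render_silhouette <- function(params, spec = render_spec(),
                              geometry = geometry_config()) {
  assert_that(inherits(params, "body_params"), "params must be a body_params")
  assert_that(inherits(spec, "render_spec"), "spec must be a render_spec")
  render_body(params, spec, geometry, violation = NULL)
}

#' Render a silhouette violating one acquisition rule
#'
#' Produces an image that breaks exactly the named quality-control rule:
#' `tilted_head` (head sheared 18 degrees), `arm_raised` (arm extended
#' forward at shoulder height), `legs_apart` (leg column split below the
#' crotch), `subject_too_small` (half-scale body), `touching_border` (crown
#' on the top image row).
#'
#' @inheritParams render_silhouette
#' @param violation One of `"tilted_head"`, `"arm_raised"`, `"legs_apart"`,
#'   `"subject_too_small"`, `"touching_border"`.
#' @return A numeric raster matrix in `[0, 1]`.
#' @export
render_qc_violation <- function(params, spec = render_spec(),
                                violation = c("tilted_head", "arm_raised",
                                              "legs_apart", "subject_too_small",
                                              "touching_border"),
                                geometry = geometry_config()) {
  violation <- match.arg(violation)
  render_body(params, spec, geometry, violation = violation)$image
}

render_body <- function(params, spec, geometry, violation = NULL) {
  H <- spec$image_height
  W <- spec$image_width
  ppc <- spec$pixels_per_cm %||% (spec$fill_fraction * H / params$stature)
  if (identical(violation, "subject_too_small")) ppc <- ppc * 0.5
  hpx <- params$stature * ppc
  if (hpx > 0.985 * H) {
    stop_silfat(sprintf("body (%.0f px) does not fit the %d px image height",
                        hpx, H), "silfat_rendering_bounds")
  }
  knots <- body_profile_knots(params, geometry)

  jitter <- spec$pose_jitter
  lean_deg <- 0
  if (jitter > 0) {
    draws <- with_seed(spec$seed, {
      list(mult = stats::rnorm(length(knots$w), 0, WIDTH_JITTER_SD * jitter),
           lean = stats::rnorm(1, 0, LEAN_JITTER_SD_DEG * jitter))
    })
    knots$w <- knots$w * (1 + draws$mult)
    lean_deg <- draws$lean
  }

  top <- as.integer(floor((H - hpx) / 2))
  if (identical(violation, "touching_border")) top <- 0L
  body_rows <- (top + 1L):min(top + as.integer(ceiling(hpx)), H)
  tt <- (body_rows - top - 0.5) / hpx
  tt <- pmin(pmax(tt, 0), 1)
  wcm <- stats::approx(knots$t, knots$w, xout = tt, rule = 2)$y
  wpx <- wcm * ppc
  if (max(wpx) > 0.9 * W) {
    stop_silfat("body wider than the image at this scale", "silfat_rendering_bounds")
  }

  center <- rep((W + 1) / 2, length(body_rows))
  if (lean_deg != 0) {
    # lean about the ankles
    bot <- top + hpx
    center <- center + tan(lean_deg * pi / 180) * (bot - body_rows)
  }
  neck_row <- top + NECK_MIN_T * hpx
  if (identical(violation, "tilted_head")) {
    head <- tt < NECK_MIN_T
    center[head] <- center[head] + tan(18 * pi / 180) * (neck_row - body_rows[head])
  }

  mask <- matrix(FALSE, H, W)
  split_legs <- identical(violation, "legs_apart")
  for (i in seq_along(body_rows)) {
    r <- body_rows[i]
    half <- wpx[i] / 2
    lc <- max(1L, as.integer(ceiling(center[i] - half)))
    rc <- min(W, as.integer(floor(center[i] + half)))
    if (rc < lc) { lc <- as.integer(round(center[i])); rc <- lc }
    if (split_legs && tt[i] > 0.530) {
      g <- max(3L, as.integer(round(0.3 * (rc - lc + 1L))))
      cmid <- as.integer(round(center[i]))
      l2 <- cmid - as.integer(ceiling(g / 2))
      r2 <- cmid + as.integer(ceiling(g / 2))
      if (l2 > lc && r2 < rc) {
        mask[r, lc:l2] <- TRUE
        mask[r, r2:rc] <- TRUE
        next
      }
    }
    mask[r, lc:rc] <- TRUE
  }

  if (identical(violation, "arm_raised")) {
    arm_rows <- body_rows[tt >= 0.200 & tt <= 0.235]
    if (length(arm_rows)) {
      front <- max(which(mask[arm_rows[1L], ]))
      tip <- min(front + as.integer(round(0.18 * hpx)), W - 5L)
      mask[arm_rows, (front - 2L):tip] <- TRUE
    }
  }

  fg <- spec$foreground_value / 255
  bg <- spec$background_value / 255
  image <- matrix(bg, H, W)
  image[mask] <- fg

  lm_t <- c(eye = knots$t_eye, chest = knots$t_sites[["chest"]],
            belly = knots$t_sites[["belly"]], thigh = knots$t_sites[["thigh"]],
            calf = knots$t_sites[["calf"]], malleolus = knots$t_mall)
  landmarks <- top + as.integer(round(lm_t * hpx))
  names(landmarks) <- paste0(names(lm_t), "_row")

  structure(list(image = image, mask = mask,
                 ground_truth = list(
                   landmarks = landmarks,
                   true_features = profile_true_features(knots, params$stature,
                                                         ppc, geometry)),
                 pixels_per_cm = ppc, subject_id = params$subject_id),
            class = "silhouette_render")
}

#' @export
print.silhouette_render <- function(x, ...) {
  cat(sprintf("<silhouette_render> %s: %d x %d px, %.2f px/cm\n",
              x$subject_id %||% "?", nrow(x$image), ncol(x$image),
              x$pixels_per_cm))
  invisible(x)
}

#' Exact occupancy features for a cohort, without rendering
#'
#' Evaluates the continuous body outline analytically (trapezoid integration
#' of the piecewise-linear profile) and returns the feature vectors the
#' pixel pipeline would measure in the infinite-resolution limit. This is
#' the generator's ground-truth oracle for the geometry module and a fast
#' feature source for regression simulations.
#'
#' @param cohort A `cohort` (list of [body_params()]).
#' @param pixels_per_cm Scale used only to express `span_px`.
#' @param geometry A [geometry_config()].
#' @return A list of `feature_vector` objects.
#' @export
true_cohort_features <- function(cohort, pixels_per_cm = 10,
                                 geometry = geometry_config()) {
  lapply(cohort, function(p) {
    k <- body_profile_knots(p, geometry)
    tf <- profile_true_features(k, p$stature, pixels_per_cm, geometry)
    structure(c(list(subject_id = p$subject_id), tf,
                list(gender = p$gender, stature = p$stature)),
              class = "feature_vector")
  })
}

#' Write ground-truth landmark rows as a sidecar CSV
#'
#' @param renders List of `silhouette_render` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(renders, path) {
  rows <- lapply(renders, function(r) {
    c(list(subject_id = r$subject_id), as.list(r$ground_truth$landmarks))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
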