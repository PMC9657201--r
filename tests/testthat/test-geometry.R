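# Geometry: landmark detection against generator ground truth, frame
# arithmetic, occupancy and width definitions, invariances.

test_that("landmarks on a jitter-free render recover ground truth within 2 rows", {
  p <- fixture_body()
  r <- render_silhouette(p, render_spec(megapixels = 5, pose_jitter = 0))
  sil <- binarize(r$image, threshold = 0.5)
  lm <- detect_landmarks(sil)
  gt <- r$ground_truth$landmarks
  for (nm in names(gt)) {
    expect_lte(abs(lm[[nm]] - gt[[nm]]), 2,
               label = sprintf("%s (got %d, truth %d)", nm, lm[[nm]], gt[[nm]]))
  }
})

test_that("landmark rows normalized by span agree across resolutions", {
  p <- fixture_body(gender = "male", fm_total = 17, fm_abdominal = 1.9,
                    stature = 178.8, weight = 80.1)
  rel_rows <- lapply(c(2, 8), function(mp) {
    sil <- conditioned(p, render_spec(megapixels = mp, pose_jitter = 0))
    lm <- detect_landmarks(sil)
    span <- lm$malleolus_row - lm$eye_row
    (unlist(lm) - lm$eye_row) / span
  })
  expect_lt(max(abs(rel_rows[[1]] - rel_rows[[2]])), 0.01)
})

test_that("detect_landmarks refuses degenerate silhouettes", {
  small <- matrix(FALSE, 30, 30)
  small[10:19, 10:20] <- TRUE
  expect_error(detect_landmarks(binary_silhouette(small)),
               class = "silfat_degenerate_input")
})

test_that("virtual frame arithmetic follows its definition", {
  mask <- matrix(FALSE, 1300, 700)
  mask[80:1200, 200:500] <- TRUE
  sil <- binary_silhouette(mask)
  lm <- landmark_set(100, 300, 500, 700, 900, 1100, image_height = 1300)
  fr <- build_virtual_frame(lm, sil, frame_fraction = 0.4)
  expect_equal(fr$span, 1000)
  expect_equal(fr$right_col - fr$left_col + 1L, 400L)
  expect_equal(fr$top_row, 100)
  expect_equal(fr$bottom_row, 1100)
  # frame narrower than the silhouette: overflow
  expect_error(build_virtual_frame(lm, sil, frame_fraction = 0.25),
               class = "silfat_frame_overflow")
})

test_that("occupancy_ratio counts pixels exactly on constructed fixtures", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:6, 2:6] <- TRUE  # 25 foreground
  sil <- binary_silhouette(mask, check = FALSE)
  fr <- manual_frame(1, 11, 1, 10)  # rows 1..10 x cols 1..10 = 100 cells
  expect_equal(occupancy_ratio(sil, fr), 25 / 75, tolerance = 1e-15)
  expect_equal(occupancy_ratio(sil, fr, mode = "fraction"), 0.25)

  one <- matrix(FALSE, 12, 12)
  one[5, 5] <- TRUE
  expect_equal(occupancy_ratio(binary_silhouette(one, check = FALSE), fr), 1 / 99)
})

test_that("occupancy_ratio equals a brute-force double loop on random fixtures", {
  set.seed(13)
  for (i in 1:20) {
    mask <- matrix(runif(15 * 15) < 0.4, 15, 15)
    mask[8, 8] <- TRUE
    sil <- binary_silhouette(mask, check = FALSE)
    fr <- manual_frame(2, 12, 3, 13)
    fg <- 0; bg <- 0
    for (r in 2:11) for (cc in 3:13) {
      if (mask[r, cc]) fg <- fg + 1 else bg <- bg + 1
    }
    if (fg == 0 || bg == 0) next
    expect_identical(occupancy_ratio(sil, fr), fg / bg)
  }
})

test_that("site widths are exact on a rectangle silhouette", {
  mask <- matrix(FALSE, 260, 80)
  mask[21:240, 21:60] <- TRUE  # 220 rows x 40 cols
  sil <- binary_silhouette(mask)
  lm <- landmark_set(30, 80, 120, 160, 200, 230, image_height = 260)
  w <- site_widths(sil, lm)   # span 200, width 40 everywhere
  expect_equal(unname(w), rep(0.2, 4), tolerance = 1e-15)
  w0 <- site_widths(sil, lm, width_band = 0)  # single-row mode identical here
  expect_equal(w, w0)
})

test_that("features are invariant to background padding", {
  p <- fixture_body()
  r <- render_silhouette(p, small_spec(mp = 0.5))
  sil <- binarize(r$image, threshold = 0.5)
  fv <- silhouette_features(sil, "female")
  padded <- matrix(FALSE, sil$height + 40, sil$width + 30)
  padded[31:(30 + sil$height), 11:(10 + sil$width)] <- sil$mask
  fv2 <- silhouette_features(binary_silhouette(padded), "female")
  for (nm in c("occupancy_ratio", "width_chest", "width_belly",
               "width_thigh", "width_calf", "span_px")) {
    expect_equal(fv2[[nm]], fv[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("extract_features composes the individual operations and bars weight", {
  p <- fixture_body()
  sil <- conditioned(p, small_spec(mp = 0.5))
  cfg <- geometry_config()
  lm <- detect_landmarks(sil, cfg)
  fr <- build_virtual_frame(lm, sil, cfg$frame_fraction)
  fv <- extract_features(sil, lm, fr, "female", subject_id = "X",
                         stature = p$stature)
  expect_equal(fv$occupancy_ratio, occupancy_ratio(sil, fr))
  w <- site_widths(sil, lm, width_band = cfg$width_band)
  expect_equal(fv$width_belly, unname(w[["belly"]]))
  expect_equal(fv$span_px, fr$span)
  expect_error(extract_features(sil, lm, fr, "female",
                                metadata = list(weight_kg = 70)),
               class = "silfat_contract_error")
  expect_false("weight_kg" %in% names(features_table(list(fv))))
})

test_that("belly width increases with fat mass across a cohort", {
  co <- sample_cohort(60, 1, seed = 31)
  fvs <- true_cohort_features(co)
  belly_cm <- vapply(seq_along(co), function(i) {
    fvs[[i]]$width_belly * 0.918 * co[[i]]$stature
  }, numeric(1))
  fm <- vapply(co, `[[`, numeric(1), "fm_total")
  expect_gt(cor(fm, belly_cm, method = "spearman"), 0.9)
})
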