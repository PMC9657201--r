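# Synthetic cohort and renderer: seeded determinism, cohort marginals,
# shape monotonicity, rendering contracts.

test_that("sample_cohort is deterministic and validates arguments", {
  a <- sample_cohort(1, 1, seed = 77)
  b <- sample_cohort(1, 1, seed = 77)
  expect_identical(a, b)
  c1 <- sample_cohort(5, 0.6, seed = 1)
  c2 <- sample_cohort(5, 0.6, seed = 2)
  expect_false(identical(c1, c2))
  expect_error(sample_cohort(0, 0.5), class = "silfat_invalid_argument")
  expect_error(sample_cohort(5, 1.2), class = "silfat_invalid_argument")
  expect_error(sample_cohort(5, -0.1), class = "silfat_invalid_argument")
})

test_that("cohort marginals converge to the configured table values", {
  df <- as.data.frame(sample_cohort(10000, 1, seed = 5))
  cfg <- cohort_config()$female
  for (v in c("stature", "weight", "fm_total", "fm_abdominal")) {
    col <- c(stature = "stature_cm", weight = "weight_kg",
             fm_total = "fm_total_kg", fm_abdominal = "fm_abdominal_kg")[[v]]
    target <- cfg[[v]]
    se <- target[["sd"]] / sqrt(nrow(df))
    expect_lt(abs(mean(df[[col]]) - target[["mean"]]), 3 * se,
              label = sprintf("%s mean", v))
    expect_true(all(df[[col]] >= target[["min"]] & df[[col]] <= target[["max"]]),
                info = sprintf("%s range", v))
  }
  # law-of-large-numbers SD check against the configured SD
  expect_lt(abs(sd(df$fm_total_kg) / 10.9 - 1), 0.05)
  # female fat mass mean within 2 SE of the table value at study size
  df84 <- as.data.frame(sample_cohort(84, 1, seed = 21))
  expect_lt(abs(mean(df84$fm_total_kg) - 22.8), 2 * 10.9 / sqrt(84))
})

test_that("subject invariants hold across a mixed cohort", {
  co <- sample_cohort(400, 0.5, seed = 8)
  df <- as.data.frame(co)
  expect_true(all(df$fm_abdominal_kg > 0))
  expect_true(all(df$fm_abdominal_kg < df$fm_total_kg))
  depths <- as.matrix(df[, grep("^depth_", names(df))])
  expect_true(all(depths > 0))
  expect_setequal(unique(df$gender), c("female", "male"))
})

test_that("the depth mapping is strictly increasing in fat mass at the belly and chest", {
  base <- segment_depths(20, 2, 165)
  plus_fm <- segment_depths(25, 2, 165)
  plus_ab <- segment_depths(20, 3, 165)
  expect_gt(plus_fm[["belly"]], base[["belly"]])
  expect_gt(plus_fm[["chest"]], base[["chest"]])
  expect_gt(plus_ab[["belly"]], base[["belly"]])
  expect_gt(plus_ab[["chest"]], base[["chest"]])
})

test_that("rendering is deterministic and monotone in fat mass", {
  p <- fixture_body()
  sp <- small_spec(mp = 1)
  r1 <- render_silhouette(p, sp)
  r2 <- render_silhouette(p, sp)
  expect_identical(r1$image, r2$image)
  spj <- small_spec(mp = 1, jitter = 1, seed = 99)
  expect_identical(render_silhouette(p, spj)$image,
                   render_silhouette(p, spj)$image)

  heavier <- fixture_body(fm_total = 22.8 + 5, id = "FIX02")
  rh <- render_silhouette(heavier, sp)
  wa <- sum(r1$mask[r1$ground_truth$landmarks[["belly_row"]], ])
  wb <- sum(rh$mask[rh$ground_truth$landmarks[["belly_row"]], ])
  expect_gt(wb, wa)
  expect_gt(rh$ground_truth$true_features$width_belly,
            r1$ground_truth$true_features$width_belly)
})

test_that("rendered silhouettes satisfy the ground-truth contracts", {
  p <- fixture_body(gender = "male", fm_total = 17, fm_abdominal = 1.9,
                    stature = 178.8, weight = 80.1)
  r <- render_silhouette(p, small_spec(mp = 1))
  lmk <- r$ground_truth$landmarks
  expect_true(all(diff(lmk[c("eye_row", "chest_row", "belly_row",
                             "thigh_row", "calf_row", "malleolus_row")]) > 0))
  expect_equal(count_components(r$mask), 1L)
  expect_false(any(r$mask[1, ]) || any(r$mask[, 1]) ||
                 any(r$mask[, ncol(r$mask)]))
  tf <- r$ground_truth$true_features
  expect_gt(tf$occupancy_ratio, 0)
  widths <- unlist(tf[c("width_chest", "width_belly", "width_thigh", "width_calf")])
  expect_true(all(widths > 0 & widths < 1))
})

test_that("rendering errors on a body that does not fit", {
  p <- fixture_body()
  sp <- render_spec(megapixels = 0.5, pixels_per_cm = 50, pose_jitter = 0)
  expect_error(render_silhouette(p, sp), class = "silfat_rendering_bounds")
})

test_that("qc violation renders break only the intended rule", {
  p <- fixture_body()
  sp <- small_spec(mp = 0.5)
  expect_error(render_qc_violation(p, sp, "not_a_mode"))

  img <- render_qc_violation(p, sp, "subject_too_small")
  sil <- binarize(img, threshold = 0.5, strict = FALSE)
  qc <- quality_check(sil)
  expect_identical(qc$failures, "subject_too_small")
  expect_lt(qc$metrics$span_fraction, 0.5)

  qc_tilt <- quality_check(binarize(render_qc_violation(p, sp, "tilted_head"),
                                    threshold = 0.5, strict = FALSE))
  expect_identical(qc_tilt$failures, "head_not_horizontal")
  expect_gt(qc_tilt$metrics$head_tilt_deg, 8)

  qc_arm <- quality_check(binarize(render_qc_violation(p, sp, "arm_raised"),
                                   threshold = 0.5, strict = FALSE))
  expect_identical(qc_arm$failures, "arm_not_alongside")
  expect_true(quality_check(conditioned(p, sp))$passed)
})
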