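# Conditioning: resolution standardization, binarization, QC.

test_that("standardize_resolution scales by sqrt and preserves aspect ratio", {
  img <- matrix(runif(2000 * 1000), 2000, 1000)
  out <- standardize_resolution(img, 5e6)
  expect_equal(dim(out), c(3162, 1581))
  expect_equal(dim(out)[1] / dim(out)[2], 2, tolerance = 1e-3)
  expect_identical(standardize_resolution(out, 5e6), out)
  expect_error(standardize_resolution(matrix(numeric(0), 0, 0)),
               class = "silfat_error")
})

test_that("standardize_resolution round-trip alters the mask by under 1%", {
  p <- fixture_body()
  r <- render_silhouette(p, small_spec(mp = 0.25))
  up <- standardize_resolution(r$image, 1e6)
  back <- standardize_resolution(up, prod(dim(r$image)))
  expect_equal(dim(back), dim(r$image))
  m2 <- binarize(back, threshold = 0.5)$mask
  expect_lt(mean(m2 != r$mask), 0.01)
})

test_that("binarize recovers a perfect-contrast render exactly", {
  p <- fixture_body()
  r <- render_silhouette(p, small_spec(mp = 0.5))
  sil <- binarize(r$image, threshold = 128)  # 8-bit threshold accepted
  expect_identical(sil$mask, r$mask)
  sil_otsu <- binarize(r$image, threshold = "otsu")
  expect_identical(sil_otsu$mask, r$mask)
})

test_that("binarize keeps the largest component and fills holes", {
  m <- matrix(0, 40, 40)
  m[10:30, 10:25] <- 1   # body, 336 px
  m[15:20, 15:18] <- 0   # interior hole
  m[35, 35] <- 1         # stray blob (<1% of body)
  sil <- binarize(m, threshold = 0.5)
  expect_equal(sum(sil$mask), 21 * 16)   # hole filled, blob dropped
  expect_false(sil$mask[35, 35])
})

test_that("binarize is invariant to intensity inversion", {
  p <- fixture_body()
  r <- render_silhouette(p, small_spec(mp = 0.25))
  a <- binarize(r$image, threshold = 0.5, foreground = "light")
  b <- binarize(1 - r$image, threshold = 0.5, foreground = "dark")
  expect_identical(a$mask, b$mask)
})

test_that("binarize errors on empty or badly framed input", {
  expect_error(binarize(matrix(0, 10, 10), threshold = 0.5),
               class = "silfat_no_subject")
  edge <- matrix(0, 20, 20)
  edge[5:15, 1:10] <- 1   # touches left border
  expect_error(binarize(edge, threshold = 0.5), class = "silfat_framing_error")
  expect_s3_class(binarize(edge, threshold = 0.5, strict = FALSE),
                  "binary_silhouette")
})

test_that("quality_check passes compliant renders and reports degenerate masks", {
  p <- fixture_body()
  qc <- quality_check(conditioned(p, small_spec(mp = 0.5)))
  expect_true(qc$passed)
  expect_length(qc$failures, 0)

  two <- matrix(FALSE, 60, 60)
  two[10:30, 10:20] <- TRUE
  two[40:55, 35:45] <- TRUE
  qc2 <- quality_check(binary_silhouette(two, check = FALSE))
  expect_false(qc2$passed)
  expect_true("multiple_bodies" %in% qc2$failures)

  tiny <- matrix(FALSE, 100, 50)
  tiny[40:49, 20:24] <- TRUE
  qc3 <- quality_check(binary_silhouette(tiny, check = FALSE))
  expect_false(qc3$passed)
  expect_true("subject_too_small" %in% qc3$failures)
})

test_that("condition_image runs the file-to-silhouette path on PNG and PGM", {
  p <- fixture_body()
  r <- render_silhouette(p, small_spec(mp = 0.25))
  for (ext in c("png", "pgm")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_raster(r$image, f)
    out_sil <- tempfile(fileext = ".png")
    out_qc <- tempfile(fileext = ".json")
    res <- condition_image(f, out_sil, out_qc, threshold = 0.5,
                           target_pixels = prod(dim(r$image)))
    expect_identical(res$silhouette$mask, r$mask)
    expect_true(res$qc$passed)
    expect_true(file.exists(out_sil) && file.exists(out_qc))
    qc_json <- jsonlite::read_json(out_qc)
    expect_true(qc_json$passed)
    unlink(c(f, out_sil, out_qc))
  }
})

test_that("raster files round-trip through PNG and PGM", {
  img <- matrix(runif(30 * 20), 30, 20)
  img <- round(img * 255) / 255
  for (ext in c("png", "pgm")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_raster(img, f)
    back <- read_raster(f)
    expect_equal(dim(back), dim(img))
    expect_equal(back, img, tolerance = 1 / 254)
    unlink(f)
  }
})
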