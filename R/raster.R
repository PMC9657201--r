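# Raster images are numeric matrices in [0, 1], row 1 = top of the image
# (rows are image lines, columns are pixels along a line).

#' Read a grayscale raster image (PNG or PGM)
#'
#' Color PNGs are converted to luminance (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path File path ending in `.png`, `.pgm` (binary P5 or ASCII P2).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_raster <- function(path) {
  assert_that(is.character(path) && length(path) == 1L && file.exists(path),
              sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] >= 3L) {
        img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      } else {
        img <- img[, , 1]
      }
    }
    img
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop_silfat(sprintf("unsupported image format: '%s'", ext),
                "silfat_invalid_argument")
  }
}

#' Write a grayscale raster image (PNG or PGM)
#'
#' @param image Numeric matrix in `[0, 1]` (values are clamped).
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  assert_that(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop_silfat(sprintf("unsupported image format: '%s'", ext),
                "silfat_invalid_argument")
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  assert_that(magic %in% c("P2", "P5"), "not a PGM file (expected P2 or P5 magic)")
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    assert_that(length(ch) == 1L, "truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  assert_that(w >= 1L && h >= 1L && mx >= 1L && mx <= 255L,
              "unsupported PGM dimensions or maxval")
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE, comment.char = "#")
  }
  assert_that(length(vals) == w * h, "truncated PGM pixel data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx
}

write_pgm <- function(image, path) {
  vals <- as.integer(round(t(image) * 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con, eos = NULL)
  writeBin(as.raw(vals), con)
  invisible(path)
}

# EBImage treats the first matrix dimension as x; wrap so callers think in
# (rows, cols).
resize_raster <- function(image, new_nrow, new_ncol) {
  out <- EBImage::resize(image, w = new_nrow, h = new_ncol)
  pmin(pmax(as.matrix(out), 0), 1)
}
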