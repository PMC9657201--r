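#' Conditioned binary silhouette
#'
#' The canonical container for one conditioned body profile: a logical mask
#' (`TRUE` = body) with row 1 at the top of the image. A strictly valid
#' silhouette has exactly one 8-connected foreground component that touches
#' neither the left, right, nor top border (bottom contact is tolerated only
#' when `allow_bottom_contact = TRUE`). [quality_check()] accepts leniently
#' constructed silhouettes and reports violations instead of erroring.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param check If `TRUE`, enforce the single-component and border invariants.
#' @param allow_bottom_contact Permit foreground on the bottom image row.
#' @return An object of class `binary_silhouette` with elements `mask`,
#'   `width`, `height`.
#' @export
binary_silhouette <- function(mask, check = TRUE, allow_bottom_contact = FALSE) {
  assert_that(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix")
  assert_that(!anyNA(mask), "mask must not contain NA")
  if (check) {
    assert_that(any(mask), "mask has no foreground pixels", "silfat_no_subject")
    n <- count_components(mask)
    assert_that(n == 1L,
                sprintf("mask has %d foreground components (expected 1)", n),
                "silfat_framing_error")
    assert_that(!any(mask[1L, ]) && !any(mask[, 1L]) && !any(mask[, ncol(mask)]),
                "foreground touches the top, left, or right border",
                "silfat_framing_error")
    if (!allow_bottom_contact) {
      assert_that(!any(mask[nrow(mask), ]),
                  "foreground touches the bottom border",
                  "silfat_framing_error")
    }
  }
  structure(list(mask = mask, width = ncol(mask), height = nrow(mask)),
            class = "binary_silhouette")
}

#' @export
print.binary_silhouette <- function(x, ...) {
  cat(sprintf("<binary_silhouette> %d x %d px, %d foreground px (%.1f%%)\n",
              x$height, x$width, sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Write a silhouette as an 8-bit image (255 foreground / 0 background)
#'
#' @param sil A [binary_silhouette()].
#' @param path Output path (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(sil, path) {
  assert_that(inherits(sil, "binary_silhouette"), "sil must be a binary_silhouette")
  write_raster(matrix(as.numeric(sil$mask), sil$height, sil$width), path)
}

# Row extent and per-row foreground counts, shared by QC and landmarks.
sil_profile <- function(mask) {
  counts <- rowSums(mask)
  fg <- which(counts > 0)
  if (!length(fg)) return(NULL)
  list(top = fg[1L], bottom = fg[length(fg)], counts = counts,
       body_height = fg[length(fg)] - fg[1L] + 1L)
}
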