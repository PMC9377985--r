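# Image and mask IO. Intensities are normalized to [0, 1] by bit depth on
# read (8-bit / 255, 16-bit / 65535). Writes: 8-bit PNG for .png paths,
# 16- or 32-bit TIFF for .tif/.tiff paths (the PNG writer available to the
# package is 8-bit; precision-critical outputs use TIFF).

#' Load a grayscale image
#'
#' Reads a PNG or TIFF image as a numeric matrix in `[0, 1]`. Multi-channel
#' images are accepted only when all color channels are equal (they are
#' collapsed to one); an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (rows = image rows, top to bottom).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    stop("unsupported image format \".", ext,
         "\"; supported formats: png, tif, tiff")
  )
  if (is.matrix(a)) return(a)
  nch <- dim(a)[3]
  if (nch == 2L) return(a[, , 1L])   # gray + alpha
  color <- a[, , seq_len(min(nch, 3L)), drop = FALSE]
  for (ch in 2:dim(color)[3]) {
    if (max(abs(color[, , ch] - color[, , 1L])) > 1e-9) {
      stop("color image with unequal channels: convert to grayscale ",
           "before loading (", path, ")")
    }
  }
  color[, , 1L]
}

#' Save a grayscale image
#'
#' Writes a `[0, 1]` matrix as 8-bit PNG (`.png`) or 16-bit TIFF
#' (`.tif`/`.tiff`; pass `bits = 32` for float TIFF, ~1e-7 precision).
#' Values outside `[0, 1]` are clipped in every path (TIFF storage of
#' out-of-range floats is undefined); to persist a signed field such as a
#' level-set function, map it affinely into `[0, 1]` and record the range
#' (the CLI does this via the run manifest).
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param path Destination path; the extension selects the format.
#' @param bits TIFF sample depth, 16 (default) or 32 (float).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image))
  ext <- tolower(tools::file_ext(path))
  clipped <- pmin(pmax(image, 0), 1)
  if (ext == "png") {
    png::writePNG(clipped, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(clipped, path,
                    bits.per.sample = if (bits == 32L) 32L else 16L,
                    reduce = FALSE)
  } else {
    stop("unsupported image format \".", ext,
         "\"; supported formats: png, tif, tiff")
  }
  invisible(path)
}

#' Load a binary mask
#'
#' Reads an image file and maps nonzero pixels to 1.
#'
#' @inheritParams load_image
#' @return Integer 0/1 matrix.
#' @export
load_mask <- function(path) {
  (load_image(path) > 0) * 1L
}

#' Save a binary mask
#'
#' Writes a 0/1 (or logical) mask as an 8-bit PNG with values `{0, 255}` —
#' lossless and directly viewable.
#'
#' @param mask Binary matrix.
#' @param path Destination `.png` path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  check_mask(mask, "mask")
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}
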