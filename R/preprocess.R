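#' Scale 8-bit pixel intensities to the unit interval
#'
#' Fixed-range min-max scaling: every intensity is divided by 255, mapping
#' the 8-bit range \[0, 255\] onto \[0, 1\]. The scaling is fixed-range (not
#' per-image min/max) so that identical patches taken from different images
#' produce identical graph weights.
#'
#' @param img Numeric matrix or array with values in \[0, 255\].
#' @return An object of the same shape with values in \[0, 1\].
#' @examples
#' normalize_minmax(matrix(c(0, 128, 255, 64), 2, 2))
#' @export
normalize_minmax <- function(img) {
  if (!is.numeric(img)) {
    stop("`img` must be a numeric matrix or array", call. = FALSE)
  }
  if (anyNA(img) || any(img < 0) || any(img > 255)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  img / 255
}

#' Convert a colour image to grayscale
#'
#' Three-channel images are reduced to a single channel by Rec. 601 luminance
#' weighting, 0.299 R + 0.587 G + 0.114 B, rounded to the nearest integer so
#' the result is again an 8-bit intensity grid. Single-channel input is
#' returned unchanged (dropping a trailing singleton channel dimension).
#'
#' @param img Integer-valued matrix (grayscale) or M x N x 3 array (RGB),
#'   values in \[0, 255\].
#' @return An M x N matrix of intensities in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    return(img)
  }
  if (!is.array(img) || length(dim(img)) != 3L) {
    stop("`img` must be a matrix or a 3-d array", call. = FALSE)
  }
  ch <- dim(img)[3L]
  if (ch == 1L) {
    return(matrix(img[, , 1L], dim(img)[1L], dim(img)[2L]))
  }
  if (ch != 3L) {
    stop("unsupported channel count: ", ch, " (expected 1 or 3)", call. = FALSE)
  }
  gray <- round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] +
                  0.114 * img[, , 3L])
  matrix(gray, dim(img)[1L], dim(img)[2L])
}

#' Partition a normalized image into non-overlapping square patches
#'
#' Tiles an M x N image into P = (M/p)(N/p) patches of size p x p. Patches
#' are ordered row-major over the patch grid, and pixels inside a patch keep
#' their row-major raster order; `stitch_patches()` inverts the operation
#' exactly.
#'
#' @param img Numeric matrix (a normalized image; any real matrix is
#'   accepted).
#' @param p Patch size. Must divide both image dimensions.
#' @return A `patch_set`: list with elements `patches` (list of p x p
#'   matrices), `patch_size`, and `dims` (the source image dimensions).
#' @examples
#' ps <- partition_patches(matrix(runif(16), 4, 4), 2)
#' length(ps$patches)  # 4
#' @seealso [stitch_patches()]
#' @export
partition_patches <- function(img, p) {
  stopifnot(is.matrix(img), is.numeric(img))
  p <- as.integer(p)
  m <- nrow(img)
  n <- ncol(img)
  if (length(p) != 1L || is.na(p) || p < 1L || m %% p != 0L || n %% p != 0L) {
    valid <- Filter(function(d) m %% d == 0L && n %% d == 0L, seq_len(min(m, n)))
    stop(sprintf(
      "patch size %s does not divide the %d x %d image; valid sizes: %s",
      p, m, n, paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  idx <- 0L
  patches <- vector("list", (m %/% p) * (n %/% p))
  for (pr in seq_len(m %/% p)) {
    for (pc in seq_len(n %/% p)) {
      idx <- idx + 1L
      patches[[idx]] <- img[(pr - 1L) * p + seq_len(p),
                            (pc - 1L) * p + seq_len(p), drop = FALSE]
    }
  }
  structure(
    list(patches = patches, patch_size = p, dims = c(m, n)),
    class = "patch_set"
  )
}

#' Reassemble a patch set into the original image
#'
#' Inverse of [partition_patches()]: placing the patches back in row-major
#' order reproduces the source matrix bit-exactly.
#'
#' @param ps A `patch_set`.
#' @return The reconstructed numeric matrix.
#' @export
stitch_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  p <- ps$patch_size
  m <- ps$dims[1L]
  n <- ps$dims[2L]
  out <- matrix(NA_real_, m, n)
  idx <- 0L
  for (pr in seq_len(m %/% p)) {
    for (pc in seq_len(n %/% p)) {
      idx <- idx + 1L
      out[(pr - 1L) * p + seq_len(p), (pc - 1L) * p + seq_len(p)] <-
        ps$patches[[idx]]
    }
  }
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf(
    "Patch set: %d patches of %d x %d from a %d x %d image\n",
    length(x$patches), x$patch_size, x$patch_size, x$dims[1L], x$dims[2L]
  ))
  invisible(x)
}

#' Read an image file as an 8-bit intensity array
#'
#' Supports PNG (via the png package), TIFF (via the tiff package), and
#' plain-text CSV matrices of raw 0-255 intensities. PNG/TIFF pixel values
#' are rescaled from \[0, 1\] back to 8-bit integers.
#'
#' @param path File path; format inferred from the extension.
#' @return A matrix (grayscale) or M x N x 3 array (RGB) of 0-255 values.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    px <- tiff::readTIFF(path)
  } else if (ext %in% c("csv", "txt")) {
    return(as.matrix(utils::read.csv(path, header = FALSE)))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  px <- round(px * 255)
  if (length(dim(px)) == 3L && dim(px)[3L] == 4L) {
    px <- px[, , 1:3]  # drop alpha
  }
  if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1L] else px
}

#' Write an 8-bit intensity array to disk
#'
#' Counterpart of [read_image()]; values round-trip bit-exactly through the
#' 8-bit PNG/TIFF encodings.
#'
#' @param img Matrix or M x N x 3 array of 0-255 intensities.
#' @param path Destination; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package", call. = FALSE)
    }
    png::writePNG(img / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  } else if (ext %in% c("csv", "txt")) {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}
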