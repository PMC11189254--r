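# Reader (and internal writer, used by tests) for the IDX binary format in
# which the MNIST handwritten-digit files are distributed: big-endian, magic
# number 2051 for image files (dimensions M x H x W, unsigned bytes) and 2049
# for label files.

read_idx_header <- function(con, expected_magic, n_dims, path) {
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (!identical(magic, expected_magic))
    stop(sprintf("%s: bad IDX magic number %d (expected %d)",
                 path, magic, expected_magic), call. = FALSE)
  dims <- readBin(con, "integer", n = n_dims, size = 4L, endian = "big")
  if (length(dims) != n_dims || any(dims <= 0))
    stop(sprintf("%s: truncated or invalid IDX header", path), call. = FALSE)
  dims
}

#' Load an MNIST-style image/label pair in IDX format
#'
#' Reads the big-endian IDX files used to distribute the MNIST
#' handwritten-digit dataset (magic 2051 for images, 2049 for labels) and
#' rescales pixel values from 0..255 to \[0,1\]. The canonical training and
#' test files contain 60000 and 10000 images of 28 x 28 pixels.
#'
#' @param images_path Path to the image file (magic 2051).
#' @param labels_path Optional path to the matching label file (magic 2049).
#' @return A [gray_image_set()].
#' @export
load_mnist <- function(images_path, labels_path = NULL) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, 2051L, 3L, images_path)
  M <- dims[1L]; H <- dims[2L]; W <- dims[3L]
  raw_px <- readBin(con, "integer", n = M * H * W, size = 1L, signed = FALSE)
  if (length(raw_px) != M * H * W)
    stop(sprintf("%s: truncated IDX image payload", images_path),
         call. = FALSE)
  # IDX stores images row-major: for each image, rows of pixels in order.
  arr <- aperm(array(raw_px / 255, c(W, H, M)), c(3L, 2L, 1L))
  labels <- NULL
  if (!is.null(labels_path)) {
    lcon <- file(labels_path, "rb")
    on.exit(close(lcon), add = TRUE)
    ldims <- read_idx_header(lcon, 2049L, 1L, labels_path)
    if (ldims[1L] != M)
      stop("load_mnist: label count does not match image count",
           call. = FALSE)
    labels <- readBin(lcon, "integer", n = M, size = 1L, signed = FALSE)
    if (length(labels) != M)
      stop(sprintf("%s: truncated IDX label payload", labels_path),
           call. = FALSE)
  }
  gray_image_set(arr, labels)
}

# Internal IDX writers (round-trip fixtures in tests).
write_idx_images <- function(imgs, path) {
  d <- dim(imgs$images)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(2051L, d), con, size = 4L, endian = "big")
  px <- as.integer(round(aperm(imgs$images, c(3L, 2L, 1L)) * 255))
  writeBin(as.raw(px), con)
  invisible(path)
}

write_idx_labels <- function(labels, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  invisible(path)
}
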