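#' @title Image containers
#'
#' @description
#' earpheno works with plain base-R objects on an 8-bit intensity scale:
#' a grayscale image is a numeric `H x W` matrix with values in `[0, 255]`
#' (row index = image row, column index = image column), and an RGB image is
#' an `H x W x 3` array on the same scale. All operators preserve dimensions
#' and the 8-bit range.
#'
#' @name image-containers
NULL

# ---- internal conversion helpers -------------------------------------------

# EBImage stores pixel data with x (column) as the first array dimension;
# matrices here are row-major-looking [y, x], so every hand-off transposes.
ebi <- function(m) EBImage::Image(t(m))

from_ebi <- function(im) t(EBImage::imageData(im))

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

is_gray <- function(img) is.matrix(img) && is.numeric(img)

check_intensities <- function(img, what = "image") {
  if (!is.numeric(img)) stop(what, " must be numeric", call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1])) stop(what, " contains missing values", call. = FALSE)
  if (rng[1] < 0 || rng[2] > 255)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

check_gray <- function(img) {
  if (!is_gray(img)) stop("expected a grayscale image (numeric matrix)", call. = FALSE)
  check_intensities(img, "grayscale image")
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

#' Read a plot photograph
#'
#' Reads a PNG, JPEG or TIFF photograph into the package's 8-bit
#' representation: an `H x W x 3` array for color files or an `H x W` matrix
#' for grayscale files, intensities in `[0, 255]`.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return An RGB array or grayscale matrix with 8-bit intensities.
#' @export
read_plot_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  px <- EBImage::imageData(im) * 255
  if (length(d) == 2L) return(round(t(px)))
  if (d[3] >= 3L) return(round(aperm(px[, , 1:3, drop = FALSE], c(2, 1, 3))))
  round(t(px[, , 1]))
}

#' Write a mask or label map as a PNG
#'
#' Binary masks are written as black/white 8-bit PNGs; label maps are written
#' as 16-bit grayscale PNGs (label values preserved up to 65535), convenient
#' for inspecting segmentation output.
#'
#' @param x A binary mask (0/1 matrix) or an integer label map.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  stopifnot(is.matrix(x))
  mx <- max(x)
  if (mx <= 1) {
    EBImage::writeImage(ebi(x * 1.0), path, type = "png")
  } else {
    if (mx > 65535) stop("more than 65535 labels cannot be stored in 16-bit PNG")
    EBImage::writeImage(ebi(x / 65535), path, type = "png", bits = 16L)
  }
  invisible(path)
}

#' Write an 8-bit image to disk
#'
#' @param img Grayscale matrix or RGB array with intensities in `[0, 255]`.
#' @param path Output path; the format is chosen from the file extension
#'   (png, jpeg/jpg or tiff/tif).
#' @return `path`, invisibly.
#' @export
write_plot_image <- function(img, path) {
  check_intensities(img)
  type <- switch(tolower(tools::file_ext(path)),
                 png = "png", jpg = , jpeg = "jpeg", tif = , tiff = "tiff",
                 stop("unsupported image extension: ", path))
  data <- if (is_rgb(img)) {
    EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  } else {
    ebi(img / 255)
  }
  EBImage::writeImage(data, path, type = type)
  invisible(path)
}
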