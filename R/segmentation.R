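#' Phansalkar threshold parameters
#'
#' Parameters of the local adaptive threshold used for kernels: over a
#' circular window of the given radius the mean `m` and standard deviation
#' `s` of the normalized intensities are computed and the pixel is foreground
#' when its normalized value exceeds
#' `T = m * (1 + p * exp(-q m) + k * (s / r - 1))`.
#' The method is designed for bright, low-contrast objects on a dark
#' background, which is exactly what de-husked kernels on dark cloth are.
#'
#' @param radius Window radius in pixels (default 15).
#' @param k Sensitivity constant, conventionally in `(0.2, 0.5)`
#'   (default 0.25).
#' @param r Dynamic range of the standard deviation for normalized images
#'   (default 0.5).
#' @param p,q Exponential amplitude and decay that boost the threshold in
#'   dark regions (defaults 2 and 10).
#' @return A list of class `phansalkar_params`.
#' @export
phansalkar_params <- function(radius = 15L, k = 0.25, r = 0.5, p = 2, q = 10) {
  if (radius < 1) stop("radius must be >= 1")
  if (r <= 0) stop("r must be > 0")
  if (k < 0.2 || k > 0.5)
    warning("k outside the conventional (0.2, 0.5) range")
  structure(list(radius = as.integer(radius), k = k, r = r, p = p, q = q),
            class = "phansalkar_params")
}

#' Phansalkar local threshold
#'
#' Binarizes a grayscale image with the local threshold described in
#' [phansalkar_params()]. Intensities are normalized to `[0, 1]`; the window
#' statistics use only in-bounds pixels at the borders, and the standard
#' deviation is the population form.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param params A [phansalkar_params()] object.
#' @param bracket `"standard"` applies `k * (s/r - 1)`; `"printed"` applies
#'   the variant `k * s/r` with the trailing `- 1` outside the product (an
#'   alternative reading of the formula occasionally seen in print).
#' @return Binary mask (0/1 matrix) of the same dimensions; 1 = foreground.
#' @export
phansalkar_threshold <- function(img, params = phansalkar_params(),
                                 bracket = c("standard", "printed")) {
  check_gray(img)
  bracket <- match.arg(bracket)
  if (params$radius >= min(dim(img)))
    stop("radius must be smaller than the image dimensions")
  mask <- phansalkar_mask_cpp(img / 255, params$radius, params$k, params$r,
                              params$p, params$q, bracket == "printed")
  mask
}

#' Fill holes in a binary mask
#'
#' Every background component not connected to the image border becomes
#' foreground, producing solid shapes that survive watershed splitting
#' without fragmenting. Foreground never shrinks and the operation is
#' idempotent.
#'
#' @param mask Binary 0/1 matrix.
#' @return Binary 0/1 matrix of the same dimensions.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  out <- from_ebi(EBImage::fillHull(ebi((mask > 0) * 1)))
  storage.mode(out) <- "integer"
  out
}

#' Global Otsu binarization
#'
#' Used on the blurred image of the ear branch, where a single global
#' threshold separates the merged ear blobs from the flattened background.
#' A constant image yields an all-background mask.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @return Binary 0/1 matrix.
#' @export
binarize_otsu <- function(img) {
  check_gray(img)
  if (diff(range(img)) < .Machine$double.eps) {
    out <- matrix(0L, nrow(img), ncol(img))
    return(out)
  }
  th <- EBImage::otsu(ebi(img / 255), range = c(0, 1), levels = 256)
  out <- (img / 255 > th) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Tolerance-based watershed splitting
#'
#' Splits touching convex objects in a binary mask. The Euclidean distance
#' transform of the mask is computed; internal maxima are suppressed unless
#' they exceed the saddle ("neck") connecting them to a larger maximum by
#' more than `tolerance` (a difference of inscribed-circle radii, in pixels),
#' and a marker-based watershed is flooded from the surviving maxima. Larger
#' tolerances merge more aggressively; as the tolerance grows the labeling
#' approaches one label per connected component. The returned labels
#' partition the entire foreground (adjacent labels touch; no one-pixel
#' background divide is drawn).
#'
#' @param mask Binary 0/1 matrix.
#' @param tolerance Radius difference in pixels, >= 0.
#' @return Integer label matrix; 0 = background, labels `1..n` without gaps.
#' @export
adjustable_watershed <- function(mask, tolerance = 3) {
  stopifnot(is.matrix(mask))
  if (tolerance < 0) stop("tolerance must be >= 0")
  m <- (mask > 0) * 1
  if (!any(mask > 0)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(ebi(m))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  labels <- from_ebi(ws)
  storage.mode(labels) <- "integer"
  relabel_consecutive(labels)
}

# Remap positive labels onto 1..n with no gaps, preserving order.
relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) return(labels)
  if (identical(u, seq_along(u))) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  pos <- labels > 0
  labels[pos] <- lut[labels[pos]]
  labels
}

#' Number of labels in a label map
#'
#' @param labels Integer label matrix (0 = background).
#' @return Count of distinct positive labels.
#' @export
n_labels <- function(labels) length(unique(labels[labels > 0]))
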