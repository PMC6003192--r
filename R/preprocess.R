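#' Preprocessing configuration
#'
#' Bundles the parameters of the contrast-enhancement chain applied to a raw
#' plot photo before thresholding: constant pixel subtraction (suppresses the
#' dark background and its illumination gradient), contrast-limited adaptive
#' histogram equalization (CLAHE, enhances kernel edges without amplifying
#' noise) and unsharp masking (sharpens the enhanced edges).
#'
#' @param subtract_value Intensity subtracted from every pixel, in `[0, 255]`.
#'   Default 100, chosen so that a dark-cloth background with a moderate
#'   illumination gradient is driven to zero while kernels survive.
#' @param clahe_block Side length (pixels) of the square local region whose
#'   histogram is equalized. Default 29.
#' @param clahe_bins Number of histogram bins, at most 256. Default 256.
#' @param clahe_max_slope Maximum slope of the intensity transfer function;
#'   1 leaves the image unchanged, larger values allow stronger local
#'   contrast stretch. Default 5.
#' @param unsharp_radius Gaussian sigma (pixels) of the unsharp blur. Default 5.
#' @param unsharp_weight Mask weight in `[0, 1)`. Default 0.70.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(subtract_value = 100,
                              clahe_block = 29L,
                              clahe_bins = 256L,
                              clahe_max_slope = 5,
                              unsharp_radius = 5,
                              unsharp_weight = 0.70) {
  if (subtract_value < 0 || subtract_value > 255)
    stop("subtract_value must lie in [0, 255]")
  if (clahe_bins > 256 || clahe_bins < 2) stop("clahe_bins must lie in [2, 256]")
  if (clahe_max_slope < 1) stop("clahe_max_slope must be >= 1")
  if (clahe_block < 3) stop("clahe_block must be >= 3")
  if (unsharp_weight < 0 || unsharp_weight >= 1)
    stop("unsharp_weight must lie in [0, 1)")
  if (unsharp_radius <= 0) stop("unsharp_radius must be > 0")
  structure(list(subtract_value = subtract_value,
                 clahe_block = as.integer(clahe_block),
                 clahe_bins = as.integer(clahe_bins),
                 clahe_max_slope = clahe_max_slope,
                 unsharp_radius = unsharp_radius,
                 unsharp_weight = unsharp_weight),
            class = "preprocess_config")
}

#' Subtract a constant from every pixel
#'
#' Clamps at zero, so the 8-bit domain is preserved; applied to an RGB image
#' the constant is subtracted from each channel. Used to flatten a dark,
#' unevenly lit background before segmentation.
#'
#' @param img Grayscale matrix or RGB array, intensities in `[0, 255]`.
#' @param value Constant in `[0, 255]`.
#' @return Image of the same kind and dimensions.
#' @export
subtract_constant <- function(img, value = 100) {
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 255)
    stop("value must be a single number in [0, 255]")
  check_intensities(img)
  out <- pmax(img - value, 0)
  attributes(out) <- attributes(img)
  out
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Weighted luminance conversion with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to integers in `[0, 255]`.
#'
#' @param img `H x W x 3` array with intensities in `[0, 255]`.
#' @return `H x W` grayscale matrix. A grayscale matrix input is returned
#'   unchanged (already 8-bit).
#' @export
rgb_to_gray8 <- function(img) {
  if (is_gray(img)) {
    check_gray(img)
    return(round(img))
  }
  if (!is_rgb(img)) stop("expected an H x W x 3 RGB array")
  check_intensities(img, "RGB image")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  g <- round(clamp8(g))
  dim(g) <- dim(img)[1:2]
  g
}

# Iteratively clip a histogram at `limit` counts per bin, redistributing the
# excess uniformly. Converges to the fixed point where no bin exceeds the
# limit by more than a negligible amount; at limit = n/bins this is the
# uniform histogram, which makes the equalization mapping the identity.
clip_histogram <- function(h, limit) {
  h <- as.numeric(h)
  nb <- length(h)
  for (iter in 1:100) {
    excess <- sum(pmax(h - limit, 0))
    if (excess < 1e-9) break
    h <- pmin(h, limit) + excess / nb
  }
  h
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based histogram equalization with a slope limit. The image is divided
#' into a grid of roughly `block x block` tiles; each tile's histogram is
#' clipped at `max_slope * n / bins` counts (excess redistributed uniformly)
#' and turned into an equalization mapping, and every pixel is remapped by
#' bilinear interpolation between the four nearest tile mappings. With
#' `max_slope = 1` the clipped histograms are uniform and the mapping is the
#' identity: the image is returned unchanged.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param block Side length of the local region (pixels), >= 3 and no larger
#'   than the image.
#' @param bins Histogram bins (<= 256).
#' @param max_slope Contrast limit, >= 1.
#' @return Grayscale matrix of the same dimensions, integer intensities.
#' @export
clahe <- function(img, block = 29L, bins = 256L, max_slope = 5) {
  check_gray(img)
  H <- nrow(img); W <- ncol(img)
  if (block < 3) stop("block must be >= 3")
  if (block > min(H, W)) stop("block must not exceed the image dimensions")
  if (bins > 256 || bins < 2) stop("bins must lie in [2, 256]")
  if (max_slope < 1) stop("max_slope must be >= 1")

  m <- round(img)
  ny <- max(1L, as.integer(ceiling(H / block)))
  nx <- max(1L, as.integer(ceiling(W / block)))
  ye <- round(seq(0, H, length.out = ny + 1))
  xe <- round(seq(0, W, length.out = nx + 1))
  bins <- as.integer(bins)
  v <- pmin(pmax(floor(m * bins / 256), 0), bins - 1)  # bin index, 0-based
  out_levels <- (seq_len(bins) - 1) * 255 / (bins - 1)

  M <- array(0, c(bins, ny, nx))
  for (ty in seq_len(ny)) {
    for (tx in seq_len(nx)) {
      sub <- v[(ye[ty] + 1):ye[ty + 1], (xe[tx] + 1):xe[tx + 1]]
      n <- length(sub)
      h <- tabulate(as.vector(sub) + 1L, nbins = bins)
      h <- clip_histogram(h, max_slope * n / bins)
      cdf <- cumsum(h)
      first <- which(h > 1e-12)[1]
      cmin <- cdf[first]
      if (!is.finite(cmin) || n - cmin <= 1e-12) {
        M[, ty, tx] <- out_levels  # flat tile: identity ramp
      } else {
        M[, ty, tx] <- (cdf - cmin) / (n - cmin) * 255
      }
    }
  }

  ycent <- (ye[-1] + ye[-(ny + 1)]) / 2
  xcent <- (xe[-1] + xe[-(nx + 1)]) / 2
  py <- seq_len(H) - 0.5
  px <- seq_len(W) - 0.5

  interp_idx <- function(pos, centers) {
    nt <- length(centers)
    if (nt == 1L) return(list(i0 = rep(1L, length(pos)), i1 = rep(1L, length(pos)),
                              w = rep(0, length(pos))))
    i0 <- pmin(pmax(findInterval(pos, centers), 1L), nt - 1L)
    i1 <- i0 + 1L
    w <- (pos - centers[i0]) / (centers[i1] - centers[i0])
    list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
  }
  yi <- interp_idx(py, ycent)
  xi <- interp_idx(px, xcent)

  vi <- v + 1L
  IY0 <- matrix(yi$i0, H, W); IY1 <- matrix(yi$i1, H, W)
  WY  <- matrix(yi$w, H, W)
  IX0 <- matrix(xi$i0, H, W, byrow = TRUE); IX1 <- matrix(xi$i1, H, W, byrow = TRUE)
  WX  <- matrix(xi$w, H, W, byrow = TRUE)
  gather <- function(IY, IX) {
    matrix(M[cbind(as.vector(vi), as.vector(IY), as.vector(IX))], H, W)
  }
  out <- (1 - WY) * (1 - WX) * gather(IY0, IX0) +
         (1 - WY) * WX       * gather(IY0, IX1) +
         WY       * (1 - WX) * gather(IY1, IX0) +
         WY       * WX       * gather(IY1, IX1)
  round(clamp8(out))
}

# Normalized 1-D Gaussian kernel, truncated at ceiling(3.5 sigma).
gaussian_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Exact separable Gaussian convolution with edge replication; works for any
# image size, including images smaller than the kernel support.
gaussian_filter <- function(m, sigma) {
  k1 <- gaussian_taps(sigma)
  r <- (length(k1) - 1) / 2
  H <- nrow(m); W <- ncol(m)
  idx <- function(i, n) pmin(pmax(i, 1), n)
  v <- matrix(0, H, W)
  for (t in -r:r) v <- v + m[idx(seq_len(H) + t, H), , drop = FALSE] * k1[t + r + 1]
  out <- matrix(0, H, W)
  for (t in -r:r) out <- out + v[, idx(seq_len(W) + t, W), drop = FALSE] * k1[t + r + 1]
  out
}

#' Gaussian blur
#'
#' Convolution with a normalized, truncated Gaussian kernel
#' (support `ceiling(3.5 sigma)`), borders handled by edge replication so the
#' global mean is conserved within rounding.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param sigma Standard deviation of the Gaussian, in pixels.
#' @return Grayscale matrix of the same dimensions, integer intensities.
#' @export
gaussian_blur <- function(img, sigma) {
  check_gray(img)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  round(clamp8(gaussian_filter(img, sigma)))
}

#' Unsharp mask
#'
#' Subtracts a weighted Gaussian blur and rescales:
#' `(img - weight * gaussian(img, radius)) / (1 - weight)`, clamped to
#' `[0, 255]`. With `weight = 0` the image is returned unchanged; weights
#' approaching 1 blow up the rescaling and are rejected.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param radius Gaussian sigma of the blur, in pixels.
#' @param weight Mask weight in `[0, 1)`.
#' @return Grayscale matrix of the same dimensions, integer intensities.
#' @export
unsharp_mask <- function(img, radius = 5, weight = 0.70) {
  check_gray(img)
  if (!is.numeric(weight) || weight < 0 || weight >= 1)
    stop("weight must lie in [0, 1)")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (weight == 0) return(round(img))
  blur <- gaussian_filter(img, radius)
  round(clamp8((img - weight * blur) / (1 - weight)))
}
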