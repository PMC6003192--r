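#' Pixel-to-centimetre scale
#'
#' The scale is user-supplied (read off a ruler photographed at the same
#' camera height); all particle measurements are converted with it.
#'
#' @param pixels_per_cm Positive scalar.
#' @return A list of class `scale_calibration`.
#' @export
scale_calibration <- function(pixels_per_cm) {
  if (!is.numeric(pixels_per_cm) || length(pixels_per_cm) != 1 ||
      !is.finite(pixels_per_cm) || pixels_per_cm <= 0)
    stop("pixels_per_cm must be a single positive number")
  structure(list(pixels_per_cm = pixels_per_cm), class = "scale_calibration")
}

#' Particle size/shape filter
#'
#' @param min_area,max_area Area bounds in cm^2 (`max_area` may be `Inf`).
#' @param min_circ,max_circ Circularity bounds in `[0, 1]`.
#' @return A list of class `particle_filter`.
#' @export
particle_filter <- function(min_area = 0, max_area = Inf,
                            min_circ = 0, max_circ = 1) {
  if (min_area > max_area) stop("min_area must be <= max_area")
  if (min_circ > max_circ) stop("min_circ must be <= max_circ")
  structure(list(min_area = min_area, max_area = max_area,
                 min_circ = min_circ, max_circ = max_circ),
            class = "particle_filter")
}

#' Default kernel particle filter
#'
#' Retains objects of 0.03--1.0 cm^2 with circularity 0.15--1.00: a maize
#' kernel face is roughly 0.3--0.8 cm^2 and fairly round, so this window
#' excludes debris, silk strands and merged clumps.
#'
#' @return A [particle_filter()].
#' @export
kernel_particle_filter <- function() particle_filter(0.03, 1.0, 0.15, 1.0)

#' Default ear particle filter
#'
#' Retains objects larger than 10 cm^2; an ear silhouette is far larger,
#' stray kernels and debris far smaller.
#'
#' @return A [particle_filter()].
#' @export
ear_particle_filter <- function() particle_filter(10, Inf, 0, 1)

# Corner-corrected chain-code perimeter (Vossepoel-Smeulders weights):
# straight steps count 0.980, diagonal steps 1.406, and each direction
# change subtracts 0.091. The correction removes the systematic
# overestimation of the raw sqrt(2)-weighted chain on smooth boundaries,
# so a finely rasterized disc measures circularity ~1.
chain_perimeter <- function(pts) {
  k <- nrow(pts)
  if (k < 3) return(NA_real_)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  st <- nxt - pts
  adx <- abs(st[, 1]); ady <- abs(st[, 2])
  keep <- adx + ady > 0  # drop duplicated contour points
  st <- st[keep, , drop = FALSE]
  if (nrow(st) < 3) return(NA_real_)
  adx <- abs(st[, 1]); ady <- abs(st[, 2])
  n_straight <- sum(adx + ady == 1)
  n_diag <- sum(adx == 1 & ady == 1)
  dir <- atan2(st[, 2], st[, 1])
  n_corner <- sum(dir != c(dir[-1], dir[1]))
  0.980 * n_straight + 1.406 * n_diag - 0.091 * n_corner
}

# Maximum Feret diameter and minimum caliper width from the convex hull of
# the pixel-corner point set (each boundary pixel contributes its 4 unit
# square corners, so a w x l pixel rectangle measures exactly w and
# sqrt(w^2 + l^2)).
feret_calipers <- function(boundary_px) {
  pts <- rbind(
    boundary_px + matrix(c(-0.5, -0.5), nrow(boundary_px), 2, byrow = TRUE),
    boundary_px + matrix(c(-0.5,  0.5), nrow(boundary_px), 2, byrow = TRUE),
    boundary_px + matrix(c( 0.5, -0.5), nrow(boundary_px), 2, byrow = TRUE),
    boundary_px + matrix(c( 0.5,  0.5), nrow(boundary_px), 2, byrow = TRUE)
  )
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  h <- nrow(hull)
  if (h == 1) return(c(major = 0, minor = 0))
  dmat <- as.matrix(stats::dist(hull))
  major <- max(dmat)
  # rotating calipers over hull edge normals
  nxt <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
  ed <- nxt - hull
  len <- sqrt(rowSums(ed^2))
  ok <- len > 0
  ed <- ed[ok, , drop = FALSE]; len <- len[ok]
  if (nrow(ed) == 0) return(c(major = major, minor = 0))
  widths <- vapply(seq_len(nrow(ed)), function(i) {
    nrm <- c(-ed[i, 2], ed[i, 1]) / len[i]
    pr <- hull %*% nrm
    max(pr) - min(pr)
  }, numeric(1))
  c(major = major, minor = min(widths))
}

#' Measure labeled particles
#'
#' Computes per-object geometry in physical units: area (pixel count /
#' `pixels_per_cm`^2), perimeter (corner-corrected boundary chain), length
#' and width (maximum Feret diameter and minimum caliper width over the
#' boundary pixel corners), moment-based ellipse axes, circularity
#' `4 * pi * area / perimeter^2` capped at 1, and the pixel centroid.
#' Objects too small to carry a boundary chain (under ~3 boundary pixels)
#' are assigned circularity 1 and the perimeter of the equal-area circle.
#'
#' @param labels Integer label matrix (0 = background, labels `1..n`).
#' @param scale A [scale_calibration()].
#' @return A `data.frame` with one row per label: `label`, `area_cm2`,
#'   `perimeter_cm`, `major_cm`, `minor_cm`, `ellipse_major_cm`,
#'   `ellipse_minor_cm`, `circularity`, `centroid_x`, `centroid_y` (pixel
#'   coordinates, x = column, y = row).
#' @export
measure_particles <- function(labels, scale = scale_calibration(1)) {
  stopifnot(is.matrix(labels))
  if (!inherits(scale, "scale_calibration"))
    stop("scale must be a scale_calibration object")
  ppc <- scale$pixels_per_cm
  n <- max(labels)
  empty <- data.frame(label = integer(), area_cm2 = numeric(),
                      perimeter_cm = numeric(), major_cm = numeric(),
                      minor_cm = numeric(), ellipse_major_cm = numeric(),
                      ellipse_minor_cm = numeric(), circularity = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  if (n < 1) return(empty)

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  areas_px <- tabulate(lab, nbins = n)
  cx <- rowsum(as.numeric(idx[, "col"]), lab) / areas_px
  cy <- rowsum(as.numeric(idx[, "row"]), lab) / areas_px

  # second central moments for ellipse-equivalent axes
  dx <- idx[, "col"] - cx[lab]
  dy <- idx[, "row"] - cy[lab]
  sxx <- rowsum(dx * dx, lab) / areas_px
  syy <- rowsum(dy * dy, lab) / areas_px
  sxy <- rowsum(dx * dy, lab) / areas_px

  contours <- EBImage::ocontour(ebi(labels))
  cl <- as.integer(names(contours))

  out <- empty[rep(1, n), ]
  for (i in seq_len(n)) {
    apx <- areas_px[i]
    ci <- which(cl == i)
    pts <- if (length(ci)) contours[[ci]] else
      cbind(idx[lab == i, "col"] - 1L, idx[lab == i, "row"] - 1L)
    per_px <- chain_perimeter(pts)
    circ <- if (is.na(per_px)) {
      per_px <- 2 * sqrt(pi * apx)
      1
    } else {
      min(4 * pi * apx / per_px^2, 1)
    }
    fc <- feret_calipers(pts)
    tr <- sxx[i] + syy[i]
    dt <- sqrt(max((sxx[i] - syy[i])^2 + 4 * sxy[i]^2, 0))
    l1 <- max((tr + dt) / 2, 0); l2 <- max((tr - dt) / 2, 0)
    out[i, ] <- list(i, apx / ppc^2, per_px / ppc,
                     max(fc["major"], fc["minor"]) / ppc,
                     min(fc["major"], fc["minor"]) / ppc,
                     4 * sqrt(l1) / ppc, 4 * sqrt(l2) / ppc,
                     circ, cx[i], cy[i])
  }
  rownames(out) <- NULL
  out
}

#' Filter particles by size and circularity
#'
#' Retains rows whose area and circularity fall inside the filter bounds
#' (inclusive); row order is preserved and the operation is idempotent.
#'
#' @param parts A particle `data.frame` from [measure_particles()].
#' @param f A [particle_filter()].
#' @return The retained subset of `parts`.
#' @export
filter_particles <- function(parts, f = kernel_particle_filter()) {
  if (!inherits(f, "particle_filter")) stop("f must be a particle_filter")
  if (nrow(parts) == 0) return(parts)
  keep <- parts$area_cm2 >= f$min_area & parts$area_cm2 <= f$max_area &
    parts$circularity >= f$min_circ & parts$circularity <= f$max_circ
  parts[keep, , drop = FALSE]
}

#' Write a per-particle CSV
#'
#' @param parts A particle `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particles_csv <- function(parts, path) {
  write.csv(parts, path, row.names = FALSE)
  invisible(path)
}
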