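#' Synthetic plot-image specification
#'
#' Describes a rendered stand-in for a nadir photograph of de-husked maize
#' ears on dark cloth: ellipse-shaped ears carrying a lattice of bright
#' convex kernels separated by darker grooves, over a dark noisy background
#' with an optional illumination gradient and optional saturated reflection
#' patches. Every stochastic choice is fixed by `seed`, so the same spec
#' renders bitwise-identical images.
#'
#' @param n_ears Number of ears on the plot image.
#' @param ear_length_cm,ear_width_cm Ranges (min, max) the per-ear ellipse
#'   axes are drawn from, in cm.
#' @param kernel_rows Range of visible kernel rows across the ear width
#'   (integer min, max).
#' @param kernels_per_row_visible Optional fixed count of kernels along the
#'   ear axis; `NULL` (default) fills the ear given the kernel length.
#' @param kernel_length_cm Range the per-ear kernel length (along the ear
#'   axis) is drawn from, in cm.
#' @param kernel_brightness Intensity of the flat kernel face (8-bit); the
#'   boundary rolls off to 75% of it.
#' @param kernel_falloff Relative width of the radial roll-off at the kernel
#'   boundary, in `(0, 1]`; small values give crisp dent-kernel edges,
#'   large values fuzzy flint-like ones.
#' @param groove_darkness Intensity of the grooves/cob surface between
#'   kernels; kept below the pixel-subtraction offset so grooves vanish in
#'   the kernel branch.
#' @param background_level Mean background intensity.
#' @param background_gradient Left-to-right additive illumination ramp
#'   amplitude.
#' @param reflection_probability Per-kernel probability of a saturated
#'   specular patch.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param pixels_per_cm Rendering scale.
#' @param seed Integer seed fixing all stochastic choices.
#' @return A list of class `synthetic_ear_spec`.
#' @export
synthetic_ear_spec <- function(n_ears = 5,
                               ear_length_cm = c(12, 18),
                               ear_width_cm = c(3.8, 5.2),
                               kernel_rows = c(6L, 8L),
                               kernels_per_row_visible = NULL,
                               kernel_length_cm = c(0.8, 1.1),
                               kernel_brightness = 230,
                               kernel_falloff = 0.25,
                               groove_darkness = 70,
                               background_level = 30,
                               background_gradient = 25,
                               reflection_probability = 0,
                               noise_sd = 4,
                               pixels_per_cm = 20,
                               seed = 1L) {
  stopifnot(n_ears >= 1, all(ear_length_cm > 0), all(ear_width_cm > 0),
            all(kernel_rows >= 1), all(kernel_length_cm > 0),
            pixels_per_cm > 0, noise_sd >= 0,
            reflection_probability >= 0, reflection_probability <= 1)
  structure(as.list(environment()), class = "synthetic_ear_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Paint one kernel: a convex ellipse with a flat bright face and a radial
# roll-off of relative width `roll` at the boundary (dent kernels have flat
# faces and narrow groove transitions), optionally rotated, composited with
# max() so overlaps stay bright.
paint_kernel <- function(img, cy, cx, a_row, b_col, center, edge, theta = 0,
                         roll = 0.25) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(max(a_row, b_col)) + 1L
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(img)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  if (theta != 0) {
    dyr <- dy * cos(theta) + dx * sin(theta)
    dxr <- -dy * sin(theta) + dx * cos(theta)
  } else {
    dyr <- dy; dxr <- dx
  }
  r2 <- (dyr / a_row)^2 + (dxr / b_col)^2
  f <- pmin(pmax(1 - r2, 0) / (roll * (2 - roll)), 1)
  val <- edge + (center - edge) * f
  patch <- img[ys, xs]
  inside <- r2 <= 1
  patch[inside] <- pmax(patch[inside], val[inside])
  img[ys, xs] <- patch
  img
}

finish_image <- function(intensity, spec) {
  H <- nrow(intensity); W <- ncol(intensity)
  if (spec$noise_sd > 0)
    intensity <- intensity + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  intensity <- clamp8(intensity)
  gains <- c(1, 0.92, 0.70)  # warm, near-achromatic tint
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- round(clamp8(intensity * gains[ch]))
  img
}

background_field <- function(H, W, spec) {
  ramp <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  matrix(spec$background_level, H, W) + spec$background_gradient * ramp
}

#' Render a synthetic plot image with exact ground truth
#'
#' Ears are laid out vertically on a non-overlapping grid (side by side, not
#' in contact, as plot photos are arranged); each carries a kernel lattice
#' clipped to its ellipse. Ground truth (per-ear dimensions, visible kernel
#' counts and kernel lengths) is exact by construction.
#'
#' @param spec A [synthetic_ear_spec()].
#' @return A list with `image` (RGB array) and `truth` (class
#'   `ground_truth`: `$ears` data frame, `$kernel_lengths` list, `$plot`
#'   aggregates).
#' @export
render_plot_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ear_spec"))
  withr::with_seed(spec$seed, render_plot_image_impl(spec))
}

render_plot_image_impl <- function(spec) {
  ppc <- spec$pixels_per_cm
  gap_cm <- 1.2
  per_row <- min(spec$n_ears, 8L)
  n_rows <- ceiling(spec$n_ears / per_row)
  cell_w <- (max(spec$ear_width_cm) + gap_cm) * ppc
  cell_h <- (max(spec$ear_length_cm) + gap_cm) * ppc
  W <- as.integer(ceiling(per_row * cell_w + gap_cm * ppc))
  H <- as.integer(ceiling(n_rows * cell_h + gap_cm * ppc))

  intensity <- background_field(H, W, spec)
  ears <- data.frame(ear = seq_len(spec$n_ears), length_cm = NA_real_,
                     width_cm = NA_real_, visible_kernels = NA_integer_,
                     mean_kernel_length_cm = NA_real_)
  kernel_lengths <- vector("list", spec$n_ears)

  for (e in seq_len(spec$n_ears)) {
    row_i <- (e - 1) %/% per_row
    col_i <- (e - 1) %% per_row
    L <- runif1(spec$ear_length_cm)
    Wd <- runif1(spec$ear_width_cm)
    nr <- if (spec$kernel_rows[1] == spec$kernel_rows[2]) spec$kernel_rows[1] else
      sample(spec$kernel_rows[1]:spec$kernel_rows[2], 1)
    kl <- runif1(spec$kernel_length_cm)

    cx <- (col_i + 0.5) * cell_w + gap_cm * ppc / 2 + stats::runif(1, -0.2, 0.2) * ppc
    cy <- (row_i + 0.5) * cell_h + gap_cm * ppc / 2 + stats::runif(1, -0.2, 0.2) * ppc
    a_ear <- L / 2 * ppc   # vertical semi-axis (ear length)
    b_ear <- Wd / 2 * ppc  # horizontal semi-axis (ear width)

    # base ellipse: groove/cob surface
    ys <- max(1L, floor(cy - a_ear)):min(H, ceiling(cy + a_ear))
    xs <- max(1L, floor(cx - b_ear)):min(W, ceiling(cx + b_ear))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    inside <- (dy / a_ear)^2 + (dx / b_ear)^2 <= 1
    patch <- intensity[ys, xs]
    patch[inside] <- spec$groove_darkness
    intensity[ys, xs] <- patch

    # kernel lattice: nr rows across the width, filled along the length
    kw <- Wd / nr
    a_k <- kl / 2 * 0.90 * ppc   # kernel semi-axis along the ear (vertical)
    b_k <- kw / 2 * 0.86 * ppc   # kernel semi-axis across the ear
    kpr <- if (!is.null(spec$kernels_per_row_visible)) spec$kernels_per_row_visible
           else max(1L, floor(L * 0.98 / kl))
    y_off <- (seq_len(kpr) - (kpr + 1) / 2) * kl * ppc
    x_off <- (seq_len(nr) - (nr + 1) / 2) * kw * ppc
    center <- spec$kernel_brightness
    edge <- spec$kernel_brightness * 0.75
    roll <- spec$kernel_falloff

    count <- 0L
    lens <- numeric(0)
    add_kernel <- function(yo, xo, a_use, b_use) {
      intensity <<- paint_kernel(intensity, cy + yo, cx + xo, a_use, b_use,
                                 center, edge, roll = roll)
      if (spec$reflection_probability > 0 &&
          stats::runif(1) < spec$reflection_probability) {
        intensity <<- paint_kernel(intensity,
                                   cy + yo + stats::runif(1, -0.3, 0.3) * a_use,
                                   cx + xo + stats::runif(1, -0.3, 0.3) * b_use,
                                   a_use * 0.45, b_use * 0.45, 255, 255,
                                   roll = 1)
      }
      count <<- count + 1L
      lens <<- c(lens, 2 * a_use / ppc)
    }
    for (xo in x_off) {
      horiz <- ((abs(xo) + b_k) / b_ear)^2
      if (horiz >= 1) next
      for (yo in y_off) {
        # largest along-axis semi-axis that keeps the kernel inside the ear;
        # tip kernels shrink, as on a real dent ear
        a_max <- a_ear * sqrt(1 - horiz) - abs(yo)
        if (a_max < 0.45 * a_k) next
        a_use <- min(a_k, a_max)
        add_kernel(yo, xo, a_use, b_k)
      }
    }
    # tip cap kernels on the ear axis, so the kernel-covered body reaches
    # the full nominal ear length (rows converge at the tip of a real ear)
    a_cap <- a_k * 0.8
    for (s in c(-1, 1)) add_kernel(s * (a_ear - 1.02 * a_cap), 0, a_cap,
                                   b_k * 0.8)
    ears[e, c("length_cm", "width_cm")] <- c(L, Wd)
    ears$visible_kernels[e] <- count
    kernel_lengths[[e]] <- lens
    ears$mean_kernel_length_cm[e] <- if (count > 0) mean(lens) else NA_real_
  }

  truth <- structure(list(
    ears = ears,
    kernel_lengths = kernel_lengths,
    plot = list(
      n_ears = spec$n_ears,
      total_visible_kernels = sum(ears$visible_kernels),
      mean_kernel_length_cm = mean(unlist(kernel_lengths)),
      pixels_per_cm = spec$pixels_per_cm
    )), class = "ground_truth")
  list(image = finish_image(intensity, spec), truth = truth)
}

#' Render scattered loose kernels with a known count
#'
#' Emulates photographs of threshed kernels spread on dark cloth: `n`
#' convex kernel patches at random orientations, a stated fraction placed
#' touching an earlier kernel (clusters), the rest isolated.
#'
#' @param n Number of kernels (>= 1).
#' @param clustering Fraction in `[0, 1]` of kernels placed in contact with
#'   a previously placed kernel.
#' @param seed Integer seed.
#' @param pixels_per_cm Rendering scale.
#' @param kernel_length_cm Kernel length range, cm.
#' @param background_level,noise_sd,kernel_brightness,kernel_falloff As in
#'   [synthetic_ear_spec()].
#' @return A list with `image` (RGB array) and `count` (= `n`).
#' @export
render_loose_kernels <- function(n, clustering = 0, seed = 1L,
                                 pixels_per_cm = 20,
                                 kernel_length_cm = c(0.8, 1.1),
                                 background_level = 30, noise_sd = 4,
                                 kernel_brightness = 230,
                                 kernel_falloff = 0.35) {
  stopifnot(n >= 1, clustering >= 0, clustering <= 1)
  spec <- list(background_level = background_level, background_gradient = 0,
               noise_sd = noise_sd)
  withr::with_seed(seed, {
    ppc <- pixels_per_cm
    side_cm <- max(4, ceiling(sqrt(n) * 1.9) + 2)
    H <- W <- as.integer(side_cm * ppc)
    intensity <- background_field(H, W, spec)
    centers <- matrix(numeric(0), 0, 2)
    rad_px <- numeric(0)
    center <- kernel_brightness
    edge <- kernel_brightness * 0.75
    margin <- ppc  # keep kernels off the border
    for (i in seq_len(n)) {
      kl <- runif1(kernel_length_cm)
      a <- kl / 2 * ppc
      b <- a * 0.55
      rmax <- a
      placed <- FALSE
      if (i > 1 && stats::runif(1) < clustering) {
        for (try in 1:50) {
          j <- sample(nrow(centers), 1)
          ang <- stats::runif(1, 0, 2 * pi)
          d <- (rad_px[j] + rmax) * 0.75  # overlapping: forms a cluster
          cy <- centers[j, 1] + d * sin(ang)
          cx <- centers[j, 2] + d * cos(ang)
          if (cy > margin && cy < H - margin && cx > margin && cx < W - margin) {
            placed <- TRUE; break
          }
        }
      }
      if (!placed) {
        for (try in 1:400) {
          cy <- stats::runif(1, margin, H - margin)
          cx <- stats::runif(1, margin, W - margin)
          if (nrow(centers) == 0) { placed <- TRUE; break }
          dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          if (min(dd) > (max(rad_px) + rmax) * 1.35) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place kernels at the requested density")
      }
      theta <- stats::runif(1, 0, pi)
      intensity <- paint_kernel(intensity, cy, cx, a, b, center, edge, theta,
                                roll = kernel_falloff)
      centers <- rbind(centers, c(cy, cx))
      rad_px <- c(rad_px, rmax)
    }
    list(image = finish_image(intensity, spec), count = n)
  })
}

#' Simulate a genotype-by-replicate trial table
#'
#' Draws `value(g, r) = mu + B_r + G_g + e_gr` with genotype effects
#' `G ~ N(0, sigma_g2)`, residuals `e ~ N(0, sigma_e2)` and optional fixed
#' replicate (block) shifts. With several traits the genotype effects are
#' drawn jointly with the requested genetic correlation.
#'
#' @param n_geno Number of genotypes.
#' @param nreps Number of replicates.
#' @param sigma_g2,sigma_e2 Genotypic and residual variances (>= 0).
#' @param traits Character vector of trait names (default one trait).
#' @param genetic_corr True genetic correlation between every trait pair
#'   when `length(traits) > 1`.
#' @param mu Grand mean.
#' @param rep_sd Standard deviation of the fixed replicate shifts
#'   (default 0).
#' @param seed Integer seed.
#' @return A tidy trial table (`genotype`, `rep`, `trait`, `value`).
#' @export
simulate_trial_table <- function(n_geno = 200, nreps = 3,
                                 sigma_g2 = 2, sigma_e2 = 1,
                                 traits = "trait", genetic_corr = 0,
                                 mu = 10, rep_sd = 0, seed = 1L) {
  stopifnot(n_geno >= 2, nreps >= 1, sigma_g2 >= 0, sigma_e2 >= 0)
  nt <- length(traits)
  withr::with_seed(seed, {
    if (nt == 1) {
      G <- matrix(rnorm(n_geno, 0, sqrt(sigma_g2)), n_geno, 1)
    } else {
      R <- matrix(genetic_corr, nt, nt); diag(R) <- 1
      Z <- matrix(rnorm(n_geno * nt), n_geno, nt)
      G <- Z %*% chol(R) * sqrt(sigma_g2)
    }
    B <- rnorm(nreps, 0, rep_sd)
    rows <- vector("list", nt)
    for (ti in seq_len(nt)) {
      E <- matrix(rnorm(n_geno * nreps, 0, sqrt(sigma_e2)), n_geno, nreps)
      vals <- mu + outer(G[, ti], rep(1, nreps)) +
        outer(rep(1, n_geno), B) + E
      rows[[ti]] <- data.frame(
        genotype = rep(sprintf("g%03d", seq_len(n_geno)), nreps),
        rep = rep(sprintf("r%d", seq_len(nreps)), each = n_geno),
        trait = traits[ti],
        value = as.vector(vals))
    }
    do.call(rbind, rows)
  })
}

#' Write a fixture suite to a directory
#'
#' Renders a set of synthetic plot images with their ground truth and one
#' simulated trial table: `plot_###.png`, `plot_###_truth.json` and
#' `trial_table.csv` under `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param specs A list of [synthetic_ear_spec()] objects.
#' @param trial_args Arguments passed to [simulate_trial_table()].
#' @return Invisibly, the vector of files written.
#' @export
write_fixture_suite <- function(dir, specs, trial_args = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(specs)) {
    rendered <- render_plot_image(specs[[i]])
    img_path <- file.path(dir, sprintf("plot_%03d.png", i))
    truth_path <- file.path(dir, sprintf("plot_%03d_truth.json", i))
    write_plot_image(rendered$image, img_path)
    jsonlite::write_json(list(ears = rendered$truth$ears,
                              plot = rendered$truth$plot),
                         truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, img_path, truth_path)
  }
  tt <- do.call(simulate_trial_table, trial_args)
  tt_path <- file.path(dir, "trial_table.csv")
  write_trial_table(tt, tt_path)
  invisible(c(files, tt_path))
}
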