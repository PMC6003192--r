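#' Pipeline configuration
#'
#' Bundles every parameter of the two-branch plot pipeline. The kernel
#' branch enhances contrast, thresholds locally and splits touching kernels
#' with a tight watershed tolerance; the ear branch blurs the kernels away,
#' thresholds globally and splits touching ears with a loose tolerance.
#'
#' @param scale A [scale_calibration()] (pixels per cm); required, since a
#'   ruler shot interpreted by the user is the only source of scale.
#' @param preprocess A [preprocess_config()].
#' @param phansalkar A [phansalkar_params()].
#' @param kernel_tolerance Watershed tolerance (px) for kernels (default 3).
#' @param ear_sigma Gaussian sigma (px) that removes kernel texture in the
#'   ear branch (default 10).
#' @param ear_tolerance Watershed tolerance (px) for ears (default 40).
#' @param kernel_filter,ear_filter [particle_filter()]s applied after
#'   measurement.
#' @param count_model,weight_model [linear_calibration()]s turning the
#'   visible kernel count and mean kernel length into total kernel number
#'   and weight.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scale,
                            preprocess = preprocess_config(),
                            phansalkar = phansalkar_params(),
                            kernel_tolerance = 3,
                            ear_sigma = 10,
                            ear_tolerance = 40,
                            kernel_filter = kernel_particle_filter(),
                            ear_filter = ear_particle_filter(),
                            count_model = kernel_count_model(),
                            weight_model = kernel_weight_model()) {
  if (missing(scale)) stop("scale (pixels per cm) is required")
  if (is.numeric(scale)) scale <- scale_calibration(scale)
  stopifnot(inherits(scale, "scale_calibration"),
            inherits(preprocess, "preprocess_config"),
            inherits(phansalkar, "phansalkar_params"),
            kernel_tolerance >= 0, ear_tolerance >= 0, ear_sigma > 0)
  structure(list(scale = scale, preprocess = preprocess,
                 phansalkar = phansalkar,
                 kernel_tolerance = kernel_tolerance,
                 ear_sigma = ear_sigma, ear_tolerance = ear_tolerance,
                 kernel_filter = kernel_filter, ear_filter = ear_filter,
                 count_model = count_model, weight_model = weight_model),
            class = "pipeline_config")
}

#' Kernel branch: segment and measure visible kernels
#'
#' Runs subtraction on the color image, grayscale conversion, CLAHE,
#' unsharp masking, the Phansalkar local threshold, hole filling, watershed
#' splitting at the kernel tolerance, particle measurement and the kernel
#' size/shape filter.
#'
#' @param img RGB array or grayscale matrix (8-bit intensities).
#' @param cfg A [pipeline_config()].
#' @param keep_labels Return the label map alongside the measurements.
#' @return A list: `kn` (retained kernel count), `stats` (mean length,
#'   width, area, perimeter; total kernel area; all `NA` when `kn` is 0),
#'   `particles` (retained rows of [measure_particles()]), and optionally
#'   `labels`.
#' @export
extract_kernel_attributes <- function(img, cfg, keep_labels = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  pp <- cfg$preprocess
  g <- rgb_to_gray8(subtract_constant(img, pp$subtract_value))
  g <- clahe(g, pp$clahe_block, pp$clahe_bins, pp$clahe_max_slope)
  g <- unsharp_mask(g, pp$unsharp_radius, pp$unsharp_weight)
  mask <- fill_holes(phansalkar_threshold(g, cfg$phansalkar))
  labels <- adjustable_watershed(mask, cfg$kernel_tolerance)
  parts <- measure_particles(labels, cfg$scale)
  kept <- filter_particles(parts, cfg$kernel_filter)
  kn <- nrow(kept)
  stats <- if (kn == 0) {
    warning("no kernel particles retained")
    list(mean_length_cm = NA_real_, mean_width_cm = NA_real_,
         mean_area_cm2 = NA_real_, mean_perimeter_cm = NA_real_,
         total_area_cm2 = 0)
  } else {
    list(mean_length_cm = mean(kept$major_cm),
         mean_width_cm = mean(kept$minor_cm),
         mean_area_cm2 = mean(kept$area_cm2),
         mean_perimeter_cm = mean(kept$perimeter_cm),
         total_area_cm2 = sum(kept$area_cm2))
  }
  out <- list(kn = kn, stats = stats, particles = kept)
  if (keep_labels) out$labels <- labels
  out
}

#' Ear branch: segment and measure whole ears
#'
#' Runs subtraction, grayscale conversion, a strong Gaussian blur that
#' erases kernel texture, Otsu binarization, hole filling, watershed
#' splitting at the ear tolerance, measurement and the minimum-area ear
#' filter.
#'
#' @inheritParams extract_kernel_attributes
#' @return A list: `ear_count`, `ears` (retained rows of
#'   [measure_particles()]; lengths are Feret diameters), and optionally
#'   `labels`.
#' @export
extract_ear_attributes <- function(img, cfg, keep_labels = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  g <- rgb_to_gray8(subtract_constant(img, cfg$preprocess$subtract_value))
  b <- gaussian_blur(g, cfg$ear_sigma)
  mask <- fill_holes(binarize_otsu(b))
  labels <- adjustable_watershed(mask, cfg$ear_tolerance)
  parts <- measure_particles(labels, cfg$scale)
  kept <- filter_particles(parts, cfg$ear_filter)
  out <- list(ear_count = nrow(kept), ears = kept)
  if (keep_labels) out$labels <- labels
  out
}

#' Run the full pipeline on one plot image
#'
#' Combines the kernel and ear branches and applies the calibrations: the
#' total kernel number from the visible count, and the total kernel weight
#' from count and mean kernel length.
#'
#' @param img RGB array or grayscale matrix.
#' @param cfg A [pipeline_config()].
#' @param plot_id Identifier written into the output row.
#' @return A one-row `data.frame` (plot phenotype record): ear count and
#'   mean ear dimensions, visible and estimated total kernel number, kernel
#'   size summaries, total kernel area and estimated total kernel weight.
#' @export
run_plot <- function(img, cfg, plot_id = "plot") {
  ke <- extract_kernel_attributes(img, cfg)
  ea <- extract_ear_attributes(img, cfg)
  kn <- ke$kn
  tkn <- total_kernel_number(kn, cfg$count_model)
  tkw <- if (kn > 0 && is.finite(ke$stats$mean_length_cm) &&
             ke$stats$mean_length_cm > 0) {
    total_kernel_weight(kn, ke$stats$mean_length_cm,
                        cfg$count_model, cfg$weight_model)
  } else 0
  data.frame(
    plot = plot_id,
    ear_count = ea$ear_count,
    mean_ear_length_cm = if (ea$ear_count) mean(ea$ears$major_cm) else NA_real_,
    mean_ear_width_cm = if (ea$ear_count) mean(ea$ears$minor_cm) else NA_real_,
    visible_kernel_number = kn,
    total_kernel_number = tkn,
    mean_kernel_length_cm = ke$stats$mean_length_cm,
    mean_kernel_width_cm = ke$stats$mean_width_cm,
    mean_kernel_area_cm2 = ke$stats$mean_area_cm2,
    mean_kernel_perimeter_cm = ke$stats$mean_perimeter_cm,
    total_kernel_area_cm2 = ke$stats$total_area_cm2,
    estimated_total_kernel_weight_g = tkw,
    status = "ok",
    stringsAsFactors = FALSE)
}

#' Batch-process a directory of plot images
#'
#' One image is one plot; the plot id is the file name without extension.
#' Failures are caught, logged as a flagged row and the batch continues, so
#' the output always has one row per input image. Rows are ordered by plot
#' id, independent of processing order.
#'
#' @param input A directory containing PNG/JPEG/TIFF images, or a character
#'   vector of image paths.
#' @param cfg A [pipeline_config()].
#' @param output Optional CSV path for the phenotype table.
#' @param save_masks Optional directory to write kernel label maps as
#'   16-bit PNGs.
#' @return The phenotype `data.frame`, invisibly if `output` is given.
#' @export
run_batch <- function(input, cfg, output = NULL, save_masks = NULL) {
  paths <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|jpe?g|tiff?)$", ignore.case = TRUE,
               full.names = TRUE)
  } else input
  if (length(paths) == 0) stop("no input images found")
  if (!is.null(save_masks))
    dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    tryCatch({
      img <- read_plot_image(p)
      row <- run_plot(img, cfg, plot_id = id)
      if (!is.null(save_masks)) {
        ke <- extract_kernel_attributes(img, cfg, keep_labels = TRUE)
        write_mask_png(ke$labels, file.path(save_masks, paste0(id, "_kernels.png")))
      }
      row
    }, error = function(e) {
      message("plot ", id, " failed: ", conditionMessage(e))
      row <- run_plot_failure_row(id, conditionMessage(e))
      row
    })
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$plot), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(output)) {
    write.csv(res, output, row.names = FALSE)
    return(invisible(res))
  }
  res
}

run_plot_failure_row <- function(id, msg) {
  data.frame(plot = id, ear_count = NA_integer_,
             mean_ear_length_cm = NA_real_, mean_ear_width_cm = NA_real_,
             visible_kernel_number = NA_integer_,
             total_kernel_number = NA_real_,
             mean_kernel_length_cm = NA_real_,
             mean_kernel_width_cm = NA_real_,
             mean_kernel_area_cm2 = NA_real_,
             mean_kernel_perimeter_cm = NA_real_,
             total_kernel_area_cm2 = NA_real_,
             estimated_total_kernel_weight_g = NA_real_,
             status = paste0("error: ", msg),
             stringsAsFactors = FALSE)
}
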