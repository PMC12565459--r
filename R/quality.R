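#' Shannon entropy of an image (bits)
#'
#' Intensities are binned into 256 equal-width levels over the working range
#' (default \[0, 255\]) and the Shannon entropy of the histogram is returned;
#' the value lies in \[0, 8\] bits.
#'
#' @param image Numeric array or matrix.
#' @param range Working intensity range (default `c(0, 255)`).
#' @return Entropy in bits.
#' @export
image_entropy <- function(image, range = c(0, 255)) {
  x <- as.numeric(image)
  if (length(x) == 0L) eg_abort("empty image", "invalid_input")
  bin <- pmin(pmax(floor((x - range[1]) / diff(range) * 256), 0), 255)
  p <- tabulate(bin + 1L, nbins = 256L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Population standard deviation of image intensities
#' @param image Numeric array or matrix.
#' @return Standard deviation in intensity units.
#' @export
image_std <- function(image) {
  x <- as.numeric(image)
  if (length(x) == 0L) eg_abort("empty image", "invalid_input")
  sqrt(mean((x - mean(x))^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(peak^2 / MSE)` with an 8-bit-like working peak of 255.
#' Identical images have infinite PSNR, reported as `Inf`.
#'
#' @param reference,test Arrays of equal shape.
#' @param peak Peak intensity (default 255).
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
image_psnr <- function(reference, test, peak = 255) {
  if (!all(dim(reference) == dim(test))) eg_abort("shape mismatch", "shape_error")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over a 3x3 uniform (8-neighborhood) window with the
#' standard constants `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`. Volumes
#' are evaluated slice-wise and averaged. Equals 1 iff the images are
#' identical.
#'
#' @param reference,test Matrices or 3D arrays of equal shape.
#' @param peak Dynamic range (default 255).
#' @return SSIM value in \[-1, 1\].
#' @export
image_ssim <- function(reference, test, peak = 255) {
  if (!all(dim(reference) == dim(test))) eg_abort("shape mismatch", "shape_error")
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2
  ssim_2d <- function(x, y) {
    mx <- conv3x3_replicate(x) / 9; my <- conv3x3_replicate(y) / 9
    vx <- conv3x3_replicate(x^2) / 9 - mx^2
    vy <- conv3x3_replicate(y^2) / 9 - my^2
    cxy <- conv3x3_replicate(x * y) / 9 - mx * my
    mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
           ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (length(dim(reference)) == 3L) {
    mean(vapply(seq_len(dim(reference)[3]), function(z)
      ssim_2d(reference[, , z], test[, , z]), numeric(1)))
  } else {
    ssim_2d(as.matrix(reference), as.matrix(test))
  }
}

#' Quality report for a fused image against its two sources
#'
#' Computes entropy and STD of the fused image, and PSNR/SSIM against each of
#' the two source weights (the reference direction is recorded, since the
#' choice of reference is not canonical in fusion evaluation).
#'
#' @param fused Fused volume or slice (working range \[0, 255\]).
#' @param sources Named list of the two source images (rescaled to the same
#'   working range).
#' @param fused_type Label for the fused image type (e.g. `"T1Gd+FLAIR"`).
#' @return A tibble in long format: `fused_type`, `metric`, `reference`,
#'   `value`.
#' @export
fusion_quality <- function(fused, sources, fused_type = "fused") {
  stopifnot(is.list(sources), length(sources) == 2L)
  src <- lapply(sources, rescale_0_255)
  rows <- list(
    tibble::tibble(fused_type = fused_type, metric = "entropy",
                   reference = NA_character_, value = image_entropy(fused)),
    tibble::tibble(fused_type = fused_type, metric = "std",
                   reference = NA_character_, value = image_std(fused)))
  for (nm in names(src)) {
    rows <- c(rows, list(
      tibble::tibble(fused_type = fused_type, metric = "psnr", reference = nm,
                     value = image_psnr(src[[nm]], fused)),
      tibble::tibble(fused_type = fused_type, metric = "ssim", reference = nm,
                     value = image_ssim(src[[nm]], fused))))
  }
  dplyr::bind_rows(rows)
}

#' Min-max normalize quality metrics across fused types
#'
#' Per metric (and reference direction), values are min-max normalized across
#' fused image types to \[0, 1\] for heatmap display; a metric constant across
#' all types is mapped to 0 with a warning.
#'
#' @param reports Long-format tibble from [fusion_quality()] rows (>= 2 fused
#'   types).
#' @return The input tibble with a `normalized` column.
#' @export
normalize_metrics <- function(reports) {
  if (dplyr::n_distinct(reports$fused_type) < 2L)
    eg_abort("need at least two fused types to normalize", "invalid_parameter")
  out <- reports |>
    dplyr::group_by(.data$metric, .data$reference) |>
    dplyr::mutate(normalized = {
      v <- .data$value
      if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else {
        warning("metric '", .data$metric[1], "' constant across fused types; normalized to 0")
        rep(0, length(v))
      }
    }) |>
    dplyr::ungroup()
  out
}

#' Heatmap of normalized fused-image quality metrics
#'
#' @param object Tibble from [normalize_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot quality_metrics
autoplot.quality_metrics <- function(object, ...) {
  plot_quality_heatmap(object)
}

#' @rdname autoplot.quality_metrics
#' @param reports Normalized long-format quality tibble.
#' @export
plot_quality_heatmap <- function(reports) {
  df <- dplyr::mutate(reports, label = ifelse(is.na(.data$reference),
                                              .data$metric,
                                              paste0(.data$metric, " vs ", .data$reference)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fused_type, y = .data$label,
                                   fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "fused image type", y = NULL, fill = "normalized") +
    ggplot2::theme_minimal()
}
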