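#' ROI specification
#'
#' @param label Mask label defining the region of interest (default 2, the
#'   peritumoral edema label under BraTS conventions).
#' @param min_voxels Minimum ROI size (default 8).
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(label = 2L, min_voxels = 8L) {
  if (!label %in% c(1L, 2L, 4L))
    eg_abort("label must be one of 1, 2, 4", "invalid_parameter")
  structure(list(label = as.integer(label), min_voxels = as.integer(min_voxels)),
            class = "roi_spec")
}

#' Extract a region of interest from a volume
#'
#' Crops the volume and mask to the bounding box of the requested label and
#' collects the ROI voxel intensities.
#'
#' @param volume 3D numeric array.
#' @param mask Integer 3D array on the same grid.
#' @param spec A [roi_spec()].
#' @param spacing Voxel spacing (mm), length 3.
#' @return A list of class `roi`: `values`, `volume_bb`, `mask_bb` (logical),
#'   `bbox` (2x3 matrix), `spacing`, `n_voxels`.
#' @export
extract_roi <- function(volume, mask, spec = roi_spec(), spacing = c(1, 1, 1)) {
  if (!all(dim(volume) == dim(mask)))
    eg_abort("volume and mask are not on the same grid", "shape_error")
  sel <- mask == spec$label
  n <- sum(sel)
  if (n == 0L) eg_abort(paste0("label ", spec$label, " absent from mask"), "empty_roi")
  if (n < spec$min_voxels)
    eg_abort(paste0("ROI has ", n, " voxels; need >= ", spec$min_voxels), "empty_roi")
  idx <- which(sel, arr.ind = TRUE)
  bbox <- rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
  sl <- lapply(1:3, function(d) bbox["lo", d]:bbox["hi", d])
  volume_bb <- volume[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  mask_bb <- sel[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
  structure(list(values = volume_bb[mask_bb], volume_bb = volume_bb,
                 mask_bb = mask_bb, bbox = bbox, spacing = as.numeric(spacing),
                 n_voxels = n), class = "roi")
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray level `floor((v - min) / bin_width) + 1`, anchored at the ROI minimum
#' so that adding a constant to the volume leaves all discretized-texture
#' features unchanged.
#'
#' @param roi An `roi` object (or any list with `values` and `mask_bb`).
#' @param bin_width Positive bin width in intensity units (default 25).
#' @return A list of class `discretized_roi`: `levels` (integer array over the
#'   bounding box, `NA` outside the ROI), `values` (per-voxel levels),
#'   `ng` (number of levels), `n_voxels`, `spacing`.
#' @export
discretize_roi <- function(roi, bin_width = 25) {
  if (bin_width <= 0) eg_abort("bin_width must be positive", "invalid_parameter")
  lv <- floor((roi$values - min(roi$values)) / bin_width) + 1L
  arr <- array(NA_integer_, dim(roi$mask_bb))
  arr[roi$mask_bb] <- as.integer(lv)
  structure(list(levels = arr, values = as.integer(lv), ng = max(lv),
                 n_voxels = length(lv), spacing = roi$spacing),
            class = "discretized_roi")
}

# trilinear resampling of a volume to a new spacing (optional preprocessing;
# masks are never resampled by the pipeline)
resample_volume <- function(volume, spacing, new_spacing) {
  dims <- dim(volume)
  new_dims <- pmax(2L, as.integer(round(dims * spacing / new_spacing)))
  gr <- lapply(1:3, function(d) {
    if (new_dims[d] == 1L) return(1)
    seq(1, dims[d], length.out = new_dims[d])
  })
  out <- array(0, new_dims)
  x0 <- pmin(pmax(floor(gr[[1]]), 1L), dims[1] - 1L); tx <- gr[[1]] - x0
  y0 <- pmin(pmax(floor(gr[[2]]), 1L), dims[2] - 1L); ty <- gr[[2]] - y0
  z0 <- pmin(pmax(floor(gr[[3]]), 1L), dims[3] - 1L); tz <- gr[[3]] - z0
  TY <- matrix(ty, nrow = new_dims[1], ncol = new_dims[2], byrow = TRUE)
  for (k in seq_len(new_dims[3])) {
    sl <- volume[, , z0[k]] * (1 - tz[k]) + volume[, , z0[k] + 1L] * tz[k]
    slx <- sl[x0, , drop = FALSE] * (1 - tx) + sl[x0 + 1L, , drop = FALSE] * tx
    out[, , k] <- slx[, y0, drop = FALSE] * (1 - TY) + slx[, y0 + 1L, drop = FALSE] * TY
  }
  out
}
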