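#' Extraction configuration
#'
#' @param bin_width Discretization bin width (default 25 intensity units).
#' @param roi A [roi_spec()] (default: edema, label 2).
#' @param wavelet Extract the eight wavelet sub-band blocks (default TRUE).
#' @param resample_spacing Optional target spacing (mm) for trilinear volume
#'   resampling before extraction; `NULL` (default) disables resampling.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 25, roi = roi_spec(), wavelet = TRUE,
                              resample_spacing = NULL) {
  structure(list(bin_width = bin_width, roi = roi, wavelet = wavelet,
                 resample_spacing = resample_spacing),
            class = "extraction_config")
}

.image_feature_block <- function(volume_bb, mask_bb, spacing, bin_width, prefix) {
  roi <- list(values = volume_bb[mask_bb], volume_bb = volume_bb,
              mask_bb = mask_bb, spacing = spacing)
  d <- discretize_roi(roi, bin_width)
  v <- c(firstorder_features(roi$values, spacing, bin_width),
         glcm_features(d), gldm_features(d), glrlm_features(d),
         glszm_features(d), ngtdm_features(d))
  names(v) <- paste0(prefix, "_", names(v))
  v
}

#' Names of the eight wavelet sub-bands
#' @return Character vector `c("LLL", ..., "HHH")`.
#' @export
wavelet_band_names <- function()
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' The full 851-feature registry
#'
#' Stable ordering of the feature bank: 14 shape features (mask only), 93
#' original-image features (18 first-order + 24 GLCM + 14 GLDM + 16 GLRLM +
#' 16 GLSZM + 5 NGTDM), and the same 93 for each of the 8 wavelet sub-bands
#' (744 in total). Shipped as `inst/extdata/feature_registry.csv`.
#'
#' @return A tibble with columns `name`, `image_type`, `family`, `feature`.
#' @export
feature_registry <- function() {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
            "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
            "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
            "SumAverage", "SumEntropy", "SumSquares")
  gldm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
            "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized", "ZonePercentage",
             "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
             "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  shape <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "MajorAxisLength", "MinorAxisLength",
             "LeastAxisLength", "Elongation", "Flatness", "Maximum3DDiameter",
             "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
             "Maximum2DDiameterRow")
  fam <- function(family, feats) tibble::tibble(family = family, feature = feats)
  img_block <- dplyr::bind_rows(fam("firstorder", fo), fam("glcm", glcm),
                                fam("gldm", gldm), fam("glrlm", glrlm),
                                fam("glszm", glszm), fam("ngtdm", ngtdm))
  blocks <- list(tibble::tibble(image_type = "shape", family = "shape",
                                feature = shape))
  for (it in c("original", paste0("wavelet.", wavelet_band_names())))
    blocks[[length(blocks) + 1L]] <- dplyr::mutate(img_block, image_type = it,
                                                   .before = 1)
  reg <- dplyr::bind_rows(blocks)
  reg$name <- ifelse(reg$image_type == "shape",
                     paste0("shape_", reg$feature),
                     paste0(reg$image_type, "_", reg$family, "_", reg$feature))
  reg[, c("name", "image_type", "family", "feature")]
}

#' Extract the full 851-feature radiomic vector
#'
#' Shape features from the mask, 93 intensity/texture features from the
#' original image, and 93 from each of the eight stationary-wavelet sub-bands
#' of the ROI bounding box. All values are checked finite.
#'
#' @param volume 3D numeric array.
#' @param mask Integer label mask on the same grid.
#' @param spacing Voxel spacing (mm), length 3.
#' @param config An [extraction_config()].
#' @return Named numeric vector of 851 features, ordered as in
#'   [feature_registry()].
#' @export
extract_features <- function(volume, mask, spacing = c(1, 1, 1),
                             config = extraction_config()) {
  if (!is.null(config$resample_spacing)) {
    volume <- resample_volume(volume, spacing, config$resample_spacing)
    # masks are never resampled: extraction then requires matching grids
    if (!all(dim(volume) == dim(mask)))
      eg_abort("resampled volume no longer matches the mask grid", "shape_error")
    spacing <- config$resample_spacing
  }
  roi <- extract_roi(volume, mask, config$roi, spacing)
  out <- c(shape_features(roi$mask_bb, spacing),
           .image_feature_block(roi$volume_bb, roi$mask_bb, spacing,
                                config$bin_width, "original"))
  if (isTRUE(config$wavelet)) {
    bands <- wavelet_subbands(roi$volume_bb)
    for (bn in names(bands))
      out <- c(out, .image_feature_block(bands[[bn]], roi$mask_bb, spacing,
                                         config$bin_width,
                                         paste0("wavelet.", bn)))
  }
  bad <- !is.finite(out)
  if (any(bad))
    eg_abort(paste0("non-finite feature(s): ",
                    paste(head(names(out)[bad], 5), collapse = ", ")),
             "nonfinite_feature")
  out
}

#' Extract a cohort-level feature table
#'
#' One row per subject: `subject_id`, `grade`, `image_type`, then the 851
#' feature columns. `image_type` is either one of the four original weights or
#' an `A+B` fused pair, in which case the pair is fused with
#' [lrd_fuse_volume()] first.
#'
#' @param cohort A `phantom_cohort` (or list of `subject_record`s).
#' @param image_type Modality name (e.g. `"FLAIR"`) or pair (e.g.
#'   `"T1Gd+FLAIR"`).
#' @param config An [extraction_config()].
#' @param fusion_cfg A [fusion_config()] used when `image_type` is a pair.
#' @return A tibble of features.
#' @export
extract_cohort_features <- function(cohort, image_type = "FLAIR",
                                    config = extraction_config(),
                                    fusion_cfg = fusion_config()) {
  subjects <- if (inherits(cohort, "phantom_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(rec) {
    vol <- if (grepl("+", image_type, fixed = TRUE))
      fuse_subject_pair(rec, image_type, fusion_cfg)
    else rec$modalities[[image_type]]
    if (is.null(vol)) eg_abort(paste0("unknown image type ", image_type),
                               "invalid_parameter")
    fv <- extract_features(vol, rec$mask, rec$spacing, config)
    tibble::tibble(subject_id = rec$subject_id, grade = rec$grade,
                   image_type = image_type, !!!as.list(fv))
  })
  dplyr::bind_rows(rows)
}
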