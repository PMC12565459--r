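#' Texture descriptor for the planted edema texture
#'
#' Describes the stationary Gaussian random field planted inside the edema
#' shell of a phantom subject: white noise smoothed with a Gaussian kernel of
#' standard deviation `corr_len` voxels (which therefore sets the spatial
#' correlation length), rescaled to standard deviation `sd` and shifted to
#' `mean` intensity units.
#'
#' @param corr_len Correlation length in voxels (Gaussian kernel sigma, >= 0).
#' @param mean Mean intensity of the texture field (arbitrary MRI-like units).
#' @param sd Standard deviation of the texture field.
#' @return A list of class `texture_descriptor`.
#' @export
texture_descriptor <- function(corr_len = 1, mean = 140, sd = 10) {
  stopifnot(corr_len >= 0, sd >= 0)
  structure(list(corr_len = corr_len, mean = mean, sd = sd),
            class = "texture_descriptor")
}

#' Phantom cohort parameters
#'
#' Parameters of the synthetic BraTS-like cohort: four co-registered MRI
#' weights per subject (T1, T1Gd, T2, FLAIR), a nested three-label tumor mask
#' (1 = necrotic core, 2 = peritumoral edema, 4 = enhancing tumor), a binary
#' LGG/HGG grade, and a grade-dependent Gaussian-random-field texture planted
#' in the edema shell. Defaults emulate the study cohort: an imbalanced
#' 81% HGG / 19% LGG population on 1 mm isotropic grids, with the HGG edema
#' texture coarser (longer correlation length), brighter and more variable
#' than the LGG one so that texture features carry a strong grade signal.
#'
#' @param volume_shape Integer triple, each >= 16.
#' @param spacing_mm Positive numeric triple, voxel spacing in mm.
#' @param n_subjects Number of subjects in a cohort.
#' @param hgg_fraction Fraction of HGG subjects, in (0, 1).
#' @param edema_texture_lgg,edema_texture_hgg [texture_descriptor()] objects.
#' @param noise_sd Additive white-noise standard deviation (intensity units).
#' @param seed Master seed for the cohort.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(volume_shape = c(48L, 48L, 48L),
                           spacing_mm = c(1, 1, 1),
                           n_subjects = 100L,
                           hgg_fraction = 0.81,
                           edema_texture_lgg = texture_descriptor(1.0, 140, 10),
                           edema_texture_hgg = texture_descriptor(3.0, 165, 22),
                           noise_sd = 2,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L))
    eg_abort("volume_shape must be three integers, each >= 16", "invalid_parameter")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    eg_abort("spacing_mm must be three positive numbers", "invalid_parameter")
  if (hgg_fraction <= 0 || hgg_fraction >= 1)
    eg_abort("hgg_fraction must lie strictly in (0, 1)", "invalid_parameter")
  if (noise_sd < 0) eg_abort("noise_sd must be nonnegative", "invalid_parameter")
  stopifnot(inherits(edema_texture_lgg, "texture_descriptor"),
            inherits(edema_texture_hgg, "texture_descriptor"))
  structure(list(volume_shape = volume_shape, spacing_mm = as.numeric(spacing_mm),
                 n_subjects = as.integer(n_subjects), hgg_fraction = hgg_fraction,
                 edema_texture_lgg = edema_texture_lgg,
                 edema_texture_hgg = edema_texture_hgg,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

# Periodic Gaussian smoothing of a 3D array via FFT; sigma in voxels.
gaussian_smooth_3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  dims <- dim(x)
  k1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(fft(k1(dims[1])), fft(k1(dims[2]))), fft(k1(dims[3])))
  dim(K) <- dims
  Re(fft(fft(x) * K, inverse = TRUE)) / prod(dims)
}

# Fixed per-modality intensity model: brain base value, shell contrasts, and
# the weight/offset with which the planted edema texture enters the modality.
# Edema is brightest in the FLAIR-like channel, enhancing shell in T1Gd.
.modality_model <- list(
  T1    = list(brain = 120, core = 40,  enh = 90,  edema_w = 0.35, edema_off = 10),
  T1Gd  = list(brain = 115, core = 30,  enh = 220, edema_w = 0.35, edema_off = 10),
  T2    = list(brain = 90,  core = 140, enh = 110, edema_w = 0.80, edema_off = 50),
  FLAIR = list(brain = 100, core = 80,  enh = 120, edema_w = 1.00, edema_off = 60)
)

#' Names of the four MRI weights
#' @return Character vector `c("T1", "T1Gd", "T2", "FLAIR")`.
#' @export
modality_names <- function() names(.modality_model)

#' Generate a single phantom subject
#'
#' Builds a skull-stripped head ellipsoid (background exactly 0) containing a
#' nested tumor: an ellipsoidal necrotic core (label 1) inside an enhancing
#' shell (label 4) inside an edema shell (label 2). Edema-voxel intensities are
#' drawn from the grade's texture descriptor (a smoothed Gaussian random
#' field); the four modalities differ by fixed affine intensity remaps and
#' shell contrasts. Additive Gaussian noise of sd `params$noise_sd` is applied
#' inside the head.
#'
#' @param params A [phantom_params()] object.
#' @param grade `"LGG"` or `"HGG"`.
#' @param seed Integer seed for this subject (defaults to `params$seed`).
#' @param subject_id Subject identifier string.
#' @return A list of class `subject_record` with elements `subject_id`,
#'   `modalities` (named list of 3D arrays), `mask` (integer 3D array),
#'   `grade` and `spacing`.
#' @export
generate_subject <- function(params, grade = c("HGG", "LGG"), seed = params$seed,
                             subject_id = "sub-001") {
  stopifnot(inherits(params, "phantom_params"))
  grade <- match.arg(grade)
  dims <- params$volume_shape
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  ctr <- (dims + 1) / 2
  m <- min(dims)
  # tumor centre jittered within +/- 6% of the grid
  tctr <- ctr + runif(3, -0.06, 0.06) * dims
  ax <- c(1, 0.92, 0.84) * runif(3, 0.95, 1.05)   # ellipsoid axis ratios

  idx <- arrayInd(seq_len(prod(dims)), dims)
  r_head <- sqrt(((idx[, 1] - ctr[1]) / (0.46 * dims[1]))^2 +
                 ((idx[, 2] - ctr[2]) / (0.46 * dims[2]))^2 +
                 ((idx[, 3] - ctr[3]) / (0.46 * dims[3]))^2)
  r_tum <- sqrt(((idx[, 1] - tctr[1]) / ax[1])^2 +
                ((idx[, 2] - tctr[2]) / ax[2])^2 +
                ((idx[, 3] - tctr[3]) / ax[3])^2)
  head_in <- r_head <= 1
  r_core <- 0.10 * m; r_enh <- 0.17 * m; r_edema <- 0.28 * m

  mask <- integer(prod(dims))
  mask[head_in & r_tum <= r_edema] <- 2L
  mask[head_in & r_tum <= r_enh] <- 4L
  mask[head_in & r_tum <= r_core] <- 1L
  dim(mask) <- dims

  tex <- if (grade == "HGG") params$edema_texture_hgg else params$edema_texture_lgg
  z <- array(rnorm(prod(dims)), dims)
  z <- gaussian_smooth_3d(z, tex$corr_len)
  z <- (z - mean(z)) / sd(z)
  tfield <- tex$mean + tex$sd * z

  grad <- 1 - 0.15 * pmin(r_head, 1)^2  # mild radial shading inside the head
  modalities <- lapply(.modality_model, function(mm) {
    v <- numeric(prod(dims))
    v[head_in] <- mm$brain * grad[head_in]
    v[mask == 2L] <- mm$edema_off + mm$edema_w * tfield[mask == 2L]
    v[mask == 4L] <- mm$enh
    v[mask == 1L] <- mm$core
    if (params$noise_sd > 0)
      v[head_in] <- v[head_in] + rnorm(sum(head_in), 0, params$noise_sd)
    v <- pmax(v, 0)
    v[!head_in] <- 0
    dim(v) <- dims
    v
  })

  structure(list(subject_id = subject_id, modalities = modalities,
                 mask = mask, grade = grade, spacing = params$spacing_mm),
            class = "subject_record")
}

#' Generate a graded phantom cohort
#'
#' Generates `params$n_subjects` subjects with
#' `round(hgg_fraction * n_subjects)` HGG cases, grade order shuffled
#' reproducibly from the master seed, each subject drawn from its own derived
#' seed. The manifest is a tibble with one row per subject.
#'
#' @param params A [phantom_params()] object with `n_subjects >= 10`.
#' @return A list of class `phantom_cohort` with elements `subjects` (list of
#'   `subject_record`) and `manifest` (tibble: subject_id, grade, seed, path).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$n_subjects
  if (n < 10L) eg_abort("n_subjects must be >= 10", "invalid_parameter")
  n_hgg <- round(params$hgg_fraction * n)
  if (n_hgg < 1L || n_hgg > n - 1L)
    eg_abort("hgg_fraction yields an empty class", "invalid_parameter")
  grades <- c(rep("HGG", n_hgg), rep("LGG", n - n_hgg))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)
  grades <- sample(grades)
  seeds <- (as.numeric(params$seed) * 1009 + 7919 * seq_len(n)) %% 2147483647
  ids <- sprintf("sub-%03d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n))
    subjects[[i]] <- generate_subject(params, grades[i], seed = seeds[i],
                                      subject_id = ids[i])
  names(subjects) <- ids
  manifest <- tibble::tibble(subject_id = ids, grade = grades,
                             seed = as.integer(seeds), path = NA_character_,
                             excluded = FALSE)
  structure(list(subjects = subjects, manifest = manifest, params = params),
            class = "phantom_cohort")
}

#' Write a subject's volumes and mask as NIfTI
#'
#' @param record A `subject_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths (four modalities
#'   plus `mask`).
#' @export
write_subject <- function(record, dir) {
  stopifnot(inherits(record, "subject_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (mn in names(record$modalities)) {
    p <- file.path(dir, paste0(record$subject_id, "_", mn, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(record$modalities[[mn]],
                                       pixdim = record$spacing), p)
    paths[mn] <- p
  }
  p <- file.path(dir, paste0(record$subject_id, "_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(record$mask, pixdim = record$spacing,
                                     datatype = "int16"), p)
  paths["mask"] <- p
  invisible(paths)
}

#' Write a cohort to disk with its manifest
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory.
#' @return The manifest tibble (with `path` filled in), invisibly; also written
#'   as `manifest.csv` in `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    sdir <- file.path(dir, man$subject_id[i])
    write_subject(cohort$subjects[[i]], sdir)
    man$path[i] <- sdir
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a subject back from NIfTI files
#'
#' @param dir Directory written by [write_subject()].
#' @param subject_id Subject identifier.
#' @param grade Grade label to attach (from a manifest), or `NA`.
#' @return A `subject_record`.
#' @export
read_subject <- function(dir, subject_id, grade = NA_character_) {
  modalities <- lapply(setNames(modality_names(), modality_names()), function(mn) {
    img <- RNifti::readNifti(file.path(dir, paste0(subject_id, "_", mn, ".nii.gz")))
    array(as.numeric(img), dim(img))
  })
  mski <- RNifti::readNifti(file.path(dir, paste0(subject_id, "_mask.nii.gz")))
  spacing <- as.numeric(RNifti::pixdim(mski))[1:3]
  mask <- array(as.integer(mski), dim(mski))
  structure(list(subject_id = subject_id, modalities = modalities, mask = mask,
                 grade = grade, spacing = spacing),
            class = "subject_record")
}
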