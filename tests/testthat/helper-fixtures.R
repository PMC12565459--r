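# small fixtures shared across test files; everything is generated in code

small_params <- function(...) {
  phantom_params(volume_shape = c(24L, 24L, 24L), n_subjects = 12L,
                 hgg_fraction = 0.5, ...)
}

# one cached small subject per grade (generation is cheap but not free)
.fixture_env <- new.env(parent = emptyenv())
small_subject <- function(grade = "HGG", seed = 7L) {
  key <- paste0(grade, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_subject(small_params(), grade, seed = seed)
  .fixture_env[[key]]
}

digital_ball <- function(r, dims = rep(2L * r + 7L, 3L)) {
  ctr <- (dims + 1) / 2
  idx <- arrayInd(seq_len(prod(dims)), dims)
  array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= r, dims)
}

# tiny discretized ROI from an explicit level array (NA = outside ROI)
levels_roi <- function(arr) {
  structure(list(levels = arr, values = as.integer(arr[!is.na(arr)]),
                 ng = max(arr, na.rm = TRUE),
                 n_voxels = sum(!is.na(arr)), spacing = c(1, 1, 1)),
            class = "discretized_roi")
}
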