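# Coiflet-1 analysis filters (6 taps)
.coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
               0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
.coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
               0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# circular (periodic) convolution along one margin of a 3D array
.circ_filter_axis <- function(x, h, axis) {
  n <- dim(x)[axis]
  out <- array(0, dim(x))
  for (k in seq_along(h)) {
    src <- ((seq_len(n) - (k - 1) - 1) %% n) + 1  # x[(i - (k-1)) mod n]
    out <- out + h[k] * switch(axis,
                               x[src, , , drop = FALSE],
                               x[, src, , drop = FALSE],
                               x[, , src, drop = FALSE])
  }
  out
}

#' One-level undecimated 3D wavelet decomposition (Coiflet-1)
#'
#' Stationary (undecimated) separable wavelet transform: the low- and
#' high-pass Coiflet-1 analysis filters are applied along each of the three
#' axes with periodic boundary handling, yielding the eight `{L,H}^3`
#' sub-bands, each the same shape as the input so the ROI mask applies
#' unchanged. Letter i of a band name refers to array dimension i.
#'
#' @param volume 3D numeric array (typically the ROI bounding box).
#' @return Named list of 8 arrays: `LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`,
#'   `HHL`, `HHH`.
#' @export
wavelet_subbands <- function(volume) {
  if (length(dim(volume)) != 3L) eg_abort("volume must be 3D", "shape_error")
  if (any(dim(volume) < 6L))
    warning("bounding box smaller than the wavelet filter; periodic wrapping applied")
  bands <- list()
  for (b1 in c("L", "H")) {
    f1 <- .circ_filter_axis(volume, if (b1 == "L") .coif1_lo else .coif1_hi, 1L)
    for (b2 in c("L", "H")) {
      f2 <- .circ_filter_axis(f1, if (b2 == "L") .coif1_lo else .coif1_hi, 2L)
      for (b3 in c("L", "H")) {
        f3 <- .circ_filter_axis(f2, if (b3 == "L") .coif1_lo else .coif1_hi, 3L)
        bands[[paste0(b1, b2, b3)]] <- f3
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
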