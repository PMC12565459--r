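#' Fusion configuration for Laplacian re-decomposition (LRD)
#'
#' @param tau Pyramid depth (default 3).
#' @param omega1 Strong-edge enhancement gain (default 1.5).
#' @param omega2 Weak-detail enhancement gain (default 0.3).
#' @param lem_window 3x3 all-ones local-energy filtering template.
#' @param pair Optional ordered weight-name pair `c(A, B)`; A wins ties.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(tau = 3L, omega1 = 1.5, omega2 = 0.3,
                          lem_window = matrix(1, 3, 3), pair = NULL) {
  if (tau < 1L) eg_abort("tau must be >= 1", "invalid_parameter")
  if (omega1 <= 0 || omega2 <= 0)
    eg_abort("omega1 and omega2 must be positive", "invalid_parameter")
  if (!is.matrix(lem_window) || any(dim(lem_window) != c(3L, 3L)) ||
      any(lem_window != 1))
    eg_abort("lem_window must be a 3x3 all-ones matrix", "invalid_parameter")
  structure(list(tau = as.integer(tau), omega1 = omega1, omega2 = omega2,
                 lem_window = lem_window, pair = pair),
            class = "fusion_config")
}

# shift a matrix by (di, dj) with edge replication
shift_replicate <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + di, 1L), n)
  ci <- pmin(pmax(seq_len(p) + dj, 1L), p)
  m[ri, ci, drop = FALSE]
}

# 3x3 windowed weighted sum with edge replication
conv3x3_replicate <- function(m, w = matrix(1, 3, 3)) {
  out <- matrix(0, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1)
    out <- out + w[di + 2L, dj + 2L] * shift_replicate(m, di, dj)
  out
}

#' Maximum local difference (MLD) map
#'
#' Edge-strength map over a 3x3 neighborhood: for each of the four directions
#' through the center (horizontal, vertical, two diagonals) the 3-pixel
#' directional sum is compared against three times the center value; the MLD
#' is the maximum absolute difference. Borders use edge replication; a
#' constant offset leaves the map unchanged.
#'
#' @param image A finite-valued 2D matrix.
#' @return A nonnegative matrix of the same shape.
#' @export
max_local_difference <- function(image) {
  if (!is.matrix(image)) eg_abort("image must be a 2D matrix", "shape_error")
  if (!all(is.finite(image))) eg_abort("image must be finite", "invalid_input")
  c3 <- 3 * image
  s_h <- shift_replicate(image, 0L, -1L) + image + shift_replicate(image, 0L, 1L)
  s_v <- shift_replicate(image, -1L, 0L) + image + shift_replicate(image, 1L, 0L)
  s_d <- shift_replicate(image, -1L, -1L) + image + shift_replicate(image, 1L, 1L)
  s_a <- shift_replicate(image, -1L, 1L) + image + shift_replicate(image, 1L, -1L)
  pmax(abs(c3 - s_h), abs(c3 - s_v), abs(c3 - s_d), abs(c3 - s_a))
}

#' Gradient-domain image enhancement (GDIE)
#'
#' Lifts high-frequency detail with a spatially adaptive gain: the detail
#' layer is the residual of a 3x3 mean filter, and the per-pixel gain C(i,j)
#' interpolates between `omega2` (weak detail) and `omega1` (strong edges)
#' over the tertile interval division of the nonzero MLD range.
#'
#' @param image A finite-valued 2D matrix.
#' @param cfg A [fusion_config()].
#' @return The enhanced image `H = image + C * detail`, same shape.
#' @export
gdie_enhance <- function(image, cfg = fusion_config()) {
  if (!is.matrix(image)) eg_abort("image must be a 2D matrix", "shape_error")
  mld <- max_local_difference(image)
  detail <- image - conv3x3_replicate(image) / 9
  nz <- mld[mld > 0]
  if (length(nz) == 0L) return(image)  # constant image: nothing to lift
  t1 <- unname(quantile(nz, 1 / 3)); t2 <- unname(quantile(nz, 2 / 3))
  if (t2 > t1) {
    frac <- pmin(pmax((mld - t1) / (t2 - t1), 0), 1)
  } else {
    frac <- as.numeric(mld >= t1)
  }
  C <- cfg$omega2 + (cfg$omega1 - cfg$omega2) * frac
  image + C * detail
}

reduce1d_rows <- function(m) {
  w <- c(1, 4, 6, 4, 1) / 16
  n <- nrow(m); n_out <- ceiling(n / 2)
  out <- matrix(0, n_out, ncol(m))
  ctr <- 2 * seq_len(n_out) - 1
  for (k in -2:2) {
    ri <- pmin(pmax(ctr + k, 1L), n)
    out <- out + w[k + 3L] * m[ri, , drop = FALSE]
  }
  out
}

expand1d_rows <- function(m, n_out) {
  # coarse sample j sits at fine position 2j-1; normalized 5-tap interpolation
  w <- c(1, 4, 6, 4, 1)
  n <- nrow(m)
  out <- matrix(0, n_out, ncol(m)); wt <- numeric(n_out)
  for (k in -2:2) {
    j <- (seq_len(n_out) - k + 1)
    ok <- (j %% 2 == 0) & j >= 2 & j <= 2 * n  # j/2 is a valid coarse index
    src <- j[ok] %/% 2
    out[ok, ] <- out[ok, , drop = FALSE] + w[k + 3L] * m[src, , drop = FALSE]
    wt[ok] <- wt[ok] + w[k + 3L]
  }
  out / wt
}

lp_reduce <- function(img) t(reduce1d_rows(t(reduce1d_rows(img))))
lp_expand <- function(img, shape) t(expand1d_rows(t(expand1d_rows(img, shape[1])), shape[2]))

#' Laplacian pyramid decomposition
#'
#' Burt–Adelson pyramid with the standard 5-tap \[1,4,6,4,1\]/16 kernel:
#' Gaussian REDUCE by a factor 2 per level (ceil halving), high band
#' `L_k = G_k - EXPAND(G_{k+1})`.
#'
#' @param image A 2D matrix with min dimension >= `2^tau`.
#' @param tau Number of high-frequency levels.
#' @return A list of class `pyramid_levels`: `highs` (list of length `tau`),
#'   `low` (residual), `shapes`.
#' @export
lp_decompose <- function(image, tau = 3L) {
  if (!is.matrix(image)) eg_abort("image must be a 2D matrix", "shape_error")
  if (min(dim(image)) < 2^tau)
    eg_abort("image too small for requested pyramid depth", "invalid_parameter")
  g <- image; highs <- vector("list", tau); shapes <- vector("list", tau + 1L)
  for (k in seq_len(tau)) {
    shapes[[k]] <- dim(g)
    g_next <- lp_reduce(g)
    highs[[k]] <- g - lp_expand(g_next, dim(g))
    g <- g_next
  }
  shapes[[tau + 1L]] <- dim(g)
  structure(list(highs = highs, low = g, shapes = shapes), class = "pyramid_levels")
}

#' Laplacian pyramid reconstruction
#'
#' Exact inverse of [lp_decompose()]: iteratively EXPAND the running low band
#' and add the high bands from coarse to fine.
#'
#' @param pyr A `pyramid_levels` object.
#' @return The reconstructed 2D matrix.
#' @export
lp_reconstruct <- function(pyr) {
  g <- pyr$low
  for (k in rev(seq_along(pyr$highs))) {
    if (!all(dim(pyr$highs[[k]]) == pyr$shapes[[k]]))
      eg_abort("inconsistent pyramid level shapes", "shape_error")
    g <- lp_expand(g, pyr$shapes[[k]]) + pyr$highs[[k]]
  }
  g
}

#' Decision-graph re-decomposition (DGR) of two high-frequency bands
#'
#' Splits each band into an overlapping domain (OD: redundant information,
#' where both bands are significant — magnitude at or above the band's median
#' magnitude — or carry numerically identical nonzero coefficients) and a
#' non-overlapping domain (NOD: complementary information). The split is
#' additive: `od + nod` reproduces each band exactly.
#'
#' @param l_a,l_b High-frequency sub-band matrices of equal shape.
#' @return A list of class `domain_maps`: `od_a`, `od_b`, `nod_a`, `nod_b`,
#'   `overlap` (binary matrix).
#' @export
dgr_decompose <- function(l_a, l_b) {
  if (!all(dim(l_a) == dim(l_b))) eg_abort("band shape mismatch", "shape_error")
  sig <- function(x) abs(x) > 0 & abs(x) >= median(abs(x))
  same <- abs(l_a - l_b) <= 1e-9 * pmax(abs(l_a), abs(l_b)) & abs(l_a) > 0 & abs(l_b) > 0
  overlap <- (sig(l_a) & sig(l_b)) | same
  ov <- overlap * 1
  structure(list(od_a = l_a * ov, od_b = l_b * ov,
                 nod_a = l_a * (1 - ov), nod_b = l_b * (1 - ov),
                 overlap = ov), class = "domain_maps")
}

#' Low-band fusion by local energy maximum (LEM)
#'
#' Per-pixel local energy is the 3x3 windowed sum of absolute values under the
#' all-ones template; each fused pixel takes the source with larger local
#' energy, ties going to source A.
#'
#' @param g_a,g_b Low-pass residual bands of equal shape.
#' @param lem_window 3x3 all-ones template.
#' @return Fused low band.
#' @export
fuse_low_lem <- function(g_a, g_b, lem_window = matrix(1, 3, 3)) {
  if (!is.matrix(lem_window) || any(dim(lem_window) != c(3, 3)))
    eg_abort("lem_window must be 3x3", "invalid_parameter")
  if (!all(dim(g_a) == dim(g_b))) eg_abort("band shape mismatch", "shape_error")
  e_a <- conv3x3_replicate(abs(g_a), lem_window)
  e_b <- conv3x3_replicate(abs(g_b), lem_window)
  ifelse(e_a >= e_b, g_a, g_b)
}

#' Overlapping-domain fusion rule
#'
#' Local decision maximums `LDM_X = MLD_X * LEM_X` are compared pixelwise to
#' form the binary decision graph `D = [LDM_A >= LDM_B]`; the fused OD band is
#' `D * O_A + (1 - D) * O_B`.
#'
#' @param dom A `domain_maps` object.
#' @param mld_a,mld_b Nonnegative MLD maps (typically of the GDIE-enhanced
#'   bands), same shape as the domains.
#' @return List with `fused` (matrix) and `decision` (binary matrix `D`).
#' @export
fuse_overlap <- function(dom, mld_a, mld_b) {
  if (any(mld_a < 0) || any(mld_b < 0))
    eg_abort("MLD maps must be nonnegative", "invalid_input")
  if (!all(dim(mld_a) == dim(dom$od_a)) || !all(dim(mld_b) == dim(dom$od_b)))
    eg_abort("map shape mismatch", "shape_error")
  l_a <- dom$od_a + dom$nod_a; l_b <- dom$od_b + dom$nod_b
  ldm_a <- mld_a * conv3x3_replicate(abs(l_a))
  ldm_b <- mld_b * conv3x3_replicate(abs(l_b))
  d <- (ldm_a >= ldm_b) * 1
  list(fused = d * dom$od_a + (1 - d) * dom$od_b, decision = d)
}

#' Non-overlapping-domain fusion rule
#'
#' Complementary information is fused by simple addition: `N_A + N_B`.
#'
#' @param dom A `domain_maps` object.
#' @return Fused NOD band.
#' @export
fuse_nonoverlap <- function(dom) dom$nod_a + dom$nod_b

binary_dilate3 <- function(b) {
  out <- matrix(FALSE, nrow(b), ncol(b))
  for (di in -1:1) for (dj in -1:1) out <- out | shift_replicate(b, di, dj)
  out
}

#' Fuse two co-registered 2D slices with LRD
#'
#' Full pipeline: GDIE enhancement of both inputs drives the decision maps;
#' Laplacian pyramids of the original slices supply the sub-band payload; per
#' level, DGR splits the bands into OD/NOD which are fused by the LDM decision
#' graph and by addition respectively; the inverse re-decomposition scheme
#' (IRS) re-assigns pixels within one pixel of the OD boundary to the globally
#' dominant source of that level; low bands are fused by LEM; the result is
#' reconstructed and clipped to the inputs' intensity range. Deterministic;
#' ties favor input `a`.
#'
#' @param a,b 2D matrices of equal shape, finite values.
#' @param cfg A [fusion_config()].
#' @return Fused 2D matrix of the same shape.
#' @export
lrd_fuse_slice <- function(a, b, cfg = fusion_config()) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    eg_abort("inputs must be 2D matrices of equal shape", "shape_error")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    eg_abort("inputs must be finite", "invalid_input")
  h_a <- gdie_enhance(a, cfg); h_b <- gdie_enhance(b, cfg)
  pyr_a <- lp_decompose(a, cfg$tau); pyr_b <- lp_decompose(b, cfg$tau)
  pyr_ha <- lp_decompose(h_a, cfg$tau); pyr_hb <- lp_decompose(h_b, cfg$tau)
  highs <- vector("list", cfg$tau)
  for (k in seq_len(cfg$tau)) {
    l_a <- pyr_a$highs[[k]]; l_b <- pyr_b$highs[[k]]
    dom <- dgr_decompose(l_a, l_b)
    mld_a <- max_local_difference(pyr_ha$highs[[k]])
    mld_b <- max_local_difference(pyr_hb$highs[[k]])
    fo <- fuse_overlap(dom, mld_a, mld_b)
    fk <- fo$fused + fuse_nonoverlap(dom)
    ov <- dom$overlap > 0
    if (any(ov) && !all(ov)) {
      ring <- binary_dilate3(ov) & binary_dilate3(!ov)  # within 1 px of boundary
      src_a <- mean(fo$decision[ov]) >= 0.5
      fk[ring] <- if (src_a) l_a[ring] else l_b[ring]
    }
    highs[[k]] <- fk
  }
  fused <- lp_reconstruct(structure(list(
    highs = highs, low = fuse_low_lem(pyr_a$low, pyr_b$low, cfg$lem_window),
    shapes = pyr_a$shapes), class = "pyramid_levels"))
  rng <- range(c(a, b))
  pmin(pmax(fused, rng[1]), rng[2])
}

rescale_0_255 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) * 255 else x * 0
}

#' Fuse two co-registered volumes slice-wise with LRD
#'
#' Both volumes are min-max rescaled to the \[0, 255\] working range, fused
#' axial slice by axial slice with [lrd_fuse_slice()], and reassembled with
#' the inputs' spacing metadata.
#'
#' @param a,b 3D arrays on the same grid.
#' @param cfg A [fusion_config()].
#' @param spacing Voxel spacing carried to the output (attribute `spacing`).
#' @return Fused 3D array in \[0, 255\] with attribute `spacing`.
#' @export
lrd_fuse_volume <- function(a, b, cfg = fusion_config(),
                            spacing = attr(a, "spacing") %||% c(1, 1, 1)) {
  if (length(dim(a)) != 3L || !all(dim(a) == dim(b)))
    eg_abort("volumes are not co-registered (grid mismatch)", "coregistration_error")
  a <- rescale_0_255(a); b <- rescale_0_255(b)
  out <- array(0, dim(a))
  for (z in seq_len(dim(a)[3]))
    out[, , z] <- lrd_fuse_slice(a[, , z], b[, , z], cfg)
  attr(out, "spacing") <- spacing
  out
}

#' The six fused image types used in the study
#' @return Character vector of `"A+B"` pair names.
#' @export
fusion_pairs <- function() {
  c("T1+FLAIR", "T1Gd+FLAIR", "T1Gd+T1", "T1Gd+T2", "T2+FLAIR", "T2+T1")
}

#' Fuse a named modality pair of a phantom subject
#'
#' @param record A `subject_record`.
#' @param pair Pair name like `"T1Gd+FLAIR"` (A+B; A wins ties).
#' @param cfg A [fusion_config()].
#' @return Fused volume (3D array, \[0, 255\]).
#' @export
fuse_subject_pair <- function(record, pair, cfg = fusion_config()) {
  parts <- strsplit(pair, "+", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% names(record$modalities)) ||
      parts[1] == parts[2])
    eg_abort(paste0("invalid fusion pair: ", pair), "invalid_parameter")
  cfg$pair <- parts
  lrd_fuse_volume(record$modalities[[parts[1]]], record$modalities[[parts[2]]],
                  cfg, spacing = record$spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
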