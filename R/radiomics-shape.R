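# Mesh extraction on a binary mask by marching tetrahedra: each grid cell
# (corners = 8 neighbouring voxel centres, mask padded with background) is
# split into the six tetrahedra sharing the main diagonal; the 0.5-isosurface
# of binary data cuts every crossed tetrahedron edge at its midpoint, so each
# (tetrahedron, inside-pattern) case contributes a fixed triangle geometry and
# a fixed clipped-volume fraction (corner piece = 1/8, half split = 1/2 of the
# tetrahedron by the midpoint-cut similarity argument).

# corner index c = bx + 2*by + 4*bz; six tetrahedra share edge 0-7
.mt_tets <- list(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
                 c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

.mt_corner_xyz <- function(c) c(bitwAnd(c, 1L), bitwAnd(c, 2L) %/% 2L, bitwAnd(c, 4L) %/% 4L)

# vectorized area of triangles with vertex matrices (n x 3 each)
.tri_area_vec <- function(q1, q2, q3) {
  u <- q2 - q1; v <- q3 - q1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Surface area and mesh volume of a binary mask. The volume uses the exact
# midpoint-cut closed form on the binary field (corner piece = 1/8, half
# split = 1/2 of a tetrahedron). The area interpolates the cuts on the
# Gaussian-smoothed occupancy field whenever that field preserves the binary
# inside/outside topology (true for shapes thicker than the smoothing
# kernel), which suppresses the staircase bias a purely binary triangulation
# gives on smooth shapes; sub-resolution structures fall back to the
# half-binary blend so they cannot vanish.
mesh_stats <- function(mask_bb, spacing) {
  dm <- dim(mask_bb)
  p <- array(0, dm + 4L)
  p[3:(dm[1] + 2L), 3:(dm[2] + 2L), 3:(dm[3] + 2L)] <- mask_bb * 1
  # 3x3x3 Gaussian (sigma 0.8 voxels) smoothing of the padded occupancy
  g1 <- exp(-(-1:1)^2 / (2 * 0.8^2)); g1 <- g1 / sum(g1)
  sm <- p
  for (ax in 1:3) {
    n <- dim(sm)[ax]
    shift_ax <- function(a, s) {
      i <- pmin(pmax(seq_len(n) + s, 1L), n)
      switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    }
    sm <- g1[1] * shift_ax(sm, -1L) + g1[2] * sm + g1[3] * shift_ax(sm, 1L)
  }
  # vertices whose smoothed value disagrees with the binary side of the
  # isolevel; rare for shapes thicker than the kernel, pervasive for
  # sub-resolution structures
  viol <- (p == 1 & sm <= 0.5) | (p == 0 & sm >= 0.5)
  val <- if (sum(viol) / max(1, sum(p == 1)) < 0.05)
    ifelse(p == 1, pmax(sm, 0.51), pmin(sm, 0.49))
  else 0.5 * (p + sm)
  # cell grid: one layer of padding around the mask is enough
  keep <- lapply(seq_along(dm), function(ax) 2:(dm[ax] + 3L))
  pb <- p[keep[[1]], keep[[2]], keep[[3]]] > 0.5
  vv <- val[keep[[1]], keep[[2]], keep[[3]]]
  d <- dim(pb) - 1L
  corner <- function(a, bx, by, bz)
    as.vector(a[(1:d[1]) + bx, (1:d[2]) + by, (1:d[3]) + bz])
  cb <- lapply(0:7, function(c) { b <- .mt_corner_xyz(c); corner(pb, b[1], b[2], b[3]) })
  ncell <- length(cb[[1]])
  n_in8 <- Reduce(`+`, cb)
  mixed <- n_in8 > 0L & n_in8 < 8L
  vol <- sum(n_in8 == 8L) * prod(spacing)
  if (!any(mixed)) return(list(surface_area = 0, mesh_volume = vol))
  cbm <- lapply(cb, function(x) x[mixed])
  cvm <- lapply(0:7, function(c) {
    b <- .mt_corner_xyz(c); corner(vv, b[1], b[2], b[3])[mixed]
  })
  tetvol <- prod(spacing) / 6
  area <- 0
  for (t in 1:6) {
    ids <- .mt_tets[[t]] + 1L
    pos <- t(vapply(.mt_tets[[t]], .mt_corner_xyz, numeric(3))) *
      matrix(spacing, 4, 3, byrow = TRUE)
    b <- lapply(1:4, function(i) cbm[[ids[i]]])
    v <- lapply(1:4, function(i) cvm[[ids[i]]])
    case <- b[[1]] + 2L * b[[2]] + 4L * b[[3]] + 8L * b[[4]]
    vol <- vol + sum(tetvol * c(0, 1 / 8, 1 / 2, 7 / 8, 1)[
      (b[[1]] + b[[2]] + b[[3]] + b[[4]]) + 1L])
    cut <- function(sel, i, j) {
      tt <- (0.5 - v[[i]][sel]) / (v[[j]][sel] - v[[i]][sel])
      tt <- pmin(pmax(tt, 0), 1)
      outer(rep(1, sum(sel)), pos[i, ]) + tt * outer(rep(1, sum(sel)),
                                                     pos[j, ] - pos[i, ])
    }
    for (cs in 1:14) {
      sel <- case == cs
      if (!any(sel)) next
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
      n_in <- length(inside)
      if (n_in == 1L || n_in == 3L) {
        apex <- if (n_in == 1L) inside else setdiff(1:4, inside)
        oth <- setdiff(1:4, apex)
        area <- area + sum(.tri_area_vec(cut(sel, apex, oth[1]),
                                         cut(sel, apex, oth[2]),
                                         cut(sel, apex, oth[3])))
      } else {
        outs <- setdiff(1:4, inside)
        qa <- cut(sel, inside[1], outs[1]); qb <- cut(sel, inside[1], outs[2])
        qd <- cut(sel, inside[2], outs[2]); qe <- cut(sel, inside[2], outs[1])
        area <- area + sum(.tri_area_vec(qa, qb, qd) + .tri_area_vec(qa, qd, qe))
      }
    }
  }
  list(surface_area = area, mesh_volume = vol)
}

# boundary voxels: inside voxels with at least one 6-neighbour outside
boundary_voxels <- function(mask_bb) {
  p <- array(FALSE, dim(mask_bb) + 2L)
  i1 <- 2:(dim(mask_bb)[1] + 1L); i2 <- 2:(dim(mask_bb)[2] + 1L); i3 <- 2:(dim(mask_bb)[3] + 1L)
  p[i1, i2, i3] <- mask_bb
  nb <- p[i1 - 1L, i2, i3] & p[i1 + 1L, i2, i3] &
    p[i1, i2 - 1L, i3] & p[i1, i2 + 1L, i3] &
    p[i1, i2, i3 - 1L] & p[i1, i2, i3 + 1L]
  which(mask_bb & !nb, arr.ind = TRUE)
}

max_pairwise <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

#' The 14 shape features of a 3D mask
#'
#' Mesh volume and surface area come from a marching-tetrahedra triangulation
#' of the binary mask; axis lengths derive from the eigenvalues of the
#' physical-coordinate covariance matrix; maximum diameters are the largest
#' pairwise distances between boundary voxel centres (overall and within each
#' orthogonal plane family).
#'
#' @param mask_bb Logical 3D array (ROI mask, typically cropped to its
#'   bounding box).
#' @param spacing Voxel spacing in mm, length 3.
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask_bb, spacing = c(1, 1, 1)) {
  n <- sum(mask_bb)
  if (n == 0L) eg_abort("empty mask", "empty_roi")
  ms <- mesh_stats(mask_bb, spacing)
  vvol <- n * prod(spacing)
  mvol <- ms$mesh_volume; area <- ms$surface_area
  # clipped at the isoperimetric bound (mesh discretization can nominally
  # exceed it by a fraction of a percent)
  sph <- if (area > 0) min((36 * pi * mvol^2)^(1 / 3) / area, 1) else 0
  svr <- if (mvol > 0) area / mvol else 0

  coords <- which(mask_bb, arr.ind = TRUE)
  phys <- sweep(coords, 2, spacing, `*`)
  if (n >= 2L) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  bd <- boundary_voxels(mask_bb)
  bphys <- sweep(bd, 2, spacing, `*`)
  d3 <- max_pairwise(bphys)
  plane_max <- function(fix_dim) {
    keep <- setdiff(1:3, fix_dim)
    m <- 0
    for (v in unique(bd[, fix_dim])) {
      sel <- bd[, fix_dim] == v
      m <- max(m, max_pairwise(bphys[sel, keep, drop = FALSE]))
    }
    m
  }
  c(shape_MeshVolume = mvol,
    shape_VoxelVolume = vvol,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = svr,
    shape_Sphericity = sph,
    shape_MajorAxisLength = major,
    shape_MinorAxisLength = minor,
    shape_LeastAxisLength = least,
    shape_Elongation = elong,
    shape_Flatness = flat,
    shape_Maximum3DDiameter = d3,
    shape_Maximum2DDiameterSlice = plane_max(3),   # in-plane of axis 1-2
    shape_Maximum2DDiameterColumn = plane_max(2),  # in-plane of axis 1-3
    shape_Maximum2DDiameterRow = plane_max(1))     # in-plane of axis 2-3
}
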