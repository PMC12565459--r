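# the 13 unique 3D direction offsets (half of the 26-neighbourhood)
directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# aligned values of A and its d-shifted copy (no wrap); A has NA outside ROI;
# NULL when the offset exceeds the array extent
.offset_pairs <- function(A, d) {
  dims <- dim(A)
  if (any(dims - abs(d) < 1)) return(NULL)
  sx <- max(1, 1 - d[1]):min(dims[1], dims[1] - d[1])
  sy <- max(1, 1 - d[2]):min(dims[2], dims[2] - d[2])
  sz <- max(1, 1 - d[3]):min(dims[3], dims[3] - d[3])
  list(a = A[sx, sy, sz, drop = FALSE],
       b = A[sx + d[1], sy + d[2], sz + d[3], drop = FALSE],
       src = list(sx, sy, sz))
}

.glcm_one <- function(A, ng, d) {
  pr <- .offset_pairs(A, d)
  if (is.null(pr)) return(matrix(0, ng, ng))
  ok <- !is.na(pr$a) & !is.na(pr$b)
  if (!any(ok)) return(matrix(0, ng, ng))
  cnt <- tabulate((pr$a[ok] - 1L) * ng + pr$b[ok], nbins = ng * ng)
  P <- matrix(cnt, ng, ng, byrow = TRUE)
  P + t(P)
}

.glcm_stats <- function(P) {
  tot <- sum(P)
  if (tot == 0) return(NULL)
  present <- which(rowSums(P) > 0)
  p <- P[present, present, drop = FALSE] / tot
  iv <- present
  ngp <- length(iv)
  I <- matrix(iv, ngp, ngp); J <- t(I)
  px <- rowSums(p)                 # symmetric: px == py
  mu <- sum(iv * px)
  sig2 <- sum((iv - mu)^2 * px)
  ks <- sort(unique(as.vector(I + J)))
  ps <- vapply(ks, function(k) sum(p[I + J == k]), numeric(1))
  kd <- sort(unique(as.vector(abs(I - J))))
  pd <- vapply(kd, function(k) sum(p[abs(I - J) == k]), numeric(1))
  da <- sum(kd * pd)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hx <- ent(px)
  pipj <- px[row(p)] * px[col(p)]
  nz <- p > 0
  hxy1 <- -sum(p[nz] * log2(pipj[nz]))
  hxy2 <- ent(pipj)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  ng_tot <- max(iv)   # Ng for the normalized inverse-difference variants
  mcc <- if (ngp == 1L) 1 else {
    # Q[i,j] = sum_k p(i,k) p(j,k) / (px(i) px(k))
    Q <- sweep(p, 1, px, "/") %*% t(sweep(p, 2, px, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }
  corr <- if (sig2 > 0) (sum(I * J * p) - mu^2) / sig2 else 1
  c(Autocorrelation = sum(I * J * p),
    JointAverage = mu,
    ClusterProminence = sum((I + J - 2 * mu)^4 * p),
    ClusterShade = sum((I + J - 2 * mu)^3 * p),
    ClusterTendency = sum((I + J - 2 * mu)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(p / (1 + abs(I - J))),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + (I - J)^2 / ng_tot^2)),
    Idn = sum(p / (1 + abs(I - J) / ng_tot)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[I != J] / (I - J)[I != J]^2),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * ps),
    SumEntropy = ent(ps),
    SumSquares = sum((I - mu)^2 * p))
}

#' The 24 gray-level co-occurrence matrix (GLCM) features
#'
#' Symmetric distance-1 co-occurrence matrices are built for each of the 13
#' unique 3D directions; features are computed per direction and averaged.
#'
#' @param d A `discretized_roi`.
#' @return Named numeric vector of 24 features (prefix `glcm_`).
#' @export
glcm_features <- function(d) {
  dirs <- directions13()
  acc <- NULL; nd <- 0
  for (k in seq_len(nrow(dirs))) {
    st <- .glcm_stats(.glcm_one(d$levels, d$ng, dirs[k, ]))
    if (is.null(st)) next
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1
  }
  if (nd == 0) {  # single-voxel-like ROI: no voxel pairs in any direction
    st <- .glcm_stats(matrix(2, 1, 1))
    acc <- st; nd <- 1
  }
  out <- acc / nd
  names(out) <- paste0("glcm_", names(out))
  out
}

# run-length triples (level i, run length j, count) for one direction
.glrlm_runs <- function(A, d) {
  dims <- dim(A)
  cx <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  cy <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  cz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  t <- cx * d[1] + cy * d[2] + cz * d[3]
  # line identifier: |d|^2 * p - (d . p) * d is constant along the line and
  # integer-valued; sorting by (line, t) orders voxels along each line
  s2 <- sum(d^2)
  lx <- s2 * cx - t * d[1]; ly <- s2 * cy - t * d[2]; lz <- s2 * cz - t * d[3]
  off <- 3 * max(dims) + 1; base <- as.numeric(10 * max(dims) + 3)
  key <- (lx + off) + (ly + off) * base + (lz + off) * base * base
  ord <- order(key, t)
  lv <- as.vector(A)[ord]
  lv[is.na(lv)] <- 0L
  keys <- key[ord]
  n <- length(lv)
  brk <- c(TRUE, keys[-1] != keys[-n] | lv[-1] != lv[-n])
  grp <- cumsum(brk)
  len <- tabulate(grp)
  lev <- lv[brk]
  keep <- lev > 0L
  list(i = lev[keep], j = len[keep])
}

# generic emphasis statistics shared by the run/zone/dependence families
.rlm_stats <- function(i, j, cnt, np, size_name) {
  nr <- sum(cnt)
  p <- cnt / nr
  si <- rowsum(cnt, i); gi <- as.numeric(rownames(si))
  sj <- rowsum(cnt, j); gj <- as.numeric(rownames(sj))
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  ent <- -sum(p * log2(p))
  v <- c(sum(p / j^2), sum(p * j^2),
         sum(si^2) / nr, sum(si^2) / nr^2,
         sum(sj^2) / nr, sum(sj^2) / nr^2,
         nr / np,
         sum(p * (i - mu_i)^2), sum(p * (j - mu_j)^2), ent,
         sum(p / i^2), sum(p * i^2),
         sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
         sum(p * j^2 / i^2), sum(p * i^2 * j^2))
  names(v) <- c(paste0("Short", size_name, "Emphasis"), paste0("Long", size_name, "Emphasis"),
                "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                paste0(size_name, "LengthNonUniformity"), paste0(size_name, "LengthNonUniformityNormalized"),
                paste0(size_name, "Percentage"),
                "GrayLevelVariance", paste0(size_name, "Variance"), paste0(size_name, "Entropy"),
                "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                paste0("Short", size_name, "LowGrayLevelEmphasis"),
                paste0("Short", size_name, "HighGrayLevelEmphasis"),
                paste0("Long", size_name, "LowGrayLevelEmphasis"),
                paste0("Long", size_name, "HighGrayLevelEmphasis"))
  v
}

#' The 16 gray-level run-length matrix (GLRLM) features
#'
#' Runs of identical gray level are collected along each of the 13 unique 3D
#' directions; features are computed per direction and averaged.
#'
#' @param d A `discretized_roi`.
#' @return Named numeric vector of 16 features (prefix `glrlm_`).
#' @export
glrlm_features <- function(d) {
  dirs <- directions13()
  acc <- NULL
  for (k in seq_len(nrow(dirs))) {
    r <- .glrlm_runs(d$levels, dirs[k, ])
    tab <- rowsum(rep(1L, length(r$i)), paste(r$i, r$j))
    ij <- do.call(rbind, strsplit(rownames(tab), " "))
    st <- .rlm_stats(as.numeric(ij[, 1]), as.numeric(ij[, 2]), as.numeric(tab),
                     d$n_voxels, "Run")
    acc <- if (is.null(acc)) st else acc + st
  }
  out <- acc / nrow(dirs)
  nm <- names(out)
  map <- c(LowGrayLevelEmphasis = "LowGrayLevelRunEmphasis",
           HighGrayLevelEmphasis = "HighGrayLevelRunEmphasis")
  nm[nm %in% names(map)] <- map[nm[nm %in% names(map)]]
  names(out) <- paste0("glrlm_", nm)
  out
}

#' The 16 gray-level size-zone matrix (GLSZM) features
#'
#' Zones are 26-connected components of constant gray level; the zone matrix
#' is unique (no direction averaging).
#'
#' @param d A `discretized_roi`.
#' @return Named numeric vector of 16 features (prefix `glszm_`).
#' @export
glszm_features <- function(d) {
  A <- d$levels
  nid <- array(NA_integer_, dim(A))
  roi <- !is.na(A)
  nid[roi] <- seq_len(sum(roi))
  edges <- list()
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) {
    pr <- .offset_pairs(A, dirs[k, ])
    if (is.null(pr)) next
    nn <- .offset_pairs(nid, dirs[k, ])
    ok <- !is.na(pr$a) & !is.na(pr$b) & pr$a == pr$b
    if (any(ok)) edges[[length(edges) + 1L]] <- rbind(nn$a[ok], nn$b[ok])
  }
  n <- sum(roi)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  lev_by_voxel <- A[roi]
  lev <- lev_by_voxel[match(seq_along(sizes), comp)]
  st <- .rlm_stats(lev, sizes, rep(1, length(sizes)), d$n_voxels, "Zone")
  nm <- names(st)
  map <- c(ShortZoneEmphasis = "SmallAreaEmphasis", LongZoneEmphasis = "LargeAreaEmphasis",
           ZoneLengthNonUniformity = "SizeZoneNonUniformity",
           ZoneLengthNonUniformityNormalized = "SizeZoneNonUniformityNormalized",
           LowGrayLevelEmphasis = "LowGrayLevelZoneEmphasis",
           HighGrayLevelEmphasis = "HighGrayLevelZoneEmphasis",
           ShortZoneLowGrayLevelEmphasis = "SmallAreaLowGrayLevelEmphasis",
           ShortZoneHighGrayLevelEmphasis = "SmallAreaHighGrayLevelEmphasis",
           LongZoneLowGrayLevelEmphasis = "LargeAreaLowGrayLevelEmphasis",
           LongZoneHighGrayLevelEmphasis = "LargeAreaHighGrayLevelEmphasis")
  nm[nm %in% names(map)] <- map[nm[nm %in% names(map)]]
  names(st) <- paste0("glszm_", nm)
  st
}

# 26-neighbour equal-level counts and neighbour level sums/counts
.neighbour_maps <- function(A) {
  dims <- dim(A)
  eq <- array(0L, dims); nsum <- array(0, dims); ncnt <- array(0L, dims)
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) for (s in c(1L, -1L)) {
    dd <- dirs[k, ] * s
    pr <- .offset_pairs(A, dd)
    if (is.null(pr)) next
    ok <- !is.na(pr$a) & !is.na(pr$b)
    sub <- array(0L, dim(pr$a)); sub[ok & pr$a == pr$b] <- 1L
    eq[pr$src[[1]], pr$src[[2]], pr$src[[3]]] <-
      eq[pr$src[[1]], pr$src[[2]], pr$src[[3]], drop = FALSE] + sub
    subs <- array(0, dim(pr$a)); subs[ok] <- pr$b[ok]
    nsum[pr$src[[1]], pr$src[[2]], pr$src[[3]]] <-
      nsum[pr$src[[1]], pr$src[[2]], pr$src[[3]], drop = FALSE] + subs
    subc <- array(0L, dim(pr$a)); subc[ok] <- 1L
    ncnt[pr$src[[1]], pr$src[[2]], pr$src[[3]]] <-
      ncnt[pr$src[[1]], pr$src[[2]], pr$src[[3]], drop = FALSE] + subc
  }
  list(eq = eq, nsum = nsum, ncnt = ncnt)
}

#' The 14 gray-level dependence matrix (GLDM) features
#'
#' The dependence of a voxel is the number of 26-neighbours within the ROI
#' whose gray level differs by at most `alpha` (default 0); the stored
#' dependence size is that count plus one, so it is always positive.
#'
#' @param d A `discretized_roi`.
#' @param alpha Gray-level tolerance (default 0).
#' @return Named numeric vector of 14 features (prefix `gldm_`).
#' @export
gldm_features <- function(d, alpha = 0) {
  A <- d$levels
  roi <- !is.na(A)
  if (alpha == 0) {
    nb <- .neighbour_maps(A)
    dep <- nb$eq[roi] + 1L
  } else {
    dep <- .gldm_dep_alpha(A, alpha)[roi] + 1L
  }
  lev <- A[roi]
  tab <- rowsum(rep(1L, length(lev)), paste(lev, dep))
  ij <- do.call(rbind, strsplit(rownames(tab), " "))
  st <- .rlm_stats(as.numeric(ij[, 1]), as.numeric(ij[, 2]), as.numeric(tab),
                   d$n_voxels, "Dependence")
  map <- c(ShortDependenceEmphasis = "SmallDependenceEmphasis",
           LongDependenceEmphasis = "LargeDependenceEmphasis",
           DependenceLengthNonUniformity = "DependenceNonUniformity",
           DependenceLengthNonUniformityNormalized = "DependenceNonUniformityNormalized",
           ShortDependenceLowGrayLevelEmphasis = "SmallDependenceLowGrayLevelEmphasis",
           ShortDependenceHighGrayLevelEmphasis = "SmallDependenceHighGrayLevelEmphasis",
           LongDependenceLowGrayLevelEmphasis = "LargeDependenceLowGrayLevelEmphasis",
           LongDependenceHighGrayLevelEmphasis = "LargeDependenceHighGrayLevelEmphasis")
  nm <- names(st)
  nm[nm %in% names(map)] <- map[nm[nm %in% names(map)]]
  names(st) <- paste0("gldm_", nm)
  # drop the two entries not in the canonical 14-feature GLDM set
  st[!names(st) %in% c("gldm_GrayLevelNonUniformityNormalized", "gldm_DependencePercentage")]
}

.gldm_dep_alpha <- function(A, alpha) {
  dims <- dim(A)
  dep <- array(0L, dims)
  dirs <- directions13()
  for (k in seq_len(nrow(dirs))) for (s in c(1L, -1L)) {
    pr <- .offset_pairs(A, dirs[k, ] * s)
    if (is.null(pr)) next
    ok <- !is.na(pr$a) & !is.na(pr$b) & abs(pr$a - pr$b) <= alpha
    sub <- array(0L, dim(pr$a)); sub[ok] <- 1L
    dep[pr$src[[1]], pr$src[[2]], pr$src[[3]]] <-
      dep[pr$src[[1]], pr$src[[2]], pr$src[[3]], drop = FALSE] + sub
  }
  dep
}

#' The 5 neighbourhood gray-tone difference matrix (NGTDM) features
#'
#' For each gray level i, `s_i` accumulates the absolute difference between i
#' and the mean level of the 26-neighbourhood (restricted to the ROI) over all
#' voxels of level i having at least one neighbour. Coarseness of a uniform
#' ROI is reported at the documented sentinel 1e6.
#'
#' @param d A `discretized_roi`.
#' @return Named numeric vector of 5 features (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(d) {
  A <- d$levels
  nb <- .neighbour_maps(A)
  roi <- !is.na(A) & nb$ncnt > 0L
  lev <- A[roi]
  nvp <- length(lev)
  if (nvp == 0L)
    return(c(ngtdm_Coarseness = 1e6, ngtdm_Contrast = 0, ngtdm_Busyness = 0,
             ngtdm_Complexity = 0, ngtdm_Strength = 0))
  diffv <- abs(lev - nb$nsum[roi] / nb$ncnt[roi])
  ni <- rowsum(rep(1L, nvp), lev); iv <- as.numeric(rownames(ni))
  si <- rowsum(diffv, lev)
  pi_ <- as.numeric(ni) / nvp; si <- as.numeric(si)
  ngp <- length(iv)
  coars <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  if (ngp > 1) {
    DI <- outer(iv, iv, `-`)
    contrast <- (sum(outer(pi_, pi_) * DI^2) / (ngp * (ngp - 1))) * (sum(si) / nvp)
    busy_den <- sum(abs(outer(iv * pi_, iv * pi_, `-`)))
    busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    PS <- outer(pi_ * si, pi_ * si, `+`)
    PP <- outer(pi_, pi_, `+`)
    complexity <- sum(abs(DI) * PS / PP) / nvp
    strength <- if (sum(si) > 0) sum(PP * DI^2) / sum(si) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coars, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}
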