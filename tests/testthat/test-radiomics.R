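test_that("ROI extraction counts voxels and rejects absent labels", {
  mask <- array(0L, c(8, 8, 8)); mask[2:6, 2:6, 2:5] <- 2L
  vol <- array(runif(512), c(8, 8, 8))
  roi <- extract_roi(vol, mask)
  expect_equal(roi$n_voxels, 100)
  expect_equal(length(roi$values), 100)
  expect_error(extract_roi(vol, array(0L, c(8, 8, 8))), class = "empty_roi")
  expect_error(extract_roi(vol, mask, roi_spec(label = 4)), class = "empty_roi")
  expect_error(extract_roi(vol[1:4, , ], mask), class = "shape_error")
  # nested phantom: edema shell outnumbers the core
  rec <- small_subject("HGG", seed = 7)
  e <- extract_roi(rec$modalities$T1, rec$mask, roi_spec(2))
  k <- extract_roi(rec$modalities$T1, rec$mask, roi_spec(1))
  expect_gt(e$n_voxels, k$n_voxels)
})

test_that("discretization is min-anchored with fixed bin width", {
  roi <- function(v) list(values = v, mask_bb = array(TRUE, c(length(v), 1, 1)),
                          spacing = c(1, 1, 1))
  expect_equal(discretize_roi(roi(c(0, 10, 24)))$ng, 1)
  expect_equal(discretize_roi(roi(c(0, 25, 50)))$values, c(1L, 2L, 3L))
  expect_equal(discretize_roi(roi(seq(0, 249.99, length.out = 50)))$ng, 10)
  expect_error(discretize_roi(roi(1:5), bin_width = 0), class = "invalid_parameter")
})

test_that("first-order statistics match closed forms and a naive oracle", {
  const <- firstorder_features(rep(5, 50))
  expect_equal(unname(const["firstorder_Variance"]), 0)
  expect_equal(unname(const["firstorder_Uniformity"]), 1)
  expect_equal(unname(const["firstorder_Entropy"]), 0)
  v <- firstorder_features(1:100)
  expect_equal(unname(v["firstorder_Mean"]), 50.5)
  expect_equal(unname(v["firstorder_Median"]), 50.5)
  expect_equal(unname(v["firstorder_Range"]), 99)
  expect_length(v, 18)
  set.seed(1)
  x <- runif(500, 0, 255)
  got <- firstorder_features(x, spacing = c(1, 2, 3), bin_width = 25)
  n <- length(x); mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  lv <- floor((x - min(x)) / 25) + 1
  pr <- as.numeric(table(lv)) / n
  sub <- x[x >= quantile(x, .1) & x <= quantile(x, .9)]
  oracle <- c(sum(x^2), 6 * sum(x^2), -sum(pr * log2(pr)), min(x),
              unname(quantile(x, .1)), unname(quantile(x, .9)), max(x), mu,
              median(x), unname(quantile(x, .75) - quantile(x, .25)),
              max(x) - min(x), sum(abs(x - mu)) / n,
              sum(abs(sub - mean(sub))) / length(sub), sqrt(sum(x^2) / n),
              (sum((x - mu)^3) / n) / m2^1.5, (sum((x - mu)^4) / n) / m2^2,
              m2, sum(pr^2))
  expect_equal(unname(got), oracle, tolerance = 1e-9)
})

test_that("shape features behave on balls, rods and the phantom shell", {
  sf <- shape_features(digital_ball(8))
  expect_length(sf, 14)
  expect_gte(unname(sf["shape_Sphericity"]), 0.9)
  expect_lte(unname(sf["shape_Sphericity"]), 1.0)
  r <- 8
  expect_equal(unname(sf["shape_MeshVolume"]), 4 / 3 * pi * r^3, tolerance = 0.05)
  expect_equal(unname(sf["shape_SurfaceArea"]), 4 * pi * r^2, tolerance = 0.05)
  expect_equal(unname(sf["shape_Maximum3DDiameter"]), 2 * r, tolerance = 0.1)
  # 1 x 1 x N rod: both eigen ratios vanish
  rod <- array(FALSE, c(3, 3, 21)); rod[2, 2, ] <- TRUE
  sr <- shape_features(rod)
  expect_lt(unname(sr["shape_Elongation"]), 1e-6)
  expect_lt(unname(sr["shape_Flatness"]), 1e-6)
  expect_equal(unname(sr["shape_Maximum3DDiameter"]), 20)
  # anisotropic spacing scales the voxel volume
  sv <- shape_features(digital_ball(5), spacing = c(1, 1, 2))
  expect_equal(unname(sv["shape_VoxelVolume"]), 2 * sum(digital_ball(5)))
  # single voxel: finite documented fallbacks
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_true(all(is.finite(shape_features(single))))
})

test_that("wavelet sub-bands are undecimated, named and complete", {
  set.seed(2)
  v <- array(runif(10 * 9 * 8), c(10, 9, 8))
  b <- wavelet_subbands(v)
  expect_named(b, wavelet_band_names())
  for (x in b) expect_identical(dim(x), dim(v))
  cb <- wavelet_subbands(array(3, c(8, 8, 8)))
  for (nm in setdiff(names(cb), "LLL")) expect_lt(max(abs(cb[[nm]])), 1e-10)
  expect_gt(mean(cb$LLL), 1)   # low-pass retains the DC component
  expect_warning(wavelet_subbands(array(1, c(4, 4, 4))), "filter")
})

test_that("GLCM matches the nested-loop oracle and its closed forms", {
  # constant ROI: Ng = 1
  dc <- levels_roi(array(1L, c(4, 4, 2)))
  g <- glcm_features(dc)
  expect_length(g, 24)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_MaximumProbability"]), 1)
  expect_equal(unname(g["glcm_JointEntropy"]), 0)
  # checkerboard slab: contrast from explicitly counted pairs
  chk <- array(NA_integer_, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) chk[i, j, 1] <- 1L + (i + j) %% 2L
  contr <- c()
  for (k in seq_len(nrow(oracle_dirs))) {
    P <- oracle_glcm(chk, 2L, oracle_dirs[k, ])
    if (sum(P) == 0) next
    p <- P / sum(P)
    contr <- c(contr, sum(outer(1:2, 1:2, function(a, b) (a - b)^2) * p))
  }
  expect_equal(unname(glcm_features(levels_roi(chk))["glcm_Contrast"]),
               mean(contr), tolerance = 1e-12)
})

test_that("GLRLM runs and run percentage match the enumerable oracle", {
  seq5 <- array(c(1L, 1L, 1L, 2L, 2L), c(5, 1, 1))
  runs <- edemagrade:::.glrlm_runs(seq5, c(1, 0, 0))
  expect_equal(sort(paste(runs$i, runs$j)), c("1 3", "2 2"))
  # run percentage along that direction: 2 runs / 5 voxels
  expect_equal(length(runs$i) / 5, 2 / 5)
  g <- glrlm_features(levels_roi(seq5))
  expect_length(g, 16)
  # constant ROI maximises long-run emphasis along every direction
  const <- levels_roi(array(1L, c(6, 1, 1)))
  gc <- glrlm_features(const)
  expect_gte(unname(gc["glrlm_LongRunEmphasis"]), 1)
})

test_that("GLSZM, GLDM and NGTDM satisfy their degenerate closed forms", {
  const <- levels_roi(array(1L, c(4, 4, 2)))
  gz <- glszm_features(const)
  expect_length(gz, 16)
  expect_equal(unname(gz["glszm_ZonePercentage"]), 1 / 32)  # one zone, 32 voxels
  gd <- gldm_features(const)
  expect_length(gd, 14)
  gn <- ngtdm_features(const)
  expect_length(gn, 5)
  expect_equal(unname(gn["ngtdm_Coarseness"]), 1e6)  # uniform ROI sentinel
})

test_that("direction-averaged features are invariant to axial 90-degree rotation", {
  A <- random_level_roi(c(5, 5, 2), ng = 3, seed = 9, na_frac = 0.15)
  B <- aperm(A, c(2, 1, 3))[dim(A)[2]:1, , , drop = FALSE]  # rot90 in-plane
  for (fn in list(glcm_features, glrlm_features)) {
    fa <- fn(levels_roi(A)); fb <- fn(levels_roi(B))
    expect_equal(fa, fb, tolerance = 1e-9)
  }
})

test_that("full extraction yields 851 finite, shift-invariant features", {
  rec <- small_subject("LGG", seed = 5)
  fv <- extract_features(rec$modalities$FLAIR, rec$mask, rec$spacing)
  expect_length(fv, 851)
  expect_true(all(is.finite(fv)))
  reg <- feature_registry()
  expect_identical(names(fv), reg$name)
  expect_equal(sum(reg$image_type == "shape"), 14)
  expect_equal(sum(reg$image_type == "original"), 93)
  expect_equal(sum(startsWith(reg$image_type, "wavelet")), 744)
  # shape block depends on the mask only
  fv2 <- extract_features(rec$modalities$T2, rec$mask, rec$spacing)
  expect_identical(fv[1:14], fv2[1:14])
  # adding a constant leaves every discretized-texture feature unchanged
  fs <- extract_features(rec$modalities$FLAIR + 100, rec$mask, rec$spacing)
  tex <- grepl("original_(glcm|glrlm|glszm|gldm|ngtdm)", names(fv))
  expect_equal(fv[tex], fs[tex], tolerance = 1e-9)
})

test_that("undersized ROIs are rejected with a typed error", {
  vol <- array(runif(8^3), c(8, 8, 8))
  mask <- array(0L, c(8, 8, 8)); mask[4:5, 4, 4] <- 2L  # 2 voxels < min_voxels
  expect_error(extract_features(vol, mask), class = "empty_roi")
})

test_that("the shipped registry CSV matches feature_registry()", {
  f <- system.file("extdata", "feature_registry.csv", package = "edemagrade")
  expect_true(nzchar(f))
  shipped <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(shipped$name, feature_registry()$name)
})
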