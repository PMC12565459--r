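test_that("MLD matches a brute-force directional-sum oracle", {
  expect_equal(max_local_difference(matrix(3, 6, 6)), matrix(0, 6, 6))
  # single bright pixel: maximum at the pixel itself
  img <- matrix(0, 5, 5); img[3, 3] <- 10
  mld <- max_local_difference(img)
  expect_equal(which(mld == max(mld)), 13L)  # centre of the 5x5
  # shift invariance
  set.seed(1)
  x <- matrix(runif(49), 7, 7)
  expect_equal(max_local_difference(x), max_local_difference(x + 17.3))
  # brute-force oracle on a random 5x5 (interior pixels)
  oracle_mld <- function(m, i, j) {
    g <- function(a, b) m[min(max(a, 1), nrow(m)), min(max(b, 1), ncol(m))]
    s <- c(g(i, j - 1) + g(i, j) + g(i, j + 1),
           g(i - 1, j) + g(i, j) + g(i + 1, j),
           g(i - 1, j - 1) + g(i, j) + g(i + 1, j + 1),
           g(i - 1, j + 1) + g(i, j) + g(i + 1, j - 1))
    max(abs(3 * m[i, j] - s))
  }
  m <- matrix(runif(25, 0, 255), 5, 5)
  got <- max_local_difference(m)
  for (i in 1:5) for (j in 1:5) expect_equal(got[i, j], oracle_mld(m, i, j))
  expect_error(max_local_difference(array(0, c(2, 2, 2))), class = "shape_error")
})

test_that("GDIE lifts edges more than flat regions and respects its bounds", {
  cfg <- fusion_config()
  cc <- matrix(4, 10, 10)
  expect_equal(gdie_enhance(cc, cfg), cc)
  # omega1 == omega2 collapses to a uniform gain over the detail layer
  cfg_u <- fusion_config(omega1 = 0.7, omega2 = 0.7)
  set.seed(2)
  x <- matrix(runif(64, 0, 255), 8, 8)
  detail <- x - edemagrade:::conv3x3_replicate(x) / 9
  expect_equal(gdie_enhance(x, cfg_u) - x, 0.7 * detail, tolerance = 1e-12)
  # step edge: edge-adjacent lift exceeds flat-region lift
  step <- cbind(matrix(0, 16, 8), matrix(200, 16, 8))
  h <- gdie_enhance(step, fusion_config(omega1 = 1.5, omega2 = 0.3))
  lift <- abs(h - step)
  edge_cols <- 7:10; flat_cols <- c(1:4, 13:16)
  expect_gte(mean(lift[, edge_cols]), mean(lift[, flat_cols]))
  # larger omega1 cannot reduce edge amplitude
  h2 <- gdie_enhance(step, fusion_config(omega1 = 2.5, omega2 = 0.3))
  expect_gte(mean(abs(h2 - step)[, edge_cols]), mean(lift[, edge_cols]))
  expect_error(fusion_config(omega1 = 0), class = "invalid_parameter")
})

test_that("Laplacian pyramid halves shapes and inverts exactly", {
  set.seed(3)
  x <- matrix(runif(64 * 64, 0, 255), 64)
  p <- lp_decompose(x, 3)
  expect_equal(vapply(p$highs, nrow, integer(1)), c(64L, 32L, 16L))
  expect_identical(dim(p$low), c(8L, 8L))
  expect_lt(max(abs(lp_reconstruct(p) - x)), 1e-6 * diff(range(x)))
  # constant image: zero high bands, constant low band
  pc <- lp_decompose(matrix(7, 32, 32), 3)
  for (h in pc$highs) expect_lt(max(abs(h)), 1e-10)
  expect_equal(as.vector(pc$low), rep(7, 16), tolerance = 1e-12)
  # ramp restored
  ramp <- matrix(seq(0, 255, length.out = 48), 48, 48)
  expect_lt(max(abs(lp_reconstruct(lp_decompose(ramp, 3)) - ramp)), 1e-6 * 255)
  # zero pyramid reconstructs to zero
  pz <- lp_decompose(matrix(0, 32, 32), 2)
  expect_equal(lp_reconstruct(pz), matrix(0, 32, 32))
  # odd sizes still round-trip
  xo <- matrix(runif(37 * 51), 37, 51)
  expect_lt(max(abs(lp_reconstruct(lp_decompose(xo, 2)) - xo)), 1e-9)
  # expansion of a pure low band roughly preserves the mean
  pl <- lp_decompose(matrix(5, 64, 64), 3)
  for (k in 1:3) pl$highs[[k]] <- pl$highs[[k]] * 0
  expect_equal(mean(lp_reconstruct(pl)), 5, tolerance = 0.01)
  expect_error(lp_decompose(matrix(0, 4, 4), 3), class = "invalid_parameter")
})

test_that("DGR splits bands additively with sensible overlap maps", {
  set.seed(4)
  l_a <- matrix(rnorm(256), 16)
  l_b <- matrix(rnorm(256), 16)
  dom <- dgr_decompose(l_a, l_b)
  expect_equal(dom$od_a + dom$nod_a, l_a)
  expect_equal(dom$od_b + dom$nod_b, l_b)
  expect_true(all(dom$overlap %in% c(0, 1)))
  # nothing co-occurs with a zero band
  dom0 <- dgr_decompose(l_a, matrix(0, 16, 16))
  expect_equal(sum(dom0$overlap), 0)
  expect_equal(dom0$nod_a, l_a)
  # identical large-amplitude bands overlap everywhere
  big <- matrix(c(5, -5), 16, 16)
  domi <- dgr_decompose(big, big)
  expect_equal(sum(domi$overlap), 256)
  expect_equal(domi$nod_a, matrix(0, 16, 16))
  # disjoint supports: no overlap, NOD equals the inputs
  left <- cbind(matrix(rnorm(128, sd = 10), 16, 8), matrix(0, 16, 8))
  right <- cbind(matrix(0, 16, 8), matrix(rnorm(128, sd = 10), 16, 8))
  domd <- dgr_decompose(left, right)
  expect_equal(sum(domd$overlap), 0)
  expect_equal(domd$nod_a, left)
  expect_equal(domd$nod_b, right)
  expect_error(dgr_decompose(l_a, matrix(0, 8, 8)), class = "shape_error")
})

test_that("LEM low-band fusion matches a brute-force windowed-energy oracle", {
  g <- matrix(1:64, 8, 8)
  expect_equal(fuse_low_lem(g, g), g)
  expect_equal(fuse_low_lem(g * 3, g), g * 3)   # uniformly larger magnitude
  set.seed(5)
  g_a <- matrix(rnorm(64), 8); g_b <- matrix(rnorm(64), 8)
  got <- fuse_low_lem(g_a, g_b)
  energy <- function(m, i, j) {
    s <- 0
    for (di in -1:1) for (dj in -1:1)
      s <- s + abs(m[min(max(i + di, 1), 8), min(max(j + dj, 1), 8)])
    s
  }
  for (i in 1:8) for (j in 1:8)
    expect_equal(got[i, j],
                 if (energy(g_a, i, j) >= energy(g_b, i, j)) g_a[i, j] else g_b[i, j])
  expect_error(fuse_low_lem(g_a, g_b, matrix(1, 2, 2)), class = "invalid_parameter")
})

test_that("overlap fusion follows the LDM decision graph; NOD fusion is addition", {
  set.seed(6)
  l_a <- matrix(rnorm(64, sd = 4), 8); l_b <- matrix(rnorm(64, sd = 4), 8)
  dom <- dgr_decompose(l_a, l_b)
  mld_a <- max_local_difference(l_a); mld_b <- max_local_difference(l_b)
  fo <- fuse_overlap(dom, mld_a, mld_b)
  # explicit per-pixel oracle
  lem <- function(m) edemagrade:::conv3x3_replicate(abs(m))
  ldm_a <- mld_a * lem(l_a); ldm_b <- mld_b * lem(l_b)
  for (i in 1:8) for (j in 1:8)
    expect_equal(fo$fused[i, j],
                 if (ldm_a[i, j] >= ldm_b[i, j]) dom$od_a[i, j] else dom$od_b[i, j])
  # dominance and degenerate cases
  fo2 <- fuse_overlap(dom, mld_b + 1e6, mld_b)
  expect_equal(fo2$fused, dom$od_a)
  domi <- dgr_decompose(l_a, l_a)
  expect_equal(fuse_overlap(domi, mld_a, mld_b)$fused,
               fuse_overlap(domi, mld_b, mld_a)$fused)
  expect_error(fuse_overlap(dom, mld_a - 5, mld_b), class = "invalid_input")
  # NOD: simple addition
  expect_equal(fuse_nonoverlap(dom), dom$nod_a + dom$nod_b)
  dz <- dgr_decompose(l_a, matrix(0, 8, 8))
  expect_equal(fuse_nonoverlap(dz), l_a)
})

test_that("slice fusion is deterministic, shape-preserving and side-faithful", {
  cc <- matrix(42, 32, 32)
  expect_equal(lrd_fuse_slice(cc, cc), cc, tolerance = 1e-9)
  set.seed(7)
  a <- matrix(runif(64 * 64, 0, 255), 64)
  b <- matrix(runif(64 * 64, 0, 255), 64)
  f1 <- lrd_fuse_slice(a, b); f2 <- lrd_fuse_slice(a, b)
  expect_identical(dim(f1), dim(a))
  expect_identical(f1, f2)
  expect_error(lrd_fuse_slice(a, b[1:32, 1:32]), class = "shape_error")
  bad <- a; bad[1] <- NA
  expect_error(lrd_fuse_slice(bad, b), class = "invalid_input")
  # structure on opposite halves: each half correlates more with its source
  base <- matrix(runif(64 * 64, 90, 110), 64)
  al <- base; al[, 1:32] <- al[, 1:32] + 120 * (matrix(runif(64 * 32), 64) > 0.5)
  br <- base; br[, 33:64] <- br[, 33:64] + 120 * (matrix(runif(64 * 32), 64) > 0.5)
  fz <- lrd_fuse_slice(al, br)
  expect_gt(cor(as.vector(fz[, 1:32]), as.vector(al[, 1:32])),
            cor(as.vector(fz[, 1:32]), as.vector(br[, 1:32])))
  expect_gt(cor(as.vector(fz[, 33:64]), as.vector(br[, 33:64])),
            cor(as.vector(fz[, 33:64]), as.vector(al[, 33:64])))
})

test_that("volume fusion preserves the grid, spacing and self-identity", {
  rec <- small_subject("HGG", seed = 9)
  v <- rec$modalities$FLAIR
  f <- lrd_fuse_volume(v, v, spacing = rec$spacing)
  expect_identical(dim(f), dim(v))
  expect_equal(attr(f, "spacing"), rec$spacing)
  vs <- edemagrade:::rescale_0_255(v)
  expect_lt(max(abs(f - vs)), 0.01 * 255)
  expect_error(lrd_fuse_volume(v, v[1:10, , ]), class = "coregistration_error")
  expect_error(fuse_subject_pair(rec, "T1+T1"), class = "invalid_parameter")
})
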