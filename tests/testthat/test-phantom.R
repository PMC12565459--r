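test_that("parameter validation rejects degenerate settings", {
  expect_error(phantom_params(volume_shape = c(8, 24, 24)), class = "invalid_parameter")
  expect_error(phantom_params(hgg_fraction = 1), class = "invalid_parameter")
  expect_error(phantom_params(noise_sd = -1), class = "invalid_parameter")
  expect_error(generate_cohort(phantom_params(n_subjects = 5L)),
               class = "invalid_parameter")
  expect_error(generate_cohort(phantom_params(n_subjects = 20L, hgg_fraction = 0.01)),
               class = "invalid_parameter")
})

test_that("a subject carries all four labels, nested shells and a usable edema ROI", {
  rec <- small_subject("HGG", seed = 7)
  expect_setequal(unique(as.vector(rec$mask)), c(0L, 1L, 2L, 4L))
  expect_gte(sum(rec$mask == 2), 64)
  expect_named(rec$modalities, modality_names())
  for (m in rec$modalities) expect_identical(dim(m), dim(rec$mask))
  # geometric nesting: core inside enhancing bounding box inside edema's
  bb <- function(lab) apply(which(rec$mask == lab, arr.ind = TRUE), 2, range)
  b1 <- bb(1); b4 <- bb(4); b2 <- bb(2)
  expect_true(all(b1[1, ] >= b4[1, ]) && all(b1[2, ] <= b4[2, ]))
  expect_true(all(b4[1, ] >= b2[1, ]) && all(b4[2, ] <= b2[2, ]))
  # edema shell voxels outnumber the core
  expect_gt(sum(rec$mask == 2), sum(rec$mask == 1))
  # skull-stripped background is exactly zero
  expect_true(all(rec$modalities$T1[rec$mask == 0 &
    rec$modalities$T1 < .Machine$double.eps] == 0))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_subject(small_params(), "HGG", seed = 42)
  b <- generate_subject(small_params(), "HGG", seed = 42)
  expect_identical(a, b)
  c <- generate_subject(small_params(), "HGG", seed = 43)
  expect_false(identical(a$modalities$FLAIR, c$modalities$FLAIR))
})

test_that("HGG texture is more autocorrelated than LGG when planted that way", {
  pp <- phantom_params(volume_shape = c(32, 32, 32), n_subjects = 10L,
                       edema_texture_lgg = texture_descriptor(1, 140, 15),
                       edema_texture_hgg = texture_descriptor(4, 140, 15),
                       noise_sd = 0)
  lag1_ac <- function(rec) {
    v <- rec$modalities$FLAIR
    sel <- rec$mask == 2
    idx <- which(sel, arr.ind = TRUE)
    idx <- idx[idx[, 1] < dim(sel)[1], , drop = FALSE]
    nxt <- cbind(idx[, 1] + 1L, idx[, 2], idx[, 3])
    ok <- sel[nxt]
    x <- v[idx[ok, , drop = FALSE]]; y <- v[nxt[ok, , drop = FALSE]]
    expect_gt(length(x), 1000)
    cor(x, y)
  }
  expect_gt(lag1_ac(generate_subject(pp, "HGG", seed = 3)),
            lag1_ac(generate_subject(pp, "LGG", seed = 3)))
})

test_that("cohorts honour the HGG fraction and are reproducible", {
  pp <- phantom_params(volume_shape = c(16, 16, 16), n_subjects = 100L,
                       hgg_fraction = 0.81, seed = 5)
  co <- generate_cohort(pp)
  expect_equal(sum(co$manifest$grade == "HGG"), 81)
  expect_equal(sum(co$manifest$grade == "LGG"), 19)
  expect_equal(nrow(co$manifest), 100)
  pp2 <- small_params(seed = 1); pp3 <- small_params(seed = 2)
  c2 <- generate_cohort(pp2); c3 <- generate_cohort(pp3)
  expect_identical(names(c2$manifest), names(c3$manifest))
  expect_false(identical(c2$subjects[[1]]$modalities$FLAIR,
                         c3$subjects[[1]]$modalities$FLAIR))
  # 50/50 split at n = 10
  c10 <- generate_cohort(phantom_params(volume_shape = c(16, 16, 16),
                                        n_subjects = 10L, hgg_fraction = 0.5))
  expect_equal(unname(table(c10$manifest$grade)["HGG"]), 5)
})

test_that("cohorts round-trip through NIfTI identically", {
  pp <- phantom_params(volume_shape = c(16, 16, 16), n_subjects = 10L, seed = 3)
  co <- generate_cohort(pp)
  d1 <- withr::local_tempdir()
  write_cohort(co, d1)
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(man$subject_id, co$manifest$subject_id)
  back <- read_subject(file.path(d1, "sub-001"), "sub-001")
  expect_equal(back$mask, co$subjects[[1]]$mask, ignore_attr = TRUE)
  expect_equal(as.numeric(back$modalities$FLAIR),
               as.numeric(co$subjects[[1]]$modalities$FLAIR), tolerance = 1e-6)
  # identical params give identical bytes on disk
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(pp), d2)
  f1 <- file.path(d1, "sub-001", "sub-001_FLAIR.nii.gz")
  f2 <- file.path(d2, "sub-001", "sub-001_FLAIR.nii.gz")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("the planted edema texture separates grades in GLCM contrast", {
  # scaled-down power check: 20 replicate cohorts, noiseless texture
  set.seed(2024)
  pwr <- replicate(20, {
    seed <- sample.int(1e6, 1)
    pp <- phantom_params(volume_shape = c(20, 20, 20), n_subjects = 10L,
                         noise_sd = 0, seed = seed)
    contrast <- function(grade, s) {
      rec <- generate_subject(pp, grade, seed = s)
      roi <- extract_roi(rec$modalities$FLAIR, rec$mask, roi_spec(), rec$spacing)
      unname(glcm_features(discretize_roi(roi))["glcm_Contrast"])
    }
    seeds <- seed + seq_len(100)
    hgg <- vapply(seeds[1:50], function(s) contrast("HGG", s), numeric(1))
    lgg <- vapply(seeds[51:100], function(s) contrast("LGG", s), numeric(1))
    t.test(hgg, lgg)$p.value < 0.05
  })
  set.seed(NULL)
  expect_gte(mean(pwr), 0.9)
})
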