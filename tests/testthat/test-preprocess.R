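make_gray <- function(m, mmpp = 0.09) ebus_image(m, (dim(m) + 1) / 2, mmpp)

test_that("contrast stretch implements the three-branch map", {
  m <- matrix(seq(0, 255, length.out = 256), 16, 16)
  img <- make_gray(m)
  p <- contrast_params(L = 0.2, H = 0.8, gamma = 2)
  out <- contrast_stretch(img, p)$pixels
  x <- m / 255
  # brute-force per-pixel evaluation of the piecewise definition
  expected <- round(255 * ifelse(x < 0.2, 0, ifelse(x > 0.8, 1, x^2)))
  expect_equal(out, expected)
  # below-threshold branch: a pixel at L/2 maps to 0 for any gamma
  img2 <- make_gray(matrix(255 * 0.1, 4, 4))
  expect_true(all(contrast_stretch(img2, p)$pixels == 0))
})

test_that("identity parameters leave the image unchanged and map is monotone", {
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  img <- make_gray(m)
  expect_equal(contrast_stretch(img, contrast_params(0, 1, 1))$pixels, m)
  for (p in list(contrast_params(0.1, 0.9, 0.5), contrast_params(0.3, 0.6, 2))) {
    xs <- make_gray(matrix(0:255, 16, 16))
    ys <- contrast_stretch(xs, p)$pixels
    expect_true(all(diff(as.vector(ys)[order(as.vector(xs$pixels))]) >= 0))
  }
  expect_error(contrast_params(0.9, 0.2), "L < H")
})

test_that("percentile thresholds widen a gradient image to full range", {
  m <- matrix(0:255, 16, 16)
  img <- make_gray(m)
  p <- percentile_thresholds(img)
  expect_equal(p$L, 0.01, tolerance = 0.01)
  expect_equal(p$H, 0.99, tolerance = 0.01)
  out <- contrast_stretch(img, p)$pixels
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_error(percentile_thresholds(make_gray(matrix(42, 8, 8))), "degenerate")
})

test_that("phantom thresholds straddle the median", {
  ph <- fix_phantom("benign", seed = 41L)
  p <- percentile_thresholds(ph$image)
  med <- median(ph$image$pixels) / 255
  expect_lt(p$L, med)
  expect_gt(p$H, med)
})

test_that("boundary detection recovers a perfect circle within 2 px", {
  n <- 220; ctr <- c(110.5, 110.5)
  rad <- sqrt(outer(((1:n) - ctr[1])^2, ((1:n) - ctr[2])^2, "+"))
  img <- ebus_image(matrix(255 * (rad <= 70), n, n), ctr, 0.09)
  bm <- detect_boundary(img)
  rr <- sqrt(rowSums((bm$boundary -
                        matrix(ctr, nrow(bm$boundary), 2, byrow = TRUE))^2))
  expect_true(all(abs(rr - 70) <= 2 + 1e-9))
  # rotational symmetry: 8 rays fill nearly the same area as 360
  bm8 <- detect_boundary(img, n_rays = 8)
  expect_lt(abs(sum(bm8$mask) / sum(bm$mask) - 1), 0.05)
})

test_that("boundary detection rejects degenerate inputs", {
  dark <- ebus_image(matrix(0, 100, 100), c(50, 50), 0.09)
  expect_error(detect_boundary(dark), "all-dark")
  img <- ebus_image(matrix(255, 100, 100), c(50, 50), 0.09)
  expect_error(detect_boundary(img, n_rays = 4), "n_rays")
})

test_that("ROI extraction is a pixel-wise AND with the mask", {
  m <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  img <- make_gray(m)
  ones <- lesion_mask(matrix(1L, 10, 10))
  zeros <- lesion_mask(matrix(0L, 10, 10))
  half <- lesion_mask(matrix(rep(c(1L, 0L), each = 50), 10, 10))
  expect_equal(extract_roi(img, ones)$pixels, m)
  expect_true(all(extract_roi(img, zeros)$pixels == 0))
  hp <- extract_roi(img, half)$pixels
  expect_true(all(hp[, 6:10] == 0))
  expect_equal(hp[, 1:5], m[, 1:5])
  expect_error(extract_roi(img, lesion_mask(matrix(1L, 5, 5))), "shapes")
})

test_that("patch selection respects ring geometry and the mask", {
  ph <- fix_phantom("benign", seed = 51L)
  # mask entirely outside the ring -> no patches
  far <- matrix(0L, 220, 220); far[1:30, 1:30] <- 1L
  ps0 <- select_patches(ph$image, lesion_mask(far))
  expect_equal(ps0$n_patches, 0L)
  # default phantom geometry gives between one and fourteen windows
  ps <- select_patches(ph$image, ph$mask)
  expect_gte(ps$n_patches, 1L)
  expect_lte(ps$n_patches, 14L)
  # each patch's corners lie inside ring-and-mask
  rad <- sqrt(outer(((1:220) - ph$image$probe_center[1])^2,
                    ((1:220) - ph$image$probe_center[2])^2, "+"))
  okm <- rad >= 2 / 0.09 & rad <= 5 / 0.09 & ph$mask$mask == 1L
  for (i in seq_len(ps$n_patches)) {
    r0 <- ps$origins$row[i]; c0 <- ps$origins$col[i]
    expect_true(all(okm[c(r0, r0 + 31), c(c0, c0 + 31)]))
  }
  # windows are pairwise non-overlapping
  if (ps$n_patches > 1) {
    org <- as.matrix(ps$origins)
    for (i in 1:(nrow(org) - 1)) for (j in (i + 1):nrow(org)) {
      expect_true(any(abs(org[i, ] - org[j, ]) >= 32))
    }
  }
})

test_that("greedy tiling matches the exhaustive oracle on random masks", {
  for (s in 1:20) {
    ok <- random_blob_mask(70, seed = 700 + s) == 1L
    got <- tile_windows(ok, 16L)
    want <- oracle_tile(ok, 16L)
    expect_equal(unname(got), unname(want))
  }
})

test_that("augmentation applies the class-asymmetric op sets", {
  co <- generate_cohort(2, 1, seed = 6L, image_size_px = 180)
  co$records$split <- c("train", "test", "train")  # 1 mal train, 1 ben train
  aug <- augment_cohort(co)
  rec <- aug$records
  expect_equal(sum(rec$label == "malignant" & rec$split == "train"), 3L)  # 1 -> 3
  expect_equal(sum(rec$label == "benign" & rec$split == "train"), 5L)     # 1 -> 5
  expect_equal(sum(rec$split == "test"), 1L)   # test untouched
  expect_error(augment_cohort(co, split = "test"), "train split only")
  # rotating the 90-degree output three more times reproduces the original
  orig <- co$images[[1]]$pixels
  r <- orig
  for (k in 1:4) r <- ebusemble:::rot90cw(r)
  expect_identical(r, orig)
  r90 <- aug$images[[which(rec$id == paste0(rec$id[1], "_rot90"))]]$pixels
  expect_identical(ebusemble:::rot90cw(ebusemble:::rot90cw(ebusemble:::rot90cw(r90))), orig)
  # masks are transformed consistently with their images
  i180 <- which(rec$id == paste0(rec$id[1], "_rot180"))
  expect_identical(aug$masks[[i180]]$mask, ebusemble:::rot180(co$masks[[1]]$mask))
})

test_that("augmenting an empty training split is a no-op", {
  co <- generate_cohort(1, 1, seed = 8L, image_size_px = 180)
  co$records$split <- c("test", "test")
  aug <- augment_cohort(co)
  expect_equal(nrow(aug$records), 2L)
})
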