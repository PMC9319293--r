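test_that("quantization bins the in-mask range into equal-width slabs", {
  m1 <- matrix(1L, 4, 4)
  expect_true(all(quantize_gray(matrix(7, 4, 4), m1, 32)[m1 == 1] == 1L))
  two <- matrix(c(0, 255, 0, 255), 2, 2)
  expect_setequal(unique(as.vector(quantize_gray(two, matrix(1L, 2, 2), 2))), c(1L, 2L))
  # linear ramp: level k covers exactly the k-th equal-width intensity slab
  ramp <- matrix(seq(0, 100, length.out = 64), 8, 8)
  q <- quantize_gray(ramp, matrix(1L, 8, 8), 32)
  expected <- pmin(floor(ramp / 100 * 32) + 1, 32)
  expect_equal(as.vector(q), as.vector(expected))
  expect_error(quantize_gray(ramp, matrix(0L, 8, 8)), "empty mask")
})

test_that("GLCM pair counting matches hand enumeration", {
  g <- matrix(c(1L, 2L, 1L, 2L), 2, 2)  # rows: (1,1) / (2,2)
  P <- glcm_matrix(g, c(0L, 1L), n_levels = 2)
  expect_equal(P, matrix(c(2, 0, 0, 2), 2, 2))
  cb <- matrix(c(1L, 2L, 2L, 1L), 2, 2)  # checkerboard
  Pcb <- glcm_matrix(cb, c(0L, 1L), n_levels = 2)
  expect_equal(diag(Pcb), c(0, 0))
  fcb <- ebusemble:::glcm_features_one(Pcb / sum(Pcb))
  expect_equal(unname(fcb["Contrast"]), 1)  # maximal for 2 adjacent levels
  expect_error(glcm_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2)), "2 pixels")
})

test_that("normalized GLCM sums to 1 and symmetrized GLCM is symmetric", {
  set.seed(3)
  for (k in 1:10) {
    q <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    if (sum(q > 0) < 4) next
    P <- glcm_matrix(q, c(-1L, 1L), n_levels = 3, normalize = TRUE)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
})

test_that("constant region takes the documented degenerate values", {
  q <- matrix(1L, 5, 5)
  f <- glcm_features(q, n_levels = 2)
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["JointEntropy"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Correlation"]), 0)  # convention for sigma = 0
  r <- glrlm_features(q, n_levels = 2)
  # one maximal run per line in each direction, all at one gray level
  expect_equal(unname(r["RunPercentage"]),
               mean(c(5, 5, 9, 9)) / 25)
  expect_equal(unname(r["GrayLevelVariance"]), 0)
})

test_that("AWS matches its defining formula", {
  # symmetric matrix: S_U = S_L, so AWS = S_U
  P <- matrix(c(0.2, 0.1, 0.1, 0.6), 2, 2)
  expect_equal(aws_feature(P), 0.1)
  # diagonal-only: homogeneous, AWS = 0
  expect_equal(aws_feature(diag(c(0.5, 0.3, 0.2))), 0)
  # hand-evaluated asymmetric 3x3 case
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- 0.3; P3[1, 3] <- 0.1; P3[2, 1] <- 0.1; P3[3, 1] <- 0.2
  P3[2, 2] <- 0.3
  su <- 0.3 * 1 + 0.1 * 2          # 0.5
  sl <- 0.1 * 1 + 0.2 * 2          # 0.5
  w <- su / (su + sl)
  expect_equal(aws_feature(P3), w * su + (1 - w) * sl)
  expect_equal(aws_feature(P3), oracle_aws(P3))
})

test_that("feature banks have the canonical sizes and unique names", {
  set.seed(5)
  q <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
  tex <- texture_features(q, 3)
  expect_length(tex, 75L)
  expect_false(any(duplicated(names(tex))))
  expect_true(all(is.finite(tex)))
  nm <- ebus_feature_names()
  expect_length(nm, 89L)
  expect_false(any(duplicated(nm)))
})

test_that("angle-averaged features are invariant to exact 90-degree rotation", {
  set.seed(8)
  q <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
  qr <- ebusemble:::rot90cw(q)
  expect_equal(glcm_features(q, 4), glcm_features(qr, 4), tolerance = 1e-9)
  expect_equal(glrlm_features(q, 4), glrlm_features(qr, 4), tolerance = 1e-9)
  expect_equal(gldm_features(q, 4), gldm_features(qr, 4), tolerance = 1e-9)
  expect_equal(glszm_features(q, 4), glszm_features(qr, 4), tolerance = 1e-9)
  expect_equal(ngtdm_features(q, 4), ngtdm_features(qr, 4), tolerance = 1e-9)
})

test_that("shape features match analytic values on simple figures", {
  n <- 121
  rad <- sqrt(outer(((1:n) - 61)^2, ((1:n) - 61)^2, "+"))
  circ <- matrix(as.integer(rad <= 40), n, n)
  f <- shape_features(circ)
  expect_equal(unname(f["PixelArea"]), pi * 40^2, tolerance = 0.02)
  expect_gt(unname(f["Sphericity"]), 0.9)
  expect_lt(unname(f["Sphericity"]), 1.05)
  expect_equal(unname(f["MaximumDiameter"]), 80, tolerance = 0.04)
  expect_equal(unname(f["EquivalentDiameter"]), 80, tolerance = 0.02)
  expect_equal(unname(f["Elongation"]), 1, tolerance = 0.02)
  # isoperimetric ordering: a square is less circular than a circle
  sq <- matrix(0L, n, n); sq[25:95, 25:95] <- 1L
  expect_lt(shape_features(sq)["Sphericity"], f["Sphericity"])
  # degenerate single-pixel mask
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  f1 <- shape_features(one)
  expect_equal(unname(f1["MaximumDiameter"]), 0)
  expect_equal(unname(f1["PixelArea"]), 1)
  expect_error(shape_features(matrix(0L, 5, 5)), "empty")
})

test_that("the assembled vector has 89 named entries and no NaN", {
  ph <- fix_phantom("benign", seed = 61L)
  rec <- list(gender = "female", smoking = "ex-smoker", age = 55,
              lesion_size = "<3cm")
  v <- assemble_features(ph$image, ph$mask, rec)
  expect_length(v, 89L)
  expect_identical(names(v), ebus_feature_names())
  expect_false(anyNA(v))
  # two identical lesions differing only in age differ only at the age entry
  rec2 <- rec; rec2$age <- 70
  v2 <- assemble_features(ph$image, ph$mask, rec2)
  d <- which(v != v2)
  expect_identical(names(v)[d], "clin_age")
  expect_error(assemble_features(ph$image, ph$mask, rec[-2]), "clinical")
})

test_that("a constant-intensity lesion yields finite degenerate features", {
  flat <- ebus_image(matrix(128, 80, 80), c(40, 40), 0.09)
  mask <- lesion_mask(matrix(as.integer(
    sqrt(outer(((1:80) - 40)^2, ((1:80) - 40)^2, "+")) <= 25), 80, 80))
  v <- radiomics_features(flat, mask)
  expect_false(anyNA(v))
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["aws_AWS"]), 0)
})
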