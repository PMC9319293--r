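test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(image_size_px = 220, class_label = "malignant",
                     lesion_radius_mm = 8.5, rng_seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$mask, b$mask$mask)
  sp2 <- sp; sp2$rng_seed <- 8L
  expect_false(identical(generate_phantom(sp2)$image$pixels, a$image$pixels))
})

test_that("phantom spec validation rejects bad geometry", {
  expect_error(phantom_spec(image_size_px = 32), "image_size_px")
  expect_error(phantom_spec(mm_per_px = 0), "mm_per_px")
  # lesion too small to hold a 32x32 window inside the 2-5 mm ring
  sp <- phantom_spec(image_size_px = 220, lesion_radius_mm = 2.5, rng_seed = 1L)
  expect_error(generate_phantom(sp), "ring")
})

test_that("homogeneous phantom has near-constant per-patch variance", {
  ph <- fix_phantom("benign", seed = 21L)
  ps <- select_patches(ph$image, ph$mask)
  expect_gt(ps$n_patches, 1L)
  vs <- vapply(ps$patches, function(p) var(as.vector(p)), numeric(1))
  expect_lt(max(vs) / min(vs), 3)  # stationary speckle: same order throughout
})

test_that("malignant phantoms have higher mean per-patch GLCM contrast", {
  # quantize on the absolute 8-bit scale so patch contrast compares
  # heterogeneity, not each patch's own dynamic range
  contrast_of <- function(cls, seeds) {
    mean(vapply(seeds, function(s) {
      ph <- fix_phantom(cls, seed = s)
      ps <- select_patches(ph$image, ph$mask)
      mean(vapply(ps$patches, function(p) {
        q <- matrix(pmin(floor(p / 256 * 16) + 1L, 16L), 32, 32)
        unname(glcm_features(q, 16)["Contrast"])
      }, numeric(1)))
    }, numeric(1)))
  }
  seeds <- 101:150
  expect_gt(contrast_of("malignant", seeds), 1.3 * contrast_of("benign", seeds))
})

test_that("texture is painted only inside the mask", {
  ph <- fix_phantom("malignant", seed = 31L)
  outside <- ph$image$pixels[ph$mask$mask == 0L]
  inside <- ph$image$pixels[ph$mask$mask == 1L]
  # background is dark; lesion (plus probe) is bright
  expect_lt(quantile(outside, 0.99), 60)
  expect_gt(mean(inside), 80)
})

test_that("cohort metadata follows the class-conditional distributions", {
  co <- generate_cohort(124, 76, seed = 5L, image_size_px = 180)
  rec <- co$records
  expect_equal(nrow(rec), 200L)
  expect_true(all(rec$age >= 17 & rec$age <= 86))
  expect_setequal(unique(rec$gender), c("male", "female"))
  expect_true(all(rec$smoking %in% c("non-smoker", "smoker", "ex-smoker")))
  m_age <- rec$age[rec$label == "malignant"]
  se <- 13.21 / sqrt(124)
  expect_lt(abs(mean(m_age) - 64.32), 3 * se)
  # stratified 80:20 split matching the published training counts
  expect_equal(sum(rec$split == "train" & rec$label == "malignant"), 99L)
  expect_equal(sum(rec$split == "train" & rec$label == "benign"), 61L)
  # aligned containers
  expect_length(co$images, 200L)
  expect_length(co$masks, 200L)
  expect_identical(vapply(co$images, function(i) i$id, character(1)), rec$id)
})

test_that("single-class and empty cohorts are handled", {
  co <- generate_cohort(0, 10, seed = 2L, image_size_px = 180)
  expect_true(all(co$records$label == "benign"))
  expect_equal(sum(co$records$split == "train"), 8L)
  expect_error(generate_cohort(-1, 5), "counts")
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(3, 3, seed = 9L, image_size_px = 180)
  b <- generate_cohort(3, 3, seed = 9L, image_size_px = 180)
  expect_identical(a$records, b$records)
  expect_identical(a$images[[2]]$pixels, b$images[[2]]$pixels)
})

test_that("cohorts round-trip through PNG + CSV", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(2, 2, seed = 4L, image_size_px = 180)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  back <- read_cohort(dir)
  expect_equal(back$records$id, co$records$id)
  expect_equal(back$images[[1]]$pixels, co$images[[1]]$pixels)
  expect_equal(back$masks[[3]]$mask, co$masks[[3]]$mask)
})
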