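# Class-conditional clinical metadata distributions for the synthetic cohort:
# counts observed in the 124-malignant / 76-benign study population.
.clinical_dist <- list(
  malignant = list(n = 124, male = 74, age_mean = 64.32, age_sd = 13.21,
                   size_ge3 = 75, smoking = c(non = 52, current = 35, ex = 37)),
  benign = list(n = 76, male = 29, age_mean = 57.63, age_sd = 15.51,
                size_ge3 = 38, smoking = c(non = 29, current = 27, ex = 20))
)

rtruncnorm1 <- function(n, mean, sd, lo = 17, hi = 86) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)], 1)
}

sample_records <- function(n, label) {
  d <- .clinical_dist[[label]]
  data.frame(
    gender = sample(c("male", "female"), n, replace = TRUE,
                    prob = c(d$male, d$n - d$male)),
    smoking = sample(c("non-smoker", "smoker", "ex-smoker"), n, replace = TRUE,
                     prob = d$smoking[c("non", "current", "ex")]),
    age = rtruncnorm1(n, d$age_mean, d$age_sd),
    lesion_size = sample(c(">=3cm", "<3cm"), n, replace = TRUE,
                         prob = c(d$size_ge3, d$n - d$size_ge3)),
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic EBUS cohort
#'
#' Draws `n_malignant + n_benign` phantom frames with ground-truth masks and
#' class-conditional patient metadata (gender, smoking history, truncated-
#' normal age in `[17, 86]`, and lesion-size category, with the class means
#' and proportions of the study population). The mean lesion radius of each
#' phantom is drawn conditional on its lesion-size category. Rows are
#' stratified 80:20 into train and test.
#'
#' @param n_malignant,n_benign class counts (>= 0); defaults are the study's
#'   124 and 76.
#' @param seed integer seed; every image gets a derived sub-seed, so the
#'   cohort is a pure function of `seed`.
#' @param image_size_px frame side in px (default 776).
#' @param mm_per_px pixel spacing (default 0.09).
#' @return An `ebus_cohort`: list with `images` (list of [ebus_image()]),
#'   `masks` (list of [lesion_mask()]), and `records` (data.frame with
#'   `id, gender, smoking, age, lesion_size, label, split`), all
#'   index-aligned.
#' @export
generate_cohort <- function(n_malignant = 124L, n_benign = 76L, seed = 1L,
                            image_size_px = 776L, mm_per_px = 0.09) {
  if (n_malignant < 0 || n_benign < 0) stop("counts must be >= 0")
  set.seed(seed)
  labels <- c(rep("malignant", n_malignant), rep("benign", n_benign))
  n <- length(labels)
  rec <- do.call(rbind, c(
    if (n_malignant > 0) list(sample_records(n_malignant, "malignant")),
    if (n_benign > 0) list(sample_records(n_benign, "benign"))))
  if (is.null(rec)) rec <- data.frame(gender = character(0), smoking = character(0),
                                      age = numeric(0), lesion_size = character(0),
                                      label = character(0))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  # lesion radius (mm) conditional on size category (<3 cm vs >=3 cm diameter)
  radius_mm <- ifelse(rec$lesion_size == "<3cm", runif(n, 8, 14), runif(n, 15, 26))
  split <- rep("test", n)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_tr <- round(0.8 * length(idx))
    split[sample(idx, n_tr)] <- "train"
  }
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(image_size_px = image_size_px, mm_per_px = mm_per_px,
                       class_label = labels[i], lesion_radius_mm = radius_mm[i],
                       rng_seed = sub_seeds[i])
    ph <- generate_phantom(sp)
    ph$image$id <- sprintf("%s_%03d", substr(labels[i], 1, 3), i)
    images[[i]] <- ph$image
    masks[[i]] <- ph$mask
  }
  rec <- cbind(id = vapply(images, function(im) im$id, character(1),
                           USE.NAMES = FALSE)[seq_len(n)],
               rec, split = split, stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  structure(list(images = images, masks = masks, records = rec),
            class = "ebus_cohort")
}

#' @export
print.ebus_cohort <- function(x, ...) {
  cat(sprintf("<ebus_cohort> %d images (%d malignant / %d benign), %d train / %d test\n",
              length(x$images), sum(x$records$label == "malignant"),
              sum(x$records$label == "benign"),
              sum(x$records$split == "train"), sum(x$records$split == "test")))
  invisible(x)
}

# the class-asymmetric op lists: malignant images are rotated but not flipped
.aug_ops <- list(malignant = c("rot90", "rot180"),
                 benign = c("rot90", "rot180", "fliph", "flipv"))

augment_one <- function(image, mask, op) {
  d <- dim(image$pixels)
  img <- image
  img$pixels <- transform_pixels(image$pixels, op)
  img$probe_center <- transform_point(image$probe_center, op, d[1], d[2])
  img$id <- paste0(image$id, "_", op)
  msk <- mask
  if (!is.null(mask)) {
    msk$mask <- transform_pixels(mask$mask, op)
    if (!is.null(mask$boundary))
      msk$boundary <- t(apply(mask$boundary, 1, transform_point,
                              op = op, H = d[1], W = d[2]))
  }
  list(image = img, mask = msk)
}

#' Class-asymmetric training-set augmentation
#'
#' Each malignant training image yields two extra images (exact 90 and 180
#' degree rotations); each benign training image yields four (the two
#' rotations plus horizontal and vertical flips), balancing the classes.
#' Masks, probe centres, and metadata are transformed consistently. The test
#' split is never touched.
#'
#' @param cohort an `ebus_cohort`.
#' @param split which split to augment; only `"train"` is legal (augmenting
#'   test data would leak into evaluation).
#' @return The augmented `ebus_cohort`: original rows plus augmented rows
#'   (`split = "train"`, ids suffixed with the op name).
#' @export
augment_cohort <- function(cohort, split = "train") {
  stopifnot(inherits(cohort, "ebus_cohort"))
  if (!identical(split, "train"))
    stop("augmentation is defined for the train split only")
  idx <- which(cohort$records$split == "train")
  images <- cohort$images
  masks <- cohort$masks
  rec <- cohort$records
  for (i in idx) {
    ops <- .aug_ops[[rec$label[i]]]
    for (op in ops) {
      a <- augment_one(cohort$images[[i]], cohort$masks[[i]], op)
      images[[length(images) + 1L]] <- a$image
      masks[[length(masks) + 1L]] <- a$mask
      newrow <- rec[i, , drop = FALSE]
      newrow$id <- a$image$id
      rec <- rbind(rec, newrow)
    }
  }
  rownames(rec) <- NULL
  structure(list(images = images, masks = masks, records = rec),
            class = "ebus_cohort")
}

#' Write / read a cohort as PNG images plus a CSV metadata table
#'
#' Images go to `<dir>/images/<id>.png`, masks to `<dir>/masks/<id>.png`,
#' and metadata to `<dir>/metadata.csv` with header
#' `id,gender,smoking,age,lesion_size,label,split`.
#'
#' @param cohort an `ebus_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ebus_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$images)) {
    id <- cohort$records$id[i]
    write_ebus_png(cohort$images[[i]], file.path(dir, "images", paste0(id, ".png")))
    if (!is.null(cohort$masks[[i]]))
      png::writePNG(cohort$masks[[i]]$mask + 0, file.path(dir, "masks", paste0(id, ".png")))
  }
  write.csv(cohort$records[, c("id", "gender", "smoking", "age", "lesion_size",
                               "label", "split")],
            file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param mm_per_px pixel spacing to attach on read.
#' @export
read_cohort <- function(dir, mm_per_px = 0.09) {
  rec <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  images <- lapply(rec$id, function(id)
    read_ebus_png(file.path(dir, "images", paste0(id, ".png")),
                  mm_per_px = mm_per_px, id = id))
  masks <- lapply(rec$id, function(id) {
    p <- file.path(dir, "masks", paste0(id, ".png"))
    if (file.exists(p)) lesion_mask(round(png::readPNG(p))) else NULL
  })
  structure(list(images = images, masks = masks, records = rec),
            class = "ebus_cohort")
}
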