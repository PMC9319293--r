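# ordered outer-contour polygon of the largest object in a binary mask
mask_contour <- function(m) {
  oc <- EBImage::ocontour(EBImage::bwlabel(m))
  if (length(oc) == 0L) return(NULL)
  sizes <- vapply(oc, nrow, integer(1))
  xy <- oc[[which.max(sizes)]]  # (x, y) 0-based = (row-1, col-1) for matrices
  cbind(xy[, 1] + 1, xy[, 2] + 1)
}

polygon_length <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Shape-2D features of a lesion mask
#'
#' Nine planar shape descriptors of the binary mask: pixel area, perimeter
#' (arc length of the outer contour polygon), perimeter-to-area ratio, major
#' and minor axis lengths (4 sqrt of the principal-component eigenvalues of
#' the pixel coordinates), elongation (minor/major ratio's square root form,
#' `sqrt(lambda_minor / lambda_major)`), sphericity (2-D circularity,
#' `2 sqrt(pi A) / P`), maximum 2-D diameter (largest pairwise distance
#' between contour vertices), and equivalent circular diameter
#' (`2 sqrt(A / pi)`).
#'
#' Degenerate conventions: a single-pixel mask has maximum diameter 0 and its
#' perimeter falls back to the 4 exposed pixel edges.
#'
#' @param mask a [lesion_mask()] or binary matrix.
#' @return Named numeric vector of 9 features.
#' @export
shape_features <- function(mask) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  area <- sum(m)
  if (area == 0) stop("empty mask")
  pts <- mask_contour(m)
  perim <- polygon_length(pts)
  if (perim == 0) perim <- 4 * sqrt(area)  # sub-resolution object
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) >= 2L) {
    cv <- stats::cov(idx)
    ev <- sort(eigen(cv, only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  } else {
    major <- 0; minor <- 0; elong <- 1
  }
  maxdiam <- 0
  if (!is.null(pts) && nrow(pts) >= 2L) {
    hull <- pts[chull(pts), , drop = FALSE]
    if (nrow(hull) >= 2L)
      maxdiam <- sqrt(max(as.vector(stats::dist(hull))^2))
  }
  c(PixelArea = area,
    Perimeter = perim,
    PerimeterAreaRatio = perim / area,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Elongation = elong,
    Sphericity = 2 * sqrt(pi * area) / perim,
    MaximumDiameter = maxdiam,
    EquivalentDiameter = 2 * sqrt(area / pi))
}

#' Canonical 89-feature name vector
#'
#' The fixed, versioned order of the feature vector: 9 shape-2D, 24 GLCM,
#' 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 1 AWS, 4 clinical.
#'
#' @return Character vector of length 89.
#' @export
ebus_feature_names <- function() {
  q <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  tex <- names(texture_features(q))
  c(paste0("shape_", names(shape_features(matrix(1L, 2, 2)))),
    tex, "aws_AWS",
    "clin_gender", "clin_smoking", "clin_age", "clin_lesion_size")
}

#' Radiomics feature vector (85 values) for one lesion
#'
#' Quantizes the in-mask intensities and computes 9 shape + 75 matrix-texture
#' features plus the AWS heterogeneity feature. Computation is restricted to
#' the mask bounding box for speed.
#'
#' @param roi an [ebus_image()] (masked or not; only in-mask pixels are
#'   used) or intensity matrix.
#' @param mask a [lesion_mask()] or binary matrix.
#' @param n_levels gray levels for quantization (default 32).
#' @return Named numeric vector of 85 features.
#' @export
radiomics_features <- function(roi, mask, n_levels = 32L) {
  x <- if (inherits(roi, "ebus_image")) to_gray(roi$pixels) else roi
  m <- if (inherits(mask, "lesion_mask")) mask$mask else matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("empty mask")
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  xb <- x[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mb <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  q <- quantize_gray(xb, mb, n_levels)
  c(prefix_names(shape_features(m), "shape"),
    texture_features(q, max(max(q), 2L)),
    aws_AWS = aws_feature_avg(q, max(max(q), 2L)))
}

# clinical encodings: forest splits are invariant to monotone codes
encode_clinical <- function(record) {
  smoking_code <- c("non-smoker" = 0, "ex-smoker" = 1, "smoker" = 2)
  c(clin_gender = as.numeric(record$gender == "male"),
    clin_smoking = unname(smoking_code[record$smoking]),
    clin_age = as.numeric(record$age),
    clin_lesion_size = as.numeric(record$lesion_size %in% c(">=3cm", ">=3 cm")))
}

#' Assemble the 89-value feature vector
#'
#' Concatenates the 85 radiomics features with the 4 encoded clinical
#' features (gender male=1, smoking ordinal non=0/ex=1/current=2, age in
#' years, lesion size >=3 cm = 1). Order and names are fixed; see
#' [ebus_feature_names()].
#'
#' @inheritParams radiomics_features
#' @param record one patient record (list or single data.frame row with
#'   `gender`, `smoking`, `age`, `lesion_size`).
#' @return Named numeric vector of length 89, no missing values.
#' @export
assemble_features <- function(roi, mask, record, n_levels = 32L) {
  need <- c("gender", "smoking", "age", "lesion_size")
  if (!all(need %in% names(record)) ||
      any(vapply(record[need], function(v) length(v) != 1 || is.na(v), logical(1))))
    stop("missing clinical field")
  out <- c(radiomics_features(roi, mask, n_levels), encode_clinical(record))
  stopifnot(length(out) == 89L, !anyNA(out))
  out
}

#' Feature matrix for a whole cohort
#'
#' Runs enhancement-independent feature assembly per image: each lesion's
#' 89-vector from its (optionally detected) mask plus its clinical row.
#'
#' @param cohort an `ebus_cohort`.
#' @param masks optional list of [lesion_mask()] to use instead of the
#'   cohort's own (e.g. detected masks).
#' @param n_levels gray levels for quantization.
#' @return Numeric matrix, one row per image, 89 named columns.
#' @export
cohort_features <- function(cohort, masks = NULL, n_levels = 32L) {
  if (is.null(masks)) masks <- cohort$masks
  rows <- lapply(seq_along(cohort$images), function(i)
    assemble_features(cohort$images[[i]], masks[[i]],
                      cohort$records[i, ], n_levels))
  out <- do.call(rbind, rows)
  rownames(out) <- cohort$records$id
  out
}
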