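#' Contrast-stretch parameters
#'
#' Thresholds are on the normalized `[0, 1]` intensity scale. The stretch maps
#' intensities below `L` to 0, above `H` to 1, and raises in-band intensities
#' to the power `gamma`.
#'
#' @param L,H low/high normalized thresholds, `0 <= L < H <= 1`.
#' @param gamma positive exponent (default 1).
#' @return A `contrast_params` list.
#' @export
contrast_params <- function(L, H, gamma = 1) {
  if (!(L >= 0 && L < H && H <= 1)) stop("need 0 <= L < H <= 1")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(L = L, H = H, gamma = gamma), class = "contrast_params")
}

#' Contrast stretching
#'
#' Piecewise intensity map on the normalized image: 0 below `L`, 1 above `H`,
#' and `x^gamma` for `L <= x <= H`; the result is rescaled back to 8-bit.
#' The map is non-decreasing for every valid parameter set and is the
#' identity for `L = 0, H = 1, gamma = 1`.
#'
#' @param image a grayscale [ebus_image()].
#' @param params a [contrast_params()].
#' @return An enhanced [ebus_image()].
#' @export
contrast_stretch <- function(image, params) {
  stopifnot(inherits(image, "ebus_image"), inherits(params, "contrast_params"))
  if (!is.matrix(image$pixels)) stop("contrast_stretch expects a grayscale image")
  x <- image$pixels / 255
  y <- x^params$gamma
  y[x < params$L] <- 0
  y[x > params$H] <- 1
  out <- image
  out$pixels <- round(y * 255)
  out
}

#' Percentile contrast thresholds
#'
#' `L` and `H` at the 1st and 99th percentiles of the sorted normalized
#' intensities, the setting that widens a typical EBUS histogram to the full
#' 8-bit range.
#'
#' @param image a grayscale [ebus_image()].
#' @param probs two percentile probabilities (default `c(0.01, 0.99)`).
#' @param gamma exponent passed through to [contrast_params()].
#' @return A [contrast_params()]. Errors on a constant image (degenerate
#'   contrast, `L == H`).
#' @export
percentile_thresholds <- function(image, probs = c(0.01, 0.99), gamma = 1) {
  stopifnot(inherits(image, "ebus_image"))
  x <- as.vector(to_gray(image$pixels)) / 255
  q <- unname(quantile(x, probs))
  if (q[1] >= q[2]) stop("degenerate contrast: image is (near-)constant")
  contrast_params(q[1], q[2], gamma)
}

#' Ray-cast lesion boundary detection
#'
#' Casts `n_rays` equally spaced radial rays from the probe centre. Along each
#' ray the intensity profile is smoothed, and the boundary radius is the first
#' location past the probe disc where the profile stays below `drop_frac`
#' times its running maximum for `persist` consecutive samples. Radii are
#' median-filtered over angle, and the mask is filled by interpolating the
#' boundary radius over angle (so the filled region is exactly
#' `r <= R(theta)`).
#'
#' @param enhanced a grayscale [ebus_image()] (typically contrast-stretched).
#' @param n_rays number of rays (>= 8; default 360).
#' @param min_radius_px radii closer to the probe than this are skipped.
#' @param drop_frac fraction of the running maximum that counts as "outside".
#' @param dark_floor absolute normalized intensity a sample must also fall
#'   below: hypoechoic tissue inside the lesion (e.g. necrosis) stays above
#'   this after contrast stretching, while true background does not.
#' @param persist number of consecutive below-threshold samples required
#'   (samples beyond the image edge count as dark).
#' @param smooth_px moving-average window (px) applied to each profile.
#' @param median_window angular median-filter window (rays, odd).
#' @return A [lesion_mask()] with the boundary polygon.
#' @export
detect_boundary <- function(enhanced, n_rays = 360L, min_radius_px = 12,
                            drop_frac = 0.45, dark_floor = 0.08, persist = 20L,
                            smooth_px = 5L, median_window = 5L) {
  stopifnot(inherits(enhanced, "ebus_image"))
  if (n_rays < 8L) stop("n_rays must be >= 8")
  px <- to_gray(enhanced$pixels) / 255
  if (max(px) < 0.02) stop("all-dark image: no boundary to detect")
  n <- dim(px)
  ctr <- enhanced$probe_center
  rmax <- floor(min(ctr[1] - 1, ctr[2] - 1, n[1] - ctr[1], n[2] - ctr[2]))
  if (rmax <= min_radius_px + persist)
    stop("probe centre too close to the image edge")
  thetas <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  radii_px <- seq_len(rmax)
  # nearest-pixel sampling of all rays at once
  rr <- round(outer(radii_px, -cos(thetas)) + ctr[1])
  cc <- round(outer(radii_px, sin(thetas)) + ctr[2])
  prof <- matrix(px[cbind(as.vector(rr), as.vector(cc))], rmax, n_rays)
  # moving-average smoothing down each profile
  k <- rep(1 / smooth_px, smooth_px)
  prof_s <- apply(prof, 2, function(p) as.vector(stats::filter(p, k, sides = 2)))
  prof_s[is.na(prof_s)] <- prof[is.na(prof_s)]

  radii <- vapply(seq_len(n_rays), function(j) {
    p <- prof_s[, j]
    # running max over lesion radii only: the bright probe disc is excluded
    p0 <- p
    p0[seq_len(min(min_radius_px, rmax))] <- 0
    runmax <- cummax(p0)
    lo <- p < drop_frac * pmax(runmax, 0.05) & p < dark_floor
    lo[seq_len(min(min_radius_px, rmax))] <- FALSE
    lo <- c(lo, rep(TRUE, persist))  # beyond the image edge is dark
    if (persist > 1L) {
      ok <- lo
      for (s in seq_len(persist - 1L))
        ok <- ok & c(lo[-seq_len(s)], rep(TRUE, s))
    } else ok <- lo
    hit <- which(ok[seq_len(rmax)])
    if (length(hit) == 0L) rmax else min(hit[1] - 1, rmax)
  }, numeric(1))

  if (all(radii >= rmax)) stop("no ray exits a bright region: boundary not found")
  # circular median filter over angle
  if (median_window > 1L) {
    h <- median_window %/% 2L
    ext <- c(tail(radii, h), radii, head(radii, h))
    radii <- vapply(seq_len(n_rays),
                    function(j) median(ext[j:(j + 2L * h)]), numeric(1))
  }
  # fill: pixel is inside iff its radius <= angularly interpolated boundary
  rad <- radius_field(n[1], n[2], ctr)
  ang <- angle_field(n[1], n[2], ctr)
  rb_pix <- approx(x = c(thetas, 2 * pi), y = c(radii, radii[1]),
                   xout = as.vector(ang))$y
  mask <- matrix(as.integer(as.vector(rad) <= rb_pix), n[1], n[2])
  bound <- cbind(ctr[1] - radii * cos(thetas), ctr[2] + radii * sin(thetas))
  lesion_mask(mask, boundary = bound)
}

#' Region-of-interest extraction
#'
#' Pixel-wise product (logical AND against the binary mask): outside-mask
#' pixels become 0, in-mask pixels keep their intensity.
#'
#' @param image an [ebus_image()].
#' @param mask a [lesion_mask()] aligned with `image`.
#' @return The masked [ebus_image()].
#' @export
extract_roi <- function(image, mask) {
  stopifnot(inherits(image, "ebus_image"), inherits(mask, "lesion_mask"))
  d <- dim(image$pixels)
  if (!all(d[1:2] == dim(mask$mask))) stop("image and mask shapes differ")
  out <- image
  out$pixels <- apply_planes(image$pixels, function(m) m * mask$mask)
  out
}

#' Annulus ring specification
#'
#' The 2-5 mm annulus around the probe is where echotexture discriminates
#' best; 32 px is the biggest square window that fits within that ring at
#' 0.09 mm/px.
#'
#' @param r_inner,r_outer ring radii in mm (`r_inner < r_outer`).
#' @param patch_side window side in px (>= 1).
#' @return A `ring_spec` list.
#' @export
ring_spec <- function(r_inner = 2, r_outer = 5, patch_side = 32L) {
  if (r_inner >= r_outer) stop("r_inner must be < r_outer")
  if (patch_side < 1) stop("patch_side must be >= 1")
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 patch_side = as.integer(patch_side)), class = "ring_spec")
}

# greedy row-major tiling: accept a window when its four corners are all TRUE
# in `ok` and it does not overlap a previously accepted window.
# Returns a matrix of accepted 1-based (row, col) origins.
tile_windows <- function(ok, side) {
  n <- dim(ok)
  if (n[1] < side || n[2] < side) return(matrix(integer(0), 0, 2))
  s1 <- side - 1L
  nr <- n[1] - s1; nc <- n[2] - s1
  qual <- ok[1:nr, 1:nc, drop = FALSE] &
    ok[1:nr, (1 + s1):n[2], drop = FALSE] &
    ok[(1 + s1):n[1], 1:nc, drop = FALSE] &
    ok[(1 + s1):n[1], (1 + s1):n[2], drop = FALSE]
  cand <- which(t(qual))  # row-major order
  if (length(cand) == 0L) return(matrix(integer(0), 0, 2))
  cr <- (cand - 1L) %/% nc + 1L
  cc <- (cand - 1L) %% nc + 1L
  occ <- matrix(FALSE, n[1], n[2])
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    r0 <- cr[i]; c0 <- cc[i]
    if (!any(occ[r0:(r0 + s1), c0:(c0 + s1)])) {
      occ[r0:(r0 + s1), c0:(c0 + s1)] <- TRUE
      keep[i] <- TRUE
    }
  }
  cbind(row = cr[keep], col = cc[keep])
}

#' Select 32 x 32 patches in the probe annulus
#'
#' Converts the ring radii to pixels via the image's `mm_per_px`, then tiles
#' axis-aligned `patch_side`-square windows greedily in row-major order,
#' keeping a window when all four of its corner pixels lie inside the ring
#' intersected with the lesion mask and it does not overlap an already
#' accepted window. Windows are half-open `[r, r+side) x [c, c+side)` in
#' 0-based terms; origins are reported 1-based.
#'
#' @param image an [ebus_image()] with `mm_per_px` set.
#' @param mask a [lesion_mask()] aligned with `image`.
#' @param ring a [ring_spec()].
#' @return A `patch_set`: list with `origins` (data.frame `row`, `col`),
#'   `patches` (list of `side x side` pixel blocks, or `side x side x 3` for
#'   RGB), `patch_side`, and `image_id`. Zero qualifying windows gives an
#'   empty, flagged set (`n_patches == 0`).
#' @export
select_patches <- function(image, mask, ring = ring_spec()) {
  stopifnot(inherits(image, "ebus_image"), inherits(mask, "lesion_mask"),
            inherits(ring, "ring_spec"))
  d <- dim(image$pixels)
  if (!all(d[1:2] == dim(mask$mask))) stop("image and mask shapes differ")
  rad <- radius_field(d[1], d[2], image$probe_center)
  r_in <- ring$r_inner / image$mm_per_px
  r_out <- ring$r_outer / image$mm_per_px
  ok <- rad >= r_in & rad <= r_out & mask$mask == 1L
  org <- tile_windows(ok, ring$patch_side)
  s1 <- ring$patch_side - 1L
  patches <- lapply(seq_len(nrow(org)), function(i) {
    r0 <- org[i, 1]; c0 <- org[i, 2]
    if (is.matrix(image$pixels)) image$pixels[r0:(r0 + s1), c0:(c0 + s1)]
    else image$pixels[r0:(r0 + s1), c0:(c0 + s1), , drop = FALSE]
  })
  structure(list(origins = data.frame(row = org[, 1], col = org[, 2]),
                 patches = patches, patch_side = ring$patch_side,
                 image_id = image$id, n_patches = nrow(org)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set '%s'> %d windows of %d x %d\n",
              x$image_id, x$n_patches, x$patch_side, x$patch_side))
  invisible(x)
}
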