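#' EBUS image container
#'
#' A single radial-probe EBUS frame. Pixels are stored as a numeric matrix
#' (grayscale) or an H x W x 3 array (RGB) with intensities in `[0, 255]`.
#' The probe sits at `probe_center` (1-based `(row, col)`), and `mm_per_px`
#' calibrates ring geometry in millimetres.
#'
#' @param pixels numeric matrix (gray) or H x W x 3 array (RGB), values in
#'   `[0, 255]`.
#' @param probe_center numeric length-2 `(row, col)`, 1-based, inside the image.
#' @param mm_per_px positive pixel spacing in mm.
#' @param id character image identifier.
#' @return An object of class `ebus_image`.
#' @export
ebus_image <- function(pixels, probe_center, mm_per_px, id = "img") {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L &&
                              dim(pixels)[3] == 3L)))
    stop("pixels must be a matrix or an H x W x 3 array")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  d <- dim(pixels)
  if (probe_center[1] < 1 || probe_center[1] > d[1] ||
      probe_center[2] < 1 || probe_center[2] > d[2])
    stop("probe_center must lie inside the image")
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) stop("mm_per_px must be > 0")
  structure(list(pixels = pixels, probe_center = as.numeric(probe_center),
                 mm_per_px = mm_per_px, id = as.character(id)),
            class = "ebus_image")
}

#' @export
print.ebus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ebus_image '%s'> %d x %d %s, probe at (%.1f, %.1f), %.3f mm/px\n",
              x$id, d[1], d[2], if (length(d) == 3L) "RGB" else "gray",
              x$probe_center[1], x$probe_center[2], x$mm_per_px))
  invisible(x)
}

#' Lesion mask container
#'
#' Binary lesion region aligned with its image, with the enclosing boundary
#' polygon (ordered `(row, col)` vertices).
#'
#' @param mask integer/logical matrix of 0/1.
#' @param boundary optional n x 2 matrix of ordered boundary vertices.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, boundary = NULL) {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  structure(list(mask = mask, boundary = boundary), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d, %d lesion px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# grayscale view of an ebus_image's pixels (ITU-R 601 luma for RGB)
to_gray <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# pixel radius/angle fields about a centre; cached per (dim, centre)
radius_field <- function(nr, nc, center) {
  rr <- matrix(seq_len(nr) - center[1], nr, nc)
  cc <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  sqrt(rr^2 + cc^2)
}

angle_field <- function(nr, nc, center) {
  rr <- matrix(seq_len(nr) - center[1], nr, nc)
  cc <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  (atan2(cc, -rr)) %% (2 * pi)  # 0 points "up", increasing clockwise
}

# Exact lossless 90-degree-family transforms on matrices (and their centres).
rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
fliph <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]  # mirror left-right
flipv <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]  # mirror up-down

apply_planes <- function(pixels, f) {
  if (is.matrix(pixels)) return(f(pixels))
  out <- lapply(seq_len(dim(pixels)[3]), function(k) f(pixels[, , k]))
  array(unlist(out), dim = c(dim(out[[1]]), length(out)))
}

# transform a (row, col) point under the same ops; H, W are the *input* dims
transform_point <- function(p, op, H, W) {
  switch(op,
         identity = p,
         rot90 = c(p[2], H + 1 - p[1]),
         rot180 = c(H + 1 - p[1], W + 1 - p[2]),
         fliph = c(p[1], W + 1 - p[2]),
         flipv = c(H + 1 - p[1], p[2]),
         stop("unknown op"))
}

transform_pixels <- function(pixels, op) {
  f <- switch(op, identity = identity, rot90 = rot90cw, rot180 = rot180,
              fliph = fliph, flipv = flipv, stop("unknown op"))
  apply_planes(pixels, f)
}

#' Read / write EBUS images as 8-bit PNG
#'
#' @param image an `ebus_image`.
#' @param path file path.
#' @return `write_ebus_png` returns `path` invisibly; `read_ebus_png` returns
#'   an `ebus_image` (probe centre defaults to the image centre).
#' @param probe_center,mm_per_px,id metadata attached on read.
#' @export
write_ebus_png <- function(image, path) {
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_ebus_png
#' @export
read_ebus_png <- function(path, probe_center = NULL, mm_per_px = 0.09,
                          id = sub("\\.png$", "", basename(path))) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , seq_len(min(3L, dim(px)[3])), drop = TRUE]
  if (length(dim(px)) == 3L && dim(px)[3] != 3L) px <- px[, , 1]
  px <- round(px * 255)
  if (is.null(probe_center)) probe_center <- (dim(px)[1:2] + 1) / 2
  ebus_image(px, probe_center, mm_per_px, id)
}
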