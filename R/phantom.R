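#' Phantom specification for synthetic EBUS frames
#'
#' Describes one synthetic radial-EBUS frame: a bright probe disc at the image
#' centre, a speckle-textured star-convex lesion surrounding it, and a dark
#' background. Benign lesions carry stationary multiplicative speckle;
#' malignant lesions add hyperechoic dots, hyperechoic arcs, and anechoic
#' (dark) patches — the qualitative echotexture classes that distinguish the
#' two on real B-mode frames.
#'
#' @param image_size_px side of the square frame in pixels (>= 64).
#' @param probe_center `(row, col)` of the probe; defaults to the image centre
#'   (a radial probe sits at the centre by construction).
#' @param probe_radius_mm radius of the bright probe disc (20 MHz miniature
#'   probes are ~1.4 mm across).
#' @param mm_per_px pixel spacing; the default 0.09 makes the 2-5 mm annulus
#'   about 33 px wide, admitting one row of 32 x 32 windows.
#' @param class_label `"benign"` or `"malignant"`.
#' @param lesion_radius_mm mean lesion radius in mm.
#' @param texture_params list with `speckle_sigma` (Gaussian smoothing of the
#'   speckle field, px), `dot_density` (hyperechoic dots per mm^2),
#'   `arc_count` (hyperechoic arcs), `anechoic_fraction` (target fraction of
#'   lesion area covered by dark patches). Zero dot density is permitted
#'   (fully homogeneous texture).
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size_px = 776,
                         probe_center = NULL,
                         probe_radius_mm = 0.7,
                         mm_per_px = 0.09,
                         class_label = c("benign", "malignant"),
                         lesion_radius_mm = 12,
                         texture_params = NULL,
                         rng_seed = 1L) {
  class_label <- match.arg(class_label)
  if (image_size_px < 64) stop("image_size_px must be >= 64")
  if (mm_per_px <= 0) stop("mm_per_px must be > 0")
  if (is.null(probe_center))
    probe_center <- c((image_size_px + 1) / 2, (image_size_px + 1) / 2)
  defaults <- if (class_label == "malignant") {
    list(speckle_sigma = 1.2, dot_density = 0.8, arc_count = 3L,
         anechoic_fraction = 0.06)
  } else {
    list(speckle_sigma = 1.2, dot_density = 0, arc_count = 0L,
         anechoic_fraction = 0)
  }
  if (!is.null(texture_params)) defaults[names(texture_params)] <- texture_params
  structure(list(image_size_px = as.integer(image_size_px),
                 probe_center = probe_center,
                 probe_radius_mm = probe_radius_mm,
                 mm_per_px = mm_per_px,
                 class_label = class_label,
                 lesion_radius_mm = lesion_radius_mm,
                 texture_params = defaults,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# mean-one Rayleigh envelope smoothed with a small Gaussian kernel:
# standard B-mode speckle phantom practice.
speckle_field <- function(nr, nc, sigma_px) {
  s <- sqrt(2 / pi)  # Rayleigh scale with unit mean
  e <- matrix(s * sqrt(-2 * log(runif(nr * nc))), nr, nc)
  if (sigma_px > 0) {
    sz <- 2L * ceiling(2 * sigma_px) + 1L
    brush <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma_px)
    e <- EBImage::filter2(e, brush)
  }
  e
}

# star-convex boundary radius (px) as a function of angle, low-order harmonics
star_radius <- function(theta, r0_px, n_harmonics = 3L, amp_range = c(0.02, 0.08)) {
  r <- rep(1, length(theta))
  for (k in seq_len(n_harmonics)) {
    a <- runif(1, amp_range[1], amp_range[2])
    phi <- runif(1, 0, 2 * pi)
    r <- r + a * sin(k * theta + phi)
  }
  r0_px * r
}

#' Generate one synthetic EBUS phantom
#'
#' Renders the frame described by a [phantom_spec()]: dark speckled
#' background, bright probe disc, and a lesion whose ground-truth mask is
#' returned alongside. Output is a pure function of the spec (including its
#' `rng_seed`).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (an [ebus_image()], 8-bit grayscale) and
#'   `mask` (a [lesion_mask()] with the ground-truth boundary polygon).
#'   Errors with a geometry message if the lesion cannot contain a single
#'   32 x 32 window inside the 2-5 mm ring.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$rng_seed)
  n <- spec$image_size_px
  ctr <- spec$probe_center
  tp <- spec$texture_params
  rad <- radius_field(n, n, ctr)
  ang <- angle_field(n, n, ctr)

  r0 <- spec$lesion_radius_mm / spec$mm_per_px
  r0 <- min(r0, 0.45 * n)  # keep the lesion inside the frame
  thetas <- seq(0, 2 * pi, length.out = 361L)[-361L]
  rb <- star_radius(thetas, r0)
  rb <- pmin(rb, 0.47 * n)
  # per-pixel boundary radius by linear interpolation over angle (periodic)
  rb_pix <- approx(x = c(thetas, 2 * pi), y = c(rb, rb[1]),
                   xout = as.vector(ang))$y
  mask <- matrix(as.integer(as.vector(rad) <= rb_pix), n, n)

  probe_px <- spec$probe_radius_mm / spec$mm_per_px
  probe <- rad <= probe_px
  lesion_tex <- mask == 1L & !probe

  img <- 0.035 * speckle_field(n, n, tp$speckle_sigma)       # background
  les <- 0.45 * speckle_field(n, n, tp$speckle_sigma)        # lesion speckle
  img[lesion_tex] <- les[lesion_tex]

  if (tp$dot_density > 0 || tp$arc_count > 0 || tp$anechoic_fraction > 0) {
    overlay <- matrix(0, n, n)
    lesion_area_mm2 <- sum(lesion_tex) * spec$mm_per_px^2
    # hyperechoic dots: small bright Gaussian bumps
    n_dots <- rpois(1, tp$dot_density * lesion_area_mm2)
    if (n_dots > 0) {
      idx <- which(lesion_tex)
      pick <- idx[sample.int(length(idx), min(n_dots, length(idx)))]
      pr <- (pick - 1L) %% n + 1L
      pc <- (pick - 1L) %/% n + 1L
      for (d in seq_along(pick)) {
        srad <- runif(1, 1.2, 2.2); amp <- runif(1, 0.35, 0.6)
        w <- ceiling(2 * srad)
        rs <- max(1L, pr[d] - w):min(n, pr[d] + w)
        cs <- max(1L, pc[d] - w):min(n, pc[d] + w)
        dd <- outer((rs - pr[d])^2, (cs - pc[d])^2, "+")
        overlay[rs, cs] <- overlay[rs, cs] + amp * exp(-dd / (2 * srad^2))
      }
    }
    # hyperechoic arcs: bright circular segments about the probe
    if (tp$arc_count > 0) {
      for (a in seq_len(tp$arc_count)) {
        rho <- runif(1, 2.5 / spec$mm_per_px, 0.8 * r0)
        th0 <- runif(1, 0, 2 * pi); span <- runif(1, 0.35, 1.0)
        amp <- runif(1, 0.25, 0.4); wid <- 1.3
        dth <- (ang - th0) %% (2 * pi)
        on_arc <- dth <= span
        overlay <- overlay + ifelse(on_arc, amp * exp(-(rad - rho)^2 / (2 * wid^2)), 0)
      }
    }
    overlay[!lesion_tex] <- 0
    img <- img + overlay
    # anechoic patches: dark discs covering ~anechoic_fraction of the lesion
    if (tp$anechoic_fraction > 0) {
      target <- tp$anechoic_fraction * sum(lesion_tex)
      covered <- 0
      idx <- which(lesion_tex)
      guard <- 0L
      while (covered < target && guard < 50L) {
        guard <- guard + 1L
        p <- idx[sample.int(length(idx), 1L)]
        pr <- (p - 1L) %% n + 1L; pc <- (p - 1L) %/% n + 1L
        prad <- runif(1, 1, 2.5) / spec$mm_per_px
        d2 <- (matrix(seq_len(n), n, n) - pr)^2 +
              (matrix(seq_len(n), n, n, byrow = TRUE) - pc)^2
        patch <- d2 <= prad^2 & lesion_tex
        img[patch] <- img[patch] * 0.2
        covered <- covered + sum(patch)
      }
    }
  }

  img[probe] <- 0.95 + 0.03 * (speckle_field(n, n, 0.8)[probe] - 1)
  img <- pmin(pmax(img, 0), 1)
  pixels <- round(img * 255)

  image <- ebus_image(pixels, ctr, spec$mm_per_px,
                      id = sprintf("phantom_%s_%d", spec$class_label, spec$rng_seed))
  bound <- cbind(ctr[1] - rb * cos(thetas), ctr[2] + rb * sin(thetas))
  msk <- lesion_mask(mask, boundary = bound)

  # geometry check: the 2-5 mm ring intersected with the lesion must admit
  # at least one 32 x 32 window, else downstream patch models are starved
  ring_ok <- rad >= 2 / spec$mm_per_px & rad <= 5 / spec$mm_per_px & mask == 1L
  if (nrow(tile_windows(ring_ok, 32L)) == 0L)
    stop("phantom geometry admits no 32x32 window in the 2-5 mm ring")
  list(image = image, mask = msk)
}
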