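# Shared small fixtures, built once per test run. Phantoms are kept small
# (the mm geometry of the 2-5 mm ring is identical at any frame size).

fix_env <- new.env()

fix_phantom <- function(class_label = "malignant", seed = 11L, size = 220L,
                        radius_mm = 8.5) {
  key <- paste(class_label, seed, size, radius_mm)
  if (is.null(fix_env[[key]])) {
    fix_env[[key]] <- generate_phantom(
      phantom_spec(image_size_px = size, class_label = class_label,
                   lesion_radius_mm = radius_mm, rng_seed = seed))
  }
  fix_env[[key]]
}

# deterministic separable patch data: dark smooth vs bright spotty 32x32
toy_patches <- function(n_per_class, seed) {
  set.seed(seed)
  X <- array(0, c(32, 32, 3, 2 * n_per_class))
  y <- rep(c("benign", "malignant"), each = n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    base <- matrix(runif(32 * 32, 0.3, 0.5), 32, 32)
    if (y[i] == "malignant") {
      for (k in 1:6) {
        r <- sample(3:30, 1); c_ <- sample(3:30, 1)
        base[r + (-1:1), c_ + (-1:1)] <- base[r + (-1:1), c_ + (-1:1)] + 0.45
      }
    }
    X[, , , i] <- array(rep(pmin(base, 1), 3), c(32, 32, 3))
  }
  list(X = X, y = y)
}

# deterministic separable 64x64 whole-image data
toy_images <- function(n_per_class, seed) {
  set.seed(seed)
  X <- array(0, c(64, 64, 3, 2 * n_per_class))
  y <- rep(c("benign", "malignant"), each = n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    base <- matrix(runif(64 * 64, 0.2, 0.4), 64, 64)
    if (y[i] == "malignant") base <- base + 0.3
    X[, , , i] <- array(rep(pmin(base, 1), 3), c(64, 64, 3))
  }
  list(X = X, y = y)
}
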