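#' Ensemble configuration
#'
#' Non-negative model weights summing to 1 and a decision cutoff in (0, 1).
#' The defaults are the published operating point of the framework:
#' weights (0.41, 0.08, 0.51) for the tabular, single-image, and patch
#' models, cutoff 0.53.
#'
#' @param weights numeric length-3, `w >= 0`, `sum(w) == 1` (within 1e-9).
#' @param cutoff decision cutoff in (0, 1).
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(weights = c(0.41, 0.08, 0.51), cutoff = 0.53) {
  if (length(weights) != 3L || any(weights < 0)) stop("need 3 non-negative weights")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1 (within 1e-9)")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  structure(list(weights = weights, cutoff = cutoff), class = "ensemble_config")
}

#' Weighted soft-voting fusion
#'
#' `P = w1 P1 + w2 P2 + w3 P3`; the lesion is called malignant exactly when
#' `P > cutoff` (a value equal to the cutoff is benign). When `P3` is
#' undefined for an image (no patches), `(w1, w2)` are renormalized to sum
#' to 1 for that image and the fallback is recorded in the result.
#'
#' @param p1,p2,p3 per-image malignancy probabilities in `[0, 1]`; `p3` may
#'   contain `NA` for images without patches.
#' @param cfg an [ensemble_config()].
#' @return data.frame with `p` (fused probability), `class` (0/1), and
#'   `p3_fallback` (logical).
#' @export
fuse_probs <- function(p1, p2, p3, cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "ensemble_config"))
  if (any(stats::na.omit(c(p1, p2, p3)) < 0) || any(stats::na.omit(c(p1, p2, p3)) > 1))
    stop("probabilities must lie in [0, 1]")
  w <- cfg$weights
  fb <- is.na(p3)
  p <- w[1] * p1 + w[2] * p2 + w[3] * ifelse(fb, 0, p3)
  if (any(fb)) {
    w12 <- w[1] + w[2]
    if (w12 <= 0) stop("P3 undefined and w1 + w2 = 0: cannot renormalize")
    p[fb] <- (w[1] * p1[fb] + w[2] * p2[fb]) / w12
  }
  data.frame(p = p, class = as.integer(p > cfg$cutoff), p3_fallback = fb)
}

#' Grid-search ensemble weight and cutoff optimization
#'
#' Exhaustive search over the weight simplex (step `weight_step`) crossed
#' with a cutoff grid (step `cutoff_step`), maximizing training accuracy.
#' Ties are broken toward the smallest cutoff, then the lexicographically
#' smallest `(w1, w2, w3)`. Because the simplex vertices (1,0,0), (0,1,0),
#' (0,0,1) are on the grid, the optimized training accuracy is never below
#' that of any single model.
#'
#' @param p1,p2,p3 training-set probabilities (NA-free).
#' @param labels training labels (`"benign"`/`"malignant"` or 0/1).
#' @param weight_step,cutoff_step grid steps (default 0.01).
#' @return An [ensemble_config()] with attributes `train_accuracy`.
#' @export
optimize_ensemble <- function(p1, p2, p3, labels, weight_step = 0.01,
                              cutoff_step = 0.01) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(factor(labels, levels = c("benign", "malignant"))) - 1L
  if (length(unique(y)) < 2L) stop("degenerate calibration set: one class only")
  stopifnot(!anyNA(c(p1, p2, p3)))
  steps <- round(1 / weight_step)
  grid <- list()
  k <- 0L
  for (a in 0:steps) for (b in 0:(steps - a)) {
    k <- k + 1L
    grid[[k]] <- c(a, b, steps - a - b) / steps
  }
  W <- do.call(cbind, grid)             # 3 x n_combos, lexicographic in (w1, w2)
  P <- cbind(p1, p2, p3) %*% W          # n_samples x n_combos
  cutoffs <- seq(cutoff_step, 1 - cutoff_step, cutoff_step)
  best <- list(acc = -1, cutoff = NA, w = NULL)
  n <- length(y)
  for (cu in cutoffs) {                 # ascending: first max has smallest cutoff
    pred <- P > cu
    acc <- (colSums(pred[y == 1L, , drop = FALSE]) +
              colSums(!pred[y == 0L, , drop = FALSE])) / n
    j <- which.max(acc)                 # first index = lexicographically smallest w
    if (acc[j] > best$acc + 1e-12) best <- list(acc = acc[j], cutoff = cu, w = W[, j])
  }
  out <- ensemble_config(weights = best$w, cutoff = best$cutoff)
  attr(out, "train_accuracy") <- best$acc
  out
}
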