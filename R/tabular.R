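#' Mutual information between one feature and a binary label
#'
#' Discrete features (factors, characters, logicals, or numerics with at most
#' `discrete_max` distinct values) use the plug-in contingency estimate
#' `sum p log(p / (p_x p_y))` in nats. Continuous features use the Ross
#' (2014) k-nearest-neighbour estimator for a continuous variable against a
#' discrete label, with `k = 3`: digamma-based, consistent, and robust at
#' small sample sizes. Estimates for continuous features can be slightly
#' negative by sampling noise; the population quantity is always >= 0 and is
#' 0 exactly when feature and label are independent.
#'
#' @param x feature vector (numeric or categorical).
#' @param y label vector (two classes).
#' @param k neighbour count for the continuous estimator.
#' @param discrete_max numerics with at most this many distinct values are
#'   treated as discrete.
#' @return MI estimate in nats.
#' @export
mutual_information <- function(x, y, k = 3L, discrete_max = 8L) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (length(unique(y)) < 2L) stop("labels are constant")
  discrete <- is.factor(x) || is.character(x) || is.logical(x) ||
    length(unique(x)) <= discrete_max
  if (discrete) {
    tab <- table(x, y)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    e <- outer(px, py)
    sum(ifelse(p > 0, p * log(p / e), 0))
  } else {
    mi_knn_ross(as.numeric(x), y, k)
  }
}

# Ross (2014) MI estimator for continuous x, discrete y: the radius is the
# distance to the k-th same-class neighbour, m counts the points of any class
# strictly inside that radius (the query point included). The raw estimate is
# unbiased around 0 under independence; negatives are clipped to 0 since the
# population MI is non-negative.
mi_knn_ross <- function(x, y, k = 3L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  nx <- table(ys)
  mvals <- rep(NA_real_, n)
  kvals <- integer(n)
  for (cl in names(nx)) {
    idx <- which(ys == cl)
    kk <- min(k, length(idx) - 1L)
    if (kk < 1L) next
    xc <- xs[idx]
    for (jj in seq_along(idx)) {
      d <- abs(xc - xc[jj])
      r <- sort(d)[kk + 1L]
      i <- idx[jj]
      m <- sum(abs(xs - xs[i]) < r)
      # tied values: the k-th neighbour sits at distance 0, so count the tie
      # group itself (keeps the estimator finite and deterministic)
      if (m == 0L) m <- sum(xs == xs[i])
      mvals[i] <- m
      kvals[i] <- kk
    }
  }
  ok <- !is.na(mvals)
  est <- mean(digamma(n) - digamma(as.numeric(nx[as.character(ys[ok])])) +
                digamma(kvals[ok]) - digamma(mvals[ok]))
  max(est, 0)
}

#' Mutual-information feature selection
#'
#' Scores every column of the feature matrix against the label and keeps
#' features whose MI estimate exceeds a small epsilon (clipping estimator
#' noise around zero). If nothing survives, the single top-scoring feature
#' is kept with a warning.
#'
#' @param x numeric feature matrix (samples x features, named columns).
#' @param y binary label vector.
#' @param epsilon positive-score clip (default `1e-6`).
#' @param k passed to [mutual_information()].
#' @return A `selection_result` data.frame with columns
#'   `feature`, `mi_score`, `selected`.
#' @export
select_features <- function(x, y, epsilon = 1e-6, k = 3L) {
  stopifnot(is.matrix(x) || is.data.frame(x))
  x <- as.matrix(x)
  scores <- vapply(seq_len(ncol(x)), function(j) mutual_information(x[, j], y, k),
                   numeric(1))
  sel <- scores > epsilon
  if (!any(sel)) {
    warning("no feature has positive MI; keeping the top-scoring one")
    sel[which.max(scores)] <- TRUE
  }
  structure(data.frame(feature = colnames(x), mi_score = scores,
                       selected = sel, stringsAsFactors = FALSE),
            class = c("selection_result", "data.frame"))
}

#' Random-forest configuration
#'
#' @param n_trees forest size (default 1000).
#' @param rng_seed seed used when training.
#' @return A `forest_config` list. Splits use the Gini index; with terminal
#'   `nodesize = 1` any node with at least two cases may be split, matching a
#'   minimum split size of two.
#' @export
forest_config <- function(n_trees = 1000L, rng_seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), rng_seed = as.integer(rng_seed)),
            class = "forest_config")
}

#' Train the radiomics + patient-data random forest
#'
#' Bagged forest over the MI-selected feature columns. The predicted
#' malignancy probability is the soft vote: the fraction of trees voting
#' malignant, hence always a rational number with denominator `n_trees`.
#'
#' @param x feature matrix (samples x features; will be restricted to
#'   `selection`'s selected columns when given).
#' @param y labels (`"benign"` / `"malignant"` or factor).
#' @param cfg a [forest_config()].
#' @param selection optional [select_features()] result.
#' @return An `ebus_rf` model object.
#' @export
train_rf <- function(x, y, cfg = forest_config(), selection = NULL) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("benign", "malignant"))
  if (any(table(y) < 2L)) stop("need at least 2 samples in each class")
  if (!is.null(selection)) x <- x[, selection$feature[selection$selected], drop = FALSE]
  set.seed(cfg$rng_seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = cfg$n_trees,
                                    nodesize = 1L, keep.forest = TRUE)
  structure(list(fit = fit, features = colnames(x), cfg = cfg),
            class = "ebus_rf")
}

#' Malignancy probability from the tabular model (P1)
#'
#' @param model an `ebus_rf` from [train_rf()].
#' @param x feature matrix or single named feature vector.
#' @param oob use out-of-bag votes on the training data instead of plain
#'   predictions (only valid when `x` is the training matrix; used for
#'   ensemble weight calibration).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_p1 <- function(model, x, oob = FALSE) {
  stopifnot(inherits(model, "ebus_rf"))
  if (oob) return(unname(model$fit$votes[, "malignant"]))
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!all(model$features %in% colnames(x))) stop("unknown feature names")
  unname(predict(model$fit, x[, model$features, drop = FALSE],
                 type = "prob")[, "malignant"])
}
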