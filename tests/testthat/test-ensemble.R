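test_that("fusion is the stated convex combination with a strict cutoff", {
  cfg <- ensemble_config()  # (0.41, 0.08, 0.51), cutoff 0.53
  expect_equal(sum(cfg$weights), 1)
  # agreement: fuse(p, p, p) = p for any valid weights
  for (p in c(0, 0.3, 0.53, 1)) {
    f <- fuse_probs(p, p, p, cfg)
    expect_equal(f$p, p)
  }
  # worked arithmetic: 0.41*0.9 + 0.08*0.2 + 0.51*0.8 = 0.793 -> malignant
  f <- fuse_probs(0.9, 0.2, 0.8, cfg)
  expect_equal(f$p, 0.793)
  expect_equal(f$class, 1L)
  # the boundary value equals benign (P <= cutoff)
  expect_equal(fuse_probs(0.53, 0.53, 0.53, cfg)$class, 0L)
  # convexity: fused P within [min, max] of the three inputs
  set.seed(2)
  for (k in 1:50) {
    ps <- runif(3)
    w <- diff(c(0, sort(runif(2)), 1))
    f <- fuse_probs(ps[1], ps[2], ps[3], ensemble_config(w, 0.5))
    expect_gte(f$p, min(ps) - 1e-12)
    expect_lte(f$p, max(ps) + 1e-12)
  }
  expect_error(ensemble_config(c(0.5, 0.3, 0.1)), "sum to 1")
  expect_error(ensemble_config(cutoff = 1), "cutoff")
})

test_that("undefined P3 renormalizes the first two weights", {
  cfg <- ensemble_config(c(0.4, 0.1, 0.5), 0.5)
  f <- fuse_probs(c(0.8, 0.8), c(0.3, 0.3), c(0.9, NA), cfg)
  expect_false(f$p3_fallback[1])
  expect_true(f$p3_fallback[2])
  expect_equal(f$p[2], (0.4 * 0.8 + 0.1 * 0.3) / 0.5)
})

test_that("grid optimization dominates single models and breaks ties deterministically", {
  set.seed(5)
  n <- 80
  y <- rep(c("benign", "malignant"), each = n / 2)
  yi <- as.integer(y == "malignant")
  p1 <- pmin(pmax(yi * 0.7 + runif(n) * 0.3, 0), 1)
  p2 <- runif(n)                       # uninformative model
  p3 <- pmin(pmax(yi * 0.5 + runif(n) * 0.5, 0), 1)
  ens <- optimize_ensemble(p1, p2, p3, y)
  acc_of <- function(p) max(vapply(seq(0.01, 0.99, 0.01),
                                   function(cu) mean((p > cu) == (yi == 1)), numeric(1)))
  expect_gte(attr(ens, "train_accuracy"), acc_of(p1))
  expect_gte(attr(ens, "train_accuracy"), acc_of(p2))
  expect_gte(attr(ens, "train_accuracy"), acc_of(p3))
  # the noise model gets (near-)zero weight
  expect_lte(ens$weights[2], 0.05)
  # perfectly agreeing models: deterministic tie-broken result
  e1 <- optimize_ensemble(yi, yi, yi, y)
  e2 <- optimize_ensemble(yi, yi, yi, y)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$cutoff, e2$cutoff)
  expect_equal(attr(e1, "train_accuracy"), 1)
  expect_error(optimize_ensemble(0.5, 0.5, 0.5, "malignant"), "degenerate")
})

test_that("metric arithmetic matches a brute-force recount", {
  set.seed(31)
  for (k in 1:200) {
    n <- sample(5:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    pr <- sample(0:1, n, replace = TRUE)
    m <- eval_metrics(pr, y)
    tp <- 0; fn <- 0; fp <- 0; tn <- 0
    for (i in seq_len(n)) {
      if (y[i] == 1 && pr[i] == 1) tp <- tp + 1
      if (y[i] == 1 && pr[i] == 0) fn <- fn + 1
      if (y[i] == 0 && pr[i] == 1) fp <- fp + 1
      if (y[i] == 0 && pr[i] == 0) tn <- tn + 1
    }
    expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(tp, fn, fp, tn))
    expect_equal(m$accuracy, 100 * (tp + tn) / n)
    if (tp + fn > 0) expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    else expect_true(is.na(m$sensitivity))
    # accuracy identity before rounding
    if (tp + fn > 0 && tn + fp > 0)
      expect_equal(m$accuracy,
                   (m$sensitivity * (tp + fn) + m$specificity * (tn + fp)) / n)
  }
})

test_that("rates are NA, not zero, when a denominator vanishes", {
  m <- eval_metrics(c(0, 0, 0), c(0, 0, 0))  # no malignant truth, no calls
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
  m2 <- eval_metrics(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(m2$specificity))
  expect_true(is.na(m2$npv))
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (k in 1:10) {
    y <- sample(0:1, 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- runif(40) + 0.5 * y
    m <- eval_metrics(as.integer(s > 0.5), y, scores = s)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
    expect_equal(m$auc, ref, tolerance = 1e-9)
  }
  # perfect classifier
  mp <- eval_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), scores = c(0.1, 0.2, 0.8, 0.9))
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$auc, 1)
})
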