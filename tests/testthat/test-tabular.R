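test_that("discrete MI matches closed forms and hand-evaluated tables", {
  y <- rep(c("a", "b"), 100)
  x <- as.integer(y == "b")
  expect_equal(mutual_information(x, y), log(2), tolerance = 1e-9)
  # MI of a binary feature against itself equals its entropy
  x2 <- rep(c(0L, 0L, 0L, 1L), 50)
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(mutual_information(x2, x2), h, tolerance = 1e-9)
  # hand-evaluated 2x2 joint [[0.4, 0.1], [0.1, 0.4]]
  n <- 1000
  x3 <- rep(c(0L, 0L, 1L, 1L), times = n * c(0.4, 0.1, 0.1, 0.4))
  y3 <- rep(c("a", "b", "a", "b"), times = n * c(0.4, 0.1, 0.1, 0.4))
  want <- sum(c(0.4, 0.1, 0.1, 0.4) * log(c(0.4, 0.1, 0.1, 0.4) / 0.25))
  expect_equal(mutual_information(x3, y3), want, tolerance = 1e-9)
  expect_error(mutual_information(x, rep("a", 200)), "constant")
})

test_that("continuous MI estimator vanishes for independent data", {
  set.seed(42)
  y <- rep(c("benign", "malignant"), 1000)
  x <- rnorm(2000)
  expect_lt(abs(mutual_information(x, y)), 0.01)
  # dependent continuous feature scores clearly positive
  xd <- rnorm(2000, mean = ifelse(y == "malignant", 1.5, 0))
  expect_gt(mutual_information(xd, y), 0.2)
})

test_that("MI selection keeps informative columns and flags all-noise input", {
  set.seed(7)
  n <- 500
  y <- rep(c("benign", "malignant"), n / 2)
  X <- matrix(rnorm(n * 89), n, 89,
              dimnames = list(NULL, paste0("f", 1:89)))
  X[, 1:10] <- as.integer(y == "malignant") + X[, 1:10] * 0.01
  sel <- select_features(X, y)
  expect_true(all(sel$selected[1:10]))
  # noise columns sit at (clipped) zero or tiny scores; the informative ones
  # dominate every noise column and only about half the noise survives
  expect_lt(sum(sel$selected[11:89]) / 79, 0.6)
  expect_gt(min(sel$mi_score[1:10]), max(sel$mi_score[11:89]))
  expect_true(all(sel$mi_score >= 0))
  # all-noise: fall back to the single best with a warning
  Xn <- matrix(rep(c(0, 1), 50), 100, 4, dimnames = list(NULL, paste0("n", 1:4)))
  yn <- rep(c("benign", "malignant"), each = 50)
  expect_warning(seln <- select_features(Xn, yn, epsilon = 10), "top-scoring")
  expect_equal(sum(seln$selected), 1L)
  # deterministic
  expect_identical(sel, select_features(X, y))
})

test_that("random forest learns a separable table and gives soft votes", {
  set.seed(11)
  n <- 200
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[y == "malignant", 1] <- X[y == "malignant", 1] + 4
  cfg <- forest_config(n_trees = 500, rng_seed = 3L)
  fit <- train_rf(X, y, cfg)
  p <- predict_p1(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  acc <- mean((p > 0.5) == (y == "malignant"))
  expect_gte(acc, 0.95)
  # soft vote: rational with denominator n_trees
  expect_true(all(abs(p * 500 - round(p * 500)) < 1e-9))
  # label flip symmetry with the same seed
  yf <- ifelse(y == "malignant", "benign", "malignant")
  fitf <- train_rf(X, yf, cfg)
  pf <- predict_p1(fitf, X)
  expect_equal(pf, 1 - p, tolerance = 0.05)
  expect_error(train_rf(X, rep("malignant", n), cfg), "each class")
  expect_error(predict_p1(fit, matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))),
               "unknown feature")
})

test_that("OOB probabilities are available for calibration", {
  set.seed(13)
  n <- 120
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  X[y == "malignant", 1] <- X[y == "malignant", 1] + 3
  fit <- train_rf(X, y, forest_config(n_trees = 300, rng_seed = 5L))
  oob <- predict_p1(fit, X, oob = TRUE)
  expect_length(oob, n)
  expect_true(all(oob >= 0 & oob <= 1))
  expect_gt(mean((oob > 0.5) == (y == "malignant")), 0.9)
})
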