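#' Patch-CNN configuration
#'
#' Four same-padding 3x3 convolution stages with 8, 16, 32 and 64 kernels,
#' each followed by batch normalization, ReLU, 2x2 max pooling and dropout
#' (spatial sizes 32 -> 16 -> 8 -> 4 -> 2), then fully-connected layers of
#' width 256 and 2 with a softmax output. Trained with Adam and
#' cross-entropy on 3 x 32 x 32 patches.
#'
#' @param kernels convolution kernel counts per stage.
#' @param fc_width width of the penultimate fully-connected layer.
#' @param dropout dropout rate after each pool and after the FC layer.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 128).
#' @param epochs training epochs (default 10).
#' @param patch_side input patch side (default 32).
#' @param rng_seed seed for init and shuffling.
#' @return A `patch_cnn_config` list.
#' @export
patch_cnn_config <- function(kernels = c(8L, 16L, 32L, 64L), fc_width = 256L,
                             dropout = 0.25, learning_rate = 0.001,
                             batch_size = 128L, epochs = 10L, patch_side = 32L,
                             rng_seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(kernels = as.integer(kernels), fc_width = as.integer(fc_width),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patch_side = as.integer(patch_side),
                 rng_seed = as.integer(rng_seed)),
            class = "patch_cnn_config")
}

#' Build the patch CNN
#'
#' @param cfg a [patch_cnn_config()].
#' @return An `ebus_patch_cnn` with seeded initial weights (same seed gives
#'   identical initialization).
#' @export
build_patch_cnn <- function(cfg = patch_cnn_config()) {
  stopifnot(inherits(cfg, "patch_cnn_config"))
  layers <- list()
  for (k in cfg$kernels) {
    layers <- c(layers, list(nn_layer_conv(k), nn_layer_bn(), nn_layer_relu(),
                             nn_layer_pool(), nn_layer_dropout(cfg$dropout)))
  }
  layers <- c(layers, list(nn_layer_flatten(), nn_layer_dense(cfg$fc_width),
                           nn_layer_relu(), nn_layer_dropout(cfg$dropout),
                           nn_layer_dense(2L)))
  net <- nn_build(layers, c(cfg$patch_side, cfg$patch_side, 3L), seed = cfg$rng_seed)
  structure(list(net = net, cfg = cfg, trained = FALSE, history = NULL),
            class = "ebus_patch_cnn")
}

#' Number of trainable parameters of a patch CNN
#'
#' @param model an `ebus_patch_cnn`.
#' @return Integer parameter count (weights, biases, and batch-norm scales).
#' @export
patch_cnn_n_params <- function(model) nn_count_params(model$net)

#' Train the patch CNN
#'
#' @param model an `ebus_patch_cnn`.
#' @param X patch tensor `(side, side, 3, n)`, values in `[0, 1]` (see
#'   [patch_tensor()]).
#' @param y patch labels (`"benign"`/`"malignant"`, inherited from the parent
#'   image).
#' @param epochs optional override of `cfg$epochs`.
#' @return The trained model with a per-epoch `epoch,loss,acc` history.
#' @export
train_patch_cnn <- function(model, X, y, epochs = NULL) {
  stopifnot(inherits(model, "ebus_patch_cnn"))
  if (is.null(epochs)) epochs <- model$cfg$epochs
  if (epochs == 0L) return(model)
  yi <- as.integer(factor(y, levels = c("benign", "malignant")))
  fit <- nn_fit(model$net, X, yi, epochs = epochs,
                batch_size = model$cfg$batch_size, lr = model$cfg$learning_rate,
                optimizer = "adam", seed = model$cfg$rng_seed + 1L)
  model$net <- fit$net
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Per-patch class labels
#'
#' Softmax argmax per patch; an exact tie is resolved toward benign (0).
#'
#' @param model a trained `ebus_patch_cnn`.
#' @param patches a `patch_set` from [select_patches()] or a patch tensor.
#' @return Integer vector of 0 (benign) / 1 (malignant), one per patch.
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "ebus_patch_cnn"))
  X <- if (inherits(patches, "patch_set")) patch_tensor(patches) else patches
  n <- if (is.null(dim(X)[4])) 0L else dim(X)[4]
  if (n == 0L) stop("empty patch set", call. = FALSE)
  p <- nn_predict_prob(model$net, X)
  as.integer(p[, 2] > p[, 1])
}

#' Aggregate patch labels into the per-image decision (P3)
#'
#' The probability of malignancy is the malignant-patch ratio
#' `P3 = nM / (nM + nB)`; the image is called malignant exactly when
#' `P3 > threshold` (a boundary value `P3 == threshold` is benign).
#'
#' @param labels integer 0/1 patch labels from [classify_patches()].
#' @param threshold decision threshold T (default 0.63).
#' @return A `patch_decision` list: `n_malignant`, `n_benign`, `p3`,
#'   `threshold`, `class` (0 benign / 1 malignant). Zero patches raise an
#'   `ebus_no_patches` error so the ensemble can drop this model for the
#'   image.
#' @export
aggregate_p3 <- function(labels, threshold = 0.63) {
  if (length(labels) == 0L)
    stop(structure(class = c("ebus_no_patches", "error", "condition"),
                   list(message = "no patches: P3 undefined", call = sys.call())))
  nm <- sum(labels == 1L); nb <- sum(labels == 0L)
  p3 <- nm / (nm + nb)
  structure(list(n_malignant = nm, n_benign = nb, p3 = p3,
                 threshold = threshold, class = as.integer(p3 > threshold)),
            class = "patch_decision")
}

#' Stack a patch set into a model input tensor
#'
#' Rescales patches to `[0, 1]` and replicates grayscale patches over 3
#' channels.
#'
#' @param patches a `patch_set` or list of patch pixel blocks.
#' @return Array `(side, side, 3, n)`.
#' @export
patch_tensor <- function(patches) {
  pl <- if (inherits(patches, "patch_set")) patches$patches else patches
  n <- length(pl)
  if (n == 0L) return(array(0, c(0, 0, 3, 0)))
  s <- nrow(pl[[1]])
  out <- array(0, c(s, s, 3L, n))
  for (i in seq_len(n)) {
    px <- pl[[i]] / 255
    if (is.matrix(px)) out[, , , i] <- array(rep(px, 3L), c(s, s, 3L))
    else out[, , , i] <- px
  }
  out
}
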