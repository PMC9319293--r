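#' Single-image model configuration
#'
#' The whole-image classifier follows the transfer-learning pattern: a frozen
#' convolutional feature extractor with a trainable softmax classification
#' head, trained with plain stochastic gradient descent and cross-entropy.
#' The `"small"` backbone is a compact three-stage seeded convolutional
#' extractor (8/16/32 kernels) over `input_size`-square inputs; its weights
#' are fixed at build time and never updated. A `"densenet169-pretrained"`
#' backbone would need bundled pretrained weights and is rejected with an
#' informative error.
#'
#' @param backbone `"small"` (alias `"small-test-backbone"`).
#' @param learning_rate SGD learning rate (default 0.0001).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size minibatch size (default 32).
#' @param epochs maximum head-training epochs (default 50).
#' @param patience early-stopping patience on the training-loss plateau.
#' @param input_size square input side in px (default 64).
#' @param rng_seed seed for backbone init, head init, and shuffling.
#' @return A `transfer_config` list.
#' @export
transfer_config <- function(backbone = "small", learning_rate = 1e-4,
                            momentum = 0.9, batch_size = 32L, epochs = 50L,
                            patience = 10L, input_size = 64L, rng_seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 input_size = as.integer(input_size),
                 rng_seed = as.integer(rng_seed)),
            class = "transfer_config")
}

#' Build the single-image model
#'
#' @param cfg a [transfer_config()].
#' @return An `ebus_single_image_model`: frozen backbone + trainable 2-class
#'   head (softmax output).
#' @export
build_single_image_model <- function(cfg = transfer_config()) {
  stopifnot(inherits(cfg, "transfer_config"))
  if (!cfg$backbone %in% c("small", "small-test-backbone"))
    stop(sprintf(paste0("unknown backbone '%s': pretrained weights are not ",
                        "bundled; use backbone = 'small'"), cfg$backbone))
  s <- cfg$input_size
  if (s %% 8L != 0L) stop("input_size must be a multiple of 8")
  layers <- list(nn_layer_conv(8), nn_layer_relu(), nn_layer_pool(),
                 nn_layer_conv(16), nn_layer_relu(), nn_layer_pool(),
                 nn_layer_conv(32), nn_layer_relu(), nn_layer_pool(),
                 nn_layer_flatten(), nn_layer_dense(2))
  net <- nn_build(layers, c(s, s, 3L), seed = cfg$rng_seed)
  for (i in seq_along(net$layers))
    if (net$layers[[i]]$type == "conv") net$layers[[i]]$trainable <- FALSE
  structure(list(net = net, cfg = cfg, head_index = length(layers),
                 trained = FALSE, history = NULL),
            class = "ebus_single_image_model")
}

# frozen-backbone activations for a batch of images (no dropout/BN involved,
# so extraction is deterministic and can be cached)
backbone_features <- function(model, X) {
  net_bb <- model$net
  net_bb$layers <- net_bb$layers[seq_len(model$head_index - 1L)]
  nn_forward(net_bb, X, training = FALSE)$out
}

#' Train the classification head
#'
#' Backbone activations are extracted once (the extractor is frozen, so they
#' are constants), then the softmax head is trained with SGD + momentum and
#' cross-entropy, stopping early when the training loss stops improving.
#'
#' @param model from [build_single_image_model()].
#' @param X image tensor `(input_size, input_size, 3, n)` with values in
#'   `[0, 1]` (see [image_tensor()]).
#' @param y labels (`"benign"` / `"malignant"` or factor).
#' @param epochs optional override of `cfg$epochs` (0 leaves the model
#'   unchanged).
#' @return The trained model; `$history` holds the per-epoch
#'   `epoch,loss,acc` log.
#' @export
train_single_image_model <- function(model, X, y, epochs = NULL) {
  stopifnot(inherits(model, "ebus_single_image_model"))
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs == 0L) return(model)
  yi <- as.integer(factor(y, levels = c("benign", "malignant")))
  feats <- backbone_features(model, X)
  head <- nn_build(list(nn_layer_dense(2)), ncol(feats), seed = cfg$rng_seed + 1L)
  best <- Inf; stall <- 0L; hist <- NULL
  head <- nn_opt_init(head, "sgd", cfg$learning_rate, cfg$momentum)
  set.seed(cfg$rng_seed + 2L)
  n <- nrow(feats)
  for (ep in seq_len(epochs)) {
    ord <- unlist(lapply(split(seq_len(n), yi), sample), use.names = FALSE)
    ord <- ord[order(sample(seq_along(ord)))]
    tot_loss <- 0; tot_cor <- 0
    for (b0 in seq(1L, n, cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      fw <- nn_forward(head, feats[idx, , drop = FALSE], training = TRUE)
      l <- nn_ce_loss(fw$out, yi[idx])
      bw <- nn_backward(head, fw$caches, l$dlogits)
      head <- nn_update(head, bw$grads)
      tot_loss <- tot_loss + l$loss * length(idx)
      tot_cor <- tot_cor + sum(max.col(fw$out, ties.method = "first") == yi[idx])
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n, acc = tot_cor / n))
    if (tot_loss / n < best - 1e-5) { best <- tot_loss / n; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= cfg$patience) break
  }
  model$net$layers[[model$head_index]]$W <- head$layers[[1]]$W
  model$net$layers[[model$head_index]]$b <- head$layers[[1]]$b
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Malignancy probability from the single-image model (P2)
#'
#' @param model a trained `ebus_single_image_model`.
#' @param X image tensor `(s, s, 3, n)`; see [image_tensor()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_p2 <- function(model, X) {
  stopifnot(inherits(model, "ebus_single_image_model"))
  s <- model$cfg$input_size
  if (!all(dim(X)[1:3] == c(s, s, 3L))) stop("wrong input size")
  nn_predict_prob(model$net, X)[, 2]
}

#' Stack EBUS images into a model input tensor
#'
#' Resizes each image (bilinear) to `size` x `size`, rescales to `[0, 1]`,
#' and replicates grayscale frames across 3 channels.
#'
#' @param images list of [ebus_image()].
#' @param size output side in px.
#' @return Array `(size, size, 3, n)`.
#' @export
image_tensor <- function(images, size = 64L) {
  n <- length(images)
  out <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    px <- images[[i]]$pixels / 255
    if (is.matrix(px)) {
      r <- EBImage::resize(px, w = size, h = size)
      out[, , , i] <- array(rep(r, 3L), c(size, size, 3L))
    } else {
      for (k in 1:3) out[, , k, i] <- EBImage::resize(px[, , k], w = size, h = size)
    }
  }
  out
}
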