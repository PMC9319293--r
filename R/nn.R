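# ---- compact seeded CNN engine ---------------------------------------------
#
# Minimal feed-forward engine for small image classifiers: same-padding 3x3
# convolutions (im2col + GEMM), 2x2 max pooling, spatial batch normalization,
# inverted dropout, dense layers, softmax cross-entropy, SGD(+momentum) and
# Adam. Activations are (h, w, c, n) arrays before flattening and (n, d)
# matrices after. Everything draws from R's RNG, so runs are reproducible
# from a single seed. Internal: the model modules wrap this engine.

nn_he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# index map for im2col: rows = output pixels (column-major), cols = kernel
# taps x input channels; entries are linear indices into the padded volume
nn_im2col_map <- function(h, w, cin, k) {
  pad <- (k - 1L) %/% 2L
  hp <- h + 2L * pad; wp <- w + 2L * pad
  out_r <- rep(seq_len(h), times = w)
  out_c <- rep(seq_len(w), each = h)
  taps <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = seq_len(cin))
  M <- matrix(0L, h * w, nrow(taps))
  for (t in seq_len(nrow(taps))) {
    rr <- out_r + taps$dr[t]
    cc <- out_c + taps$dc[t]
    M[, t] <- rr + (cc - 1L) * hp + (taps$ch[t] - 1L) * hp * wp
  }
  M
}

nn_pad <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  out
}

nn_layer_conv <- function(filters, ksize = 3L) {
  structure(list(type = "conv", filters = as.integer(filters),
                 ksize = as.integer(ksize), trainable = TRUE), class = "nn_layer")
}
nn_layer_relu <- function() structure(list(type = "relu"), class = "nn_layer")
nn_layer_pool <- function() structure(list(type = "pool"), class = "nn_layer")
nn_layer_bn <- function() structure(list(type = "bn", trainable = TRUE,
                                         momentum = 0.9, eps = 1e-5), class = "nn_layer")
nn_layer_dropout <- function(rate) structure(list(type = "dropout", rate = rate),
                                             class = "nn_layer")
nn_layer_flatten <- function() structure(list(type = "flatten"), class = "nn_layer")
nn_layer_dense <- function(units) structure(list(type = "dense",
                                                 units = as.integer(units),
                                                 trainable = TRUE), class = "nn_layer")

# instantiate parameters given the input shape c(h, w, c) (or d for matrices)
nn_build <- function(layers, input_shape, seed = 1L) {
  set.seed(seed)
  shape <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      k <- ly$ksize; cin <- shape[3]
      ly$W <- nn_he_init(k * k * cin, ly$filters, k * k * cin)
      ly$b <- numeric(ly$filters)
      ly$map <- nn_im2col_map(shape[1], shape[2], cin, k)
      ly$in_shape <- shape
      shape <- c(shape[1], shape[2], ly$filters)
    } else if (ly$type == "pool") {
      if (shape[1] %% 2L || shape[2] %% 2L) stop("pool needs even spatial dims")
      shape <- c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
    } else if (ly$type == "bn") {
      ly$gamma <- rep(1, shape[3]); ly$beta <- numeric(shape[3])
      ly$run_mean <- numeric(shape[3]); ly$run_var <- rep(1, shape[3])
    } else if (ly$type == "flatten") {
      ly$in_shape <- shape
      shape <- prod(shape)
    } else if (ly$type == "dense") {
      d <- shape[1]
      ly$W <- nn_he_init(d, ly$units, d)
      ly$b <- numeric(ly$units)
      shape <- ly$units
    }
    layers[[i]] <- ly
  }
  structure(list(layers = layers, input_shape = input_shape,
                 output_dim = shape, opt = NULL), class = "nn_net")
}

nn_count_params <- function(net) {
  sum(vapply(net$layers, function(ly) {
    n <- 0L
    for (p in c("W", "b", "gamma", "beta")) if (!is.null(ly[[p]])) n <- n + length(ly[[p]])
    n
  }, integer(1)))
}

nn_forward_layer <- function(ly, X, training) {
  if (ly$type == "conv") {
    d <- dim(X); n <- d[4]
    pad <- (ly$ksize - 1L) %/% 2L
    Xp <- nn_pad(X, pad)
    dp <- dim(Xp)
    Xpf <- matrix(Xp, dp[1] * dp[2] * dp[3], n)
    hw <- d[1] * d[2]
    P <- matrix(0, n * hw, ncol(ly$map))
    for (cl in seq_len(ncol(ly$map))) P[, cl] <- as.vector(Xpf[ly$map[, cl], , drop = FALSE])
    Y <- P %*% ly$W
    Y <- Y + matrix(ly$b, nrow(Y), length(ly$b), byrow = TRUE)
    out <- array(0, c(d[1], d[2], ly$filters, n))
    for (s in seq_len(n))
      out[, , , s] <- array(Y[(s - 1L) * hw + seq_len(hw), ], c(d[1], d[2], ly$filters))
    list(out = out, cache = list(P = P, in_dim = d, pad_dim = dp))
  } else if (ly$type == "relu") {
    list(out = pmax(X, 0), cache = list(mask = X > 0))
  } else if (ly$type == "pool") {
    d <- dim(X)
    ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
    cand <- list(X[ro, co, , , drop = FALSE], X[ro + 1L, co, , , drop = FALSE],
                 X[ro, co + 1L, , , drop = FALSE], X[ro + 1L, co + 1L, , , drop = FALSE])
    out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
    arg <- array(1L, dim(out))  # ties route the gradient to the first window
    arg[cand[[1]] != out & cand[[2]] == out] <- 2L
    arg[cand[[1]] != out & cand[[2]] != out & cand[[3]] == out] <- 3L
    arg[cand[[1]] != out & cand[[2]] != out & cand[[3]] != out] <- 4L
    list(out = out, cache = list(arg = arg, in_dim = d))
  } else if (ly$type == "bn") {
    d <- dim(X); n_eff <- d[1] * d[2] * d[4]
    out <- X; xhat <- X; mu <- numeric(d[3]); vr <- numeric(d[3])
    for (c_ in seq_len(d[3])) {
      xc <- X[, , c_, , drop = FALSE]
      if (training) {
        mu[c_] <- mean(xc); vr[c_] <- mean((xc - mu[c_])^2)
      } else {
        mu[c_] <- ly$run_mean[c_]; vr[c_] <- ly$run_var[c_]
      }
      xh <- (xc - mu[c_]) / sqrt(vr[c_] + ly$eps)
      xhat[, , c_, ] <- xh
      out[, , c_, ] <- ly$gamma[c_] * xh + ly$beta[c_]
    }
    list(out = out, cache = list(xhat = xhat, mu = mu, vr = vr, n_eff = n_eff,
                                 batch_stats = training))
  } else if (ly$type == "dropout") {
    if (!training || ly$rate <= 0) return(list(out = X, cache = list(mask = NULL)))
    mask <- array(rbinom(length(X), 1L, 1 - ly$rate) / (1 - ly$rate), dim(X))
    list(out = X * mask, cache = list(mask = mask))
  } else if (ly$type == "flatten") {
    d <- dim(X)
    list(out = t(matrix(X, prod(d[1:3]), d[4])), cache = list(in_dim = d))
  } else if (ly$type == "dense") {
    Y <- X %*% ly$W
    Y <- Y + matrix(ly$b, nrow(Y), length(ly$b), byrow = TRUE)
    list(out = Y, cache = list(X = X))
  } else stop("unknown layer type")
}

nn_forward <- function(net, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    # BN running stats update happens here so the net object can be returned
    ly <- net$layers[[i]]
    f <- nn_forward_layer(ly, X, training)
    if (ly$type == "bn" && training) {
      m <- ly$momentum
      net$layers[[i]]$run_mean <- m * ly$run_mean + (1 - m) * f$cache$mu
      net$layers[[i]]$run_var <- m * ly$run_var + (1 - m) * f$cache$vr
    }
    caches[[i]] <- f$cache
    X <- f$out
  }
  list(out = X, caches = caches, net = net)
}

nn_backward_layer <- function(ly, cache, dout) {
  if (ly$type == "conv") {
    d <- cache$in_dim; n <- d[4]; hw <- d[1] * d[2]
    dY <- matrix(0, n * hw, ly$filters)
    for (s in seq_len(n))
      dY[(s - 1L) * hw + seq_len(hw), ] <- matrix(dout[, , , s], hw, ly$filters)
    dW <- crossprod(cache$P, dY)
    db <- colSums(dY)
    dP <- tcrossprod(dY, ly$W)
    dp <- cache$pad_dim
    dXpf <- matrix(0, dp[1] * dp[2] * dp[3], n)
    for (cl in seq_len(ncol(ly$map))) {
      idx <- ly$map[, cl]
      dXpf[idx, ] <- dXpf[idx, ] + matrix(dP[, cl], hw, n)
    }
    pad <- (ly$ksize - 1L) %/% 2L
    dXp <- array(dXpf, dp)
    dX <- dXp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
    list(dX = dX, grads = list(W = dW, b = db))
  } else if (ly$type == "relu") {
    list(dX = dout * cache$mask, grads = NULL)
  } else if (ly$type == "pool") {
    d <- cache$in_dim
    dX <- array(0, d)
    ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
    a <- cache$arg
    dX[ro, co, , ] <- dout * (a == 1L)
    dX[ro + 1L, co, , ] <- dX[ro + 1L, co, , , drop = FALSE] + dout * (a == 2L)
    dX[ro, co + 1L, , ] <- dX[ro, co + 1L, , , drop = FALSE] + dout * (a == 3L)
    dX[ro + 1L, co + 1L, , ] <- dX[ro + 1L, co + 1L, , , drop = FALSE] + dout * (a == 4L)
    list(dX = dX, grads = NULL)
  } else if (ly$type == "bn") {
    d <- dim(dout); m <- cache$n_eff
    dX <- dout; dgamma <- numeric(d[3]); dbeta <- numeric(d[3])
    for (c_ in seq_len(d[3])) {
      dy <- dout[, , c_, , drop = FALSE]
      xh <- cache$xhat[, , c_, , drop = FALSE]
      dgamma[c_] <- sum(dy * xh)
      dbeta[c_] <- sum(dy)
      if (cache$batch_stats) {
        inv_sd <- 1 / sqrt(cache$vr[c_] + ly$eps)
        dxh <- dy * ly$gamma[c_]
        dX[, , c_, ] <- inv_sd / m * (m * dxh - sum(dxh) - xh * sum(dxh * xh))
      } else {
        dX[, , c_, ] <- dy * ly$gamma[c_] / sqrt(cache$vr[c_] + ly$eps)
      }
    }
    list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
  } else if (ly$type == "dropout") {
    if (is.null(cache$mask)) list(dX = dout, grads = NULL)
    else list(dX = dout * cache$mask, grads = NULL)
  } else if (ly$type == "flatten") {
    list(dX = array(t(dout), cache$in_dim), grads = NULL)
  } else if (ly$type == "dense") {
    list(dX = tcrossprod(dout, ly$W),
         grads = list(W = crossprod(cache$X, dout), b = colSums(dout)))
  } else stop("unknown layer type")
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- nn_backward_layer(net$layers[[i]], caches[[i]], dout)
    grads[i] <- list(b$grads)
    dout <- b$dX
  }
  list(grads = grads, dX = dout)
}

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its gradient wrt logits; y is an integer class index
nn_ce_loss <- function(logits, y) {
  p <- nn_softmax(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  onehot <- matrix(0, n, ncol(p)); onehot[cbind(seq_len(n), y)] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}

nn_opt_init <- function(net, optimizer, lr, momentum = 0.9) {
  net$opt <- list(kind = optimizer, lr = lr, momentum = momentum, t = 0L,
                  state = vector("list", length(net$layers)))
  net
}

nn_update <- function(net, grads) {
  op <- net$opt
  op$t <- op$t + 1L
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (is.null(grads[[i]]) || isFALSE(ly$trainable)) next
    st <- op$state[[i]]
    if (is.null(st)) st <- list()
    for (p in names(grads[[i]])) {
      g <- grads[[i]][[p]]
      if (op$kind == "sgd") {
        v <- if (is.null(st[[p]])) g * 0 else st[[p]]
        v <- op$momentum * v - op$lr * g
        ly[[p]] <- ly[[p]] + v
        st[[p]] <- v
      } else {  # adam
        mkey <- paste0("m_", p); vkey <- paste0("v_", p)
        m <- if (is.null(st[[mkey]])) g * 0 else st[[mkey]]
        v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        mhat <- m / (1 - 0.9^op$t)
        vhat <- v / (1 - 0.999^op$t)
        ly[[p]] <- ly[[p]] - op$lr * mhat / (sqrt(vhat) + 1e-8)
        st[[mkey]] <- m; st[[vkey]] <- v
      }
    }
    op$state[[i]] <- st
    net$layers[[i]] <- ly
  }
  net$opt <- op
  net
}

# X: (h, w, c, n) array or (n, d) matrix; y: integer classes 1..K
nn_fit <- function(net, X, y, epochs, batch_size, lr,
                   optimizer = c("adam", "sgd"), momentum = 0.9, seed = 1L,
                   verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  net <- nn_opt_init(net, optimizer, lr, momentum)
  set.seed(seed)
  n <- if (is.matrix(X)) nrow(X) else dim(X)[4]
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0))
  take <- function(idx) {
    if (is.matrix(X)) X[idx, , drop = FALSE] else X[, , , idx, drop = FALSE]
  }
  for (ep in seq_len(epochs)) {
    # stratified shuffle: interleave a permutation of each class
    ord <- unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
    ord <- ord[order(sample(seq_along(ord)))]
    tot_loss <- 0; tot_correct <- 0
    for (b0 in seq(1L, n, batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      fw <- nn_forward(net, take(idx), training = TRUE)
      net <- fw$net
      l <- nn_ce_loss(fw$out, y[idx])
      bw <- nn_backward(net, fw$caches, l$dlogits)
      net <- nn_update(net, bw$grads)
      tot_loss <- tot_loss + l$loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(fw$out, ties.method = "first") == y[idx])
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n,
                                   acc = tot_correct / n))
    if (verbose) message(sprintf("epoch %d loss %.4f acc %.3f", ep,
                                 tot_loss / n, tot_correct / n))
  }
  list(net = net, history = hist)
}

nn_predict_prob <- function(net, X, batch_size = 128L) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[4]
  out <- NULL
  for (b0 in seq(1L, n, batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    Xb <- if (is.matrix(X)) X[idx, , drop = FALSE] else X[, , , idx, drop = FALSE]
    p <- nn_softmax(nn_forward(net, Xb, training = FALSE)$out)
    out <- rbind(out, p)
  }
  out
}
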