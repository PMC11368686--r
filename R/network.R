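# Multilayer-perceptron encoder/projector with manual backpropagation.
#
# Encoder: [Linear -> BatchNorm -> LeakyReLU] per layer width.
# Projector: Linear -> ReLU -> Linear (rectifier after the first layer
# only). Trained with SGD (momentum, weight decay) under a cosine-decayed
# learning rate. All tensors are plain base-R matrices; batches are rows.

LRELU_SLOPE <- 0.01
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# torch-style Linear init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_linear <- function(n_in, n_out) {
  b <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -b, b), n_in, n_out),
       b = stats::runif(n_out, -b, b))
}

init_bn <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n))
}

# network = list of layers; each layer: list(type, params...)
init_network <- function(n_in, encoder_dims, projector_dims) {
  enc <- list()
  d <- n_in
  for (h in encoder_dims) {
    enc <- c(enc, list(list(type = "linear", par = init_linear(d, h)),
                       list(type = "bn", par = init_bn(h)),
                       list(type = "lrelu")))
    d <- h
  }
  proj <- list()
  for (j in seq_along(projector_dims)) {
    proj <- c(proj, list(list(type = "linear",
                              par = init_linear(d, projector_dims[j]))))
    if (j == 1L) proj <- c(proj, list(list(type = "relu")))
    d <- projector_dims[j]
  }
  list(encoder = enc, projector = proj)
}

# forward through a layer list; training=TRUE uses batch statistics and
# returns a cache for backprop plus updated running stats.
forward_layers <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "linear") {
      caches[[i]] <- list(X = X)
      X <- sweep(X %*% l$par$W, 2L, l$par$b, "+")
    } else if (l$type == "bn") {
      p <- l$par
      if (training) {
        n <- nrow(X)
        mu <- colMeans(X)
        xc <- sweep(X, 2L, mu)
        v <- colSums(xc^2) / n                       # biased, as in the fwd pass
        inv_std <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(xc, 2L, inv_std, "*")
        # running stats use the unbiased variance
        vu <- if (n > 1L) v * n / (n - 1L) else v
        layers[[i]]$par$run_mean <- (1 - BN_MOMENTUM) * p$run_mean +
          BN_MOMENTUM * mu
        layers[[i]]$par$run_var <- (1 - BN_MOMENTUM) * p$run_var +
          BN_MOMENTUM * vu
        caches[[i]] <- list(xhat = xhat, inv_std = inv_std)
        X <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
      } else {
        inv_std <- 1 / sqrt(p$run_var + BN_EPS)
        xhat <- sweep(sweep(X, 2L, p$run_mean), 2L, inv_std, "*")
        X <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
      }
    } else if (l$type == "lrelu") {
      caches[[i]] <- list(mask = X > 0)
      X <- ifelse(X > 0, X, LRELU_SLOPE * X)
    } else if (l$type == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- pmax(X, 0)
    }
  }
  list(out = X, caches = caches, layers = layers)
}

# backward pass; returns gradient lists aligned with layers
backward_layers <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "linear") {
      X <- caches[[i]]$X
      grads[[i]] <- list(W = crossprod(X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, l$par$W)
    } else if (l$type == "bn") {
      cch <- caches[[i]]
      xhat <- cch$xhat
      n <- nrow(xhat)
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      dxhat <- sweep(dY, 2L, l$par$gamma, "*")
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / n, "*")
      dY <- sweep(t1 - t2, 2L, cch$inv_std, "*")
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$type == "lrelu") {
      dY <- dY * ifelse(caches[[i]]$mask, 1, LRELU_SLOPE)
    } else if (l$type == "relu") {
      dY <- dY * caches[[i]]$mask
    }
  }
  grads
}

# SGD with momentum and decoupled-from-nothing (classic) weight decay:
# g <- grad + wd * p ; v <- mom * v + g ; p <- p - lr * v
sgd_step <- function(layers, grads, state, lr, momentum, weight_decay) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (is.null(grads[[i]]) || !l$type %in% c("linear", "bn")) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]] + weight_decay * l$par[[nm]]
      key <- paste0(i, ".", nm)
      v <- state[[key]]
      if (is.null(v)) v <- g else v <- momentum * v + g
      state[[key]] <- v
      layers[[i]]$par[[nm]] <- l$par[[nm]] - lr * v
    }
  }
  list(layers = layers, state = state)
}

cosine_lr <- function(lr0, epoch, epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, epochs)))
}

# deterministic inference-mode forward through the encoder only
encoder_forward <- function(encoder, X) {
  forward_layers(encoder, X, training = FALSE)$out
}
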