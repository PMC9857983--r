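# Internal mini neural-network engine: dense / batch-norm / ReLU / dropout
# stacks with hand-written backpropagation and an Adam optimizer. Sized for
# the architectures this package builds (a few hundred units per layer);
# everything is plain BLAS-backed matrix algebra on dense matrices.

# batch-norm epsilon; standardization uses biased (1/n) batch variance
.bn_eps <- 1e-3
.bn_momentum <- 0.99

# Run `fun` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded builds do not perturb user code.
.with_local_seed <- function(seed, fun) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Glorot-uniform initialization (the convention of mainstream deep-learning
# toolkits); biases and batch-norm offsets start at zero.
.layer_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(type = "dense",
       W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

.layer_bn <- function(n) {
  list(type = "bn", beta = numeric(n), run_mean = numeric(n), run_var = rep(1, n))
}

.layer_relu <- function() list(type = "relu")

.layer_dropout <- function(rate) list(type = "dropout", rate = rate)

# One hidden block: affine -> batch norm (centering, no learnable scale) ->
# ReLU -> dropout. Output layers are bare affine maps.
.hidden_block <- function(n_in, n_out, dropout_rate) {
  list(.layer_dense(n_in, n_out), .layer_bn(n_out), .layer_relu(),
       .layer_dropout(dropout_rate))
}

.stack_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- sweep(X %*% l$W, 2, l$b, "+")
    } else if (l$type == "bn") {
      if (training) {
        m <- colMeans(X)
        v <- pmax(colMeans(X * X) - m * m, 0)
        ivar <- 1 / sqrt(v + .bn_eps)
        xhat <- sweep(sweep(X, 2, m, "-"), 2, ivar, "*")
        caches[[i]] <- list(xhat = xhat, ivar = ivar, batch_mean = m, batch_var = v)
        X <- sweep(xhat, 2, l$beta, "+")
      } else {
        xhat <- sweep(sweep(X, 2, l$run_mean, "-"), 2,
                      1 / sqrt(l$run_var + .bn_eps), "*")
        X <- sweep(xhat, 2, l$beta, "+")
      }
    } else if (l$type == "relu") {
      mask <- X > 0
      caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        keep <- 1 - l$rate
        mask <- (matrix(stats::runif(length(X)), nrow(X)) >= l$rate) / keep
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      }
    }
  }
  list(out = X, caches = caches)
}

# Returns per-layer gradients (parallel to `layers`) and the gradient with
# respect to the stack input.
.stack_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(cc$X, dout), b = colSums(dout))
      dout <- tcrossprod(dout, l$W)
    } else if (l$type == "bn") {
      b <- nrow(dout)
      grads[[i]] <- list(beta = colSums(dout))
      sum_d <- colSums(dout)
      sum_dx <- colSums(dout * cc$xhat)
      dX <- sweep(dout, 2, sum_d / b, "-") -
        sweep(cc$xhat, 2, sum_dx / b, "*")
      dout <- sweep(dX, 2, cc$ivar, "*")
    } else if (l$type == "relu") {
      dout <- dout * cc$mask
    } else if (l$type == "dropout") {
      if (!is.null(cc)) dout <- dout * cc$mask
    }
  }
  list(grads = grads, dX = dout)
}

# After a training-mode forward pass, fold the cached batch statistics into
# the running (inference-time) statistics.
.stack_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(caches[[i]])) {
      layers[[i]]$run_mean <- .bn_momentum * layers[[i]]$run_mean +
        (1 - .bn_momentum) * caches[[i]]$batch_mean
      layers[[i]]$run_var <- .bn_momentum * layers[[i]]$run_var +
        (1 - .bn_momentum) * caches[[i]]$batch_var
    }
  }
  layers
}

.trainable <- function(layer) {
  switch(layer$type, dense = c("W", "b"), bn = "beta", character(0))
}

.stack_zeros_like <- function(layers) {
  lapply(layers, function(l) {
    out <- lapply(.trainable(l), function(nm) array(0, dim = dim(l[[nm]]) %||% length(l[[nm]])))
    names(out) <- .trainable(l)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step over a stack. `state` holds first/second moment estimates
# shaped like the parameters; `t` is the global step count.
.stack_adam <- function(layers, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    for (nm in .trainable(layers[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

.adam_state <- function(layers) {
  list(m = .stack_zeros_like(layers), v = .stack_zeros_like(layers))
}
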