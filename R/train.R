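#' Training configuration
#'
#' @param batch_size cells per mini-batch (default 128; at least 2, because
#'   batch normalization needs batch statistics).
#' @param max_epochs maximum passes over the training cells.
#' @param learning_rate Adam step size.
#' @param patience epochs without validation improvement before stopping.
#' @param seed single integer governing every source of randomness in
#'   [fit]: weight initialization (unless the model spec pins its own
#'   seed), the validation split, epoch shuffles, dropout masks and the
#'   reparameterization noise.
#' @param validation_fraction fraction of cells held out for early
#'   stopping, in `[0, 0.5]`. Zero monitors the training objective instead.
#' @param grad_clip optional positive number; per-tensor gradient values
#'   are clamped to `[-grad_clip, grad_clip]` (off by default, useful for
#'   very wide modalities).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, max_epochs = 100,
                         learning_rate = 1e-3, patience = 10, seed = 0,
                         validation_fraction = 0.1, grad_clip = NULL) {
  if (batch_size < 2) stop("batch_size must be >= 2 (batch norm)")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (patience < 1 || patience > max_epochs)
    stop("patience must lie in [1, max_epochs]")
  if (validation_fraction < 0 || validation_fraction > 0.5)
    stop("validation_fraction must lie in [0, 0.5]")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 grad_clip = grad_clip),
            class = "train_config")
}

# Forward + backward for one mini-batch; returns losses and per-stack grads.
.batch_step <- function(xb, yb, inf, gen, lambda) {
  b <- nrow(xb)
  tr <- .stack_forward(inf$trunk, xb, training = TRUE)
  fm <- .stack_forward(list(inf$head_mu), tr$out, training = TRUE)
  fl <- .stack_forward(list(inf$head_logvar), tr$out, training = TRUE)
  mu <- fm$out
  lv <- fl$out
  eps <- matrix(stats::rnorm(length(mu)), b)
  sdv <- exp(lv / 2)
  z <- mu + sdv * eps
  fx <- .stack_forward(gen$dec_x, z, training = TRUE)
  fy <- .stack_forward(gen$dec_y, z, training = TRUE)
  res_x <- fx$out - xb
  res_y <- fy$out - yb
  recon_x <- mean(rowSums(res_x^2))
  recon_y <- mean(rowSums(res_y^2))
  kl <- mean(rowSums(0.5 * (mu^2 + exp(lv) - 1 - lv)))
  objective <- kl + lambda * (recon_x + recon_y)

  bx <- .stack_backward(gen$dec_x, fx$caches, (2 * lambda / b) * res_x)
  by <- .stack_backward(gen$dec_y, fy$caches, (2 * lambda / b) * res_y)
  dz <- bx$dX + by$dX
  dmu <- dz + mu / b
  dlv <- dz * eps * sdv / 2 + (exp(lv) - 1) / (2 * b)
  bm <- .stack_backward(list(inf$head_mu), fm$caches, dmu)
  bl <- .stack_backward(list(inf$head_logvar), fl$caches, dlv)
  bt <- .stack_backward(inf$trunk, tr$caches, bm$dX + bl$dX)

  list(kl = kl, recon_x = recon_x, recon_y = recon_y, objective = objective,
       grads = list(trunk = bt$grads, head_mu = bm$grads, head_logvar = bl$grads,
                    dec_x = bx$grads, dec_y = by$grads),
       caches = list(trunk = tr$caches, dec_x = fx$caches, dec_y = fy$caches))
}

.clip_grads <- function(grads, clip) {
  if (is.null(clip)) return(grads)
  rapply(grads, function(g) pmin(pmax(g, -clip), clip), how = "replace")
}

# Deterministic evaluation-mode objective at z = mu (no sampling); used for
# validation monitoring and early stopping.
.eval_objective <- function(X, Y, inf, gen, lambda) {
  fw <- .encode_forward(X, inf, training = FALSE)
  rx <- mean(rowSums((X - .stack_forward(gen$dec_x, fw$mu)$out)^2))
  ry <- mean(rowSums((Y - .stack_forward(gen$dec_y, fw$mu)$out)^2))
  kl <- kl_term(fw$mu, fw$logvar)
  list(kl = kl, recon_x = rx, recon_y = ry,
       objective = kl + lambda * (rx + ry))
}

.split_batches <- function(idx, batch_size) {
  starts <- seq(1, length(idx), by = batch_size)
  chunks <- lapply(starts, function(s)
    idx[s:min(s + batch_size - 1, length(idx))])
  k <- length(chunks)
  if (k > 1 && length(chunks[[k]]) < 2) {   # batch norm needs >= 2 cells
    chunks[[k - 1]] <- c(chunks[[k - 1]], chunks[[k]])
    chunks[[k]] <- NULL
  }
  chunks
}

#' Fit the multi-view latent variable model
#'
#' Trains encoder and decoders jointly by mini-batch Adam on the single-draw
#' estimate of the lambda-weighted negative ELBO (see [elbo_objective]).
#' Cells are reshuffled every epoch with the seeded generator; a held-out
#' validation fraction monitors the deterministic evaluation-mode objective
#' and training stops early once it fails to improve for `patience` epochs.
#' The returned model carries the parameters of the best validation epoch.
#' Two calls with identical inputs and seed produce identical histories.
#'
#' @param data a [paired_dataset] whose matrices are preprocessed (each
#'   modality scaled; see [apply_preset]).
#' @param spec a [model_spec]; `input_dim_x` / `input_dim_y` must match the
#'   data. If `spec$seed` is `NA`, the training seed is reused for
#'   initialization.
#' @param config a [train_config].
#' @return Object of class `fitted_model` with elements `spec`,
#'   `inference`, `generative`, `history` (one row per epoch: kl, recon_x,
#'   recon_y, objective, val_objective), `epochs_run`, `best_epoch`,
#'   `config`.
#' @export
fit <- function(data, spec, config = train_config()) {
  stopifnot(inherits(data, "paired_dataset"), inherits(spec, "model_spec"),
            inherits(config, "train_config"))
  X <- .as_dense(data$X)
  Y <- .as_dense(data$Y)
  if (anyNA(X) || anyNA(Y) || !all(is.finite(X)) || !all(is.finite(Y)))
    stop("fit: input matrices contain NaN/Inf; preprocess first")
  if (ncol(X) != spec$input_dim_x || ncol(Y) != spec$input_dim_y)
    stop("fit: data dimensions (", ncol(X), ", ", ncol(Y),
         ") do not match spec (", spec$input_dim_x, ", ", spec$input_dim_y, ")")
  n <- nrow(X)
  if (config$batch_size > n) stop("batch_size exceeds the number of cells")
  if (n < 2 * config$batch_size)
    warning("fewer than two batches of cells; consider a smaller batch_size")

  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_rng <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(config$seed)

  if (is.na(spec$seed)) spec$seed <- config$seed
  nets <- build_networks(spec)
  inf <- nets$inference
  gen <- nets$generative
  lambda <- spec$lambda_weight

  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  st <- list(trunk = .adam_state(inf$trunk),
             head_mu = .adam_state(list(inf$head_mu)),
             head_logvar = .adam_state(list(inf$head_logvar)),
             dec_x = .adam_state(gen$dec_x),
             dec_y = .adam_state(gen$dec_y))
  t_step <- 0
  hist <- vector("list", config$max_epochs)
  best <- list(objective = Inf, inf = inf, gen = gen, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(train_idx)
    chunks <- .split_batches(perm, config$batch_size)
    tot <- c(kl = 0, recon_x = 0, recon_y = 0, objective = 0)
    for (ch in chunks) {
      step <- .batch_step(X[ch, , drop = FALSE], Y[ch, , drop = FALSE],
                          inf, gen, lambda)
      if (!is.finite(step$objective))
        stop("fit: non-finite loss at epoch ", epoch,
             "; try a lower learning_rate or grad_clip")
      g <- .clip_grads(step$grads, config$grad_clip)
      t_step <- t_step + 1
      up <- .stack_adam(inf$trunk, g$trunk, st$trunk, t_step, config$learning_rate)
      inf$trunk <- up$layers; st$trunk <- up$state
      up <- .stack_adam(list(inf$head_mu), g$head_mu, st$head_mu, t_step,
                        config$learning_rate)
      inf$head_mu <- up$layers[[1]]; st$head_mu <- up$state
      up <- .stack_adam(list(inf$head_logvar), g$head_logvar, st$head_logvar,
                        t_step, config$learning_rate)
      inf$head_logvar <- up$layers[[1]]; st$head_logvar <- up$state
      up <- .stack_adam(gen$dec_x, g$dec_x, st$dec_x, t_step, config$learning_rate)
      gen$dec_x <- up$layers; st$dec_x <- up$state
      up <- .stack_adam(gen$dec_y, g$dec_y, st$dec_y, t_step, config$learning_rate)
      gen$dec_y <- up$layers; st$dec_y <- up$state
      inf$trunk <- .stack_update_running(inf$trunk, step$caches$trunk)
      gen$dec_x <- .stack_update_running(gen$dec_x, step$caches$dec_x)
      gen$dec_y <- .stack_update_running(gen$dec_y, step$caches$dec_y)
      w <- length(ch) / length(train_idx)
      tot <- tot + w * c(step$kl, step$recon_x, step$recon_y, step$objective)
    }
    monitor_idx <- if (n_val > 0) val_idx else train_idx
    val <- .eval_objective(X[monitor_idx, , drop = FALSE],
                           Y[monitor_idx, , drop = FALSE], inf, gen, lambda)
    hist[[epoch]] <- data.frame(epoch = epoch, kl = tot["kl"],
                                recon_x = tot["recon_x"],
                                recon_y = tot["recon_y"],
                                objective = tot["objective"],
                                val_objective = val$objective,
                                row.names = NULL)
    if (val$objective < best$objective) {
      best <- list(objective = val$objective, inf = inf, gen = gen,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(list(spec = spec, inference = best$inf, generative = best$gen,
                 history = history, epochs_run = nrow(history),
                 best_epoch = best$epoch, config = config),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model: d =", x$spec$d, "| p =", x$spec$input_dim_x,
      "| q =", x$spec$input_dim_y, "| lambda =", x$spec$lambda_weight, "\n")
  cat("  epochs run:", x$epochs_run, "(best epoch", x$best_epoch, ")\n")
  cat(sprintf("  final objective %.4f, best validation objective %.4f\n",
              utils::tail(x$history$objective, 1),
              min(x$history$val_objective)))
  invisible(x)
}

#' Embed cells into the latent space
#'
#' Returns the posterior means of the latent variable for new (or training)
#' modality-X profiles: the cell embedding used by all downstream analysis.
#' Evaluation mode, no sampling — a deterministic function of (weights,
#' input), bit-stable across calls.
#'
#' @param model a `fitted_model`.
#' @param x_new m x p matrix preprocessed identically to the training X.
#' @return m x d matrix of posterior means (rownames propagated).
#' @export
embed_cells <- function(model, x_new) {
  stopifnot(inherits(model, "fitted_model"))
  x_new <- .as_dense(x_new)
  if (ncol(x_new) != model$spec$input_dim_x)
    stop("embed_cells: expected ", model$spec$input_dim_x, " features, got ",
         ncol(x_new))
  Z <- .encode_forward(x_new, model$inference, training = FALSE)$mu
  rownames(Z) <- rownames(x_new)
  colnames(Z) <- paste0("latent_", seq_len(ncol(Z)))
  Z
}

#' @rdname embed_cells
#' @param object,newdata,... `predict` method alias for [embed_cells].
#' @export
predict.fitted_model <- function(object, newdata, ...) embed_cells(object, newdata)

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds the model spec as JSON, the trained
#' weights, and the loss history as CSV. Loading reconstructs a forward
#' pass that is bit-identical in evaluation mode.
#'
#' @param model a `fitted_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_model` the directory invisibly; `load_model` a
#'   `fitted_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "fitted_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(inference = model$inference, generative = model$generative,
               best_epoch = model$best_epoch, config = model$config),
          file.path(dir, "weights.rds"))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  sp <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- model_spec(d = sp$d, input_dim_x = sp$input_dim_x,
                     input_dim_y = sp$input_dim_y,
                     decoder_widths = as.integer(unlist(sp$decoder_widths)),
                     dropout_rate = sp$dropout_rate,
                     lambda_weight = sp$lambda_weight, seed = sp$seed)
  w <- readRDS(file.path(dir, "weights.rds"))
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(spec = spec, inference = w$inference,
                 generative = w$generative, history = history,
                 epochs_run = nrow(history), best_epoch = w$best_epoch,
                 config = w$config),
            class = "fitted_model")
}
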