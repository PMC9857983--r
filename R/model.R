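#' Model specification
#'
#' Everything needed to rebuild the networks deterministically: the latent
#' dimensionality `d`, the decoder layer widths, the dropout rate, the
#' reconstruction weight lambda, the two input dimensionalities and the
#' initialization seed.
#'
#' The decoder for modality X realizes widths `d -> widths -> p` (default
#' `d -> 32 -> 64 -> 128 -> p`) where every intermediate layer is, in order,
#' an affine map, batch normalization with batch-statistic standardization
#' and a learnable offset but no learnable scale, a ReLU, and dropout. The
#' decoder for Y is identical except for its q-dimensional output. The
#' encoder consumes modality X only and mirrors the decoder
#' (`p -> 128 -> 64 -> 32`) before two affine heads that output the
#' posterior mean and log-variance in `d` dimensions; the heads carry no
#' dropout. Output layers everywhere are bare affine maps (Gaussian means
#' live on the scaled real line).
#'
#' `decoder_widths = integer(0)` selects the affine variant — single affine
#' encoder heads and single affine decoders with no batch norm, ReLU or
#' dropout — which reduces the model to probabilistic CCA and is used as an
#' analytic oracle in the tests.
#'
#' @param d latent dimensionality (>= 1).
#' @param input_dim_x,input_dim_y feature counts p and q.
#' @param decoder_widths intermediate layer widths between latent and output.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param lambda_weight nonnegative weight on the reconstruction terms.
#' @param seed integer governing weight initialization.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(d = 10, input_dim_x, input_dim_y,
                       decoder_widths = c(32, 64, 128),
                       dropout_rate = 0.05, lambda_weight = 1.0, seed = 0) {
  if (d < 1) stop("latent dimensionality d must be >= 1")
  if (length(decoder_widths) > 0 && any(decoder_widths <= 0))
    stop("decoder widths must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (lambda_weight < 0) stop("lambda_weight must be nonnegative")
  if (missing(input_dim_x) || missing(input_dim_y))
    stop("input_dim_x and input_dim_y are required")
  structure(list(d = as.integer(d),
                 input_dim_x = as.integer(input_dim_x),
                 input_dim_y = as.integer(input_dim_y),
                 decoder_widths = as.integer(decoder_widths),
                 dropout_rate = dropout_rate,
                 lambda_weight = lambda_weight,
                 seed = as.integer(seed)),
            class = "model_spec")
}

.build_decoder <- function(d, widths, out_dim, dropout_rate) {
  layers <- list()
  prev <- d
  for (w in widths) {
    layers <- c(layers, .hidden_block(prev, w, dropout_rate))
    prev <- w
  }
  c(layers, list(.layer_dense(prev, out_dim)))
}

#' Build the inference and generative networks
#'
#' Instantiates encoder and both decoders from a [model_spec], with weights
#' drawn deterministically from `spec$seed` (two builds with the same spec
#' are bitwise identical). The residual noise scale sigma of the Gaussian
#' observation model is fixed at 1; its effective value is absorbed by
#' `lambda_weight`, which already rescales the reconstruction terms.
#'
#' @param spec a [model_spec].
#' @return List with elements `inference` (encoder trunk + mu / logvar
#'   heads) and `generative` (decoders `dec_x`, `dec_y`, `sigma = 1`).
#' @export
build_networks <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  .with_local_seed(spec$seed, function() {
    enc_widths <- rev(spec$decoder_widths)
    trunk <- list()
    prev <- spec$input_dim_x
    for (w in enc_widths) {
      trunk <- c(trunk, .hidden_block(prev, w, spec$dropout_rate))
      prev <- w
    }
    inference <- structure(
      list(trunk = trunk,
           head_mu = .layer_dense(prev, spec$d),
           head_logvar = .layer_dense(prev, spec$d)),
      class = "inference_params")
    generative <- structure(
      list(dec_x = .build_decoder(spec$d, spec$decoder_widths,
                                  spec$input_dim_x, spec$dropout_rate),
           dec_y = .build_decoder(spec$d, spec$decoder_widths,
                                  spec$input_dim_y, spec$dropout_rate),
           sigma = 1),
      class = "generative_params")
    list(inference = inference, generative = generative)
  })
}

# Forward pass of the encoder; returns mu, logvar and caches for backprop.
.encode_forward <- function(x_batch, inf, training = FALSE) {
  tr <- .stack_forward(inf$trunk, x_batch, training = training)
  fm <- .stack_forward(list(inf$head_mu), tr$out, training = training)
  fl <- .stack_forward(list(inf$head_logvar), tr$out, training = training)
  list(mu = fm$out, logvar = fl$out,
       cache_trunk = tr$caches, cache_mu = fm$caches, cache_lv = fl$caches)
}

#' Encode cells into the latent posterior
#'
#' Maps a preprocessed (scaled) batch of modality-X profiles to per-cell
#' posterior means, log-variances, and one reparameterized sample
#' `mu + exp(logvar / 2) * eps` with `eps` standard normal (drawn from the
#' current RNG stream; seed the session for reproducibility).
#'
#' @param x_batch b x p matrix of preprocessed expression profiles.
#' @param params `inference_params` from [build_networks] or a fitted model.
#' @param training logical; `TRUE` uses batch statistics and dropout,
#'   `FALSE` (default) evaluation mode with running statistics.
#' @return List of class `latent_code` with `mu`, `logvar`, `sample`
#'   (b x d each).
#' @export
encode <- function(x_batch, params, training = FALSE) {
  if (inherits(params, "fitted_model")) params <- params$inference
  stopifnot(inherits(params, "inference_params"))
  x_batch <- as.matrix(x_batch)
  if (anyNA(x_batch) || !all(is.finite(x_batch)))
    stop("encode: input contains NaN/Inf")
  fw <- .encode_forward(x_batch, params, training = training)
  eps <- matrix(stats::rnorm(length(fw$mu)), nrow(fw$mu))
  structure(list(mu = fw$mu, logvar = fw$logvar,
                 sample = fw$mu + exp(fw$logvar / 2) * eps),
            class = "latent_code")
}

#' Decode latent codes into a modality's reconstruction means
#'
#' @param z b x d matrix of latent codes.
#' @param params `generative_params` from [build_networks] or a fitted model.
#' @param modality `"x"` or `"y"`.
#' @param training logical; see [encode].
#' @return b x p (or b x q) matrix of reconstruction means.
#' @export
decode <- function(z, params, modality = c("x", "y"), training = FALSE) {
  modality <- match.arg(modality)
  if (inherits(params, "fitted_model")) params <- params$generative
  stopifnot(inherits(params, "generative_params"))
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("decode: latent input contains NaN/Inf")
  layers <- if (modality == "x") params$dec_x else params$dec_y
  d_in <- nrow(layers[[1]]$W)
  if (ncol(z) != d_in)
    stop("decode: z has ", ncol(z), " columns but decoder expects ", d_in)
  .stack_forward(layers, z, training = training)$out
}

#' KL divergence of the variational posterior from the standard normal prior
#'
#' Mean over cells of `0.5 * sum_j(mu_j^2 + exp(logvar_j) - 1 - logvar_j)`,
#' the closed form of `KL(N(mu, diag(exp(logvar))) || N(0, I))`. Always
#' nonnegative, zero exactly when the posterior equals the prior.
#'
#' @param mu,logvar b x d matrices of posterior means and log-variances.
#' @return Nonnegative scalar.
#' @export
kl_term <- function(mu, logvar) {
  mu <- as.matrix(mu); logvar <- as.matrix(logvar)
  if (!identical(dim(mu), dim(logvar)))
    stop("kl_term: mu and logvar shapes differ")
  mean(rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar)))
}

#' Gaussian reconstruction error
#'
#' Mean over cells of the squared Euclidean distance between observed and
#' reconstructed rows: the negative Gaussian log-likelihood with fixed unit
#' noise scale, constants dropped. The reduction is mean over cells and sum
#' over features, which keeps the meaning of `lambda_weight` independent of
#' batch size.
#'
#' @param observed,reconstructed b x m matrices.
#' @return Nonnegative scalar.
#' @export
recon_term <- function(observed, reconstructed) {
  observed <- as.matrix(observed); reconstructed <- as.matrix(reconstructed)
  if (!identical(dim(observed), dim(reconstructed)))
    stop("recon_term: shape mismatch")
  mean(rowSums((observed - reconstructed)^2))
}

#' Single-draw estimate of the lambda-weighted negative ELBO
#'
#' Draws one reparameterized latent sample per cell (the stochastic
#' gradient variational Bayes estimator with one draw) and assembles the
#' minimized objective `kl + lambda * (recon_x + recon_y)`, the negated
#' evidence lower bound up to additive constants with the reconstruction
#' terms rescaled by lambda.
#'
#' @param x_batch,y_batch preprocessed paired batches.
#' @param inf,gen parameter sets from [build_networks] or a fitted model.
#' @param lambda_weight nonnegative reconstruction weight.
#' @param training logical; see [encode].
#' @return Object of class `loss_breakdown`: `kl`, `recon_x`, `recon_y`,
#'   `objective`.
#' @export
elbo_objective <- function(x_batch, y_batch, inf, gen, lambda_weight = 1,
                           training = FALSE) {
  if (lambda_weight < 0) stop("lambda_weight must be nonnegative")
  code <- encode(x_batch, inf, training = training)
  rx <- recon_term(x_batch, decode(code$sample, gen, "x", training = training))
  ry <- recon_term(y_batch, decode(code$sample, gen, "y", training = training))
  kl <- kl_term(code$mu, code$logvar)
  structure(list(kl = kl, recon_x = rx, recon_y = ry,
                 objective = kl + lambda_weight * (rx + ry)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("objective %.4f = kl %.4f + lambda * (recon_x %.4f + recon_y %.4f)\n",
              x$objective, x$kl, x$recon_x, x$recon_y))
  invisible(x)
}
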