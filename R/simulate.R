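#' Simulation configuration for paired two-modality data
#'
#' The generator follows the model's own assumptions: a per-cell latent
#' vector z with cluster (Gaussian mixture) or trajectory (1-D gradient)
#' structure is pushed through two fixed modality-specific maps, and
#' isotropic Gaussian noise is added to both modalities.
#'
#' @param n_cells number of cells.
#' @param d_true true latent dimensionality (<= min(p, q)).
#' @param n_clusters mixture components (ignored in trajectory mode).
#' @param p,q feature counts of modalities X and Y.
#' @param separation cluster-center spread multiplier: centers are drawn
#'   i.i.d. N(0, separation^2) per coordinate while within-cluster spread
#'   is N(0, 1), so `separation` is the between/within ratio.
#' @param noise_sd residual standard deviation added to both modalities.
#' @param nonlinearity `"linear"` (random affine maps) or `"tanh-mlp"`
#'   (random two-layer tanh networks, hidden width 16).
#' @param trajectory if `TRUE`, cells lie on a 1-D latent gradient instead
#'   of clusters and the ground truth is a pseudotime in `[0, 1]`.
#' @param count_mode if `TRUE`, export nonnegative integer counts by
#'   column-standardizing the signal, exponentiating and Poisson sampling
#'   (mean scale 5) — exercises the CPM/log1p preprocessing paths.
#' @param seed integer; the same seed reproduces the dataset exactly.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1000, d_true = 2, n_clusters = 3, p = 50,
                       q = 30, separation = 5, noise_sd = 0.3,
                       nonlinearity = c("linear", "tanh-mlp"),
                       trajectory = FALSE, count_mode = FALSE, seed = 0) {
  nonlinearity <- match.arg(nonlinearity)
  if (d_true > min(p, q)) stop("d_true must be <= min(p, q)")
  if (separation <= 0) stop("separation must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (n_clusters > n_cells) stop("more clusters than cells")
  structure(list(n_cells = as.integer(n_cells), d_true = as.integer(d_true),
                 n_clusters = as.integer(n_clusters), p = as.integer(p),
                 q = as.integer(q), separation = separation,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 trajectory = trajectory, count_mode = count_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Random modality-specific map. For the tanh network, first-layer weights
# are scaled by the latent signal scale so pre-activations are O(1): tanh
# then operates in its curved-but-injective regime and the map does not
# collapse distinct latent clusters onto identical saturation corners.
.sim_map <- function(d, out_dim, nonlinearity, z_scale = 1) {
  if (nonlinearity == "linear") {
    A <- matrix(stats::rnorm(d * out_dim), d, out_dim) / sqrt(d)
    b <- stats::rnorm(out_dim, sd = 0.1)
    function(z) sweep(z %*% A, 2, b, "+")
  } else {
    h <- 16
    W1 <- matrix(stats::rnorm(d * h), d, h) / (sqrt(d) * z_scale)
    b1 <- stats::rnorm(h, sd = 0.1)
    W2 <- matrix(stats::rnorm(h * out_dim), h, out_dim) * sqrt(3 / h)
    b2 <- stats::rnorm(out_dim, sd = 0.1)
    function(z) sweep(tanh(sweep(z %*% W1, 2, b1, "+")) %*% W2, 2, b2, "+")
  }
}

.to_counts <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  sdv[sdv == 0] <- 1
  s <- sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
  lam <- 5 * exp(pmin(s, 4))
  cnt <- matrix(stats::rpois(length(lam), lam), nrow(M))
  dimnames(cnt) <- dimnames(M)
  Matrix::Matrix(cnt, sparse = TRUE)
}

#' Simulate a paired two-modality dataset from a shared latent factor
#'
#' @param config a [sim_config].
#' @return List with `data` (a [paired_dataset]; `labels` carries cluster
#'   labels or, in trajectory mode, nothing), `latent` (n x d_true true
#'   latent matrix), `labels` (cluster assignments, `NULL` in trajectory
#'   mode), `pseudotime` (true 1-D positions, `NULL` in cluster mode), and
#'   `config`.
#' @export
simulate_paired <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_local_seed(config$seed, function() {
    n <- config$n_cells
    d <- config$d_true
    labels <- NULL
    pseudotime <- NULL
    if (config$trajectory) {
      pseudotime <- stats::runif(n)
      v <- stats::rnorm(d)
      v <- v / sqrt(sum(v^2))
      z <- outer(pseudotime - 0.5, v) * config$separation +
        matrix(stats::rnorm(n * d, sd = 0.1), n)
    } else {
      centers <- matrix(stats::rnorm(config$n_clusters * d,
                                     sd = config$separation),
                        config$n_clusters, d)
      labels <- sample(rep_len(seq_len(config$n_clusters), n))
      z <- centers[labels, , drop = FALSE] + matrix(stats::rnorm(n * d), n)
    }
    z_scale <- mean(apply(z, 2, stats::sd))
    fx <- .sim_map(d, config$p, config$nonlinearity, z_scale)
    fy <- .sim_map(d, config$q, config$nonlinearity, z_scale)
    X <- fx(z) + matrix(stats::rnorm(n * config$p, sd = config$noise_sd), n)
    Y <- fy(z) + matrix(stats::rnorm(n * config$q, sd = config$noise_sd), n)
    cell_ids <- sprintf("cell_%05d", seq_len(n))
    dimnames(X) <- list(cell_ids, sprintf("gene_%04d", seq_len(config$p)))
    dimnames(Y) <- list(cell_ids, sprintf("feat_%04d", seq_len(config$q)))
    if (config$count_mode) {
      X <- .to_counts(X)
      Y <- .to_counts(Y)
    }
    data <- paired_dataset(X, Y, cell_ids = cell_ids,
                           labels = if (!is.null(labels)) labels else NULL)
    list(data = data, latent = z, labels = labels, pseudotime = pseudotime,
         config = config)
  })
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Writes both modalities, identifiers, any labels/pseudotime and the
#' simulation config (JSON) so that [read_paired] round-trips the values —
#' exactly for integer counts, to floating precision for reals.
#'
#' @param sim result of [simulate_paired] (or a bare [paired_dataset]).
#' @param dir output directory (created).
#' @param format `"mtx"` (10x-style triplet directories `x/` and `y/`) or
#'   `"csv"`.
#' @return Manifest list: `n`, `p`, `q`, `format`, `files`.
#' @export
write_fixture <- function(sim, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  data <- if (inherits(sim, "paired_dataset")) sim else sim$data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  files <- character(0)
  if (format == "mtx") {
    for (mod in c("x", "y")) {
      sub <- file.path(dir, mod)
      dir.create(sub, showWarnings = FALSE)
      M <- if (mod == "x") data$X else data$Y
      feats <- if (mod == "x") data$feature_ids_x else data$feature_ids_y
      Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(M, sparse = TRUE)),
                                  "generalMatrix"),
                      file.path(sub, "matrix.mtx"))
      writeLines(feats, file.path(sub, "features.tsv"))
      writeLines(data$cell_ids, file.path(sub, "barcodes.tsv"))
      files <- c(files, file.path(sub, c("matrix.mtx", "features.tsv",
                                         "barcodes.tsv")))
    }
  } else {
    for (mod in c("x", "y")) {
      M <- .as_dense(if (mod == "x") data$X else data$Y)
      df <- data.frame(barcode = data$cell_ids, M, check.names = FALSE)
      colnames(df) <- c("barcode",
                        if (mod == "x") data$feature_ids_x else data$feature_ids_y)
      f <- file.path(dir, paste0(mod, ".csv"))
      utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(data$labels)) {
    f <- file.path(dir, "labels.tsv")
    utils::write.table(data.frame(data$cell_ids, data$labels), f,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  if (!inherits(sim, "paired_dataset")) {
    if (!is.null(sim$pseudotime)) {
      f <- file.path(dir, "pseudotime.tsv")
      utils::write.table(data.frame(data$cell_ids, sim$pseudotime), f,
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
    jsonlite::write_json(unclass(sim$config), file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "sim_config.json"))
  }
  list(n = nrow(data$X), p = ncol(data$X), q = ncol(data$Y),
       format = format, files = files)
}
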