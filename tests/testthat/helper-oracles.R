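# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pair enumeration for the rank statistics,
# Monte-Carlo integration for the KL term, closed-form Gaussian moments for
# the affine-model objective.

# ARI by explicit enumeration of all C(n,2) cell pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  p11 <- p1a <- p1b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      p11 <- p11 + (sa && sb)
      p1a <- p1a + sa
      p1b <- p1b + sb
    }
  }
  total <- n * (n - 1) / 2
  expected <- p1a * p1b / total
  max_idx <- (p1a + p1b) / 2
  if (max_idx == expected) return(1)
  (p11 - expected) / (max_idx - expected)
}

# Tie-aware Kendall tau-b by explicit pair enumeration.
brute_tau_b <- function(a, b) {
  n <- length(a)
  conc <- disc <- tie_a <- tie_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      da <- sign(a[i] - a[j])
      db <- sign(b[i] - b[j])
      if (da == 0) tie_a <- tie_a + 1
      if (db == 0) tie_b <- tie_b + 1
      if (da != 0 && db != 0) {
        if (da == db) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_a) * (n0 - tie_b))
}

# Monte-Carlo estimate of E_q[log q(z) - log p(z)] for a diagonal Gaussian
# posterior against the standard normal prior.
mc_kl <- function(mu, logvar, n_draws = 1e5) {
  d <- length(mu)
  eps <- matrix(rnorm(n_draws * d), n_draws)
  z <- sweep(sweep(eps, 2, exp(logvar / 2), "*"), 2, mu, "+")
  # log q - log p = sum_j(-logvar/2 - eps^2/2 + z^2/2)
  mean(rowSums(sweep(-eps^2 / 2, 2, logvar / 2, "-") + z^2 / 2))
}

# Closed-form expectation of the single-draw objective when encoder heads
# and decoders are affine: E||x - (mu + sd*eps) W - b||^2 decomposes into
# the deterministic residual plus the propagated posterior variance.
analytic_affine_objective <- function(xb, yb, inf, gen, lambda = 1) {
  fw <- pairedvae:::.encode_forward(xb, inf)
  mu <- fw$mu
  lv <- fw$logvar
  exp_recon <- function(obs, lay) {
    det_part <- mean(rowSums((obs - sweep(mu %*% lay$W, 2, lay$b, "+"))^2))
    var_part <- mean(exp(lv) %*% rowSums(lay$W^2))
    det_part + var_part
  }
  kl_term(mu, lv) + lambda * (exp_recon(xb, gen$dec_x[[1]]) +
                              exp_recon(yb, gen$dec_y[[1]]))
}

# Mean principal angle (degrees) between the column spans of two matrices.
mean_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  mean(acos(pmin(svd(crossprod(qa, qb))$d, 1))) * 180 / pi
}

# Shared small fixture: simulate, scale both modalities, return everything.
make_scaled_sim <- function(...) {
  sim <- simulate_paired(sim_config(...))
  sim$data$X <- scale_unit(sim$data$X)
  sim$data$Y <- scale_unit(sim$data$Y)
  sim
}

quick_fit <- function(sim, d = 8, epochs = 30, seed = 1, lambda = 1,
                      widths = c(32, 64, 128), batch_size = 128,
                      patience = epochs, ...) {
  spec <- model_spec(d = d, input_dim_x = ncol(sim$data$X),
                     input_dim_y = ncol(sim$data$Y), decoder_widths = widths,
                     dropout_rate = if (length(widths)) 0.05 else 0,
                     lambda_weight = lambda, seed = seed)
  fit(sim$data, spec,
      train_config(batch_size = min(batch_size, nrow(sim$data$X)),
                   max_epochs = epochs, patience = patience, seed = seed, ...))
}
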