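# Networks, loss terms and the single-draw objective.

small_spec <- function(...) {
  model_spec(d = 3, input_dim_x = 10, input_dim_y = 6,
             decoder_widths = c(4, 5), ...)
}

test_that("build_networks realizes the documented layer widths", {
  spec <- model_spec(d = 10, input_dim_x = 2000, input_dim_y = 17, seed = 1)
  nets <- build_networks(spec)
  dx_dense <- Filter(function(l) l$type == "dense", nets$generative$dec_x)
  widths <- c(nrow(dx_dense[[1]]$W), vapply(dx_dense, function(l) ncol(l$W), 1L))
  expect_identical(widths, c(10L, 32L, 64L, 128L, 2000L))
  dy_dense <- Filter(function(l) l$type == "dense", nets$generative$dec_y)
  expect_identical(ncol(dy_dense[[length(dy_dense)]]$W), 17L)
  # encoder mirrors the decoder and consumes modality X only
  tr_dense <- Filter(function(l) l$type == "dense", nets$inference$trunk)
  expect_identical(nrow(tr_dense[[1]]$W), 2000L)
  expect_identical(vapply(tr_dense, function(l) ncol(l$W), 1L),
                   c(128L, 64L, 32L))
  expect_identical(dim(nets$inference$head_mu$W), c(32L, 10L))
  expect_error(model_spec(d = 0, input_dim_x = 5, input_dim_y = 5), "d must")
  expect_error(model_spec(d = 2, input_dim_x = 5, input_dim_y = 5,
                          dropout_rate = 1), "dropout")
})

test_that("same seed gives bitwise-identical networks; dropout 0 makes the
          training pass match evaluation at equal batch statistics", {
  spec <- small_spec(seed = 42)
  n1 <- build_networks(spec)
  n2 <- build_networks(spec)
  expect_identical(n1, n2)
  expect_false(identical(n1, build_networks(small_spec(seed = 43))))

  spec0 <- small_spec(dropout_rate = 0, seed = 7)
  nets <- build_networks(spec0)
  set.seed(1)
  x <- matrix(rnorm(40), 4)
  fw <- pairedvae:::.stack_forward(nets$inference$trunk, x, training = TRUE)
  # copy batch statistics into the running slots, then eval must agree
  trunk <- nets$inference$trunk
  for (i in seq_along(trunk)) {
    if (trunk[[i]]$type == "bn") {
      trunk[[i]]$run_mean <- fw$caches[[i]]$batch_mean
      trunk[[i]]$run_var <- fw$caches[[i]]$batch_var
    }
  }
  ev <- pairedvae:::.stack_forward(trunk, x, training = FALSE)
  expect_equal(ev$out, fw$out, tolerance = 1e-12)
})

test_that("encode: degenerate variance collapses the sample onto mu,
          identical inputs give identical posteriors", {
  spec <- small_spec(dropout_rate = 0, seed = 3)
  inf <- build_networks(spec)$inference
  inf$head_logvar$W[] <- 0
  inf$head_logvar$b[] <- -2000           # variance -> 0 limit
  x <- matrix(rnorm(30), 3)
  code <- encode(x, inf)
  expect_identical(code$sample, code$mu)
  x2 <- x[c(1, 1, 2), ]
  code2 <- encode(x2, inf)
  expect_identical(code2$mu[1, ], code2$mu[2, ])
  expect_error(encode(matrix(NaN, 2, 10), inf), "NaN")
})

test_that("reparameterized draws are centered on mu (Monte-Carlo oracle)", {
  spec <- small_spec(seed = 9)
  inf <- build_networks(spec)$inference
  x <- matrix(rnorm(10), 1)
  set.seed(5)
  ref <- encode(x, inf)
  draws <- matrix(0, 1e4, 3)
  for (i in seq_len(1e4)) draws[i, ] <- encode(x, inf)$sample
  se <- exp(ref$logvar / 2) / sqrt(1e4)
  expect_true(all(abs(colMeans(draws) - ref$mu) < 4 * se))
})

test_that("decode respects shapes and acts row-wise; the affine variant is
          an exact matrix product", {
  spec <- small_spec(seed = 2)
  gen <- build_networks(spec)$generative
  z <- matrix(0, 4, 3)
  out <- decode(z, gen, "x")
  expect_identical(dim(out), c(4L, 10L))
  expect_true(all(is.finite(out)))
  set.seed(8)
  z <- matrix(rnorm(12), 4)
  stacked <- decode(rbind(z, z), gen, "y")
  expect_equal(stacked[1:4, ], stacked[5:8, ])
  expect_error(decode(matrix(0, 2, 5), gen, "x"), "expects 3")

  lin <- build_networks(model_spec(d = 3, input_dim_x = 10, input_dim_y = 6,
                                   decoder_widths = integer(0),
                                   dropout_rate = 0, seed = 2))$generative
  W <- lin$dec_x[[1]]$W
  b <- lin$dec_x[[1]]$b
  expect_equal(decode(z, lin, "x"), sweep(z %*% W, 2, b, "+"))
})

test_that("kl_term matches its closed form, stays nonnegative, and agrees
          with Monte-Carlo integration", {
  expect_identical(kl_term(matrix(0, 2, 3), matrix(0, 2, 3)), 0)
  expect_equal(kl_term(matrix(c(1, 0), 1), matrix(0, 1, 2)), 0.5)
  # nonnegativity over a grid, zero only at the prior
  grid <- expand.grid(mu = c(-2, -0.5, 0, 0.5, 2), lv = c(-1, 0, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    v <- kl_term(matrix(grid$mu[i], 1), matrix(grid$lv[i], 1))
    expect_gte(v, 0)
    if (grid$mu[i] != 0 || grid$lv[i] != 0) expect_gt(v, 0)
  }
  set.seed(31)
  mu <- c(0.5, -0.5)
  lv <- c(log(0.25), 0)
  closed <- kl_term(matrix(mu, 1), matrix(lv, 1))
  expect_lt(abs(mc_kl(mu, lv, 1e6) - closed) / closed, 0.01)
  expect_error(kl_term(matrix(0, 1, 2), matrix(0, 2, 2)), "shapes")
})

test_that("recon_term is the mean row-wise squared error", {
  expect_identical(recon_term(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_identical(recon_term(matrix(c(1, 0), 1), matrix(0, 1, 2)), 1)
  set.seed(12)
  a <- matrix(rnorm(40), 8)
  b <- matrix(rnorm(40), 8)
  brute <- mean(vapply(1:8, function(i) sum((a[i, ] - b[i, ])^2), 1))
  expect_equal(recon_term(a, b), brute)
  expect_error(recon_term(a, b[, 1:3]), "shape")
})

test_that("elbo_objective decomposes exactly and is seeded-deterministic", {
  spec <- small_spec(seed = 4)
  nets <- build_networks(spec)
  set.seed(3)
  xb <- matrix(rnorm(50), 5)
  yb <- matrix(rnorm(30), 5)
  set.seed(77)
  l1 <- elbo_objective(xb, yb, nets$inference, nets$generative, 0.7)
  set.seed(77)
  l2 <- elbo_objective(xb, yb, nets$inference, nets$generative, 0.7)
  expect_identical(l1, l2)
  expect_identical(l1$objective, l1$kl + 0.7 * (l1$recon_x + l1$recon_y))
  # lambda = 0 leaves only the KL
  l0 <- elbo_objective(xb, yb, nets$inference, nets$generative, 0)
  expect_identical(l0$objective, l0$kl)
  expect_error(elbo_objective(xb, yb, nets$inference, nets$generative, -1),
               "nonnegative")
})

test_that("encoder pinned to the prior with a perfectly pinned decoder
          yields objective zero", {
  lin <- build_networks(model_spec(d = 2, input_dim_x = 4, input_dim_y = 3,
                                   decoder_widths = integer(0),
                                   dropout_rate = 0, seed = 1))
  inf <- lin$inference
  gen <- lin$generative
  inf$head_mu$W[] <- 0; inf$head_mu$b[] <- 0
  inf$head_logvar$W[] <- 0; inf$head_logvar$b[] <- 0
  row <- c(1, -1, 2, 0.5)
  xb <- matrix(row, 4, 4, byrow = TRUE)       # identical cells
  gen$dec_x[[1]]$W[] <- 0; gen$dec_x[[1]]$b <- row
  yrow <- c(0.3, 0, -2)
  yb <- matrix(yrow, 4, 3, byrow = TRUE)
  gen$dec_y[[1]]$W[] <- 0; gen$dec_y[[1]]$b <- yrow
  l <- elbo_objective(xb, yb, inf, gen, 1)
  expect_identical(l$objective, 0)
})

test_that("single-draw objective is unbiased for the analytic affine ELBO", {
  spec <- model_spec(d = 3, input_dim_x = 8, input_dim_y = 6,
                     decoder_widths = integer(0), dropout_rate = 0, seed = 11)
  nets <- build_networks(spec)
  set.seed(20)
  xb <- matrix(rnorm(40), 5)
  yb <- matrix(rnorm(30), 5)
  ana <- analytic_affine_objective(xb, yb, nets$inference, nets$generative)
  set.seed(21)
  draws <- vapply(seq_len(2000), function(i)
    elbo_objective(xb, yb, nets$inference, nets$generative)$objective, 1)
  expect_lt(abs(mean(draws) - ana) / ana, 0.02)
})
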