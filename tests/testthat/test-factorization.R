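# --- reconstruction -------------------------------------------------------

test_that("reconstruction composes layers innermost-deepest", {
  # identity activation, U = I: reconstruction is just Z1 %*% H1
  tr <- random_truth(4, 4, dims = c(4, 3), activation = "identity", seed = 3)$truth
  tr$U <- diag(4)
  expect_equal(reconstruct_block(tr, 1), tr$Z[[1]][[1]] %*% tr$H[[1]])

  # sigmoid with Z = 0: inner term all 0.5, so every column = 0.5 * rowSums(U)
  tr2 <- random_truth(5, 6, dims = c(3, 2), activation = "sigmoid", seed = 4)$truth
  tr2$Z[[1]][[1]][] <- 0
  R <- reconstruct_block(tr2, 1)
  expect_equal(R, matrix(0.5 * rowSums(tr2$U), 5, 6))
})

test_that("reconstruction agrees with a nested-loop oracle on random models", {
  set.seed(42)
  for (rep in 1:20) {
    N <- sample(1:3, 1)
    dims <- sort(sample(2:6, N + 1), decreasing = TRUE)
    act <- sample(c("sigmoid", "relu", "identity"), 1)
    tr <- random_truth(sample(3:7, 1), sample(3:7, 1), dims = dims,
                       activation = act, seed = rep)$truth
    expect_lt(max(abs(reconstruct_block(tr, 1) - loop_reconstruct(tr, 1))), 1e-10)
  }
})

test_that("shape mismatches are reported with the offending layer", {
  tr <- random_truth(5, 6, dims = c(4, 3, 2), seed = 1)$truth
  tr$Z[[1]][[2]] <- matrix(0, 3, 5)
  expect_error(reconstruct_block(tr, 1), "layer 2")
  tr2 <- random_truth(5, 6, dims = c(4, 3), seed = 1)$truth
  tr2$U <- matrix(0, 5, 7)
  expect_error(reconstruct_block(tr2, 1), "U is")
  expect_error(reconstruct_block(tr2, 9), "out of range")
})

# --- objective ------------------------------------------------------------

test_that("objective is zero at exact reconstruction and decomposes exactly", {
  sim <- random_truth(10, c(8, 6), dims = c(4, 3), noise_sd = 0, seed = 7)
  obj <- jdsnmf_objective(sim$truth, sim$blocks, lambda = 0)
  expect_equal(obj$total, 0, tolerance = 1e-12)
  expect_equal(obj$reg_term, 0)

  obj2 <- jdsnmf_objective(sim$truth, sim$blocks, lambda = 0.3)
  expect_equal(obj2$total, sum(obj2$fit_terms) + obj2$reg_term,
               tolerance = 1e-9)
  expect_error(jdsnmf_objective(sim$truth, sim$blocks, lambda = -1),
               "non-negative")
})

test_that("objective matches a direct sum-of-squares accumulation", {
  # X = I2, U = I2, Z = 0 under sigmoid: reconstruction is 0.5 everywhere
  tr <- random_truth(2, 2, dims = c(2, 2), activation = "sigmoid", seed = 5)$truth
  tr$U <- diag(2)
  tr$Z[[1]][[1]][] <- 0
  X <- diag(2)
  expect_equal(jdsnmf_objective(tr, list(X), lambda = 0)$total, 1.0)

  lam <- 0.1
  reg_direct <- 0
  for (M in list(tr$U, tr$Z[[1]][[1]], tr$H[[1]])) {
    for (v in as.vector(M)) reg_direct <- reg_direct + v * v
  }
  expect_equal(jdsnmf_objective(tr, list(X), lambda = lam)$total,
               1.0 + lam * reg_direct, tolerance = 1e-12)
})

# --- SVD initialization ---------------------------------------------------

test_that("SVD init attains the truncated-SVD optimum on exact low-rank data", {
  set.seed(11)
  X <- matrix(rnorm(30 * 4), 30, 4) %*% matrix(rnorm(4 * 25), 4, 25)
  cfg <- model_config(c(4, 4), activation = "identity")
  m <- svd_initialize(list(X), cfg)
  expect_lt(jdsnmf_objective(m, list(X), lambda = 0)$total, 1e-6 * sum(X^2))
})

test_that("SVD init is deterministic and produces configured shapes", {
  set.seed(12)
  blocks <- list(a = matrix(rnorm(20 * 15), 20, 15),
                 b = matrix(rnorm(20 * 12), 20, 12))
  cfg <- model_config(c(6, 4, 3))
  m1 <- svd_initialize(blocks, cfg)
  m2 <- svd_initialize(blocks, cfg)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$Z, m2$Z)
  expect_identical(m1$H, m2$H)
  expect_equal(dim(m1$U), c(20L, 6L))
  expect_equal(dim(m1$Z[[1]][[1]]), c(6L, 4L))
  expect_equal(dim(m1$Z[[2]][[2]]), c(4L, 3L))
  expect_equal(dim(m1$H[[2]]), c(3L, 12L))
})

test_that("SVD init beats the median random initialization", {
  set.seed(13)
  X <- matrix(rnorm(30 * 20), 30, 20)
  cfg <- model_config(c(5, 5), activation = "identity")
  init_obj <- jdsnmf_objective(svd_initialize(list(X), cfg), list(X), 0)$total
  rand_obj <- vapply(1:20, function(s) {
    tr <- random_truth(30, 20, dims = c(5, 5), activation = "identity",
                       seed = 100 + s)$truth
    jdsnmf_objective(tr, list(X), 0)$total
  }, numeric(1))
  expect_lte(init_obj, stats::median(rand_obj))
})

test_that("degenerate and oversized configurations are rejected", {
  X <- matrix(rnorm(10 * 8), 10, 8)
  expect_error(svd_initialize(list(X), model_config(c(8, 4))), "smaller")
  expect_warning(K <- data_block(matrix(1, 5, 5)), "zero variance")
  suppressWarnings(
    expect_error(svd_initialize(list(matrix(2, 10, 8)), model_config(c(3, 2))),
                 "constant")
  )
})

# --- fitting --------------------------------------------------------------

test_that("linear special case reaches the rank-K SVD optimum", {
  set.seed(21)
  X <- matrix(rnorm(40 * 30), 40, 30)
  cfg <- model_config(c(4, 4), activation = "identity", l2_lambda = 0,
                      max_epochs = 1500, learning_rate = 5e-3)
  fit <- jdsnmf_fit(list(X), cfg)
  expect_lte(jdsnmf_objective(fit, list(X), 0)$total,
             1.05 * svd_residual(X, 4))
})

test_that("fit recovers model-generated data and respects layer constraints", {
  sim <- random_truth(30, c(20, 16), dims = c(4, 3), activation = "sigmoid",
                      noise_sd = 0.01, seed = 22)
  cfg <- model_config(c(4, 3), activation = "sigmoid", l2_lambda = 0,
                      max_epochs = 15000, learning_rate = 2e-2,
                      patience = 500, tol = 1e-8)
  fit <- jdsnmf_fit(sim$blocks, cfg,
                    init = svd_initialize(sim$blocks, cfg, preact_spread = 2))
  for (i in 1:2) {
    rmse <- sqrt(mean((sim$blocks[[i]] - reconstruct_block(fit, i))^2))
    expect_lt(rmse, 0.02)
    lat <- layer_latents(fit, i)
    expect_true(all(lat$H0 > 0 & lat$H0 < 1))  # sigmoid-derived layer
  }
  # trace bookkeeping: running minimum is monotone, terms sum to the total
  tr <- fit$trace
  expect_true(all(diff(cummin(tr$total_loss)) <= 0))
  expect_equal(tr$total_loss, tr$fit_block1 + tr$fit_block2 + tr$reg_loss,
               tolerance = 1e-9)
})

test_that("fits are reproducible and the L2 penalty shrinks factor norms", {
  sim <- random_truth(20, 15, dims = c(3, 2), noise_sd = 0.1, seed = 23)
  cfg0 <- model_config(c(3, 2), l2_lambda = 0, max_epochs = 300)
  f1 <- jdsnmf_fit(sim$blocks, cfg0)
  f2 <- jdsnmf_fit(sim$blocks, cfg0)
  expect_identical(f1$trace$total_loss, f2$trace$total_loss)

  norms <- function(m) sum(m$U^2) + sum(m$Z[[1]][[1]]^2) + sum(m$H[[1]]^2)
  cfgr <- model_config(c(3, 2), l2_lambda = 1e3, max_epochs = 300)
  freg <- jdsnmf_fit(sim$blocks, cfgr)
  expect_lt(norms(freg), norms(f1))
})

# --- feature extraction ---------------------------------------------------

test_that("extract_features returns the documented orientations", {
  sim <- random_truth(20, c(10, 8), dims = c(6, 4), noise_sd = 0.05, seed = 25)
  cfg <- model_config(c(6, 4), max_epochs = 150)
  fit <- jdsnmf_fit(sim$blocks, cfg)

  f0 <- extract_features(fit, layer = 0, block = 1, mode = "feature_matched")
  expect_equal(dim(f0), c(10L, 6L))
  expect_true(all(f0 >= 0))

  fN <- extract_features(fit, layer = 1, block = 2, mode = "feature_matched")
  expect_equal(unname(fN), unname(t(fit$H[[2]])))

  fu <- extract_features(fit, mode = "sample_matched")
  expect_equal(dim(fu), c(20L, 6L))
  expect_equal(unname(fu), unname(fit$U))

  expect_error(extract_features(fit, layer = 5, block = 1), "layer")
  expect_error(extract_features(fit, layer = 0, mode = "feature_matched",
                                block = NULL), "block")
})

test_that("tidy/glance expose the fitted factors and fit summary", {
  sim <- random_truth(12, 9, dims = c(3, 2), noise_sd = 0.05, seed = 26)
  fit <- jdsnmf_fit(sim$blocks, model_config(c(3, 2), max_epochs = 100))
  td <- tidy(fit)
  expect_true(all(c("matrix", "entity", "dimension", "value") %in% names(td)))
  expect_equal(sum(td$matrix == "U"), 12 * 3)
  gl <- glance(fit)
  expect_equal(gl$n_layers, 1L)
  expect_equal(gl$objective, min(fit$trace$total_loss))
})
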