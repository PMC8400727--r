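test_that("sample rule selects the upper tail beyond mu + 1.6449 sigma", {
  # 99 zeros and one 10: mu = 0.1, sigma = sqrt(0.99), cutoff ~ 1.74
  H0 <- matrix(c(rep(0, 99), 10), nrow = 1,
               dimnames = list(NULL, paste0("s", 1:100)))
  expect_identical(sample_membership(H0, 1), "s100")

  # direct arithmetic on a small row
  row <- c(1, 2, 3, 4, 100)
  H0b <- rbind(row)
  colnames(H0b) <- paste0("s", 1:5)
  mu <- mean(row); s <- sqrt(mean((row - mu)^2))
  expect_identical(sample_membership(H0b, 1),
                   colnames(H0b)[row > mu + 1.6449 * s])
})

test_that("degenerate (constant) dimensions select nothing, with a warning", {
  H0 <- matrix(1, 2, 10)
  expect_warning(out <- sample_membership(H0, 1), "zero spread")
  expect_length(out, 0)
  U <- matrix(0, 10, 2)
  expect_warning(fm <- feature_membership(U, 2), "zero spread")
  expect_length(fm$positive, 0)
  expect_length(fm$negative, 0)
})

test_that("feature rule is two-sided and symmetric", {
  # symmetric column: positive and negative selections mirror each other
  v <- c(-5, -3, -1, 1, 3, 5)
  U <- cbind(c(v, rep(0, 94)))
  rownames(U) <- paste0("g", 1:100)
  fm <- feature_membership(U, 1)
  neg_vals <- unname(-U[fm$negative, 1])
  expect_setequal(unname(U[fm$positive, 1]), neg_vals)
  expect_length(intersect(fm$positive, fm$negative), 0)

  # direct arithmetic: one +/- v pair among 98 zeros clears the 1% cutoff
  U2 <- cbind(c(rep(0, 98), 5, -5))
  rownames(U2) <- paste0("g", 1:100)
  s <- sqrt(mean((U2[, 1] - mean(U2[, 1]))^2))
  expect_gt(5, 2.5758 * s)
  fm2 <- feature_membership(U2, 1)
  expect_identical(fm2$positive, "g99")
  expect_identical(fm2$negative, "g100")
})

test_that("membership rates calibrate to the normal tails on iid Gaussians", {
  set.seed(31)
  n <- 10000
  H0 <- matrix(rnorm(2 * n), nrow = 2)
  frac <- length(sample_membership(H0, 1)) / n
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  U <- cbind(rnorm(n))
  fm <- feature_membership(U, 1)
  frac_f <- (length(fm$positive) + length(fm$negative)) / n
  expect_lt(abs(frac_f - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("build_modules emits one module per first-layer dimension", {
  sim <- random_truth(40, c(25, 20), dims = c(5, 3), noise_sd = 0.05, seed = 32)
  fit <- jdsnmf_fit(sim$blocks, model_config(c(5, 3), max_epochs = 200))
  mods <- build_modules(fit)
  expect_equal(attr(mods, "n_modules"), 5L)
  expect_true(all(mods$module %in% 1:5))
  expect_true(all(mods$role %in% c("sample", "positive_feature", "negative_feature")))
  # every selected id exists in the source matrices
  feats <- mods$entity[mods$role != "sample"]
  expect_true(all(feats %in% fit$row_ids))
  smp <- mods[mods$role == "sample", ]
  for (b in unique(smp$block)) {
    i <- match(b, fit$block_names)
    expect_true(all(smp$entity[smp$block == b] %in% fit$col_ids[[i]]))
  }
  # positive and negative features are disjoint within a module
  for (k in unique(mods$module)) {
    pos <- mods$entity[mods$module == k & mods$role == "positive_feature"]
    neg <- mods$entity[mods$module == k & mods$role == "negative_feature"]
    expect_length(intersect(pos, neg), 0)
  }
})

test_that("raising one latent entry adds exactly that sample to that module", {
  sim <- random_truth(30, 50, dims = c(3, 2), noise_sd = 0.05, seed = 33)
  fit <- jdsnmf_fit(sim$blocks, model_config(c(3, 2), max_epochs = 150))
  # operate on H0 directly through the membership rule
  H0 <- layer_latents(fit, 1)$H0
  colnames(H0) <- fit$col_ids[[1]]
  base <- lapply(1:3, function(k) sample_membership(H0, k))
  target <- setdiff(colnames(H0), base[[2]])[1]
  H0mod <- H0
  H0mod[2, target] <- max(H0[2, ]) + 10 * sd(H0[2, ])
  after <- lapply(1:3, function(k) sample_membership(H0mod, k))
  expect_true(target %in% after[[2]])
  # the other modules' membership is untouched
  expect_identical(after[[1]], base[[1]])
  expect_identical(after[[3]], base[[3]])
})
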