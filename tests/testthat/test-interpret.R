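test_that("local surrogates recover linear ground-truth coefficients", {
  set.seed(51)
  w <- c(3, -2, 0.5, 0)
  X <- matrix(rnorm(60 * 4), 60, 4)
  pf <- function(Z) as.numeric(Z %*% w)
  rep <- local_surrogate_importance(pf, X, instances = 1:10,
                                    n_perturbations = 400, seed = 1)
  imp <- rep$importance
  cosine <- sum(imp * abs(w)) / sqrt(sum(imp^2) * sum(w^2))
  expect_gt(cosine, 0.95)
  expect_equal(order(-imp), order(-abs(w)))  # ranking matches |coefficients|
})

test_that("local surrogate importance is seeded and flags degenerate cases", {
  set.seed(52)
  X <- matrix(rnorm(40 * 3), 40, 3)
  X[, 3] <- 1  # constant feature
  pf <- function(Z) as.numeric(Z %*% c(1, -1, 0))
  r1 <- local_surrogate_importance(pf, X, instances = 1:5,
                                   n_perturbations = 300, seed = 7)
  r2 <- local_surrogate_importance(pf, X, instances = 1:5,
                                   n_perturbations = 300, seed = 7)
  expect_identical(r1, r2)
  expect_lt(r1$importance[3], 0.05 * max(r1$importance))

  expect_warning(
    r0 <- local_surrogate_importance(function(Z) rep(1, nrow(Z)), X,
                                     instances = 1:2, n_perturbations = 100),
    "constant predictions")
  expect_true(all(r0$importance == 0))
})

test_that("forest importance normalizes to one and finds planted signal", {
  set.seed(53)
  y <- rep(c(0, 1), each = 40)
  X <- cbind(sig = y + rnorm(80, sd = 0.1),
             n1 = rnorm(80), n2 = rnorm(80), n3 = rnorm(80))
  imp <- rf_module_importance(X, y, seed = 1)
  expect_equal(sum(imp$rf_importance), 1)
  expect_equal(which.max(imp$rf_importance), 1L)

  lime <- local_surrogate_importance(function(Z) as.numeric(Z %*% c(1, 0, 0, 0)),
                                     X, instances = 1:5, n_perturbations = 200)
  rep <- module_importance_report(lime, imp)
  expect_equal(rep$rank[1], 1L)
  expect_true(all(sort(rep$rank) == 1:4))
})

test_that("age regression recovers a planted coefficient with covariates", {
  set.seed(54)
  n <- 200
  cov <- data.frame(age = runif(n, 50, 90),
                    sex = sample(c("F", "M"), n, TRUE),
                    diagnosis = sample(c("AD", "NL"), n, TRUE))
  Y <- cbind(2 * cov$age + rnorm(n, sd = 0.1),          # planted gamma = 2
             -1.5 * cov$age + rnorm(n, sd = 0.1),       # negative association
             matrix(rnorm(n * 6), n))
  res <- age_regression(Y, cov)
  expect_equal(nrow(res), 8)
  expect_gt(res$gamma[1], 1.8); expect_lt(res$gamma[1], 2.2)
  expect_lt(res$p_value[1], 1e-6)
  expect_lt(res$gamma[2], 0)  # sign contract: negative age association
})

test_that("age regression is calibrated on null modules and handles collinearity", {
  set.seed(55)
  n <- 150
  cov <- data.frame(age = rnorm(n, 70, 8),
                    sex = sample(c("F", "M"), n, TRUE),
                    diagnosis = "AD")  # constant: should be dropped
  Y <- matrix(rnorm(n * 200), n)
  expect_warning(res <- age_regression(Y, cov), "constant")
  expect_true(all(is.na(res$diagnosis_coef)))
  rate <- mean(res$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Fisher overlap matches hypergeometric enumeration and edge cases", {
  # the 2x2 table (8,2; 1,5)
  out <- overlap_fisher(module_genes = paste0("g", 1:10),
                        reference_genes = paste0("g", c(1:8, 11)),
                        universe_genes = paste0("g", 1:16))
  expect_equal(out$n_overlap, 8)
  expect_equal(out$p_value, fisher_p_enum(8, 2, 1, 5), tolerance = 1e-10)

  full <- overlap_fisher(paste0("g", 1:20), paste0("g", 1:20),
                         paste0("g", 1:400))
  expect_lt(full$p_value, 1e-20)
  expect_error(overlap_fisher("a", "a", character(0)), "empty")
})

test_that("null gene-set overlaps give approximately uniform p-values", {
  set.seed(56)
  universe <- paste0("g", 1:500)
  ps <- replicate(200, {
    overlap_fisher(sample(universe, 40), sample(universe, 40), universe)$p_value
  })
  # discrete p-values are conservative; check no inflation at 0.05
  expect_lt(mean(ps < 0.05), 0.1)
  expect_gt(mean(ps), 0.35)
})

test_that("importance-pathway correlation matches the direct formula", {
  imp <- c(1, 2, 3, 4, 5)
  expect_equal(importance_vs_pathway_regression(imp, imp * 2)$pearson_r, 1)
  expect_equal(importance_vs_pathway_regression(imp, -imp)$pearson_r, -1)

  x <- c(0.2, 1.4, 0.9, 2.2, 3.1)
  yv <- c(1, 4, 2, 5, 9)
  out <- importance_vs_pathway_regression(x, yv)
  r_direct <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(out$pearson_r, r_direct, tolerance = 1e-12)
  expect_equal(out$slope, r_direct * sd(yv) / sd(x), tolerance = 1e-12)
  expect_error(importance_vs_pathway_regression(rep(1, 5), 1:5), "variance")
})

test_that("GMT gene sets round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg9"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})
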