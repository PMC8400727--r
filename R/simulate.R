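#' Simulation design for the logistic multi-view benchmark
#'
#' Describes the sample-matched benchmark: each view is an i.i.d. standard
#' normal predictor matrix whose class-label probability follows a sparse
#' logistic model with a few large coefficients, and samples are kept only
#' when their hard labels agree across all views. Defaults are the benchmark
#' conditions: 1000 features of which 20 are informative with coefficients
#' of magnitude 10 and random sign, logistic noise `N(0, 1.6)` (variance
#' 1.6), three views, and a 750/50/100 train/validation/test split.
#'
#' @param n_features Features per view (F).
#' @param n_informative Number of nonzero coefficients.
#' @param coef_magnitude Magnitude of each nonzero coefficient.
#' @param noise_var Variance of the logistic error term.
#' @param n_train,n_valid,n_test Sample split sizes.
#' @param n_views Number of views.
#' @param intercept Logistic intercept (beta_0).
#' @param label_rule `"threshold"`: hard label = probability > 0.5;
#'   `"bernoulli"`: label drawn from Bernoulli(probability).
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_features = 1000L, n_informative = 20L,
                              coef_magnitude = 10, noise_var = 1.6,
                              n_train = 750L, n_valid = 50L, n_test = 100L,
                              n_views = 3L, intercept = 0,
                              label_rule = c("threshold", "bernoulli")) {
  if (n_informative > n_features) stop("n_informative must be <= n_features", call. = FALSE)
  if (coef_magnitude <= 0) stop("coef_magnitude must be positive", call. = FALSE)
  if (noise_var < 0) stop("noise_var must be non-negative", call. = FALSE)
  structure(
    list(n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         coef_magnitude = coef_magnitude, noise_var = noise_var,
         n_train = as.integer(n_train), n_valid = as.integer(n_valid),
         n_test = as.integer(n_test), n_views = as.integer(n_views),
         intercept = intercept, label_rule = match.arg(label_rule)),
    class = "simulation_design"
  )
}

expit <- function(x) 1 / (1 + exp(-x))

#' Simulate one logistic view
#'
#' Draws `n` samples by `F` features from `N(0,1)`, a sparse coefficient
#' vector with exactly `n_informative` nonzero entries of magnitude
#' `coef_magnitude` and random sign at random positions, and class
#' probabilities `expit(beta_0 + X beta + eps)` with
#' `eps ~ N(0, noise_var)`.
#'
#' @param design A [simulation_design()].
#' @param n Number of samples (defaults to the design's total split size).
#' @param seed Integer seed.
#' @return List with `X` (n x F), `beta`, `prob`, `y` (0/1 labels).
#' @export
simulate_view <- function(design, n = design$n_train + design$n_valid + design$n_test,
                          seed = 1L) {
  set.seed(seed)
  F_ <- design$n_features
  X <- matrix(stats::rnorm(n * F_), n, F_)
  beta <- numeric(F_)
  idx <- sample.int(F_, design$n_informative)
  beta[idx] <- design$coef_magnitude *
    sample(c(-1, 1), design$n_informative, replace = TRUE)
  eps <- stats::rnorm(n, 0, sqrt(design$noise_var))
  prob <- expit(design$intercept + as.vector(X %*% beta) + eps)
  y <- if (design$label_rule == "bernoulli") stats::rbinom(n, 1L, prob) else
    as.integer(prob > 0.5)
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, beta = beta, prob = prob, y = y)
}

#' Simulate label-consistent multi-view data
#'
#' Each view has its own predictor matrix and coefficient vector; a
#' candidate sample is one row drawn under every view's model, and it is
#' retained only when its hard labels agree across all views (rejection
#' sampling) until the design's total sample count accumulates. The result
#' carries one shared label vector and a train/validation/test partition.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return List with `views` (list of n x F matrices), `y`, `betas`, and
#'   `split` (list of `train`, `valid`, `test` index vectors).
#' @export
simulate_multiview <- function(design, seed = 1L) {
  if (design$n_views < 2L) stop("n_views must be >= 2", call. = FALSE)
  set.seed(seed)
  n_needed <- design$n_train + design$n_valid + design$n_test
  F_ <- design$n_features
  V <- design$n_views

  betas <- lapply(seq_len(V), function(v) {
    beta <- numeric(F_)
    idx <- sample.int(F_, design$n_informative)
    beta[idx] <- design$coef_magnitude *
      sample(c(-1, 1), design$n_informative, replace = TRUE)
    beta
  })

  Xs <- lapply(seq_len(V), function(v) matrix(numeric(0), 0, F_))
  y <- integer(0)
  drawn <- 0L
  while (length(y) < n_needed) {
    batch <- max(n_needed, 200L)
    cand <- lapply(seq_len(V), function(v) {
      X <- matrix(stats::rnorm(batch * F_), batch, F_)
      eps <- stats::rnorm(batch, 0, sqrt(design$noise_var))
      prob <- expit(design$intercept + as.vector(X %*% betas[[v]]) + eps)
      lab <- if (design$label_rule == "bernoulli") stats::rbinom(batch, 1L, prob) else
        as.integer(prob > 0.5)
      list(X = X, lab = lab)
    })
    labs <- vapply(cand, `[[`, integer(batch), "lab")
    keep <- rowSums(labs == labs[, 1L]) == V
    drawn <- drawn + batch
    if (any(keep)) {
      for (v in seq_len(V)) Xs[[v]] <- rbind(Xs[[v]], cand[[v]]$X[keep, , drop = FALSE])
      y <- c(y, labs[keep, 1L])
    }
    if (drawn >= 1000L && length(y) / drawn < 1e-3) {
      stop("label-consistency acceptance rate below 1e-3; ",
           "increase coef_magnitude or reduce n_views", call. = FALSE)
    }
  }
  idx <- seq_len(n_needed)
  Xs <- lapply(Xs, function(X) {
    X <- X[idx, , drop = FALSE]
    rownames(X) <- paste0("s", idx)
    colnames(X) <- paste0("f", seq_len(F_))
    X
  })
  names(Xs) <- paste0("view", seq_len(V))
  split <- list(
    train = seq_len(design$n_train),
    valid = design$n_train + seq_len(design$n_valid),
    test = design$n_train + design$n_valid + seq_len(design$n_test)
  )
  list(views = Xs, y = y[idx], betas = betas, split = split)
}

#' Generate blocks from the factorization's own generative form
#'
#' Draws a ground-truth model (mixed-sign `U`, `Z` and deepest `H`), builds
#' each block as `X_i = U g(Z_i^1 ... g(Z_i^N H_i^N)) + N(0, noise_sd)`, and
#' returns both the blocks and the true model, so recovery tests can use
#' the generator as their oracle.
#'
#' @param C Rows of the matched axis.
#' @param M_list Columns per block (vector gives several blocks).
#' @param dims Layer dimensions, as in [model_config()].
#' @param activation Activation used in the generative form.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @param scale_u Standard deviation of the entries of the true `U`.
#' @return List with `blocks` (list of matrices) and `truth` (a
#'   `jdsnmf_model` holding the generating factors).
#' @export
simulate_from_model <- function(C, M_list, dims, activation = "sigmoid",
                                noise_sd = 0.01, seed = 1L, scale_u = 1) {
  set.seed(seed)
  cfg <- model_config(dims, activation = activation)
  K <- cfg$dims
  N <- cfg$n_layers
  I <- length(M_list)
  U <- matrix(stats::rnorm(C * K[1L], sd = scale_u), C, K[1L])
  Z <- vector("list", I); H <- vector("list", I)
  for (i in seq_len(I)) {
    Z[[i]] <- if (N > 0L) lapply(seq_len(N), function(n) {
      matrix(stats::rnorm(K[n] * K[n + 1L]), K[n], K[n + 1L])
    }) else list()
    H[[i]] <- matrix(stats::rnorm(K[N + 1L] * M_list[i]), K[N + 1L], M_list[i])
  }
  truth <- new_jdsnmf_model(
    U = U, Z = Z, H = H, config = cfg,
    block_names = paste0("block", seq_len(I)),
    row_ids = paste0("r", seq_len(C)),
    col_ids = lapply(M_list, function(m) paste0("c", seq_len(m)))
  )
  blocks <- lapply(seq_len(I), function(i) {
    X <- reconstruct_block(truth, i)
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
    rownames(X) <- truth$row_ids
    colnames(X) <- truth$col_ids[[i]]
    X
  })
  names(blocks) <- truth$block_names
  list(blocks = blocks, truth = truth)
}
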