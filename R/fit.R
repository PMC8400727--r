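#' Fit the joint deep semi-NMF model
#'
#' Minimizes the joint objective
#' \deqn{\sum_i \|X_i - U\,g(Z_i^1 g(Z_i^2 \cdots g(Z_i^N H_i^N)))\|_F^2
#'       + \lambda \sum_S \|S\|_F^2}
#' over the free factors `U`, all junction matrices `Z_i^n` and the deepest
#' latents `H_i^N`, with every intermediate layer latent derived through the
#' activation `g` (and therefore non-negative by construction). Optimization
#' is full-batch Adam on analytic gradients, started from the deterministic
#' [svd_initialize()] warm start; training stops early when the best
#' objective has not improved by a relative `tol` for `patience` consecutive
#' epochs, and the best-objective snapshot is returned.
#'
#' @param blocks List of matrices or `data_block`s sharing their rows (the
#'   matched axis).
#' @param config A [model_config()].
#' @param init Optional `jdsnmf_model` to warm-start from (defaults to
#'   [svd_initialize()]).
#' @param verbose Print a progress line every 100 epochs.
#' @return A fitted `jdsnmf_model` whose `trace` is a tibble with one row
#'   per epoch (`epoch`, `total_loss`, one reconstruction-loss column per
#'   block, `reg_loss`) and attributes `stopped_early` and `best_epoch`.
#' @examples
#' sim <- simulate_from_model(C = 20, M_list = 15, dims = c(3, 2), seed = 1)
#' fit <- jdsnmf_fit(sim$blocks, model_config(c(3, 2), max_epochs = 200))
#' glance(fit)
#' @export
jdsnmf_fit <- function(blocks, config, init = NULL, verbose = FALSE) {
  blocks <- as_block_list(blocks)
  model <- init %||% svd_initialize(blocks, config)
  model$config <- config
  X <- lapply(blocks, `[[`, "values")
  I <- length(X)
  N <- config$n_layers
  lam <- config$l2_lambda
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  # flat parameter list: U, then Z_i^n, then H_i^N
  params <- c(list(U = model$U),
              unlist(lapply(seq_len(I), function(i) {
                zs <- model$Z[[i]]
                if (N > 0L) stats::setNames(zs, paste0("Z", i, "_", seq_len(N))) else list()
              }), recursive = FALSE),
              stats::setNames(model$H, paste0("H", seq_len(I))))
  m1 <- lapply(params, function(p) array(0, dim = dim(p)))
  m2 <- m1

  put_params <- function(model, params) {
    model$U <- params$U
    for (i in seq_len(I)) {
      if (N > 0L) for (n in seq_len(N)) model$Z[[i]][[n]] <- params[[paste0("Z", i, "_", n)]]
      model$H[[i]] <- params[[paste0("H", i)]]
    }
    model
  }

  # loss + analytic gradients at the current parameters
  loss_grad <- function(params) {
    model <- put_params(model, params)
    grads <- lapply(params, function(p) array(0, dim = dim(p)))
    fit_terms <- numeric(I)
    for (i in seq_len(I)) {
      fw <- forward_block(model, i, keep = "all")
      E <- fw$recon - X[[i]]
      fit_terms[i] <- sum(E * E)
      dR <- 2 * E
      A0 <- if (N > 0L) fw$A[[1L]] else model$H[[i]]
      grads$U <- grads$U + dR %*% t(A0)
      dA <- crossprod(model$U, dR)           # gradient wrt H^0
      if (N > 0L) {
        for (n in seq_len(N)) {
          dB <- dA * activation_grad(fw$B[[n]], config$activation)
          An <- if (n < N) fw$A[[n + 1L]] else model$H[[i]]
          grads[[paste0("Z", i, "_", n)]] <- dB %*% t(An)
          dA <- crossprod(model$Z[[i]][[n]], dB)
        }
      }
      grads[[paste0("H", i)]] <- dA
    }
    reg <- 0
    if (lam > 0) {
      for (nm in names(params)) {
        reg <- reg + sum(params[[nm]]^2)
        grads[[nm]] <- grads[[nm]] + 2 * lam * params[[nm]]
      }
      reg <- lam * reg
    }
    list(total = sum(fit_terms) + reg, fit_terms = fit_terms, reg = reg,
         grads = grads)
  }

  best <- Inf; best_params <- params; best_epoch <- 0L
  wait <- 0L; stopped_early <- FALSE; anneals <- 0L; t_adam <- 0L
  tr_total <- numeric(0); tr_fit <- matrix(NA_real_, 0, I); tr_reg <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    lg <- loss_grad(params)
    if (!is.finite(lg$total)) {
      stop("optimization diverged (non-finite loss) at epoch ", epoch,
           " with learning_rate = ", lr, call. = FALSE)
    }
    tr_total[epoch] <- lg$total
    tr_fit <- rbind(tr_fit, lg$fit_terms)
    tr_reg[epoch] <- lg$reg

    if (lg$total < best * (1 - config$tol)) {
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (lg$total < best) {
      best <- lg$total; best_params <- params; best_epoch <- epoch
    }
    if (wait >= config$patience) {
      if (anneals < config$max_anneals) {
        # plateau: restart from the best snapshot with a smaller step
        anneals <- anneals + 1L
        lr <- lr * config$lr_decay
        params <- best_params
        m1 <- lapply(params, function(p) array(0, dim = dim(p)))
        m2 <- m1
        t_adam <- 0L
        wait <- 0L
      } else {
        stopped_early <- TRUE
        break
      }
    }

    t_adam <- t_adam + 1L
    bc1 <- 1 - beta1^t_adam; bc2 <- 1 - beta2^t_adam
    for (nm in names(params)) {
      g <- lg$grads[[nm]]
      m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g
      m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (m1[[nm]] / bc1) / (sqrt(m2[[nm]] / bc2) + eps)
    }
    if (verbose && epoch %% 100L == 0L) {
      message(sprintf("epoch %5d  objective %.6g", epoch, lg$total))
    }
  }

  model <- put_params(model, best_params)
  trace <- tibble::tibble(epoch = seq_along(tr_total), total_loss = tr_total)
  fit_cols <- stats::setNames(as.data.frame(tr_fit),
                              paste0("fit_", model$block_names))
  trace <- dplyr::bind_cols(trace, tibble::as_tibble(fit_cols))
  trace$reg_loss <- tr_reg
  attr(trace, "stopped_early") <- stopped_early
  attr(trace, "best_epoch") <- best_epoch
  model$trace <- trace
  model
}
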