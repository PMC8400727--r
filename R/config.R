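#' Model configuration
#'
#' Hyperparameters of the joint deep semi-NMF decomposition. `dims` gives
#' the reduced dimension of every layer, `dims[1]` = K0 for the first layer
#' down to `dims[n_layers + 1]` = K_N for the deepest; dimensions must be
#' non-increasing (strictly decreasing in the canonical deep configuration;
#' equal consecutive dimensions are allowed and, with one layer and the
#' identity activation, recover plain semi-NMF).
#'
#' @param dims Integer vector of layer dimensions `K0 >= K1 >= ... >= KN`,
#'   length `n_layers + 1`.
#' @param activation Activation linking layers: `"sigmoid"` (default, as
#'   used for all omics experiments), `"relu"`, or `"identity"` (linear
#'   special case).
#' @param l2_lambda Non-negative L2 penalty on all free factors.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum optimization epochs.
#' @param patience Plateau length: epochs without sufficient improvement of
#'   the best objective before the step size is annealed (and, once the
#'   annealing budget is spent, training stops).
#' @param tol Minimum relative improvement of the best objective that counts
#'   as progress.
#' @param lr_decay Factor applied to the learning rate at each plateau; the
#'   optimizer restarts from the best snapshot with the smaller step.
#' @param max_anneals Number of plateau annealings before early stopping.
#' @param seed Integer seed for any stochastic element (reserved; the fit is
#'   deterministic given the SVD initialization).
#' @return An object of class `model_config`.
#' @export
model_config <- function(dims, activation = "sigmoid", l2_lambda = 0,
                         learning_rate = 1e-3, max_epochs = 2000L,
                         patience = 50L, tol = 1e-5, lr_decay = 0.5,
                         max_anneals = 4L, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) < 1L || any(dims < 1L)) {
    stop("dims must be positive integers", call. = FALSE)
  }
  if (length(dims) > 1L && any(diff(dims) > 0L)) {
    stop("dims must be non-increasing (K0 >= K1 >= ... >= KN)", call. = FALSE)
  }
  if (l2_lambda < 0) stop("l2_lambda must be non-negative", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (lr_decay <= 0 || lr_decay >= 1) stop("lr_decay must be in (0,1)", call. = FALSE)
  structure(
    list(n_layers = length(dims) - 1L, dims = dims,
         activation = match_activation(activation),
         l2_lambda = l2_lambda, learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         tol = tol, lr_decay = lr_decay, max_anneals = as.integer(max_anneals),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> N = %d layers, dims = (%s), %s activation, lambda = %g\n",
              x$n_layers, paste(x$dims, collapse = ", "), x$activation, x$l2_lambda))
  invisible(x)
}

check_config_blocks <- function(config, blocks) {
  C <- nrow(blocks[[1L]]$values)
  M <- vapply(blocks, function(b) ncol(b$values), integer(1))
  if (config$dims[1L] >= min(C, min(M))) {
    stop("K0 = ", config$dims[1L], " must be smaller than min(C, M_i) = ",
         min(C, min(M)), call. = FALSE)
  }
  invisible(TRUE)
}
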