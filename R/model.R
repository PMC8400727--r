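#' @importFrom generics tidy glance
#' @importFrom rlang .data
NULL

# Internal constructor. U: C x K0; Z[[i]][[n]]: K_{n-1} x K_n for n = 1..N;
# H[[i]]: K_N x M_i (the deepest free latent, unconstrained in sign).
new_jdsnmf_model <- function(U, Z, H, config, block_names, row_ids, col_ids,
                             trace = NULL) {
  structure(
    list(U = U, Z = Z, H = H, config = config,
         block_names = block_names, row_ids = row_ids, col_ids = col_ids,
         trace = trace),
    class = "jdsnmf_model"
  )
}

#' @export
print.jdsnmf_model <- function(x, ...) {
  cat(sprintf("<jdsnmf_model> %d block(s), C = %d, dims = (%s), %s activation\n",
              length(x$block_names), nrow(x$U),
              paste(x$config$dims, collapse = ", "), x$config$activation))
  if (!is.null(x$trace)) {
    cat(sprintf("  fitted: %d epochs, best objective %.6g at epoch %d%s\n",
                nrow(x$trace), min(x$trace$total_loss),
                which.min(x$trace$total_loss),
                if (isTRUE(attr(x$trace, "stopped_early"))) " (early stop)" else ""))
  }
  invisible(x)
}

n_blocks <- function(model) length(model$block_names)

check_block_index <- function(model, i) {
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > n_blocks(model)) {
    stop("block index out of range (1..", n_blocks(model), ")", call. = FALSE)
  }
  as.integer(i)
}

# Forward pass for block i. Returns pre-activations B[[n]] = Z^n %*% A^n and
# layer latents A[[n]] (A[[n]] is H^{n-1}, so A[[1]] is H^0); keep = "all"
# also returns the reconstruction U %*% H^0.
forward_block <- function(model, i, keep = c("recon", "all")) {
  keep <- match.arg(keep)
  cfg <- model$config
  N <- cfg$n_layers
  A <- model$H[[i]]                       # H^N, deepest free latent
  Bs <- vector("list", N)
  As <- vector("list", N)
  if (N > 0L) {
    for (n in rev(seq_len(N))) {
      Zn <- model$Z[[i]][[n]]
      if (ncol(Zn) != nrow(A)) {
        stop(sprintf("shape mismatch at block %d layer %d: Z is %dx%d but H is %dx%d",
                     i, n, nrow(Zn), ncol(Zn), nrow(A), ncol(A)), call. = FALSE)
      }
      Bs[[n]] <- Zn %*% A
      A <- apply_activation(Bs[[n]], cfg$activation)
      As[[n]] <- A
    }
  }
  if (ncol(model$U) != nrow(A)) {
    stop(sprintf("shape mismatch at block %d: U is %dx%d but H^0 is %dx%d",
                 i, nrow(model$U), ncol(model$U), nrow(A), ncol(A)), call. = FALSE)
  }
  recon <- model$U %*% A
  if (keep == "recon") recon else list(recon = recon, B = Bs, A = As)
}

#' Reconstruct one block from a fitted model
#'
#' Computes `U g(Z_i^1 g(Z_i^2 ... g(Z_i^N H_i^N)))`, the model's
#' approximation of block `i`; the innermost factor is the deepest layer.
#' Because `U` and the deepest latent are unconstrained in sign, the
#' reconstruction may have mixed signs even though every derived layer
#' latent is non-negative.
#'
#' @param model A `jdsnmf_model`.
#' @param i Block index.
#' @return A numeric `C x M_i` matrix.
#' @export
reconstruct_block <- function(model, i = 1L) {
  i <- check_block_index(model, i)
  forward_block(model, i, keep = "recon")
}

#' Derived layer latents of a block
#'
#' Returns the hierarchy `H^0, ..., H^N` for block `i`, where
#' `H^{n-1} = g(Z^n H^n)`. All layers except the deepest are outputs of the
#' activation and hence non-negative (in (0,1) under sigmoid); the deepest
#' `H^N` is a free parameter with unconstrained sign.
#'
#' @inheritParams reconstruct_block
#' @return A list of matrices `H0 ... HN` (names `"H0"`, `"H1"`, ...).
#' @export
layer_latents <- function(model, i = 1L) {
  i <- check_block_index(model, i)
  N <- model$config$n_layers
  out <- vector("list", N + 1L)
  names(out) <- paste0("H", 0:N)
  out[[N + 1L]] <- model$H[[i]]
  if (N > 0L) {
    fw <- forward_block(model, i, keep = "all")
    for (n in seq_len(N)) out[[n]] <- fw$A[[n]]
  }
  out
}

#' Objective value of a model on data blocks
#'
#' Total loss = sum over blocks of the squared Frobenius reconstruction
#' error, plus `lambda` times the summed squared Frobenius norms of all free
#' factors (`U`, every junction matrix `Z_i^n`, and every deepest latent
#' `H_i^N`). Derived layers are not penalized: their size is controlled
#' structurally through the activation.
#'
#' @param model A `jdsnmf_model`.
#' @param blocks The data blocks (list of matrices or `data_block`s).
#' @param lambda L2 penalty; defaults to the model's configured value.
#' @return A list with `total`, `fit_terms` (per block) and `reg_term`.
#' @export
jdsnmf_objective <- function(model, blocks, lambda = model$config$l2_lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  blocks <- as_block_list(blocks)
  if (length(blocks) != n_blocks(model)) {
    stop("model has ", n_blocks(model), " blocks but ", length(blocks),
         " were supplied", call. = FALSE)
  }
  fit_terms <- vapply(seq_along(blocks), function(i) {
    R <- reconstruct_block(model, i)
    sum((blocks[[i]]$values - R)^2)
  }, numeric(1))
  reg <- 0
  if (lambda > 0) {
    reg <- sum(model$U^2) +
      sum(vapply(model$Z, function(zs) sum(vapply(zs, function(z) sum(z^2), numeric(1))), numeric(1))) +
      sum(vapply(model$H, function(h) sum(h^2), numeric(1)))
    reg <- lambda * reg
  }
  list(total = sum(fit_terms) + reg, fit_terms = fit_terms, reg_term = reg)
}

#' Extract per-entity latent features for downstream learning
#'
#' In feature-matched mode (several cohorts sharing genes), each block's
#' samples live on its columns and the per-sample features at a given layer
#' are the columns of that block's `H^layer`, returned transposed as a
#' samples-by-dimensions matrix. In sample-matched mode the only shared
#' per-sample object is `U`, whose rows are returned (the `layer` argument
#' is ignored there).
#'
#' @param model A fitted `jdsnmf_model`.
#' @param layer Layer to read features from, `0..N` (deepest = `N`).
#' @param block Block index; required in feature-matched mode.
#' @param mode `"feature_matched"` or `"sample_matched"`.
#' @return A numeric matrix, entities in rows, latent dimensions in columns.
#' @export
extract_features <- function(model, layer = model$config$n_layers,
                             block = NULL,
                             mode = c("feature_matched", "sample_matched")) {
  mode <- match.arg(mode)
  if (mode == "sample_matched") {
    out <- model$U
    rownames(out) <- model$row_ids
    colnames(out) <- paste0("dim", seq_len(ncol(out)))
    return(out)
  }
  if (is.null(block)) stop("block index is required in feature-matched mode", call. = FALSE)
  block <- check_block_index(model, block)
  N <- model$config$n_layers
  if (layer < 0L || layer > N) {
    stop("layer must be between 0 and ", N, call. = FALSE)
  }
  H <- layer_latents(model, block)[[layer + 1L]]
  out <- t(H)
  rownames(out) <- model$col_ids[[block]]
  colnames(out) <- paste0("dim", seq_len(ncol(out)))
  out
}

#' @rdname jdsnmf_fit
#' @param x A `jdsnmf_model`.
#' @param ... Unused.
#' @export
tidy.jdsnmf_model <- function(x, ...) {
  K0 <- x$config$dims[1L]
  shared <- tibble::tibble(
    matrix = "U", block = NA_character_, layer = NA_integer_,
    entity = rep(x$row_ids, times = K0),
    dimension = rep(seq_len(K0), each = length(x$row_ids)),
    value = as.vector(x$U)
  )
  per_block <- purrr::map_dfr(seq_along(x$block_names), function(i) {
    H0 <- layer_latents(x, i)[["H0"]]
    tibble::tibble(
      matrix = "H", block = x$block_names[[i]], layer = 0L,
      entity = rep(x$col_ids[[i]], each = nrow(H0)),
      dimension = rep(seq_len(nrow(H0)), times = ncol(H0)),
      value = as.vector(H0)
    )
  })
  dplyr::bind_rows(shared, per_block)
}

#' @rdname jdsnmf_fit
#' @export
glance.jdsnmf_model <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_blocks = length(x$block_names),
    n_layers = x$config$n_layers,
    k0 = x$config$dims[1L],
    activation = x$config$activation,
    lambda = x$config$l2_lambda,
    epochs = if (is.null(tr)) NA_integer_ else nrow(tr),
    best_epoch = if (is.null(tr)) NA_integer_ else which.min(tr$total_loss),
    objective = if (is.null(tr)) NA_real_ else min(tr$total_loss),
    stopped_early = if (is.null(tr)) NA else isTRUE(attr(tr, "stopped_early"))
  )
}

#' @rdname jdsnmf_fit
#' @param object A fitted `jdsnmf_model`.
#' @export
autoplot.jdsnmf_model <- function(object, ...) {
  if (is.null(object$trace)) stop("model has no training trace", call. = FALSE)
  df <- tidyr::pivot_longer(object$trace,
                            cols = -"epoch",
                            names_to = "term", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "objective (log scale)", colour = NULL,
                  title = "JDSNMF training trace")
}
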