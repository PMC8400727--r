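#' Elementwise activation functions
#'
#' Applies the activation `g` used to link consecutive layers of the
#' factorization. `sigmoid` maps into (0, 1), `relu` clips negatives at 0;
#' both therefore make every derived layer latent non-negative. The
#' `identity` activation is a linear escape hatch: with it the model family
#' collapses to (deep) semi-NMF and is used for oracle comparisons against
#' truncated SVD.
#'
#' @param M A numeric matrix (or vector).
#' @param kind One of `"sigmoid"`, `"relu"`, `"identity"`.
#' @return A matrix of the same shape with the activation applied
#'   elementwise.
#' @examples
#' apply_activation(matrix(c(-1, 0, 1), 1), "sigmoid")
#' apply_activation(matrix(c(-2, 3), 1), "relu")
#' @export
apply_activation <- function(M, kind = c("sigmoid", "relu", "identity")) {
  kind <- match_activation(kind)
  switch(kind,
    sigmoid  = 1 / (1 + exp(-M)),
    relu     = pmax(M, 0),
    identity = M
  )
}

match_activation <- function(kind) {
  kind <- kind[[1L]]
  if (!is.character(kind) || !kind %in% c("sigmoid", "relu", "identity")) {
    stop("unsupported activation: ", deparse(kind),
         " (use \"sigmoid\", \"relu\" or \"identity\")", call. = FALSE)
  }
  kind
}

# derivative of g evaluated from the *pre-activation* matrix
activation_grad <- function(M, kind) {
  switch(kind,
    sigmoid  = { s <- 1 / (1 + exp(-M)); s * (1 - s) },
    relu     = (M > 0) * 1,
    identity = array(1, dim = dim(M))
  )
}
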