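# Independent oracles used across tests. These deliberately avoid the
# package's own linear-algebra paths: matrix products are explicit triple
# loops, activations are scalar switch statements.

loop_matmul <- function(P, Q) {
  out <- matrix(0, nrow(P), ncol(Q))
  for (r in seq_len(nrow(P))) {
    for (cc in seq_len(ncol(Q))) {
      s <- 0
      for (t in seq_len(ncol(P))) s <- s + P[r, t] * Q[t, cc]
      out[r, cc] <- s
    }
  }
  out
}

loop_activation <- function(M, kind) {
  out <- M
  for (r in seq_len(nrow(M))) {
    for (cc in seq_len(ncol(M))) {
      v <- M[r, cc]
      out[r, cc] <- switch(kind,
        sigmoid = 1 / (1 + exp(-v)),
        relu = if (v > 0) v else 0,
        identity = v)
    }
  }
  out
}

# nested-loop evaluation of U g(Z1 g(Z2 ... g(ZN HN))) for one block
loop_reconstruct <- function(model, i) {
  N <- model$config$n_layers
  A <- model$H[[i]]
  if (N > 0L) {
    for (n in rev(seq_len(N))) {
      A <- loop_activation(loop_matmul(model$Z[[i]][[n]], A), model$config$activation)
    }
  }
  loop_matmul(model$U, A)
}

# a random ground-truth model plus matching noisy blocks
random_truth <- function(C, M_list, dims, activation = "sigmoid",
                         noise_sd = 0, seed = 1L) {
  simulate_from_model(C = C, M_list = M_list, dims = dims,
                      activation = activation, noise_sd = noise_sd,
                      seed = seed)
}

# squared Frobenius residual of the best rank-k approximation
svd_residual <- function(X, k) {
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d[-seq_len(k)]^2)
}

# two-sided Fisher p-value by direct hypergeometric enumeration
fisher_p_enum <- function(a, b, cc, d) {
  m <- a + b          # module size
  r <- a + cc         # reference size
  n <- a + b + cc + d # universe
  ks <- max(0L, m + r - n):min(m, r)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r, k) + lchoose(n - r, m - k) - lchoose(n, m))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
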