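#' Module construction from first-layer latent matrices
#'
#' Each latent dimension of the first layer defines a module. Samples are
#' assigned to module `k` when their value in row `k` of that block's
#' first-layer sample latent `H^0` exceeds `mu + 1.6449 sigma` (the upper
#' 5% tail of a normal fit); features split into a positive set
#' (`> mu + 2.5758 sigma`) and a negative set (`< mu - 2.5758 sigma`),
#' together the two-sided 1% tails of the shared latent `U`. The mean and
#' standard deviation are computed per module (per latent dimension; the
#' population formula, `ddof = 0`), not pooled over the whole matrix; a
#' `global = TRUE` flag switches to matrix-wide statistics. Entities may
#' belong to several modules; degenerate (zero-spread) dimensions select
#' nothing, with a warning.
#'
#' @name modules
NULL

SAMPLE_Z <- 1.6449   # upper 5% normal quantile
FEATURE_Z <- 2.5758  # two-sided 1% normal quantile

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname modules
#' @param H0 First-layer sample latent matrix of one block (K0 x M).
#' @param k Module (latent dimension) index.
#' @param z Threshold multiplier for the sample rule.
#' @param global Compute mu/sigma over the whole matrix instead of per row.
#' @return `sample_membership()`: character vector of selected sample ids
#'   (column names of `H0`, or indices as character).
#' @export
sample_membership <- function(H0, k, z = SAMPLE_Z, global = FALSE) {
  H0 <- as.matrix(H0)
  ids <- colnames(H0) %||% as.character(seq_len(ncol(H0)))
  row <- H0[k, ]
  ref <- if (global) as.vector(H0) else row
  s <- pop_sd(ref)
  if (s == 0) {
    warning("module ", k, ": zero spread, no samples selected", call. = FALSE)
    return(character(0))
  }
  ids[row > mean(ref) + z * s]
}

#' @rdname modules
#' @param U Shared feature latent matrix (features x K0).
#' @param z_feat Threshold multiplier for the two-sided feature rule.
#' @return `feature_membership()`: list with `positive` and `negative`
#'   character vectors of feature ids (row names of `U`).
#' @export
feature_membership <- function(U, k, z_feat = FEATURE_Z, global = FALSE) {
  U <- as.matrix(U)
  ids <- rownames(U) %||% as.character(seq_len(nrow(U)))
  col <- U[, k]
  ref <- if (global) as.vector(U) else col
  s <- pop_sd(ref)
  if (s == 0) {
    warning("module ", k, ": zero spread, no features selected", call. = FALSE)
    return(list(positive = character(0), negative = character(0)))
  }
  mu <- mean(ref)
  list(positive = ids[col > mu + z_feat * s],
       negative = ids[col < mu - z_feat * s])
}

#' @rdname modules
#' @param model A fitted `jdsnmf_model` (feature-matched orientation: rows
#'   of `U` are features, columns of each `H^0` are samples).
#' @param sample_z,feature_z Threshold multipliers.
#' @return `build_modules()`: a tibble with one row per selected entity and
#'   columns `module`, `block` (`NA` for features, which live in the shared
#'   latent), `role` (`"sample"`, `"positive_feature"`,
#'   `"negative_feature"`), `entity`, `value` and `cutoff`. Every module
#'   `1..K0` appears in the `module` levels even when it selected nothing;
#'   `attr(, "n_modules")` records K0.
#' @export
build_modules <- function(model, sample_z = SAMPLE_Z, feature_z = FEATURE_Z,
                          global = FALSE) {
  K0 <- model$config$dims[1L]
  U <- model$U
  rownames(U) <- model$row_ids
  H0s <- lapply(seq_along(model$block_names), function(i) {
    H0 <- layer_latents(model, i)[["H0"]]
    colnames(H0) <- model$col_ids[[i]]
    H0
  })
  rows <- list()
  for (k in seq_len(K0)) {
    fm <- feature_membership(U, k, z_feat = feature_z, global = global)
    ref <- if (global) as.vector(U) else U[, k]
    mu <- mean(ref); s <- pop_sd(ref)
    if (length(fm$positive)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        module = k, block = NA_character_, role = "positive_feature",
        entity = fm$positive, value = U[fm$positive, k],
        cutoff = mu + feature_z * s)
    }
    if (length(fm$negative)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        module = k, block = NA_character_, role = "negative_feature",
        entity = fm$negative, value = U[fm$negative, k],
        cutoff = mu - feature_z * s)
    }
    for (i in seq_along(model$block_names)) {
      H0 <- H0s[[i]]
      sm <- sample_membership(H0, k, z = sample_z, global = global)
      refs <- if (global) as.vector(H0) else H0[k, ]
      if (length(sm)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          module = k, block = model$block_names[[i]], role = "sample",
          entity = sm, value = H0[k, sm],
          cutoff = mean(refs) + sample_z * pop_sd(refs))
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(module = integer(0), block = character(0),
                   role = character(0), entity = character(0),
                   value = numeric(0), cutoff = numeric(0))
  attr(out, "n_modules") <- K0
  out
}
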