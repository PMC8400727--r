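#' Local-surrogate (LIME-style) module importance
#'
#' Explains black-box classifiers over module-level latent features by
#' local linear surrogates: around each explained instance, feature vectors
#' are perturbed with Gaussian noise scaled to each feature's spread, the
#' classifier is queried, samples are weighted by an exponential kernel on
#' standardized distance, and a weighted ridge regression approximates the
#' classifier locally. A module's importance is the sum of the absolute
#' surrogate coefficients over all explained instances (and classifiers,
#' when several are supplied).
#'
#' @param predict_fns A scoring function `X -> class-1 probability/score`,
#'   or a named list of such functions (one per classifier).
#' @param X Numeric feature matrix (samples x modules) the classifiers were
#'   trained on; defines the perturbation scales.
#' @param instances Row indices to explain (default: all rows).
#' @param n_perturbations Perturbed samples per instance.
#' @param kernel_width Kernel width on standardized distance; default
#'   `0.75 * sqrt(ncol(X))`.
#' @param ridge Ridge penalty of the surrogate.
#' @param seed Integer seed.
#' @return A tibble with columns `module`, `classifier`, `importance`.
#' @export
local_surrogate_importance <- function(predict_fns, X, instances = NULL,
                                       n_perturbations = 1000L,
                                       kernel_width = NULL, ridge = 1e-3,
                                       seed = 1L) {
  if (is.function(predict_fns)) predict_fns <- list(classifier = predict_fns)
  X <- as.matrix(X)
  d <- ncol(X)
  instances <- instances %||% seq_len(nrow(X))
  kernel_width <- kernel_width %||% (0.75 * sqrt(d))
  sds <- apply(X, 2L, stats::sd)
  scale_sd <- ifelse(sds > 0, sds, 1)

  purrr::imap_dfr(predict_fns, function(pf, cname) {
    set.seed(seed)
    total <- numeric(d)
    warned <- FALSE
    for (idx in instances) {
      x0 <- X[idx, ]
      Z <- matrix(stats::rnorm(n_perturbations * d), n_perturbations, d)
      Z <- sweep(Z, 2L, scale_sd, "*")
      Z <- sweep(Z, 2L, x0, "+")
      yhat <- as.numeric(pf(Z))
      if (stats::sd(yhat) == 0) {
        if (!warned) {
          warning("constant predictions for '", cname,
                  "'; surrogate weights are zero", call. = FALSE)
          warned <- TRUE
        }
        next
      }
      Zs <- sweep(sweep(Z, 2L, x0, "-"), 2L, scale_sd, "/")
      w <- exp(-rowSums(Zs^2) / kernel_width^2)
      # weighted ridge on standardized perturbations
      A <- crossprod(Zs, Zs * w) + diag(ridge, d)
      b <- crossprod(Zs, w * (yhat - stats::weighted.mean(yhat, w)))
      total <- total + abs(as.numeric(solve(A, b)))
    }
    tibble::tibble(module = seq_len(d), classifier = cname, importance = total)
  })
}

#' Random-forest module importance
#'
#' Mean-decrease-in-impurity importance of each module feature for a binary
#' classification, normalized to sum to one.
#'
#' @param features Numeric matrix (samples x modules).
#' @param labels 0/1 labels.
#' @param seed Integer seed.
#' @param num_trees Number of trees.
#' @return A tibble with `module`, `rf_importance` (sums to 1).
#' @export
rf_module_importance <- function(features, labels, seed = 1L,
                                 num_trees = 500L) {
  set.seed(seed)
  fit <- randomForest::randomForest(as.matrix(features),
                                    factor(labels, levels = c(0, 1)),
                                    ntree = num_trees, importance = FALSE)
  imp <- as.numeric(fit$importance[, "MeanDecreaseGini"])
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tibble::tibble(module = seq_along(imp), rf_importance = imp)
}

#' Combine local-surrogate and forest importance into one report
#'
#' @param lime_tbl Output of [local_surrogate_importance()].
#' @param rf_tbl Output of [rf_module_importance()].
#' @return A tibble with one row per module: per-classifier summed local
#'   weights (wide), their total `lime_total`, `rf_importance`, and `rank`
#'   (1 = highest `lime_total`).
#' @export
module_importance_report <- function(lime_tbl, rf_tbl = NULL) {
  wide <- tidyr::pivot_wider(lime_tbl, names_from = "classifier",
                             values_from = "importance",
                             names_prefix = "lime_")
  wide$lime_total <- rowSums(wide[, -1, drop = FALSE])
  if (!is.null(rf_tbl)) wide <- dplyr::left_join(wide, rf_tbl, by = "module")
  wide$rank <- rank(-wide$lime_total, ties.method = "first")
  wide
}

#' Age association of module sample latents
#'
#' For each module (column of a block's first-layer sample latent,
#' transposed to samples x modules), fits ordinary least squares of the
#' latent value on age, sex, diagnosis, and the leading principal
#' components of the latent matrix that are *not* related to age
#' (correlation-test p >= `pc_p`). The age coefficient gamma and its
#' p-value flag positively (gamma > 0) or negatively (gamma < 0)
#' age-associated modules.
#'
#' @param sample_latent Numeric matrix, samples x modules.
#' @param covariates Data frame aligned with the rows, with columns `age`
#'   and optionally `sex` and `diagnosis`.
#' @param pc_p Correlation-test p-value at or above which a PC counts as
#'   age-unrelated and enters the design.
#' @param n_pcs_max Number of leading PCs screened.
#' @return A tibble with one row per module: `module`, `gamma`, `p_value`,
#'   `sex_coef`, `diagnosis_coef`, `n_pcs_used`.
#' @export
age_regression <- function(sample_latent, covariates, pc_p = 0.05,
                           n_pcs_max = 10L) {
  Y <- as.matrix(sample_latent)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(Y)) {
    stop("covariates must align with the rows of sample_latent", call. = FALSE)
  }
  if (anyNA(covariates)) stop("missing covariate values", call. = FALSE)
  if (!"age" %in% names(covariates)) stop("covariates must contain 'age'", call. = FALSE)

  keep_cov <- c("age")
  for (v in c("sex", "diagnosis")) {
    if (!v %in% names(covariates)) next
    if (length(unique(covariates[[v]])) < 2L) {
      warning("covariate '", v, "' is constant; dropped", call. = FALSE)
    } else {
      keep_cov <- c(keep_cov, v)
    }
  }

  pcs <- stats::prcomp(Y, center = TRUE, scale. = FALSE)$x
  n_scr <- min(n_pcs_max, ncol(pcs))
  unrelated <- integer(0)
  for (k in seq_len(n_scr)) {
    if (stats::sd(pcs[, k]) == 0) next
    p <- stats::cor.test(pcs[, k], covariates$age)$p.value
    if (p >= pc_p) unrelated <- c(unrelated, k)
  }
  pc_df <- if (length(unrelated)) {
    stats::setNames(as.data.frame(pcs[, unrelated, drop = FALSE]),
                    paste0("PC", unrelated))
  } else NULL

  purrr::map_dfr(seq_len(ncol(Y)), function(j) {
    df <- data.frame(y = Y[, j], covariates[keep_cov])
    if (!is.null(pc_df)) df <- cbind(df, pc_df)
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    pick <- function(prefix) {
      hit <- grep(paste0("^", prefix), rownames(cf))
      if (length(hit)) unname(cf[hit[1L], "Estimate"]) else NA_real_
    }
    tibble::tibble(
      module = j,
      gamma = unname(cf["age", "Estimate"]),
      p_value = unname(cf["age", "Pr(>|t|)"]),
      sex_coef = pick("sex"),
      diagnosis_coef = pick("diagnosis"),
      n_pcs_used = length(unrelated)
    )
  })
}

#' Fisher's exact test of gene-set overlap
#'
#' Two-sided Fisher's exact test on the 2x2 table of membership in a module
#' gene set versus a reference set, within a stated gene universe.
#'
#' @param module_genes,reference_genes Character vectors, subsets of
#'   `universe_genes`.
#' @param universe_genes The gene universe.
#' @return A tibble with `n_overlap`, `n_module`, `n_reference`,
#'   `n_universe`, `odds_ratio`, `p_value`.
#' @export
overlap_fisher <- function(module_genes, reference_genes, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0L) stop("empty gene universe", call. = FALSE)
  m <- unique(intersect(module_genes, universe_genes))
  r <- unique(intersect(reference_genes, universe_genes))
  a <- length(intersect(m, r))
  b <- length(setdiff(m, r))
  cc <- length(setdiff(r, m))
  d <- length(universe_genes) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                           alternative = "two.sided")
  tibble::tibble(
    n_overlap = a, n_module = length(m), n_reference = length(r),
    n_universe = length(universe_genes),
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

#' Correlation of module importance with pathway-overlap counts
#'
#' Pearson correlation (with two-sided test) and OLS slope between
#' per-module importance scores and per-module gene-set overlap counts.
#'
#' @param importance,counts Equal-length numeric vectors (length >= 3).
#' @return A tibble with `pearson_r`, `p_value`, `slope`.
#' @export
importance_vs_pathway_regression <- function(importance, counts) {
  stopifnot(length(importance) == length(counts))
  if (length(importance) < 3L) stop("need at least 3 modules", call. = FALSE)
  if (stats::sd(importance) == 0 || stats::sd(counts) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(importance, counts)
  fit <- stats::lm(counts ~ importance)
  tibble::tibble(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)[2L])
  )
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}
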