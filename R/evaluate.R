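#' Label-stratified data splits
#'
#' Produces either stratified k-fold cross-validation folds or a single
#' stratified train/validation/test partition (e.g. the 3:1:1 protocol).
#' Splits are disjoint, exhaustive, and seeded.
#'
#' @param labels Class label vector.
#' @param scheme `"kfold"` or `"train_valid_test"`.
#' @param n_folds Number of folds for `"kfold"`.
#' @param ratio Three positive weights for `"train_valid_test"`
#'   (default `c(3, 1, 1)`).
#' @param seed Integer seed.
#' @return For `"kfold"`: a list of `n_folds` test-index vectors. For
#'   `"train_valid_test"`: a list with `train`, `valid`, `test`.
#' @export
stratified_splits <- function(labels, scheme = c("kfold", "train_valid_test"),
                              n_folds = 5L, ratio = c(3, 1, 1), seed = 1L) {
  scheme <- match.arg(scheme)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes", call. = FALSE)
  set.seed(seed)
  classes <- split(seq_along(labels), labels)
  if (scheme == "kfold") {
    if (any(lengths(classes) < n_folds)) {
      stop("a class has fewer members than folds", call. = FALSE)
    }
    folds <- vector("list", n_folds)
    for (idx in classes) {
      idx <- sample(idx)
      fold_of <- rep(seq_len(n_folds), length.out = length(idx))
      for (f in seq_len(n_folds)) {
        folds[[f]] <- c(folds[[f]], idx[fold_of == f])
      }
    }
    lapply(folds, sort)
  } else {
    stopifnot(length(ratio) == 3L, all(ratio > 0))
    out <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (idx in classes) {
      idx <- sample(idx)
      n <- length(idx)
      n_tr <- round(n * ratio[1] / sum(ratio))
      n_va <- round(n * ratio[2] / sum(ratio))
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$valid <- c(out$valid, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[-seq_len(n_tr + n_va)])
    }
    lapply(out, sort)
  }
}

#' Classifier evaluation of extracted features
#'
#' Trains each classifier on the training rows and reports test AUC (area
#' under the ROC curve between true- and false-positive rates). Classifier
#' hyperparameters are fixed, not tuned.
#'
#' @param features Numeric matrix, samples x latent dimensions.
#' @param labels 0/1 labels aligned with the rows of `features`.
#' @param train,test Row index vectors.
#' @param classifiers Named list of classifier constructors (see
#'   [default_classifiers()]).
#' @param method Method label stored in the result.
#' @param fold Fold/replicate label stored in the result.
#' @param seed Integer seed passed to the classifiers.
#' @return A tibble with columns `method`, `fold`, `classifier`, `auc`.
#' @export
evaluate_features <- function(features, labels, train, test,
                              classifiers = default_classifiers(),
                              method = "features", fold = 1L, seed = 1L) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels[train])) < 2L || length(unique(labels[test])) < 2L) {
    stop("training or test labels contain a single class; AUC undefined",
         call. = FALSE)
  }
  purrr::imap_dfr(classifiers, function(make, name) {
    score <- make(features[train, , drop = FALSE], labels[train], seed = seed)
    tibble::tibble(
      method = method, fold = fold, classifier = name,
      auc = auc_score(labels[test], score(features[test, , drop = FALSE]))
    )
  })
}

#' Paired Wilcoxon signed-rank comparison of AUC vectors
#'
#' Two-sided paired signed-rank test, the protocol used to compare methods
#' over matched folds-by-classifier AUC values.
#'
#' @param aucs_a,aucs_b Equal-length paired AUC vectors (length >= 5).
#' @return A tibble with `statistic` and `p_value`.
#' @export
wilcoxon_compare <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) == length(aucs_b))
  if (length(aucs_a) < 5L) stop("need at least 5 paired values", call. = FALSE)
  if (all(aucs_a == aucs_b)) {
    stop("all paired differences are zero; test degenerate", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(aucs_a, aucs_b, paired = TRUE, exact = FALSE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# fit one feature-extraction method on the multiview benchmark and return
# per-sample features (rows of the shared latent / NMF basis)
extract_benchmark_features <- function(views, method, k, n_layers = 2L,
                                       lambda = 0.01, max_epochs = 600L,
                                       seed = 1L) {
  layer_dims <- function(k, n_layers) {
    round(seq(k, max(2, ceiling(k / 2)), length.out = n_layers + 1L))
  }
  if (method == "nmf") {
    Xc <- shift_nonneg(do.call(cbind, views))
    res <- nmf_multiplicative(Xc, k = k, max_iter = 200L, seed = seed)
    feats <- res$W
  } else if (method == "deep_semi_nmf") {
    cfg <- model_config(layer_dims(k, n_layers), l2_lambda = lambda,
                        max_epochs = max_epochs, seed = seed)
    fit <- jdsnmf_fit(list(all = do.call(cbind, views)), cfg)
    feats <- extract_features(fit, mode = "sample_matched")
  } else if (method == "jdsnmf") {
    cfg <- model_config(layer_dims(k, n_layers), l2_lambda = lambda,
                        max_epochs = max_epochs, seed = seed)
    fit <- jdsnmf_fit(views, cfg)
    feats <- extract_features(fit, mode = "sample_matched")
  } else {
    stop("unknown method: ", method, call. = FALSE)
  }
  unname(feats)
}

#' Multi-view feature-extraction benchmark
#'
#' For each replicate: simulate label-consistent multi-view data, fit every
#' requested feature-extraction method on all samples (unsupervised), pick
#' each method's hyperparameters by validation AUC of a fixed linear SVM,
#' and report the test AUC of that SVM on the selected features. Test
#' labels are never used for selection.
#'
#' @param design A [simulation_design()].
#' @param methods Subset of `c("nmf", "deep_semi_nmf", "jdsnmf")`.
#' @param grid Tibble/data frame of hyperparameter settings with at least a
#'   `k` column (optional `n_layers`, `lambda`); one row per candidate.
#' @param replicates Number of simulated datasets.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param classifiers Classifiers used for the final test evaluation
#'   (default: linear SVM only, the fixed benchmark classifier).
#' @param max_epochs Optimization budget per factorization fit.
#' @return A tibble of test results (`method`, `fold` = replicate,
#'   `classifier`, `auc`, `k`), with the per-replicate validation selections
#'   in `attr(, "selection")`.
#' @export
run_benchmark <- function(design, methods = c("nmf", "jdsnmf"),
                          grid = tibble::tibble(k = c(10L, 20L)),
                          replicates = 5L, seed = 1L,
                          classifiers = list(svm = clf_svm_linear),
                          max_epochs = 600L) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  if (!"n_layers" %in% names(grid)) grid$n_layers <- 2L
  if (!"lambda" %in% names(grid)) grid$lambda <- 0.01

  results <- list(); selections <- list()
  for (r in seq_len(replicates)) {
    sim <- simulate_multiview(design, seed = seed + r)
    y <- sim$y; sp <- sim$split
    for (method in methods) {
      best_auc <- -Inf; best_feats <- NULL; best_row <- NULL
      for (g in seq_len(nrow(grid))) {
        feats <- extract_benchmark_features(
          sim$views, method, k = grid$k[g], n_layers = grid$n_layers[g],
          lambda = grid$lambda[g], max_epochs = max_epochs, seed = seed + r)
        val <- evaluate_features(feats, y, train = sp$train, test = sp$valid,
                                 classifiers = list(svm = clf_svm_linear),
                                 method = method, fold = r, seed = seed + r)
        v_auc <- mean(val$auc)
        if (v_auc > best_auc) {
          best_auc <- v_auc; best_feats <- feats; best_row <- grid[g, ]
        }
      }
      res <- evaluate_features(best_feats, y, train = sp$train, test = sp$test,
                               classifiers = classifiers,
                               method = method, fold = r, seed = seed + r)
      res$k <- best_row$k
      results[[length(results) + 1L]] <- res
      selections[[length(selections) + 1L]] <-
        dplyr::mutate(best_row, method = method, replicate = r,
                      valid_auc = best_auc)
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "selection") <- dplyr::bind_rows(selections)
  out
}

#' Box plot of benchmark AUCs by method
#'
#' @param results Tibble from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$method, y = .data$auc,
                                        fill = .data$method)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "test AUC")
}
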