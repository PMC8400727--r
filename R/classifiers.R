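# Pluggable classifiers. Each returns a scoring function score(newdata) ->
# numeric score (larger = more likely class 1); AUC only needs a ranking,
# so decision values / class-1 probabilities are interchangeable here.

#' Built-in classifiers
#'
#' Fixed-hyperparameter classifier constructors used by
#' [evaluate_features()]: a linear support vector machine, a random forest,
#' and a single-hidden-layer feed-forward network with L2 weight decay.
#' Each takes a training feature matrix and 0/1 labels and returns a
#' function scoring new samples for class 1.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y 0/1 labels.
#' @param seed Integer seed (forests and nets are stochastic).
#' @return A function `newdata -> numeric scores`.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
clf_svm_linear <- function(x, y, seed = 1L) {
  # standardize features inside the SVM: latent dimensions can carry very
  # different scales depending on the factorization
  scale_ok <- apply(x, 2L, stats::sd) > 0
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                    scale = scale_ok)
  score <- function(newdata) {
    as.numeric(attr(stats::predict(fit, newdata, decision.values = TRUE),
                    "decision.values"))
  }
  # e1071's decision-value sign depends on which class it saw first;
  # orient so class 1 scores higher on the training data
  dv <- score(x)
  flip <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
  function(newdata) flip * score(newdata)
}

#' @rdname classifiers
#' @param num_trees Number of trees.
#' @export
clf_random_forest <- function(x, y, seed = 1L, num_trees = 500L) {
  set.seed(seed)
  fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = num_trees)
  function(newdata) stats::predict(fit, newdata, type = "prob")[, "1"]
}

#' @rdname classifiers
#' @param size Hidden units.
#' @param decay L2 weight decay.
#' @export
clf_nnet <- function(x, y, seed = 1L, size = 8L, decay = 1e-2) {
  set.seed(seed)
  fit <- nnet::nnet(x, y, size = size, decay = decay, maxit = 300L,
                    entropy = TRUE, trace = FALSE)
  function(newdata) as.numeric(stats::predict(fit, newdata))
}

#' @rdname classifiers
#' @export
default_classifiers <- function() {
  list(svm = clf_svm_linear, rf = clf_random_forest, nnet = clf_nnet)
}

auc_score <- function(y, score) {
  if (length(unique(y)) < 2L) {
    stop("AUC undefined: test labels contain a single class", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(y, as.numeric(score), quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
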