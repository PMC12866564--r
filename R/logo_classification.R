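#' Cross-validation configuration
#'
#' @param n_splits Folds per repeat; default 5.
#' @param n_repeats Repeats of the stratified k-fold; default 10.
#' @param seed Integer seed controlling fold assignment and the learners.
#' @param classifier \code{"rf"} (random forest, 100 trees) or \code{"svm"}
#'   (linear-kernel support vector machine).
#' @param ntree Trees for the random forest; default 100.
#' @param top_k_features Features reported by
#'   \code{\link{permutation_importance}}; default 100.
#' @param transform Feature transform: \code{"none"} (raw gene counts),
#'   \code{"binary"} (presence/absence) or \code{"log1p"}.
#' @return A list of class \code{cv_config}.
#' @export
cv_config <- function(n_splits = 5, n_repeats = 10, seed = 1,
                      classifier = c("rf", "svm"), ntree = 100,
                      top_k_features = 100,
                      transform = c("none", "binary", "log1p")) {
  if (n_splits < 2) stop_("cv_config: n_splits must be >= 2")
  structure(list(n_splits = n_splits, n_repeats = n_repeats,
                 seed = as.integer(seed), classifier = match.arg(classifier),
                 ntree = ntree, top_k_features = top_k_features,
                 transform = match.arg(transform)),
            class = "cv_config")
}

#' Binary labels from isolate metadata
#'
#' @param metadata An \code{isolate_metadata} data frame.
#' @param target_source Source label assigned 1; all others 0.
#' @return Named integer vector (isolate id -> 0/1).
#' @export
make_labels <- function(metadata, target_source = "leaf") {
  stats::setNames(as.integer(metadata$source == target_source),
                  metadata$isolate_id)
}

.apply_transform <- function(X, transform) {
  switch(transform,
         none = X,
         binary = (X > 0) + 0,
         log1p = log1p(X))
}

# classifier registry: each entry provides fit(X, y) -> model and two
# prediction functions (class in {0,1}, and a real-valued score oriented so
# that larger means class 1)
.get_classifier <- function(name, ntree = 100) {
  if (name == "rf") {
    list(
      fit = function(X, y)
        randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                   ntree = ntree),
      predict_class = function(model, X)
        as.integer(as.character(predict(model, X))),
      predict_score = function(model, X)
        predict(model, X, type = "prob")[, "1"]
    )
  } else if (name == "svm") {
    list(
      fit = function(X, y) {
        m <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                        kernel = "linear", scale = FALSE)
        dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")[, 1]
        m$score_sign <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
        m
      },
      predict_class = function(model, X)
        as.integer(as.character(predict(model, X))),
      predict_score = function(model, X)
        model$score_sign *
          attr(predict(model, X, decision.values = TRUE), "decision.values")[, 1]
    )
  } else stop_("unknown classifier '", name, "'")
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so per-fold class counts differ from proportionality by <= 1
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop_("stratified folds: class ", cls, " has ", length(idx),
            " members, fewer than n_splits = ", k,
            "; use a smaller number of folds")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation accuracy
#'
#' Folds preserve class proportions to within one item; accuracy is aggregated
#' over all \code{n_splits * n_repeats} evaluations and the SD is taken across
#' those folds. Fully determined by \code{cfg$seed}.
#'
#' @param X Feature matrix (isolates x features) or an \code{og_matrix}.
#' @param y Binary labels (0/1), aligned with the rows of \code{X}.
#' @param cfg A \code{\link{cv_config}}.
#' @return List with \code{mean_accuracy}, \code{sd_accuracy} and \code{folds}
#'   (data frame: repeat, fold, n_test, accuracy).
#' @export
repeated_stratified_cv <- function(X, y, cfg = cv_config()) {
  if (inherits(X, "og_matrix")) X <- X$counts
  X <- .apply_transform(X, cfg$transform)
  y <- as.integer(y)
  clf <- .get_classifier(cfg$classifier, cfg$ntree)
  set.seed(cfg$seed)
  rows <- list()
  for (r in seq_len(cfg$n_repeats)) {
    fold <- .stratified_folds(y, cfg$n_splits)
    for (f in seq_len(cfg$n_splits)) {
      test <- fold == f
      model <- clf$fit(X[!test, , drop = FALSE], y[!test])
      pred <- clf$predict_class(model, X[test, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, n_test = sum(test),
        accuracy = mean(pred == y[test]))
    }
  }
  folds <- do.call(rbind, rows)
  list(mean_accuracy = mean(folds$accuracy),
       sd_accuracy = stats::sd(folds$accuracy), folds = folds)
}

#' Leave-one-group-out cross-validation
#'
#' Each group (typically a genus) is held out in turn as the test set while
#' all other groups form the training set, measuring whether a classifier of
#' isolation origin generalizes across taxa. AUC is computed from the test
#' scores with \code{\link{roc_auc}}; when the held-out group is single-class
#' the accuracy is still reported and the AUC is NA.
#'
#' @param X Feature matrix (isolates x features) or an \code{og_matrix}.
#' @param y Binary labels.
#' @param groups Per-isolate group labels (e.g. genus).
#' @param cfg A \code{\link{cv_config}}.
#' @return List of class \code{logo_result} with \code{results} (data frame:
#'   held_out_group, n_test, accuracy, auc), \code{mean_accuracy},
#'   \code{sd_accuracy}, and \code{roc} (per-group ROC point data frames).
#' @export
logo_cv <- function(X, y, groups, cfg = cv_config()) {
  if (inherits(X, "og_matrix")) X <- X$counts
  X <- .apply_transform(X, cfg$transform)
  y <- as.integer(y)
  glev <- unique(groups)
  if (length(glev) < 2) stop_("logo_cv: need >= 2 groups")
  clf <- .get_classifier(cfg$classifier, cfg$ntree)
  set.seed(cfg$seed)
  rows <- list(); rocs <- list()
  for (g in glev) {
    test <- groups == g
    stopifnot(any(test), any(!test),
              length(intersect(which(test), which(!test))) == 0)
    model <- clf$fit(X[!test, , drop = FALSE], y[!test])
    pred <- clf$predict_class(model, X[test, , drop = FALSE])
    acc <- mean(pred == y[test])
    auc <- NA_real_
    if (length(unique(y[test])) == 2) {
      sc <- clf$predict_score(model, X[test, , drop = FALSE])
      ra <- roc_auc(sc, y[test])
      auc <- ra$auc
      rocs[[g]] <- ra$roc
    }
    rows[[length(rows) + 1L]] <- data.frame(
      held_out_group = g, n_test = sum(test), accuracy = acc, auc = auc,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 mean_accuracy = mean(results$accuracy),
                 sd_accuracy = stats::sd(results$accuracy),
                 roc = rocs),
            class = "logo_result")
}

#' @export
print.logo_result <- function(x, ...) {
  cat(sprintf("leave-one-group-out CV over %d groups: accuracy %.3f +/- %.3f\n",
              nrow(x$results), x$mean_accuracy, x$sd_accuracy))
  print(x$results)
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in test accuracy over
#' \code{n_perm} within-column shuffles of each feature. Deterministic given
#' the seed; ties are broken by feature id. A constant feature has importance
#' exactly 0 (permuting it cannot change predictions).
#'
#' @param model A fitted model from the classifier registry.
#' @param X_test,y_test Held-out features and labels.
#' @param classifier Classifier name the model came from (\code{"rf"} or
#'   \code{"svm"}), used to select the prediction function.
#' @param n_perm Shuffles per feature; default 20.
#' @param seed Integer seed.
#' @param top_k Number of top features returned; default all.
#' @return Data frame (feature, importance), sorted by decreasing importance.
#' @export
permutation_importance <- function(model, X_test, y_test, classifier = "rf",
                                   n_perm = 20, seed = 1, top_k = NULL) {
  clf <- .get_classifier(classifier)
  y_test <- as.integer(y_test)
  base_acc <- mean(clf$predict_class(model, X_test) == y_test)
  set.seed(seed)
  p <- ncol(X_test)
  imp <- numeric(p)
  for (j in seq_len(p)) {
    col <- X_test[, j]
    if (length(unique(col)) == 1) { imp[j] <- 0; next }
    accs <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      Xp <- X_test
      Xp[, j] <- sample(col)
      accs[r] <- mean(clf$predict_class(model, Xp) == y_test)
    }
    imp[j] <- base_acc - mean(accs)
  }
  feats <- colnames(X_test) %||% as.character(seq_len(p))
  out <- data.frame(feature = feats, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
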