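#' Stratified k-fold assignment
#'
#' Shuffles indices within each class (using the current RNG state) and
#' deals them round-robin over folds, so per-fold class counts differ by at
#' most one and remainders land in the earlier folds.
#'
#' @param labels class label per observation.
#' @param k number of folds.
#' @return integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(labels, k = 10L) {
  fold <- integer(length(labels))
  start <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    # continue dealing where the previous class stopped, so the remainder
    # sessions spread over different folds and sizes differ by at most one
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

#' Numeric 0/1 labels from manifest groups
#'
#' Dementia is class 0 (negative), depression class 1 (positive).
#'
#' @param group character vector of `"depression"`/`"dementia"`.
#' @return numeric 0/1 vector.
#' @export
labels_from_group <- function(group) {
  if (!all(group %in% c("depression", "dementia")))
    stop("unknown group value")
  as.numeric(group == "depression")
}

#' k-means clustering of session features
#'
#' Lloyd's algorithm with squared Euclidean distance, multiple seeded
#' restarts, best within-cluster sum of squares kept. Features are
#' standardized before clustering. The degenerate case of fewer distinct
#' points than clusters returns a single cluster without error.
#'
#' @param features data frame or matrix of feature columns.
#' @param k number of clusters (2 for the two patient classes).
#' @param nstart random restarts.
#' @param seed RNG seed (restarts are deterministic under it).
#' @param standardize standardize columns first (default TRUE).
#' @return list: `cluster` (assignment), `inertia` (total within-cluster
#'   SS), `centers`.
#' @export
kmeans_cluster <- function(features, k = 2L, nstart = 50L, seed = 1L,
                           standardize = TRUE) {
  x <- .feature_matrix(features)
  if (standardize) x <- standardize_fit(x)$x
  if (nrow(x) < k) stop("fewer observations than clusters")
  if (nrow(unique(x)) < k)
    return(list(cluster = rep(1L, nrow(x)), inertia = 0, centers = NULL))
  km <- .with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L,
                  algorithm = "Lloyd")))
  list(cluster = km$cluster, inertia = km$tot.withinss, centers = km$centers)
}

#' Score a 2-cluster assignment against the class labels
#'
#' Cluster ids carry no class meaning, so the two possible cluster-to-class
#' mappings are compared and the accuracy-maximizing one used (the
#' `"majority"` option maps each cluster to its majority class instead);
#' the eight confusion-matrix metrics are then computed.
#'
#' @param assignment cluster id per session (two clusters).
#' @param labels true 0/1 labels.
#' @param mapping `"accuracy"` (default) or `"majority"`.
#' @return list: `metrics` (from [compute_metrics()]), `confusion`,
#'   `mapped` (0/1 predictions after mapping).
#' @export
evaluate_clustering <- function(assignment, labels,
                                mapping = c("accuracy", "majority")) {
  mapping <- match.arg(mapping)
  cl <- unique(assignment)
  if (length(cl) != 2L) stop("need exactly two non-empty clusters")
  as1 <- as.numeric(assignment == cl[1])
  if (mapping == "accuracy") {
    pred <- if (mean(as1 == labels) >= mean((1 - as1) == labels)) as1
            else 1 - as1
  } else {
    maj1 <- round(mean(labels[assignment == cl[1]]))
    pred <- ifelse(assignment == cl[1], maj1, 1 - maj1)
  }
  cm <- confusion(labels, pred)
  list(metrics = compute_metrics(cm), confusion = cm, mapped = pred)
}

#' Train a soft-margin SVM on selected, standardized features
#'
#' Standardization is fitted on the training data and stored with the
#' model so held-out data is transformed with training statistics only.
#'
#' @param x training feature matrix (already restricted to the retained
#'   features).
#' @param y 0/1 labels.
#' @param kernel `"linear"`, `"polynomial"` (degree fixed at 3) or
#'   `"radial"`.
#' @param cost soft-margin cost C.
#' @param gamma kernel coefficient for the radial (and polynomial) kernel;
#'   default 1/ncol(x).
#' @return list of class `svm_model`: the fitted `e1071::svm`, the
#'   standardization, kernel and hyperparameters.
#' @export
train_svm <- function(x, y, kernel = "linear", cost = 1, gamma = NULL, ...) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("training data has a single class")
  std <- standardize_fit(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(std$x, factor(y, levels = c(0, 1)), scale = FALSE,
                    kernel = kernel, degree = 3L, cost = cost,
                    gamma = gamma, coef0 = if (kernel == "polynomial") 1 else 0,
                    ...)
  structure(list(fit = fit, std = std, kernel = kernel, cost = cost,
                 gamma = gamma, features = colnames(x)),
            class = "svm_model")
}

#' Predict 0/1 labels from a trained [train_svm()] model
#' @param object an `svm_model`.
#' @param x new feature matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric 0/1 predictions.
#' @export
predict.svm_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(object$features) && !is.null(colnames(x)))
    x <- x[, object$features, drop = FALSE]
  xs <- standardize_apply(x, object$std)
  as.numeric(as.character(predict(object$fit, xs)))
}

#' Per-feature weights of a linear SVM
#'
#' Absolute values of the primal linear coefficients (on the standardized
#' feature scale), sorted descending with ranks; the interpretability view
#' the linear kernel affords.
#'
#' @param model a linear-kernel `svm_model`.
#' @return data frame: `feature`, `weight` (= |coefficient|), `rank`.
#' @export
feature_contributions <- function(model) {
  if (!inherits(model, "svm_model") || model$kernel != "linear")
    stop("feature contributions require a linear-kernel model")
  w <- drop(crossprod(model$fit$coefs, model$fit$SV))
  out <- data.frame(feature = model$features, weight = abs(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Grid search of SVM hyperparameters by inner cross-validation
#'
#' Evaluates each grid point by mean accuracy over the supplied inner
#' folds (standardization refitted per inner training subset) and returns
#' the arg-max, breaking ties toward the earlier grid entry.
#'
#' @param x training feature matrix.
#' @param y 0/1 labels.
#' @param kernel SVM kernel.
#' @param cost_grid candidate cost values, in order.
#' @param gamma_grid candidate gamma values (radial kernel only).
#' @param inner_folds fold id per row of `x` (from [stratified_folds()]).
#' @return list: `cost`, `gamma` (NA unless radial), `accuracy` (inner
#'   mean at the optimum), `table` (per-candidate accuracies).
#' @export
grid_search <- function(x, y, kernel = "linear",
                        cost_grid = 10^(-3:3), gamma_grid = 10^(-3:3),
                        inner_folds) {
  if (length(cost_grid) == 0L) stop("empty grid")
  cand <- if (kernel == "radial")
    expand.grid(cost = cost_grid, gamma = gamma_grid,
                KEEP.OUT.ATTRS = FALSE)
  else data.frame(cost = cost_grid, gamma = NA_real_)
  acc <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    fold_acc <- vapply(sort(unique(inner_folds)), function(f) {
      tr <- inner_folds != f
      g <- if (is.na(cand$gamma[ci])) NULL else cand$gamma[ci]
      m <- train_svm(x[tr, , drop = FALSE], y[tr], kernel = kernel,
                     cost = cand$cost[ci], gamma = g)
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc[ci] <- mean(fold_acc)
  }
  best <- which.max(acc)  # first maximum: earlier grid entries win ties
  list(cost = cand$cost[best], gamma = cand$gamma[best],
       accuracy = acc[best], table = cbind(cand, accuracy = acc))
}

#' Nested 10-fold cross-validation with LASSO-vote feature selection
#'
#' Stratified outer folds estimate generalization; inside each outer
#' training set a single stratified inner partition is used both for the
#' LASSO marking votes (fit at just below the nonnull penalty threshold on
#' each inner training subset; features marked in all inner folds are
#' removed) and for the hyperparameter grid search. Standardization,
#' penalty threshold, marking and tuning never see the outer test fold.
#'
#' @param features data frame or matrix of feature columns.
#' @param labels 0/1 labels (1 = depression = positive).
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` or `"radial"`.
#' @param with_lasso run the LASSO-vote feature removal (default TRUE).
#' @param cost_grid,gamma_grid hyperparameter candidates for
#'   [grid_search()].
#' @param n_outer,n_inner fold counts (the protocol uses 10 and 10).
#' @param seed RNG seed controlling fold construction.
#' @param mark_threshold,lambda_scale see [mark_features()].
#' @return list of class `cv_result`: per-fold train/test metric rows,
#'   `summary` (mean and SD per metric, percent scale), `retained`
#'   (outer-fold x feature logical matrix), `params` (chosen
#'   hyperparameters per fold), `outer_folds`.
#' @export
nested_cv <- function(features, labels, kernel = "linear",
                      with_lasso = TRUE, cost_grid = 10^(-3:3),
                      gamma_grid = 10^(-3:3), n_outer = 10L,
                      n_inner = 10L, seed = 1L, mark_threshold = 0.01,
                      lambda_scale = 0.9) {
  x <- .feature_matrix(features)
  labels <- as.numeric(labels)
  if (nrow(x) < 20L) stop("need at least 20 observations")
  if (length(unique(labels)) != 2L) stop("labels must have two classes")
  seeds <- .with_seed(seed, {
    outer_folds <- stratified_folds(labels, n_outer)
    inner_seeds <- sample.int(.Machine$integer.max, n_outer)
    list(outer = outer_folds, inner = inner_seeds)
  })
  outer_folds <- seeds$outer
  if (any(tapply(labels, outer_folds, function(l) length(unique(l))) < 2L))
    stop("an outer fold lost a class; use fewer folds or more data")
  metric_names <- c("acc", "tpr", "tnr", "ppv", "npv", "f1", "kappa", "mcc")
  train_m <- test_m <- matrix(NA_real_, n_outer, 8L,
                              dimnames = list(NULL, metric_names))
  retained <- matrix(TRUE, n_outer, ncol(x),
                     dimnames = list(NULL, colnames(x)))
  params <- data.frame(fold = seq_len(n_outer), cost = NA_real_,
                       gamma = NA_real_)
  for (f in seq_len(n_outer)) {
    tr <- outer_folds != f
    xtr <- x[tr, , drop = FALSE]; ytr <- labels[tr]
    inner <- .with_seed(seeds$inner[f], stratified_folds(ytr, n_inner))
    if (with_lasso) {
      marks <- lapply(sort(unique(inner)), function(g)
        mark_features(xtr[inner != g, , drop = FALSE], ytr[inner != g],
                      threshold = mark_threshold,
                      lambda_scale = lambda_scale))
      sel <- tryCatch(vote_select(marks, n_folds = n_inner),
                      error = function(e) NULL)
      # degenerate vote (every feature marked everywhere, e.g. pure-noise
      # data): fall back to the unselected feature set for this fold
      if (!is.null(sel)) retained[f, ] <- sel$retained
    }
    xr <- xtr[, retained[f, ], drop = FALSE]
    gs <- grid_search(xr, ytr, kernel = kernel, cost_grid = cost_grid,
                      gamma_grid = gamma_grid, inner_folds = inner)
    params$cost[f] <- gs$cost; params$gamma[f] <- gs$gamma
    model <- train_svm(xr, ytr, kernel = kernel, cost = gs$cost,
                       gamma = if (is.na(gs$gamma)) NULL else gs$gamma)
    xte <- x[!tr, retained[f, ], drop = FALSE]
    train_m[f, ] <- compute_metrics(confusion(ytr, predict(model, xr)))
    test_m[f, ] <- compute_metrics(confusion(labels[!tr],
                                             predict(model, xte)))
  }
  summarize <- function(m) {
    data.frame(metric = metric_names,
               mean_pct = 100 * colMeans(m, na.rm = TRUE),
               sd_pct = 100 * apply(m, 2, stats::sd, na.rm = TRUE),
               row.names = NULL)
  }
  structure(list(train_metrics = train_m, test_metrics = test_m,
                 summary = list(train = summarize(train_m),
                                test = summarize(test_m)),
                 retained = retained, params = params,
                 outer_folds = outer_folds, kernel = kernel,
                 with_lasso = with_lasso, seed = seed),
            class = "cv_result")
}

#' Mean test accuracy of a `cv_result`
#' @param cv a [nested_cv()] result.
#' @return mean outer-fold test accuracy (proportion).
#' @export
cv_test_accuracy <- function(cv) {
  mean(cv$test_metrics[, "acc"])
}

#' Features completely rejected across the outer folds
#'
#' A feature is completely rejected when the LASSO vote removed it in
#' every outer fold of phase 2; only those features are dropped when the
#' final transfer-phase model is built.
#'
#' @param cv a [nested_cv()] result run `with_lasso = TRUE`.
#' @return logical vector: TRUE where the feature is kept for phase 3.
#' @export
phase2_retained_features <- function(cv) {
  colSums(cv$retained) > 0L
}

#' Evaluate a trained model on a transfer cohort
#'
#' Single evaluation, no refitting: feature subset and standardization are
#' frozen from training.
#'
#' @param model an `svm_model` from [train_svm()].
#' @param features transfer-cohort feature data (same columns as
#'   training).
#' @param labels transfer-cohort 0/1 labels.
#' @return list: `metrics`, `confusion`, `predictions`.
#' @export
transfer_evaluate <- function(model, features, labels) {
  x <- .feature_matrix(features)
  if (nrow(x) == 0L) stop("empty transfer set")
  if (!all(model$features %in% colnames(x)))
    stop("transfer set lacks retained features")
  pred <- predict(model, x)
  cm <- confusion(labels, pred)
  list(metrics = compute_metrics(cm), confusion = cm, predictions = pred)
}
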