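test_that("stratified folds balance classes and partition the data", {
  # the age-matched cohort sizes: 89 positives, 88 negatives over 10 folds
  labels <- rep(c(1, 0), c(89, 88))
  fold <- local_seed(1, stratified_folds(labels, 10))
  sizes <- table(fold)
  expect_true(all(sizes %in% 17:18))
  per_class <- table(fold, labels)
  expect_true(all(per_class %in% 8:9))
  expect_setequal(unique(fold), 1:10)
  # the first-dealt class puts its remainder in the earlier folds
  expect_equal(as.vector(table(fold[labels == 1])),
               c(rep(9, 9), 8))
})

test_that("k-means separates well-separated clouds and tolerates ties", {
  local_seed(2, {
    a <- matrix(rnorm(40, 0, 0.2), 20, 2)
    b <- matrix(rnorm(40, 5, 0.2), 20, 2)
  })
  km <- kmeans_cluster(rbind(a, b), seed = 7)
  expect_equal(length(unique(km$cluster[1:20])), 1L)
  expect_equal(length(unique(km$cluster[21:40])), 1L)
  expect_false(km$cluster[1] == km$cluster[21])
  # identical points: degenerate single cluster, no crash
  same <- matrix(1, 5, 3)
  expect_equal(kmeans_cluster(same, seed = 1)$cluster, rep(1L, 5))
})

test_that("k-means inertia beats 50 random partitions", {
  x <- local_seed(3, matrix(rnorm(40 * 4), 40, 4))
  km <- kmeans_cluster(x, seed = 5, standardize = FALSE)
  inertia_of <- function(assign) {
    sum(sapply(unique(assign), function(k) {
      xs <- x[assign == k, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }))
  }
  rand <- local_seed(4, replicate(50, inertia_of(sample(1:2, 40, TRUE))))
  expect_lte(km$inertia, min(rand))
  # and matches a direct recomputation of its own inertia
  expect_equal(km$inertia, inertia_of(km$cluster), tolerance = 1e-8)
})

test_that("clustering evaluation maps clusters to labels by accuracy", {
  labels <- rep(c(1, 0), each = 10)
  perfect <- evaluate_clustering(rep(c(2, 1), each = 10), labels)
  expect_equal(unname(perfect$metrics["acc"]), 1)
  expect_equal(unname(perfect$metrics["kappa"]), 1)
  # assignment independent of labels on balanced data: kappa near zero
  ind <- evaluate_clustering(rep(c(1, 2), 10), labels)
  expect_lt(abs(ind$metrics["kappa"]), 0.15)
  expect_error(evaluate_clustering(rep(1, 20), labels), "two")
})

test_that("SVM solves the symmetric toy problem exactly", {
  x <- rbind(c(-1, 0), c(1, 0), c(-1, 0.1), c(1, -0.1))
  colnames(x) <- c("u", "v")
  y <- c(0, 1, 0, 1)
  m <- train_svm(x, y, cost = 100)
  expect_equal(predict(m, x), y)
  # label flip leaves coefficient magnitudes unchanged and flips the
  # predicted classes
  m2 <- train_svm(x, 1 - y, cost = 100)
  w1 <- drop(crossprod(m$fit$coefs, m$fit$SV))
  w2 <- drop(crossprod(m2$fit$coefs, m2$fit$SV))
  expect_equal(abs(w1), abs(w2), tolerance = 1e-6)
  expect_equal(predict(m2, x), 1 - y)
})

test_that("SVM weights match the exact dense QP oracle on 6-point sets", {
  local_seed(5, for (rep in 1:10) {
    x <- matrix(rnorm(12), 6, 2)
    colnames(x) <- c("a", "b")
    y <- c(0, 0, 0, 1, 1, 1)
    x <- scale(x)
    attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
    o <- oracle_svm_linear(x, y, 1)
    m <- train_svm(x, y, cost = 1, tolerance = 1e-9)
    w <- drop(crossprod(m$fit$coefs, m$fit$SV))
    expect_equal(w, o$w, tolerance = 1e-6, ignore_attr = TRUE)
    if (!is.na(o$b))
      expect_equal(-m$fit$rho, o$b, tolerance = 1e-6, ignore_attr = TRUE)
  })
})

test_that("grid search returns singletons and breaks ties toward the front", {
  x <- local_seed(6, matrix(rnorm(60 * 2), 60, 2))
  colnames(x) <- c("a", "b")
  y <- as.numeric(x[, 1] + 0.2 * rnorm(60) > 0)
  inner <- local_seed(7, stratified_folds(y, 5))
  one <- grid_search(x, y, cost_grid = 10, inner_folds = inner)
  expect_equal(one$cost, 10)
  # duplicated grid values give equal accuracies: the first entry wins
  two <- grid_search(x, y, cost_grid = c(1, 1), inner_folds = inner)
  expect_equal(two$table$accuracy[1], two$table$accuracy[2])
  expect_equal(two$cost, two$table$cost[1])
  expect_error(grid_search(x, y, cost_grid = numeric(0),
                           inner_folds = inner), "empty")
})

test_that("linear feature contributions rank the informative feature first", {
  local_seed(8, {
    x <- cbind(sig = rnorm(80), n1 = rnorm(80), n2 = rnorm(80))
    y <- as.numeric(x[, "sig"] > 0)
  })
  m <- train_svm(x, y, cost = 1)
  fc <- feature_contributions(m)
  expect_equal(fc$feature[1], "sig")
  expect_equal(fc$rank, 1:3)
  expect_true(all(diff(fc$weight) <= 0))
  mr <- train_svm(x, y, kernel = "radial", cost = 1)
  expect_error(feature_contributions(mr), "linear")
})

test_that("duplicated columns split weight but keep predictions", {
  local_seed(9, {
    x <- cbind(a = rnorm(60), b = rnorm(60))
    y <- as.numeric(x[, "a"] - x[, "b"] > 0)
  })
  xd <- cbind(x, a2 = x[, "a"])
  m1 <- train_svm(x, y, cost = 1)
  m2 <- train_svm(xd, y, cost = 1)
  expect_equal(predict(m2, xd), predict(m1, x))
})

test_that("nested CV is deterministic, leak-free, and null-calibrated", {
  local_seed(10, {
    x <- matrix(rnorm(60 * 8), 60, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(0, 1), each = 30)
  })
  cv1 <- nested_cv(x, y, cost_grid = c(0.1, 1), n_outer = 5, n_inner = 5,
                   seed = 3)
  cv2 <- nested_cv(x, y, cost_grid = c(0.1, 1), n_outer = 5, n_inner = 5,
                   seed = 3)
  expect_identical(cv1$outer_folds, cv2$outer_folds)
  expect_equal(cv1$test_metrics, cv2$test_metrics)
  expect_equal(cv1$retained, cv2$retained)
  expect_equal(cv1$params, cv2$params)

  # outer test folds partition the data
  expect_setequal(unique(cv1$outer_folds), 1:5)
  expect_equal(length(cv1$outer_folds), 60L)

  # provenance: perturbing one outer fold's test rows cannot change the
  # selection or tuning made inside the other folds' training data
  f <- 1L
  xp <- x
  xp[cv1$outer_folds == f, ] <- xp[cv1$outer_folds == f, ] + 1000
  cvp <- nested_cv(xp, y, cost_grid = c(0.1, 1), n_outer = 5, n_inner = 5,
                   seed = 3)
  expect_equal(cvp$retained[f, ], cv1$retained[f, ])
  expect_equal(cvp$params$cost[f], cv1$params$cost[f])
  expect_equal(cvp$train_metrics[f, ], cv1$train_metrics[f, ])

  # null features: mean test accuracy inside the binomial 95% band
  acc <- cv_test_accuracy(cv1)
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 60))
  expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 60))

  # summary mean/SD recompute exactly from the stored per-fold metrics
  # (undefined per-fold ratios are dropped, not imputed)
  expect_equal(cv1$summary$test$mean_pct,
               unname(100 * colMeans(cv1$test_metrics, na.rm = TRUE)))
  expect_equal(cv1$summary$test$sd_pct,
               unname(100 * apply(cv1$test_metrics, 2, sd, na.rm = TRUE)))
})

test_that("transfer evaluation freezes the model and handles imbalance", {
  local_seed(11, {
    x <- matrix(rnorm(80 * 5), 80, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c(0, 1), each = 40)
    x[y == 1, 1] <- x[y == 1, 1] + 3
  })
  m <- train_svm(x, y, cost = 1)
  # transfer set equal to the training set: metrics equal training metrics
  tr_metrics <- compute_metrics(confusion(y, predict(m, x)))
  te <- transfer_evaluate(m, x, y)
  expect_equal(te$metrics, tr_metrics)

  # majority-class predictor on a heavily imbalanced set: high accuracy
  # but chance-corrected agreement near zero
  n_maj <- 211; n_min <- 31
  yl <- rep(c(1, 0), c(n_maj, n_min))
  pred <- rep(1, n_maj + n_min)
  mm <- compute_metrics(confusion_counts(n_maj, n_min, 0, 0))
  expect_gt(mm["acc"], 0.85)
  expect_equal(unname(mm["mcc"]), 0)

  expect_error(transfer_evaluate(m, x[0, ], numeric(0)), "empty")
})

test_that("accuracy recovers as class separation grows through the pipeline", {
  accs <- sapply(c(0, 1, 3), function(sep) {
    spec <- cohort_spec(30, 30, session_seconds = 5, class_separation = sep,
                        seed = 31)
    ft <- cohort_features(generate_cohort(spec))
    cv <- nested_cv(ft, labels_from_group(ft$group), with_lasso = FALSE,
                    cost_grid = c(0.1, 1, 10), n_outer = 10, n_inner = 5,
                    seed = 7)
    cv_test_accuracy(cv)
  })
  # non-decreasing in separation, with a 2-point tolerance
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[3], accs[1])
})
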