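test_that("lambda_max matches the analytic threshold and its limits", {
  # response orthogonal to every predictor: threshold collapses to zero
  x <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  y <- c(1, 1, 1, 1) * 2  # constant component only; centred y is 0
  expect_error(lambda_max(x, y), "zero-variance")
  y2 <- c(1, -1, -1, 1)   # orthogonal to both columns
  expect_equal(lambda_max(x, y2), 0, tolerance = 1e-14)

  # single predictor equal to the response: threshold = population Var(y)
  y3 <- local_seed(1, rnorm(50))
  expect_equal(lambda_max(matrix(y3), y3),
               sum((y3 - mean(y3))^2) / 50, tolerance = 1e-12)
})

test_that("the fitted path turns on exactly below the analytic threshold", {
  local_seed(2, for (i in 1:5) {
    x <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    lmax <- lambda_max(x, y)
    expect_true(all(fit_lasso(x, y, lmax * 1.0001)$beta == 0))
    expect_gt(max(abs(fit_lasso(x, y, lmax * 0.999)$beta)), 0)
    # bisection over the solver brackets the analytic value
    lo <- 0; hi <- 2 * lmax + 1
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (any(fit_lasso(x, y, mid)$beta != 0)) lo <- mid else hi <- mid
    }
    expect_equal((lo + hi) / 2, lmax, tolerance = 1e-8)
  })
})

test_that("lasso limits: OLS at zero penalty, null model above threshold", {
  local_seed(3, {
    x <- matrix(rnorm(40 * 3), 40, 3)
    y <- x %*% c(1, -2, 0.5) + rnorm(40, 0, 0.3)
  })
  f0 <- fit_lasso(x, y, 0)
  ols <- lm(y ~ x)
  expect_equal(f0$beta, unname(coef(ols)[-1]), tolerance = 1e-7)
  expect_equal(f0$alpha, unname(coef(ols)[1]), tolerance = 1e-7)
  expect_true(all(fit_lasso(x, y, 10 * lambda_max(x, y))$beta == 0))
})

test_that("J = 1 fits match the closed-form soft threshold to 1e-10", {
  local_seed(4, for (i in 1:100) {
    x <- rnorm(25, sd = runif(1, 0.5, 2))
    y <- 1.5 * x + rnorm(25)
    lam <- runif(1, 0, 1.2 * lambda_max(matrix(x), y))
    f <- fit_lasso(matrix(x), y, lam)
    o <- oracle_lasso_j1(x, y, lam)
    expect_equal(f$beta, unname(o["beta"]), tolerance = 1e-10)
    expect_equal(f$alpha, unname(o["alpha"]), tolerance = 1e-10)
  })
})

test_that("objective is monotone non-increasing across solver sweeps", {
  local_seed(5, for (i in 1:10) {
    x <- matrix(rnorm(30 * 12), 30, 12)
    y <- rnorm(30)
    f <- fit_lasso(x, y, 0.3 * lambda_max(x, y))
    expect_true(all(diff(f$objective) <= 1e-12))
    # solution never does worse than the null model
    null_obj <- sum((y - mean(y))^2) / (2 * 30)
    expect_lte(f$objective[length(f$objective)], null_obj + 1e-12)
  })
})

test_that("fits agree with glmnet at matched penalty", {
  local_seed(6, for (i in 1:5) {
    x <- matrix(rnorm(50 * 8), 50, 8)
    y <- as.numeric(x[, 1] - 0.5 * x[, 2] + rnorm(50) > 0)
    xs <- standardize_fit(x)$x
    lam <- runif(1, 0.1, 0.9) * lambda_max(xs, y)
    mine <- fit_lasso(xs, y, lam)
    ref <- glmnet::glmnet(xs, y, lambda = lam, standardize = FALSE,
                          thresh = 1e-14)
    expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-7)
  })
})

test_that("retained-set size is non-increasing along the penalty path", {
  local_seed(7, {
    x <- matrix(rnorm(60 * 10), 60, 10)
    y <- x %*% runif(10, -1, 1) + rnorm(60)
  })
  sizes <- sapply(seq(0.05, 1, by = 0.05) * lambda_max(x, y),
                  function(l) sum(fit_lasso(x, y, l)$beta != 0))
  expect_true(all(diff(sizes) <= 0))
})

test_that("marking keeps the informative feature in every inner fold", {
  local_seed(8, for (rep in 1:10) {
    n <- 100
    x <- matrix(rnorm(n * 8), n, 8)
    y <- as.numeric(x[, 1] > 0)  # outcome a function of feature 1 only
    marks <- mark_features(x, y)
    expect_false(marks[1])
    # a coefficient that is exactly zero is marked
    x0 <- cbind(x, dup = 0)     # zero-variance predictor stays at zero
    expect_true(mark_features(x0, y)[9])
  })
})

test_that("vote-based removal requires unanimity across the 10 folds", {
  marks <- matrix(FALSE, 10, 4)
  marks[, 1] <- TRUE                 # marked everywhere: removed
  marks[1:9, 2] <- TRUE              # 9 of 10: retained
  sel <- vote_select(marks)
  expect_false(sel$retained[1])
  expect_true(sel$retained[2])
  expect_equal(unname(sel$marks), c(10, 9, 0, 0))
  expect_error(vote_select(matrix(TRUE, 10, 3)), "empty retained")
  expect_error(vote_select(matrix(FALSE, 7, 3)), "expected 10")
})

test_that("standardization statistics come from training data only", {
  local_seed(9, {
    tr <- matrix(rnorm(40 * 3, mean = 2), 40, 3)
    te <- matrix(rnorm(10 * 3, mean = 50), 10, 3)
  })
  fit <- standardize_fit(tr)
  expect_equal(colMeans(fit$x), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(fit$x, 2, sd), rep(1, 3), tolerance = 1e-12)
  te_s <- standardize_apply(te, fit)
  # held-out data transformed with training statistics keeps its shift
  expect_true(all(colMeans(te_s) > 10))
})
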