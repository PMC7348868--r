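#' Largest penalty admitting a nonnull LASSO model
#'
#' Analytic threshold \eqn{\lambda_{max} = \max_j |\sum_i x_{ij}(y_i -
#' \bar y)| / N} above which every LASSO coefficient is exactly zero; any
#' penalty strictly below it yields at least one nonzero coefficient.
#'
#' @param x predictor matrix (N x J).
#' @param y numeric response of length N.
#' @return the threshold (nonnegative scalar).
#' @export
lambda_max <- function(x, y) {
  x <- as.matrix(x)
  if (stats::sd(y) == 0) stop("zero-variance response")
  n <- nrow(x)
  max(abs(crossprod(x, y - mean(y)))) / n
}

#' Fit a LASSO regression by coordinate descent
#'
#' Minimises
#' \deqn{\frac{1}{2N}\sum_i (y_i - \alpha - \sum_j \beta_j x_{ij})^2 +
#'   \lambda \sum_j |\beta_j|}
#' by cyclic coordinate descent with the exact soft-threshold update. The
#' objective is recorded after every sweep (it is non-increasing by
#' construction of the exact coordinate minimisation).
#'
#' @param x predictor matrix (N x J); not modified (standardize upstream if
#'   the penalty is to act on a common scale).
#' @param y numeric response.
#' @param lambda nonnegative penalty.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep.
#' @param max_iter sweep limit.
#' @return list: `alpha` (intercept), `beta` (J coefficients), `objective`
#'   (per-sweep values), `iterations`, `converged`.
#' @export
fit_lasso <- function(x, y, lambda, tol = 1e-10, max_iter = 10000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (lambda < 0) stop("lambda must be nonnegative")
  n <- nrow(x); j <- ncol(x)
  if (n < 2L) stop("need at least 2 observations")
  xm <- colMeans(x); ym <- mean(y)
  xc <- x - rep(xm, each = n)
  yc <- y - ym
  denom <- colSums(xc^2) / n
  beta <- numeric(j)
  r <- yc
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  obj <- function(b, res) sum(res^2) / (2 * n) + lambda * sum(abs(b))
  objective <- obj(beta, r)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    for (k in seq_len(j)) {
      if (denom[k] == 0) next
      rho <- sum(xc[, k] * r) / n + denom[k] * beta[k]
      bk <- soft(rho, lambda) / denom[k]
      if (bk != beta[k]) {
        r <- r - xc[, k] * (bk - beta[k])
        delta <- max(delta, abs(bk - beta[k]))
        beta[k] <- bk
      }
    }
    objective <- c(objective, obj(beta, r))
    if (delta < tol) { converged <- TRUE; break }
  }
  list(alpha = ym - sum(xm * beta), beta = beta, objective = objective,
       iterations = it, converged = converged)
}

#' Mark near-zero LASSO coefficients on one training subset
#'
#' Standardizes the predictors (training statistics only), fits the LASSO
#' at `lambda_scale` times the nonnull threshold from [lambda_max()]
#' (model performance is not considered; no inner cross-validation), and
#' marks every feature whose |coefficient| is strictly below `threshold`.
#' A coefficient exactly at the threshold is \emph{not} marked.
#'
#' @param x training predictor matrix (N x J).
#' @param y 0/1 class labels.
#' @param threshold marking cutoff on |coefficient| (default 0.01).
#' @param lambda_scale multiple of the nonnull threshold at which to fit;
#'   just below 1 so the first entering coefficients are measurable
#'   against the cutoff.
#' @param signed use the signed reading `coefficient < threshold` instead
#'   of the |coefficient| default.
#' @return logical vector of J marks (TRUE = marked for removal).
#' @export
mark_features <- function(x, y, threshold = 0.01, lambda_scale = 0.9,
                          signed = FALSE) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("training subset has a single class")
  xs <- standardize_fit(x)
  lam <- lambda_scale * lambda_max(xs$x, y)
  beta <- fit_lasso(xs$x, y, lam)$beta
  if (signed) beta < threshold else abs(beta) < threshold
}

#' Vote-based feature removal across inner folds
#'
#' A feature is removed iff it was marked in every inner fold (unanimity);
#' features unmarked in at least one fold are retained.
#'
#' @param marks list of logical mark vectors (one per inner fold) or a
#'   folds x features logical matrix.
#' @param n_folds expected fold count (the protocol uses 10); a different
#'   count errors unless it matches `length(marks)` via `n_folds = NA`.
#' @return list of class `selection_mask`: `marks` (per-feature counts),
#'   `retained` (logical), `n_folds`.
#' @export
vote_select <- function(marks, n_folds = 10L) {
  if (is.list(marks)) marks <- do.call(rbind, marks)
  if (!is.na(n_folds) && nrow(marks) != n_folds)
    stop("expected ", n_folds, " inner folds, got ", nrow(marks))
  counts <- colSums(marks)
  retained <- counts < nrow(marks)
  if (!any(retained))
    stop("all features marked in every fold: empty retained set")
  structure(list(marks = counts, retained = retained,
                 n_folds = nrow(marks)),
            class = "selection_mask")
}

#' Standardization fitted on training data
#'
#' Column means and sample SDs computed on the training matrix; columns
#' with zero SD are left centred but unscaled. Apply to held-out data with
#' [standardize_apply()] so test information never leaks into the scaling.
#'
#' @param x training matrix.
#' @return list: standardized `x`, `center`, `scale`.
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Apply a fitted standardization to new data
#' @param x matrix to transform.
#' @param fit result of [standardize_fit()].
#' @return standardized matrix.
#' @export
standardize_apply <- function(x, fit) {
  sweep(sweep(as.matrix(x), 2, fit$center), 2, fit$scale, "/")
}
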