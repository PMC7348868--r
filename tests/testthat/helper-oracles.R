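# Independent brute-force oracles used to pin implementations.

# Confusion-matrix metrics computed by a route independent of
# compute_metrics(): expand the counts into 0/1 vectors, use plain vector
# arithmetic, e1071::classAgreement for kappa and cor() (phi coefficient)
# for MCC.
oracle_metrics <- function(tp, fp, tn, fn) {
  l <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  p <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  acc <- mean(l == p)
  tpr <- if (tp + fn > 0) mean(p[l == 1] == 1) else NA_real_
  tnr <- if (tn + fp > 0) mean(p[l == 0] == 0) else NA_real_
  ppv <- if (tp + fp > 0) mean(l[p == 1] == 1) else NA_real_
  npv <- if (tn + fn > 0) mean(l[p == 0] == 0) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(tpr) && ppv + tpr > 0)
    2 * ppv * tpr / (ppv + tpr) else NA_real_
  tab <- table(factor(l, c(0, 1)), factor(p, c(0, 1)))
  kap <- e1071::classAgreement(tab)$kappa
  if (is.nan(kap)) kap <- NA_real_
  mcc <- if (length(l) > 1 && stats::sd(l) > 0 && stats::sd(p) > 0)
    stats::cor(l, p) else 0
  c(acc = acc, tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, f1 = f1,
    kappa = kap, mcc = mcc)
}

# Exact dense soft-margin SVM solver for tiny instances: enumerates every
# partition of the points into {free, at-bound C, zero} support states and
# solves the KKT system, returning the feasible solution's primal weights.
# Linear kernel only; labels in {0, 1} (0 mapped to s = +1 to match the
# factor-level convention of libsvm via e1071).
oracle_svm_linear <- function(x, y, cost) {
  n <- nrow(x)
  s <- ifelse(y == 0, 1, -1)
  K <- x %*% t(x)
  G <- (s %*% t(s)) * K
  states <- expand.grid(rep(list(c("zero", "free", "bound")), n),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    Fs <- which(st == "free"); Bs <- which(st == "bound")
    if (length(Fs) == 0) {
      # all support vectors at bound: w is fixed, b lies in an interval
      alpha <- numeric(n); alpha[Bs] <- cost
      if (abs(sum(alpha * s)) > 1e-9) next
      w <- colSums(alpha * s * x)
      fx <- as.vector(x %*% w)
      lo <- suppressWarnings(max(c((1 - fx)[s == 1 & st == "zero"],
                                   (-1 - fx)[s == -1 & st == "bound"])))
      hi <- suppressWarnings(min(c((1 - fx)[s == 1 & st == "bound"],
                                   (-1 - fx)[s == -1 & st == "zero"])))
      if (lo > hi + 1e-9) next
      return(list(w = w, b = NA_real_, alpha = alpha))
    }
    alpha <- numeric(n); alpha[Bs] <- cost
    A <- rbind(cbind(G[Fs, Fs, drop = FALSE], s[Fs]), c(s[Fs], 0))
    rhs <- c(1 - if (length(Bs)) rowSums(G[Fs, Bs, drop = FALSE]) * cost
                 else rep(0, length(Fs)),
             -cost * sum(s[Bs]))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    alpha[Fs] <- sol[seq_along(Fs)]
    b <- sol[length(sol)]
    if (any(alpha[Fs] <= 1e-9) || any(alpha[Fs] >= cost - 1e-9)) next
    w <- colSums(alpha * s * x)
    margins <- s * (as.vector(x %*% w) + b)
    if (all(margins[st == "zero"] >= 1 - 1e-7) &&
        all(margins[st == "bound"] <= 1 + 1e-7))
      return(list(w = w, b = b, alpha = alpha))
  }
  stop("oracle found no KKT-consistent state")
}

# Loop-based spectral oracles over an explicit (freq, power) table.
oracle_centroid <- function(freq, power) {
  num <- 0; den <- 0
  for (i in seq_along(freq)) { num <- num + freq[i] * power[i]
                               den <- den + power[i] }
  num / den
}
oracle_mean_freq <- oracle_centroid
oracle_median_freq <- function(freq, power) {
  tot <- sum(power); run <- 0
  for (i in seq_along(freq)) {
    run <- run + power[i]
    if (run >= tot / 2) return(freq[i])
  }
}
oracle_rolloff <- function(freq, power, k) {
  tot <- sum(power); run <- 0
  for (i in seq_along(freq)) {
    run <- run + power[i]
    if (run >= k / 100 * tot - 1e-12 * tot) return(freq[i])
  }
}

# J = 1 closed-form LASSO solution (soft threshold on the covariance).
oracle_lasso_j1 <- function(x, y, lambda) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  rho <- sum(xc * yc) / n
  den <- sum(xc^2) / n
  beta <- sign(rho) * max(abs(rho) - lambda, 0) / den
  c(alpha = mean(y) - mean(x) * beta, beta = beta)
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
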