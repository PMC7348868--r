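#' Pearson correlations of features against a clinical score, per group
#'
#' Within one patient group, correlates every feature column with the
#' group's clinical rating instrument (HAMD17 for depression, MMSE for
#' dementia) and reports the Pearson r with its two-sided p-value.
#'
#' @param features data frame with `session_id` and feature columns (e.g.
#'   from [cohort_features()]).
#' @param manifest manifest data frame carrying the scores.
#' @param group `"depression"` or `"dementia"`.
#' @param score_name score column to use; defaults to the group's
#'   instrument (`hamd17` for depression, `mmse` for dementia).
#' @return data frame: `feature`, `r`, `p`; zero-variance features get NA
#'   with no error.
#' @export
correlate_features <- function(features, manifest, group,
                               score_name = NULL) {
  if (is.null(score_name))
    score_name <- if (group == "depression") "hamd17" else "mmse"
  m <- manifest[manifest$group == group, c("session_id", score_name)]
  if (nrow(m) < 3L) stop("need at least 3 sessions in group '", group, "'")
  fx <- merge(features, m, by = "session_id")
  score <- fx[[score_name]]
  cols <- setdiff(names(features), c("session_id", "group"))
  r <- p <- rep(NA_real_, length(cols))
  for (j in seq_along(cols)) {
    x <- fx[[cols[j]]]
    if (stats::sd(x) == 0 || stats::sd(score) == 0) next
    ct <- stats::cor.test(x, score, method = "pearson")
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  data.frame(feature = cols, r = r, p = p, stringsAsFactors = FALSE)
}

#' Between-group t-tests with Bonferroni correction
#'
#' Two-sample two-tailed t-test per feature (Welch by default; the
#' equal-variance Student's variant is available), with p-values adjusted
#' over the feature family as min(1, m * p).
#'
#' @param features data frame or matrix of feature columns (non-feature
#'   columns `session_id`/`group` are ignored if present).
#' @param labels two-level factor/vector, one entry per row.
#' @param var_equal use the pooled-variance Student's t instead of Welch.
#' @param m Bonferroni family size; defaults to the number of features
#'   tested (108 for the full set).
#' @param alpha significance level applied to the adjusted p.
#' @return data frame: `feature`, `t`, `p`, `p_adj`, `significant`.
#' @export
group_ttests <- function(features, labels, var_equal = FALSE, m = NULL,
                         alpha = 0.05) {
  x <- .feature_matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (min(table(labels)) < 2L) stop("both groups need >= 2 sessions")
  if (is.null(m)) m <- ncol(x)
  tt <- apply(x, 2, function(v)
    unlist(stats::t.test(v[labels == levels(labels)[1]],
                         v[labels == levels(labels)[2]],
                         var.equal = var_equal)[c("statistic", "p.value")]))
  p_adj <- pmin(1, m * tt[2, ])
  data.frame(feature = colnames(x), t = unname(tt[1, ]),
             p = unname(tt[2, ]), p_adj = unname(p_adj),
             significant = unname(p_adj < alpha),
             stringsAsFactors = FALSE)
}

# strip id columns, return numeric matrix
.feature_matrix <- function(features) {
  if (is.data.frame(features))
    features <- features[, setdiff(names(features),
                                   c("session_id", "group")), drop = FALSE]
  as.matrix(features)
}

# Vectorized Welch t-statistics and two-sided p for a feature matrix; used
# for permutation studies where per-column t.test calls are too slow.
.welch_t_matrix <- function(x, labels) {
  g1 <- labels == levels(as.factor(labels))[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x[!g1, , drop = FALSE] - rep(m2, each = n2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Family-wise error of the Bonferroni procedure under a permutation null
#'
#' Shuffles the group labels `n_perm` times; for each permutation runs the
#' Welch t-test across all features, Bonferroni-adjusts, and records
#' whether any feature is declared significant. The returned rate estimates
#' the family-wise error under the null.
#'
#' @param features data frame or matrix of feature columns.
#' @param labels two-level labels.
#' @param n_perm number of label permutations.
#' @param alpha significance level.
#' @param seed RNG seed for the permutations.
#' @return list: `fwer` (proportion of permutations with any rejection),
#'   `n_perm`.
#' @export
permutation_fwer <- function(features, labels, n_perm = 1000, alpha = 0.05,
                             seed = 1L) {
  x <- .feature_matrix(features)
  labels <- as.factor(labels)
  m <- ncol(x)
  hits <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      p <- .welch_t_matrix(x, perm)$p
      any(pmin(1, m * p) < alpha)
    }, logical(1))
  })
  list(fwer = mean(hits), n_perm = n_perm)
}
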