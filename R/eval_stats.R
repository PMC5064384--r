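# Cross-validated ROC evaluation and univariate effect statistics.

#' Rank-based AUC with empirical ROC curve
#'
#' The area under the ROC curve via the Mann-Whitney formulation with
#' mid-ranks for ties, which equals the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `auc` and `roc` (data.frame of `fpr`, `tpr` sorted from
#'   (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # empirical ROC: sweep the threshold over unique score values
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  list(auc = auc, roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Confusion-matrix summary statistics
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from raw counts. Ratios with a zero denominator are returned as
#' `NaN` (flagged, not an error).
#'
#' @param TP,FP,TN,FN Non-negative confusion counts (total > 0).
#' @return Named list of the five ratios plus the counts.
#' @export
confusion_stats <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts must sum to a positive total")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = ratio(TP, TP + FN),
       specificity = ratio(TN, TN + FP),
       ppv = ratio(TP, TP + FP),
       npv = ratio(TN, TN + FN),
       accuracy = (TP + TN) / sum(counts))
}

#' Cohen's d with pooled standard deviation
#'
#' (mean_a - mean_b) / s_pooled, with s_pooled from the (n-1)-weighted group
#' variances. Returns `NaN` when the pooled SD is zero.
#'
#' @param group_a,group_b Numeric vectors with >= 2 values each.
#' @return Signed effect size d.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) return(NaN)
  (mean(group_a) - mean(group_b)) / sp
}

#' Welch's two-sample t test (two-sided)
#'
#' @param group_a,group_b Numeric vectors with >= 2 values each and at least
#'   one nonzero variance.
#' @return List with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("both group variances are zero")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Stratified k-fold cross-validated forest evaluation
#'
#' Partitions subjects into k folds (stratified by class, fold sizes
#' differing by at most 1), trains an oblique forest on each set of k-1
#' folds, and records held-out class probabilities. ROC and AUC are computed
#' on the pooled out-of-fold probabilities; the confusion matrix uses
#' threshold 0.5 with ties assigned to the positive class (grade IV).
#'
#' @param X Feature matrix.
#' @param y 0/1 labels; each class needs >= k members.
#' @param k Number of folds (default 5).
#' @param n_trees,mtry,min_node_size Forest parameters.
#' @param seed Master seed for fold assignment and tree fitting.
#' @param stratified Stratify folds by class (default TRUE).
#' @return A `cv_report`: `fold` (per-subject fold index), `prob` (pooled
#'   out-of-fold probabilities), `auc`, `roc`, `confusion`
#'   ([confusion_stats()] output) and `seed`.
#' @export
cross_validate <- function(X, y, k = 5L, n_trees = 300L,
                           mtry = ceiling(sqrt(ncol(X))), min_node_size = 5L,
                           seed = 1L, stratified = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  if (min(table(y)) < k)
    stop("each class needs at least k members for k-fold cross-validation")
  fold <- integer(n)
  withr::with_seed(derive_seed(seed, 51L), {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  prob <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_forest(X[!test, , drop = FALSE], y[!test], n_trees = n_trees,
                      mtry = mtry, min_node_size = min_node_size,
                      seed = derive_seed(seed, 60L, f))
    prob[test] <- predict_proba(fit, X[test, , drop = FALSE])
  }
  roc <- roc_auc(prob, y)
  pred <- as.integer(prob >= 0.5)
  conf <- confusion_stats(TP = sum(pred == 1L & y == 1L),
                          FP = sum(pred == 1L & y == 0L),
                          TN = sum(pred == 0L & y == 0L),
                          FN = sum(pred == 0L & y == 1L))
  structure(list(fold = fold, prob = prob, auc = roc$auc, roc = roc$roc,
                 confusion = conf, seed = seed),
            class = "cv_report")
}

#' Per-feature effect-size report
#'
#' Cohen's d and Welch's t test (two-sided) comparing grade IV against grade
#' II/III for the requested features.
#'
#' @param cm A [cohort_matrix][build_cohort_matrix].
#' @param features Character vector of feature names (default: all).
#' @return Data frame with `feature`, `d`, `t`, `df`, `p`.
#' @export
effect_report <- function(cm, features = colnames(cm$X)) {
  rows <- lapply(features, function(f) {
    a <- cm$X[cm$y == 1L, f]   # grade IV
    b <- cm$X[cm$y == 0L, f]
    wt <- tryCatch(welch_t(a, b),
                   error = function(e) list(t = NaN, df = NaN, p = NaN))
    data.frame(feature = f, d = cohens_d(a, b), t = wt$t, df = wt$df,
               p = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
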