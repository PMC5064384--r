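# Oblique random forest with logistic-regression node models.
#
# Each internal node draws `mtry` features, fits a logistic regression on
# them, projects the node's samples onto the fitted linear predictor, and
# splits at the threshold maximizing the Gini impurity decrease. Feature
# importance is a significance count: every feature entering a node model
# gains +1 when its Wald p-value is below 0.05 and -1 otherwise. The
# bootstrap importance aggregates these counts over refits on resampled
# cohorts and standardizes the per-feature means across features.

#' Logistic node model by iteratively reweighted least squares
#'
#' Plain IRLS (max `maxit` iterations, tolerance `tol` on the coefficient
#' change). On non-convergence or quasi-complete separation the model is
#' refitted with a small ridge penalty, which keeps coefficients and Wald
#' statistics finite. Two-sided Wald p-values are returned per coefficient.
#'
#' @param X Numeric matrix (samples x features), the node's feature subset.
#' @param y 0/1 response; both classes must be present.
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @param ridge Ridge penalty used by the fallback refit.
#' @return List with `intercept`, `coefficients`, `p_values` (one per column
#'   of `X`, Wald, two-sided), and `ridge_used`.
#' @export
fit_node_model <- function(X, y, maxit = 25L, tol = 1e-6, ridge = 1e-3) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || length(unique(y)) < 2L)
    stop("node model needs >= 2 samples with both classes present")
  fit <- irls_logistic(X, y, lambda = 0, maxit = maxit, tol = tol)
  if (is.null(fit) || !fit$converged || fit$separated) {
    fit <- irls_logistic(X, y, lambda = ridge, maxit = maxit, tol = tol)
    fit$ridge_used <- TRUE
  } else {
    fit$ridge_used <- FALSE
  }
  list(intercept = fit$beta[1], coefficients = fit$beta[-1],
       p_values = fit$p_values[-1], ridge_used = fit$ridge_used)
}

irls_logistic <- function(X, y, lambda, maxit, tol) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xd, Xd * w) + pen
    beta_new <- tryCatch(solve(H, crossprod(Xd, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      if (lambda > 0) return(list(beta = beta, p_values = rep(1, p),
                                  converged = FALSE, separated = TRUE))
      return(NULL)   # singular without penalty: caller retries with ridge
    }
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(Xd %*% beta)
  mu <- stats::plogis(eta)
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8) || max(abs(beta)) > 1e3
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xd, Xd * w) + pen
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(Inf, p))
  pv <- 2 * stats::pnorm(-abs(beta / se))
  pv[!is.finite(pv)] <- 1
  list(beta = beta, p_values = pv, converged = converged,
       separated = separated)
}

# Best Gini split on a 1-D projection. Returns NULL when no positive-gain
# split exists; ties are broken toward the smallest threshold.
best_gini_split <- function(proj, y) {
  ord <- order(proj)
  ps <- proj[ord]; ys <- y[ord]
  n <- length(ys)
  boundary <- which(diff(ps) > 0)       # split after these sorted positions
  if (!length(boundary)) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  nl <- boundary
  l1 <- cum1[boundary]
  nr <- n - nl
  r1 <- n1 - l1
  gini <- function(k, m) 2 * (k / m) * (1 - k / m)   # binary Gini impurity
  gain <- gini(n1, n) - (nl / n) * gini(l1, nl) - (nr / n) * gini(r1, nr)
  best <- which(gain > max(gain) - 1e-12)[1]         # first = smallest threshold
  if (gain[best] <= 1e-12) return(NULL)
  list(threshold = (ps[boundary[best]] + ps[boundary[best] + 1]) / 2,
       gain = gain[best])
}

# Split direction of a node: a sparse (L1-penalized) logistic fit over the
# node's feature subset, evaluated at a fixed fraction of the glmnet
# regularization path. An unpenalized maximum-likelihood projection spreads
# weight over every drawn feature; at node sizes of a few dozen samples the
# overfit noise weights dilute the informative direction so badly that tree
# ensembles stop generalizing. The L1 penalty selects within the subset and
# keeps the projection on the informative features. Falls back to the IRLS
# coefficients when the penalized path is unavailable.
PROJ_LAMBDA_FRAC <- 0.2

node_projection <- function(X, y, model) {
  g <- tryCatch(
    suppressWarnings(glmnet::glmnet(X, y, family = "binomial", nlambda = 30,
                                    lambda.min.ratio = 0.05)),
    error = function(e) NULL)
  if (!is.null(g) && length(g$lambda) >= 2L) {
    lam <- g$lambda[max(2L, ceiling(PROJ_LAMBDA_FRAC * length(g$lambda)))]
    co <- as.vector(stats::coef(g, s = lam))
    if (all(co[-1] == 0))   # too sparse: step further down the path
      co <- as.vector(stats::coef(g, s = g$lambda[min(length(g$lambda), 5L)]))
    if (any(co[-1] != 0))
      return(list(intercept = co[1], coefficients = co[-1]))
  }
  list(intercept = model$intercept, coefficients = model$coefficients)
}

# Recursive tree growth; consumes the current RNG stream. `acc` is an
# environment accumulating the significance-count importance.
grow_node <- function(X, y, mtry, min_node_size, acc) {
  n <- length(y)
  if (n < min_node_size || length(unique(y)) < 2L)
    return(list(leaf = TRUE, prob = mean(y)))
  subset <- sort(sample.int(ncol(X), mtry))
  Xs <- X[, subset, drop = FALSE]
  model <- tryCatch(fit_node_model(Xs, y), error = function(e) NULL)
  if (is.null(model)) return(list(leaf = TRUE, prob = mean(y)))
  acc$counts[subset] <- acc$counts[subset] +
    ifelse(model$p_values < 0.05, 1L, -1L)
  dir <- node_projection(Xs, y, model)
  proj <- as.vector(Xs %*% dir$coefficients) + dir$intercept
  split <- best_gini_split(proj, y)
  if (is.null(split)) return(list(leaf = TRUE, prob = mean(y)))
  left <- proj <= split$threshold
  list(leaf = FALSE, feature_subset = subset,
       coefficients = dir$coefficients, intercept = dir$intercept,
       split_threshold = split$threshold,
       left = grow_node(X[left, , drop = FALSE], y[left], mtry,
                        min_node_size, acc),
       right = grow_node(X[!left, , drop = FALSE], y[!left], mtry,
                         min_node_size, acc))
}

#' Grow a single oblique decision tree
#'
#' Each internal node draws `mtry` features, fits the logistic node model
#' (whose Wald p-values feed the significance-count importance), projects
#' the node's samples onto a sparse L1-penalized logistic direction over the
#' same subset, and splits at the Gini-optimal threshold on that projection.
#'
#' @param X Feature matrix (samples x features).
#' @param y 0/1 response with both classes present.
#' @param mtry Number of features drawn (without replacement) per node.
#' @param min_node_size Minimum samples for a node to be split further.
#' @param seed Integer seed for the feature draws.
#' @return Nested node list; leaves carry the class-1 fraction, internal
#'   nodes the feature subset, linear model and split threshold. Attribute
#'   `"importance"` holds the tree's significance counts per feature.
#' @export
grow_tree <- function(X, y, mtry = ceiling(sqrt(ncol(X))), min_node_size = 5L,
                      seed = 1L) {
  mtry <- min(mtry, ncol(X))
  acc <- new.env()
  acc$counts <- integer(ncol(X))
  root <- withr::with_seed(as.integer(seed),
                           grow_node(X, y, mtry, min_node_size, acc))
  attr(root, "importance") <- acc$counts
  root
}

predict_node <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$prob; return(out) }
  proj <- as.vector(X[idx, node$feature_subset, drop = FALSE] %*%
                      node$coefficients) + node$intercept
  left <- proj <= node$split_threshold
  if (any(left)) out <- predict_node(node$left, X, idx[left], out)
  if (any(!left)) out <- predict_node(node$right, X, idx[!left], out)
  out
}

#' Fit an oblique random forest
#'
#' Grows `n_trees` trees, each on a bootstrap resample of the subjects
#' (n draws with replacement, redrawn if a single class results). The raw
#' significance-count importance is accumulated over all node models of all
#' trees.
#'
#' @inheritParams grow_tree
#' @param n_trees Number of trees (default 300).
#' @param seed Master seed; each tree's resample and feature draws derive
#'   from it deterministically.
#' @return An object of class `oblique_forest` with `trees`, `n_trees`,
#'   `mtry`, `min_node_size`, `seed`, `raw_importance` and `feature_names`.
#' @export
fit_forest <- function(X, y, n_trees = 300L, mtry = ceiling(sqrt(ncol(X))),
                       min_node_size = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(X) < 2L * min_node_size)
    stop("need at least 2 * min_node_size samples")
  mtry <- min(mtry, ncol(X))
  importance <- integer(ncol(X))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot_seed <- derive_seed(seed, t)
    idx <- withr::with_seed(boot_seed, {
      repeat {
        i <- sample.int(nrow(X), replace = TRUE)
        if (length(unique(y[i])) == 2L) break
      }
      i
    })
    trees[[t]] <- grow_tree(X[idx, , drop = FALSE], y[idx], mtry,
                            min_node_size, seed = derive_seed(seed, t, 2L))
    importance <- importance + attr(trees[[t]], "importance")
  }
  structure(list(trees = trees, n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size, seed = seed,
                 raw_importance = importance,
                 feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X)))),
            class = "oblique_forest")
}

#' Predict class-1 probabilities from an oblique forest
#'
#' The forest probability is the mean of the leaf class-1 fractions across
#' trees; the class label is positive (grade IV) when the probability is
#' at least 0.5.
#'
#' @param object An [oblique_forest][fit_forest].
#' @param X Feature matrix with the training column count.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(object, X) {
  stopifnot(inherits(object, "oblique_forest"))
  X <- as.matrix(X)
  if (ncol(X) != length(object$raw_importance))
    stop("column count differs from training data")
  probs <- vapply(object$trees, function(tree)
    predict_node(tree, X, seq_len(nrow(X)), numeric(nrow(X))),
    numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' @rdname predict_proba
#' @export
predict.oblique_forest <- function(object, X, ...) predict_proba(object, X)

#' Bootstrapped significance-count feature importance
#'
#' Repeats the forest fit on `n_iter` stratified bootstrap resamples of the
#' subjects (resampling with replacement within each class, so both classes
#' always survive), records each fit's raw significance-count importance,
#' and averages per feature. The z-score standardizes the per-feature means
#' across features (mean 0, SD 1 over the feature set); features with
#' z > 1.96 are conventionally read as the important ones. Setting
#' `z_mode = "per_feature"` instead scales each feature's mean by its own
#' across-bootstrap SD.
#'
#' @inheritParams fit_forest
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param n_trees,mtry,min_node_size Forest parameters for every refit.
#' @param z_mode `"across_features"` (default) or `"per_feature"`.
#' @return An object of class `importance_result`: data.frame `table`
#'   (feature, mean_score, z) plus `n_iter`, `seed`, `z_mode`.
#' @export
bootstrap_importance <- function(X, y, n_iter = 1000L, n_trees = 300L,
                                 mtry = ceiling(sqrt(ncol(X))),
                                 min_node_size = 5L, seed = 1L,
                                 z_mode = c("across_features", "per_feature")) {
  z_mode <- match.arg(z_mode)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (n_iter < 2L) stop("`n_iter` must be at least 2")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  idx0 <- which(y == 0L)
  idx1 <- which(y == 1L)
  scores <- matrix(0, n_iter, ncol(X))
  for (b in seq_len(n_iter)) {
    idx <- withr::with_seed(derive_seed(seed, 7000L, b),
                            c(sample(idx0, length(idx0), replace = TRUE),
                              sample(idx1, length(idx1), replace = TRUE)))
    fit <- fit_forest(X[idx, , drop = FALSE], y[idx], n_trees = n_trees,
                      mtry = mtry, min_node_size = min_node_size,
                      seed = derive_seed(seed, 8000L, b))
    scores[b, ] <- fit$raw_importance
  }
  mean_score <- colMeans(scores)
  z <- if (z_mode == "across_features") {
    (mean_score - mean(mean_score)) / stats::sd(mean_score)
  } else {
    sds <- apply(scores, 2, stats::sd)
    mean_score / ifelse(sds > 0, sds, Inf)
  }
  structure(list(
    table = data.frame(feature = colnames(X) %||% paste0("f", seq_len(ncol(X))),
                       mean_score = mean_score, z = z,
                       stringsAsFactors = FALSE),
    n_iter = n_iter, seed = seed, z_mode = z_mode),
    class = "importance_result")
}

#' Serialize a forest to JSON / importance to CSV
#'
#' @param forest An [oblique_forest][fit_forest].
#' @param path Output path.
#' @export
write_forest_json <- function(forest, path) {
  strip <- function(node) {
    if (node$leaf) return(list(leaf = TRUE, prob = node$prob))
    list(leaf = FALSE, feature_subset = node$feature_subset,
         coefficients = node$coefficients, intercept = node$intercept,
         split_threshold = node$split_threshold,
         left = strip(node$left), right = strip(node$right))
  }
  jsonlite::write_json(
    list(n_trees = forest$n_trees, mtry = forest$mtry,
         min_node_size = forest$min_node_size, seed = forest$seed,
         feature_names = forest$feature_names,
         raw_importance = forest$raw_importance,
         trees = lapply(forest$trees, strip)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @param importance An [importance_result][bootstrap_importance].
#' @export
write_importance_csv <- function(importance, path) {
  utils::write.csv(importance$table, path, row.names = FALSE)
  invisible(path)
}
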