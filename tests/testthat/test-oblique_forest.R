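test_that("node logistic regression matches an independent GLM fit", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20 * 3), 20, 3)
    eta <- 0.5 + X %*% c(1, -0.8, 0.2)
    y <- as.integer(runif(20) < stats::plogis(eta))
  })
  fit <- fit_node_model(X, y)
  oracle <- stats::glm(y ~ X, family = stats::binomial())
  expect_false(fit$ridge_used)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
  pv_oracle <- summary(oracle)$coefficients[-1, 4]
  expect_equal(unname(fit$p_values), unname(pv_oracle), tolerance = 1e-3)
})

test_that("separable data triggers the ridge fallback with the right sign", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_node_model(X, y)
  expect_true(fit$ridge_used)
  expect_gt(fit$coefficients[1], 0)
  expect_true(is.finite(fit$p_values[1]))
})

test_that("under the null, node coefficients are rarely significant", {
  hits <- vapply(1:40, function(i) {
    withr::with_seed(1000 + i, {
      X <- matrix(rnorm(200), ncol = 1)
      y <- rep(0:1, each = 100)
    })
    fit_node_model(X, y)$p_values[1] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("trees split separable data perfectly and leave pure nodes alone", {
  d <- separable_data(n = 40, seed = 2)
  tree <- grow_tree(d$X, d$y, mtry = 2, min_node_size = 2, seed = 3)
  prob <- qboldgrade:::predict_node(tree, d$X, seq_len(nrow(d$X)),
                                    numeric(nrow(d$X)))
  expect_equal(as.integer(prob >= 0.5), d$y)

  # pure-class input collapses to a single leaf
  pure <- grow_tree(matrix(rnorm(20), 10, 2), rep(1L, 10), seed = 1)
  expect_true(pure$leaf)
  expect_equal(pure$prob, 1)
})

test_that("the chosen Gini split is optimal among thresholds on the projection", {
  gini <- function(y) {
    p <- mean(y); 2 * p * (1 - p)
  }
  brute_best_gain <- function(proj, y) {
    n <- length(y)
    cand <- sort(unique(proj))
    gains <- vapply(utils::head(cand, -1), function(th) {
      l <- proj <= th
      gini(y) - mean(l) * gini(y[l]) - mean(!l) * gini(y[!l])
    }, numeric(1))
    if (!length(gains)) return(NULL)
    max(gains)
  }
  for (i in 1:25) {
    withr::with_seed(300 + i, {
      n <- sample(5:50, 1)
      proj <- rnorm(n)
      y <- sample(0:1, n, replace = TRUE)
    })
    split <- qboldgrade:::best_gini_split(proj, y)
    expected <- brute_best_gain(proj, y)
    if (is.null(split)) {
      expect_true(is.null(expected) || expected <= 1e-12)
    } else {
      expect_equal(split$gain, expected, tolerance = 1e-10)
    }
  }
})

test_that("forests are deterministic and importance counts are bounded", {
  d <- separable_data(n = 60, seed = 5)
  f1 <- fit_forest(d$X, d$y, n_trees = 15, seed = 7)
  f2 <- fit_forest(d$X, d$y, n_trees = 15, seed = 7)
  expect_identical(f1$raw_importance, f2$raw_importance)
  expect_identical(predict_proba(f1, d$X), predict_proba(f2, d$X))

  count_nodes <- function(node) {
    if (node$leaf) return(0L)
    1L + count_nodes(node$left) + count_nodes(node$right)
  }
  total_nodes <- sum(vapply(f1$trees, count_nodes, integer(1)))
  expect_true(all(abs(f1$raw_importance) <= total_nodes * f1$mtry))

  expect_error(fit_forest(d$X, rep(1L, 60), n_trees = 2), "both classes")
})

test_that("a strongly informative feature earns the top raw importance", {
  withr::with_seed(77, {
    n <- 200
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 7] <- X[, 7] + 2 * y     # Cohen's d = 2 among 19 noise features
  })
  f <- fit_forest(X, y, n_trees = 100, seed = 13)
  expect_equal(which.max(f$raw_importance), 7)
})

test_that("forest probabilities aggregate leaves and stay in [0, 1]", {
  d <- separable_data(n = 40, seed = 8)
  f1 <- fit_forest(d$X, d$y, n_trees = 1, seed = 2)
  p1 <- predict_proba(f1, d$X)
  tree_prob <- qboldgrade:::predict_node(f1$trees[[1]], d$X,
                                         seq_len(nrow(d$X)),
                                         numeric(nrow(d$X)))
  expect_identical(p1, tree_prob)

  f <- fit_forest(d$X, d$y, n_trees = 25, seed = 2)
  p <- predict_proba(f, d$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all((p >= 0.5) == (d$y == 1)))
  expect_error(predict_proba(f, d$X[, 1:2]), "column count")
})

test_that("forest accuracy agrees with a reference random forest", {
  skip_if_not_installed("randomForest")
  withr::with_seed(42, {
    n <- 200
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 5), n, 5)
    X[, 1] <- X[, 1] + 3 * y       # axis-aligned separable
    train <- sample(n, 140)
  })
  f <- fit_forest(X[train, ], y[train], n_trees = 50, seed = 3)
  acc_own <- mean((predict_proba(f, X[-train, ]) >= 0.5) == (y[-train] == 1))
  rf <- randomForest::randomForest(X[train, ], factor(y[train]), ntree = 50)
  acc_ref <- mean(predict(rf, X[-train, ]) == factor(y[-train]))
  expect_lt(abs(acc_own - acc_ref), 0.02 + 1e-9)
})

test_that("bootstrap importance standardizes across features deterministically", {
  withr::with_seed(5, {
    n <- 60
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * 8), n, 8)
    X[, 3] <- X[, 3] + 1.5 * y
    colnames(X) <- paste0("f", 1:8)
  })
  imp <- bootstrap_importance(X, y, n_iter = 10, n_trees = 10, seed = 4)
  expect_equal(mean(imp$table$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(imp$table$z), 1, tolerance = 1e-10)
  expect_equal(imp$table$feature[which.max(imp$table$z)], "f3")

  imp2 <- bootstrap_importance(X, y, n_iter = 10, n_trees = 10, seed = 4)
  expect_identical(imp$table, imp2$table)
  expect_error(bootstrap_importance(X, y, n_iter = 1), "at least 2")
})

test_that("larger planted effects never demote the informative feature's rank", {
  rank_of_planted <- function(d_eff, seed) {
    withr::with_seed(seed, {
      n <- 150
      y <- rep(0:1, each = n / 2)
      X <- matrix(rnorm(n * 10), n, 10)
      X[, 4] <- X[, 4] + d_eff * y
    })
    f <- fit_forest(X, y, n_trees = 30, seed = 17)
    rank(f$raw_importance)[4]     # higher rank = more important
  }
  for (seed in c(101, 202, 303)) {
    ranks <- vapply(c(0.3, 1.2, 2.5), rank_of_planted, numeric(1), seed = seed)
    expect_true(all(diff(ranks) >= 0))
  }
})
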