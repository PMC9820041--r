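test_that("a separable step function is fit perfectly by one shallow tree", {
  d <- data.frame(x1 = rep(c(-1, 1), each = 25), x2 = runif(50))
  d$y <- as.numeric(d$x1 > 0)
  f <- mdg_forest(y ~ x1 + x2, d, n_trees = 1, max_depth = 1,
                  min_samples_leaf = 1, bootstrap = FALSE, seed = 1)
  expect_equal(mse(d$y, predict(f, d)), 0)
  imp <- importance(f)
  expect_equal(imp$share[imp$variable == "x1"], 1)
  expect_equal(imp$share[imp$variable == "x2"], 0)
})

test_that("a constant response yields stumps, zero importance and a warning", {
  d <- data.frame(x = rnorm(30), y = 5)
  expect_warning(f <- mdg_forest(y ~ x, d, n_trees = 3, seed = 1), "constant")
  expect_equal(unique(predict(f, d)), 5)
  expect_equal(importance(f)$raw_mdg, 0)
  expect_true(all(is.na(importance(f)$share)))
})

test_that("the depth-1 split matches an exhaustive threshold-scan oracle", {
  scan_best <- function(X, y, min_leaf = 1) {
    n <- length(y)
    ss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
    best <- list(dec = 0, var = NA, thr = NA)
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2) next
      for (t in (xs[-length(xs)] + xs[-1]) / 2) {
        L <- y[X[, j] <= t]; R <- y[X[, j] > t]
        if (length(L) < min_leaf || length(R) < min_leaf) next
        dec <- ss(y) - ss(L) - ss(R)
        if (dec > best$dec) best <- list(dec = dec, var = j, thr = t)
      }
    }
    best
  }
  set.seed(17)
  for (rep in 1:10) {
    n <- 200
    d <- data.frame(a = rnorm(n), b = runif(n), c = rpois(n, 4))
    d$y <- 2 * (d$a > 0.3) + 0.5 * d$b + rnorm(n, 0, 0.3)
    f <- mdg_forest(y ~ a + b + c, d, n_trees = 1, max_depth = 1,
                    min_samples_leaf = 1, bootstrap = FALSE)
    tr <- f$trees[[1]]
    want <- scan_best(as.matrix(d[, c("a", "b", "c")]), d$y)
    expect_equal(tr$var[1], want$var)
    expect_equal(tr$threshold[1], want$thr)
    expect_equal(tr$decrease[1], want$dec, tolerance = 1e-10)
  }
})

test_that("node impurities and decreases are consistent with the raw data", {
  set.seed(23)
  d <- data.frame(x = rnorm(80), z = rnorm(80))
  d$y <- d$x^2 + rnorm(80, 0, 0.1)
  f <- mdg_forest(y ~ x + z, d, n_trees = 1, bootstrap = FALSE,
                  min_samples_leaf = 10)
  tr <- f$trees[[1]]
  ss <- function(v) sum((v - mean(v))^2)
  # walk the tree in R, recomputing each node's sample set
  check_node <- function(node, idx) {
    expect_equal(tr$n[node], length(idx))
    expect_equal(tr$impurity[node], ss(d$y[idx]), tolerance = 1e-10)
    expect_equal(tr$prediction[node], mean(d$y[idx]), tolerance = 1e-12)
    if (tr$var[node] > 0) {
      v <- c("x", "z")[tr$var[node]]
      left <- idx[d[[v]][idx] <= tr$threshold[node]]
      right <- setdiff(idx, left)
      expect_equal(tr$decrease[node],
                   ss(d$y[idx]) - ss(d$y[left]) - ss(d$y[right]),
                   tolerance = 1e-10)
      expect_gt(tr$decrease[node], 0)  # every split strictly decreases impurity
      check_node(tr$left[node], left)
      check_node(tr$right[node], right)
    }
  }
  check_node(1L, seq_len(80))
})

test_that("impurity bookkeeping balances on every tree of a forest", {
  set.seed(29)
  d <- data.frame(a = rnorm(150), b = rnorm(150), c = runif(150))
  d$y <- d$a - 2 * d$b + rnorm(150, 0, 0.5)
  f <- mdg_forest(y ~ ., d, n_trees = 25, seed = 4)
  bk <- impurity_bookkeeping(f)
  expect_equal(bk$total_decrease, bk$root_minus_leaves, tolerance = 1e-8)
  # summed decreases also equal raw importance x n_trees
  expect_equal(sum(importance(f)$raw_mdg) * f$n_trees, sum(bk$total_decrease),
               tolerance = 1e-8)
  expect_equal(sum(importance(f)$share), 1)
})

test_that("forests are reproducible under a seed and tree-order invariant", {
  set.seed(35)
  d <- data.frame(a = rnorm(100), b = rnorm(100))
  d$y <- d$a + rnorm(100, 0, 0.2)
  f1 <- mdg_forest(y ~ ., d, n_trees = 10, seed = 42)
  f2 <- mdg_forest(y ~ ., d, n_trees = 10, seed = 42)
  expect_identical(f1$trees, f2$trees)
  newd <- data.frame(a = rnorm(20), b = rnorm(20))
  p1 <- predict(f1, newd)
  f1$trees <- rev(f1$trees)
  expect_equal(predict(f1, newd), p1)
})

test_that("feature subsampling restricts candidate split variables", {
  set.seed(41)
  d <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  d$y <- 3 * d$a + rnorm(100, 0.1)
  f <- mdg_forest(y ~ ., d, n_trees = 30, mtry = 1, seed = 5)
  imp <- importance(f)
  # with mtry = 1 the weaker variables are forced into splits too
  expect_true(all(imp$raw_mdg > 0))
  expect_error(mdg_forest(y ~ ., d, mtry = 9), "mtry")
})

test_that("pure-noise attributes collectively stay below half the importance", {
  set.seed(47)
  n <- 1000
  d <- data.frame(signal = rnorm(n))
  for (j in 1:5) d[[paste0("noise", j)]] <- rnorm(n)
  d$y <- 2 * d$signal + rnorm(n)  # signal-to-noise 2
  f <- mdg_forest(y ~ ., d, n_trees = 30, seed = 6)
  imp <- importance(f)
  noise_share <- sum(imp$share[grepl("noise", imp$variable)])
  expect_lt(noise_share, 0.5)
})

test_that("importance ranking agrees with an established forest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(53)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 2 * d$a + 0.5 * d$b + rnorm(n, 0, 0.3)
  f <- mdg_forest(y ~ ., d, n_trees = 50, seed = 7)
  rf <- randomForest::randomForest(y ~ ., d, ntree = 50, mtry = 3)
  ours <- importance(f)
  theirs <- randomForest::importance(rf)[, "IncNodePurity"]
  expect_equal(ours$variable[order(-ours$raw_mdg)],
               names(sort(-theirs)))
})
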