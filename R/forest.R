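#' Regression forest with variance-impurity (mean decrease Gini) importance
#'
#' Fits an ensemble of CART regression trees grown greedily: at each node the
#' (variable, threshold) pair maximising the decrease in weighted node
#' impurity is chosen, where impurity is the total sum of squared deviations
#' from the node mean. Leaves predict node means and the forest prediction is
#' the mean over trees. Variable importance is the mean decrease Gini (MDG):
#' for each variable, the sum over all of its splits of
#' `impurity(parent) - impurity(left) - impurity(right)`, divided by the
#' number of trees, and additionally normalized to shares summing to 1.
#'
#' Candidate thresholds sit at midpoints between consecutive sorted distinct
#' feature values; ties in impurity decrease are broken towards the lowest
#' variable index, then the lowest threshold, so a fit is fully deterministic
#' given the seed. Categorical covariates must be supplied as ordered
#' integers (factors are converted with a warning); trees split them as
#' ordered values.
#'
#' @param formula Model formula, `response ~ covariates` (no intercept is
#'   involved; `.` works as usual).
#' @param data Data frame holding the variables.
#' @param n_trees Number of trees; default 100.
#' @param mtry Number of candidate features per split, or `"all"` (default:
#'   with few well-chosen attributes, restricting features mostly adds
#'   variance).
#' @param min_samples_leaf Minimum samples in each child; default 5.
#' @param max_depth Maximum tree depth (root = depth 0), or `Inf`.
#' @param bootstrap Draw a bootstrap sample per tree (default `TRUE`).
#' @param seed Optional integer seed; the fit is reproducible given it and
#'   never disturbs the caller's RNG stream.
#' @return An object of class `mdg_forest` with elements `trees` (per-tree
#'   node tables), `importance` (data frame: variable, raw_mdg, share),
#'   `fitted`, `y`, `terms`, `call`, and the configuration. If `y` is
#'   constant no split is possible: the forest is a set of stumps predicting
#'   the constant, importances are zero, and a warning is raised.
#' @examples
#' d <- data.frame(x1 = rep(c(-1, 1), each = 20), x2 = runif(40))
#' d$y <- as.numeric(d$x1 > 0)
#' f <- mdg_forest(y ~ x1 + x2, d, n_trees = 5, min_samples_leaf = 1, seed = 1)
#' importance(f)
#' @export
mdg_forest <- function(formula, data, n_trees = 100, mtry = "all",
                       min_samples_leaf = 5, max_depth = Inf,
                       bootstrap = TRUE, seed = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric (regression forest)")
  xvars <- attr(stats::terms(mf), "term.labels")
  Xdf <- mf[, xvars, drop = FALSE]
  fac <- vapply(Xdf, function(v) is.factor(v) || is.character(v), TRUE)
  if (any(fac)) {
    warning("coercing ", paste(names(Xdf)[fac], collapse = ", "),
            " to ordered integer codes")
    for (v in names(Xdf)[fac]) Xdf[[v]] <- as.integer(as.factor(Xdf[[v]]))
  }
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 observations")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  mtry_n <- if (identical(mtry, "all")) p else as.integer(mtry)
  if (mtry_n < 1L || mtry_n > p) stop("mtry must be in 1..", p)
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L

  constant_y <- length(unique(y)) < 2L
  if (constant_y)
    warning("constant response: forest of stumps, all importances zero")

  fit_trees <- function() {
    lapply(seq_len(n_trees), function(b) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tr <- .cart_grow(X, as.numeric(y), idx, mtry_n,
                       as.integer(min_samples_leaf), md)
      tr$var <- tr$var + 1L      # 1-based variable index, 0 = leaf
      tr$left <- tr$left + 1L    # 1-based node index, 0 = none
      tr$right <- tr$right + 1L
      tr
    })
  }
  trees <- if (is.null(seed)) fit_trees() else with_seed(seed, fit_trees())

  raw <- numeric(p)
  for (tr in trees) {
    sp <- tr$var > 0L
    if (any(sp)) {
      agg <- tapply(tr$decrease[sp], factor(tr$var[sp], levels = seq_len(p)),
                    sum, default = 0)
      raw <- raw + as.numeric(agg)
    }
  }
  raw <- raw / n_trees
  tot <- sum(raw)
  share <- if (tot > 0) raw / tot else rep(NA_real_, p)
  importance <- data.frame(variable = colnames(X), raw_mdg = raw,
                           share = share)

  obj <- structure(
    list(trees = trees, importance = importance, y = as.numeric(y),
         feature_names = colnames(X), terms = stats::terms(mf),
         n_trees = n_trees, mtry = mtry_n,
         min_samples_leaf = min_samples_leaf, max_depth = max_depth,
         bootstrap = bootstrap, seed = seed, call = match.call()),
    class = "mdg_forest")
  obj$fitted <- predict(obj, newdata = data)
  obj
}

forest_matrix <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  Xdf <- mf[, object$feature_names, drop = FALSE]
  for (v in names(Xdf))
    if (is.factor(Xdf[[v]]) || is.character(Xdf[[v]]))
      Xdf[[v]] <- as.integer(as.factor(Xdf[[v]]))
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  X
}

#' @rdname mdg_forest
#' @param object,x A fitted `mdg_forest`.
#' @param newdata Data frame of covariates to predict for.
#' @param ... Unused.
#' @export
predict.mdg_forest <- function(object, newdata, ...) {
  X <- forest_matrix(object, newdata)
  acc <- numeric(nrow(X))
  for (tr in object$trees) {
    tr0 <- tr
    tr0$var <- tr$var - 1L; tr0$left <- tr$left - 1L; tr0$right <- tr$right - 1L
    acc <- acc + .cart_predict(tr0, X)
  }
  acc / length(object$trees)
}

#' Variable importance of a fitted model
#'
#' @param object A fitted model (`mdg_forest`).
#' @param ... Unused.
#' @return Data frame with `variable`, `raw_mdg` (impurity-decrease sum per
#'   tree) and `share` (normalized to sum 1; `NA` if no split occurred).
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.mdg_forest <- function(object, ...) object$importance

#' @rdname mdg_forest
#' @export
print.mdg_forest <- function(x, ...) {
  cat("Regression forest with variance-impurity importance\n")
  cat(sprintf("  %d trees, mtry = %d, min leaf = %d, bootstrap = %s\n",
              x$n_trees, x$mtry, x$min_samples_leaf, x$bootstrap))
  cat(sprintf("  n = %d observations, %d features\n",
              length(x$y), length(x$feature_names)))
  imp <- x$importance[order(-x$importance$raw_mdg), ]
  cat("  importance shares:\n")
  for (i in seq_len(nrow(imp)))
    cat(sprintf("    %-20s %6.1f%%\n", imp$variable[i], 100 * imp$share[i]))
  invisible(x)
}

#' @rdname mdg_forest
#' @export
summary.mdg_forest <- function(object, ...) {
  yhat <- object$fitted
  out <- list(
    importance = object$importance,
    train_mse = mse(object$y, yhat),
    train_r2 = r2(object$y, yhat),
    n = length(object$y), n_trees = object$n_trees)
  class(out) <- "summary.mdg_forest"
  out
}

#' @export
print.summary.mdg_forest <- function(x, ...) {
  cat(sprintf("Forest of %d trees on n = %d: training MSE %.4g, R2 %.4f\n",
              x$n_trees, x$n, x$train_mse, x$train_r2))
  print(x$importance)
  invisible(x)
}

#' @rdname mdg_forest
#' @export
residuals.mdg_forest <- function(object, ...) object$y - object$fitted

#' @rdname mdg_forest
#' @export
plot.mdg_forest <- function(x, ...) {
  imp <- x$importance[order(x$importance$raw_mdg), ]
  graphics::barplot(100 * imp$share, names.arg = imp$variable, horiz = TRUE,
                    las = 1, xlab = "importance share (%)", ...)
  invisible(x)
}

#' Per-tree impurity bookkeeping of a forest
#'
#' For each tree, the total impurity decrease claimed by splits must equal
#' the root impurity minus the summed leaf impurities. Exposed for testing
#' and diagnostics.
#'
#' @param object A fitted `mdg_forest`.
#' @return Data frame per tree: `total_decrease`, `root_minus_leaves`.
#' @export
impurity_bookkeeping <- function(object) {
  stopifnot(inherits(object, "mdg_forest"))
  do.call(rbind, lapply(seq_along(object$trees), function(i) {
    tr <- object$trees[[i]]
    leaves <- tr$var == 0L
    data.frame(tree = i,
               total_decrease = sum(tr$decrease[!leaves]),
               root_minus_leaves = tr$impurity[1] - sum(tr$impurity[leaves]))
  }))
}
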