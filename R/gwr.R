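#' Geographically weighted regression
#'
#' Local linear regression calibrated at every observation location: for
#' location `i`, coefficients solve weighted least squares with Gaussian
#' kernel weights `w_ij = exp(-d_ij^2 / (2 * bandwidth^2))` over all
#' observations `j`, and the fitted value at `i` uses its own local
#' coefficients. With `bandwidth = Inf` all weights are 1 and every local fit
#' collapses to the global OLS fit.
#'
#' If no bandwidth is given it is chosen by leave-one-out cross-validation
#' (each location predicted with its own weight set to zero) over a
#' logarithmic grid between the median nearest-neighbour distance and the
#' diameter of the point cloud. Near-singular local systems are resolved by
#' a small ridge jitter on the normal equations, with a message.
#'
#' @param formula Model formula, `response ~ covariates`.
#' @param data Data frame of variables.
#' @param coords Two-column matrix or data frame of planar `(x, y)`
#'   locations, one row per observation.
#' @param bandwidth Gaussian kernel bandwidth in coordinate units, `Inf`
#'   allowed, or `NULL` to select by cross-validation.
#' @param bandwidth_grid Number of grid points for the CV search.
#' @return An object of class `gwr`: local coefficient matrix `coefficients`
#'   (rows = locations), `fitted`, `residuals`, `bandwidth`, `cv_table` (if
#'   selected), `terms`, `call`.
#' @examples
#' d <- data.frame(x = runif(50)); d$y <- 2 * d$x + 1
#' co <- cbind(runif(50), runif(50))
#' g <- gwr(y ~ x, d, co, bandwidth = Inf)
#' range(residuals(g))
#' @export
gwr <- function(formula, data, coords, bandwidth = NULL,
                bandwidth_grid = 10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  coords <- as.matrix(coords)
  n <- nrow(X); p <- ncol(X)
  if (nrow(coords) != n || ncol(coords) != 2L)
    stop("coords must be an n x 2 matrix of locations")
  if (n <= p) stop("need n > number of coefficients")

  D2 <- as.matrix(stats::dist(coords))^2

  cv_table <- NULL
  if (is.null(bandwidth)) {
    nn <- apply(D2 + diag(Inf, n), 1, min)
    lo <- max(sqrt(stats::median(nn)), sqrt(max(D2)) * 1e-3)
    hi <- sqrt(max(D2))
    if (!(hi > lo)) { lo <- hi / 10 }
    grid <- exp(seq(log(lo), log(hi), length.out = bandwidth_grid))
    score <- vapply(grid, function(bw)
      gwr_cv_score(X, y, D2, bw), numeric(1))
    cv_table <- data.frame(bandwidth = grid, cv_score = score)
    ok <- is.finite(score)
    if (!any(ok)) stop("no bandwidth on the grid gave a stable fit; ",
                       "supply a larger bandwidth explicitly")
    bandwidth <- grid[ok][which.min(score[ok])]
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")

  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(n)
  n_ridge <- 0L
  for (i in seq_len(n)) {
    w <- kernel_weights(D2[i, ], bandwidth)
    if (sum(w) < p + 1)
      stop("bandwidth ", signif(bandwidth, 4), " leaves location ", i,
           " with effective weight mass below p + 1; increase the bandwidth")
    fit <- wls_solve(X, y, w)
    n_ridge <- n_ridge + fit$ridged
    beta[i, ] <- fit$beta
    fitted[i] <- drop(X[i, , drop = FALSE] %*% fit$beta)
  }
  if (n_ridge > 0L)
    message(n_ridge, " local systems needed a ridge jitter")

  structure(list(coefficients = beta, fitted = fitted,
                 residuals = y - fitted, y = y, bandwidth = bandwidth,
                 cv_table = cv_table, coords = coords, n_ridge = n_ridge,
                 terms = attr(mf, "terms"), call = match.call()),
            class = "gwr")
}

kernel_weights <- function(d2, bw) {
  if (is.infinite(bw)) rep(1, length(d2)) else exp(-d2 / (2 * bw^2))
}

wls_solve <- function(X, y, w) {
  XtW <- t(X * w)
  A <- XtW %*% X
  b <- XtW %*% y
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  ridged <- 0L
  if (is.null(beta)) {
    A <- A + diag(mean(diag(A)) * 1e-8 + 1e-12, ncol(X))
    beta <- solve(A, b)
    ridged <- 1L
  }
  list(beta = drop(beta), ridged = ridged)
}

gwr_cv_score <- function(X, y, D2, bw) {
  n <- nrow(X); p <- ncol(X)
  err <- numeric(n)
  for (i in seq_len(n)) {
    w <- kernel_weights(D2[i, ], bw)
    w[i] <- 0
    if (sum(w) < p + 1) return(Inf)
    fit <- tryCatch(wls_solve(X, y, w), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    err[i] <- y[i] - drop(X[i, , drop = FALSE] %*% fit$beta)
  }
  sum(err^2)
}

#' @rdname gwr
#' @param object,x A fitted `gwr` object.
#' @param newdata Data frame of covariates for prediction.
#' @param newcoords Locations of `newdata` rows; each prediction uses the
#'   local coefficients of the nearest calibration location.
#' @param ... Unused.
#' @export
predict.gwr <- function(object, newdata = NULL, newcoords = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  if (is.null(newcoords))
    stop("newcoords required to locate predictions")
  newcoords <- as.matrix(newcoords)
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- (object$coords[, 1] - newcoords[i, 1])^2 +
          (object$coords[, 2] - newcoords[i, 2])^2
    j <- which.min(d2)
    out[i] <- drop(X[i, , drop = FALSE] %*% object$coefficients[j, ])
  }
  out
}

#' @rdname gwr
#' @export
print.gwr <- function(x, ...) {
  cat(sprintf("GWR fit: n = %d, bandwidth = %s, Gaussian kernel\n",
              length(x$y),
              if (is.infinite(x$bandwidth)) "Inf (global OLS limit)"
              else signif(x$bandwidth, 4)))
  cat("Local coefficient ranges:\n")
  rng <- apply(x$coefficients, 2, range)
  for (j in seq_len(ncol(rng)))
    cat(sprintf("  %-16s [%.4g, %.4g]\n", colnames(x$coefficients)[j],
                rng[1, j], rng[2, j]))
  invisible(x)
}

#' @rdname gwr
#' @export
residuals.gwr <- function(object, ...) object$residuals

#' @rdname gwr
#' @export
summary.gwr <- function(object, ...) {
  k <- ncol(object$coefficients) - 1
  out <- list(bandwidth = object$bandwidth,
              mse = mse(object$y, object$fitted),
              r2 = r2(object$y, object$fitted),
              adj_r2 = adjusted_r2(object$y, object$fitted, k),
              n = length(object$y), k = k)
  class(out) <- "summary.gwr"
  out
}

#' @export
print.summary.gwr <- function(x, ...) {
  cat(sprintf("GWR (bandwidth %s): n = %d, k = %d, MSE %.4g, adj R2 %.4f\n",
              signif(x$bandwidth, 4), x$n, x$k, x$mse, x$adj_r2))
  invisible(x)
}
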