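#' Regression fit metrics
#'
#' Standard goodness-of-fit quantities used to compare the forest and the
#' geographically weighted regression:
#' `MSE = mean((y - yhat)^2)`,
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, and
#' `adjusted R2 = 1 - (1 - R2) * (n - 1) / (n - k - 1)` with `k` covariates.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @param k Number of independent variables (for the adjustment).
#' @return A single number. `r2()` is `NA` with a warning when `y` has zero
#'   variance; `adjusted_r2()` errors when `n - k - 1 <= 0`.
#' @examples
#' mse(c(1, 2, 3), c(1, 2, 4))          # 1/3
#' r2(c(1, 2, 3), c(1, 2, 4))           # 0.5
#' adjusted_r2(c(1, 2, 3), c(1, 2, 4), k = 1)  # 0
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((y - yhat)^2)
}

#' @rdname mse
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    warning("zero total variance in y: R2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / tss
}

#' @rdname mse
#' @export
adjusted_r2 <- function(y, yhat, k) {
  n <- length(y)
  if (n - k - 1 <= 0) stop("adjusted R2 needs n - k - 1 > 0")
  R2 <- r2(y, yhat)
  1 - (1 - R2) * (n - 1) / (n - k - 1)
}

#' Train/test/validation split
#'
#' Randomly partitions `1:n` into disjoint, exhaustive train, test and
#' validation index sets with sizes given by the fractions (default
#' 55% / 30% / 15%). Test and validation sizes are the rounded fractions;
#' the remainder goes to train, so `split_data(100)` gives exactly
#' (55, 30, 15).
#'
#' @param n Number of observations (`>= 3`).
#' @param fractions Length-3 fractions `(train, test, validation)` summing
#'   to 1.
#' @param seed Optional integer seed (RNG restored afterwards).
#' @return List of integer vectors `train`, `test`, `validation`.
#' @export
split_data <- function(n, fractions = c(0.55, 0.30, 0.15), seed = NULL) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be length 3 and sum to 1")
  if (n < 3L) stop("need n >= 3 to populate all three sets")
  n_test <- round(n * fractions[2])
  n_val <- round(n * fractions[3])
  n_train <- n - n_test - n_val
  if (min(n_train, n_test, n_val) < 1L)
    stop("n too small to populate all three sets at these fractions")
  perm <- if (is.null(seed)) sample.int(n) else with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       validation = sort(perm[n_train + n_test + seq_len(n_val)]))
}
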