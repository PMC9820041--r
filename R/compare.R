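#' Attribute importance per land-use class and period
#'
#' Fits the regression forest of change rate on the grid-cell attributes
#' separately for each land-use class and period, on the training partition
#' of a 55/30/15 split, and collects the normalized mean-decrease-Gini
#' importance shares.
#'
#' @param attributes Data frame of per-cell attributes with a `cell_id`
#'   column; all other columns are used as covariates.
#' @param changes [compute_changes()] output.
#' @param classification Data frame with `cell_id`, `label`.
#' @param classes Land-use classes to analyse.
#' @param seed Master seed; the split and each fit derive their own seeds
#'   from it with fixed offsets.
#' @param ... Passed to [mdg_forest()].
#' @return Data frame: `class`, `period`, `variable`, `raw_mdg`, `share`.
#' @export
importance_by_class <- function(attributes, changes, classification,
                                classes = c("residential", "working",
                                            "entertainment", "mixed"),
                                seed = 1, ...) {
  periods <- c("period1", "period2", "period3")
  attr_cols <- setdiff(names(attributes), "cell_id")
  out <- list()
  for (cl in classes) {
    ids <- classification$cell_id[classification$label == cl]
    sub <- merge(attributes, changes[changes$cell_id %in% ids, ],
                 by = "cell_id")
    for (pp in periods) {
      d <- sub[!is.na(sub[[pp]]), c(attr_cols, pp)]
      if (nrow(d) < 20) next
      names(d)[ncol(d)] <- "rate"
      sp <- split_data(nrow(d), seed = seed + 101)
      f <- mdg_forest(rate ~ ., d[sp$train, ],
                      seed = seed + 211 + match(pp, periods), ...)
      imp <- importance(f)
      out[[paste(cl, pp)]] <- data.frame(class = cl, period = pp, imp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare forest and GWR accuracy per land-use class and period
#'
#' For each land-use class and each of the three periods, splits the cells
#' 55/30/15 into train/test/validation, fits the regression forest and a GWR
#' on the identical training partition, and reports MSE and adjusted R^2 for
#' both models. No winner is asserted; the table only reports. Missing
#' class/period combinations (too few cells) are reported absent.
#'
#' @inheritParams importance_by_class
#' @param coords Data frame with `cell_id`, `x`, `y` cell centroids (for the
#'   GWR kernel).
#' @param partition Which partition the headline table reports, `"train"`
#'   (default) or `"test"`; both are always computed.
#' @param bandwidth GWR bandwidth; `NULL` selects by cross-validation per
#'   fit.
#' @param n_trees Forest size for the comparison fits.
#' @param min_n Minimum cells for a class/period cell to be fitted.
#' @param seed Master seed.
#' @return Object of class `model_comparison`: a data frame with one row per
#'   class x period (`mse_gwr`, `mse_rf`, `adjr2_gwr`, `adjr2_rf` on the
#'   chosen partition), with the full per-partition metric table in
#'   `attr(, "details")`.
#' @export
compare_models <- function(attributes, changes, classification, coords,
                           classes = c("residential", "working",
                                       "entertainment", "mixed"),
                           partition = c("train", "test"),
                           bandwidth = NULL, n_trees = 100, min_n = 40,
                           seed = 1) {
  partition <- match.arg(partition)
  periods <- c("period1", "period2", "period3")
  attr_cols <- setdiff(names(attributes), "cell_id")
  k <- length(attr_cols)
  rows <- list(); details <- list()
  for (cl in classes) {
    ids <- classification$cell_id[classification$label == cl]
    sub <- merge(merge(attributes, changes[changes$cell_id %in% ids, ],
                       by = "cell_id"),
                 coords, by = "cell_id")
    for (pp in periods) {
      d <- sub[!is.na(sub[[pp]]), ]
      key <- paste(cl, pp, sep = "_")
      if (nrow(d) < min_n) {
        rows[[key]] <- data.frame(class = cl, period = pp, n = nrow(d),
                                  mse_gwr = NA, mse_rf = NA,
                                  adjr2_gwr = NA, adjr2_rf = NA)
        next
      }
      dd <- d[, c(attr_cols, pp)]
      names(dd)[ncol(dd)] <- "rate"
      sp <- split_data(nrow(dd), seed = seed + 17)
      tr <- sp$train; te <- sp$test
      rf <- mdg_forest(rate ~ ., dd[tr, ], n_trees = n_trees,
                       seed = seed + 31)
      gw <- gwr(rate ~ ., dd[tr, ], coords = d[tr, c("x", "y")],
                bandwidth = bandwidth)
      met <- function(y, yhat) c(mse = mse(y, yhat),
                                 adjr2 = adjusted_r2(y, yhat, k))
      m <- rbind(
        data.frame(class = cl, period = pp, model = "rf", partition = "train",
                   t(met(dd$rate[tr], predict(rf, dd[tr, ])))),
        data.frame(class = cl, period = pp, model = "rf", partition = "test",
                   t(met(dd$rate[te], predict(rf, dd[te, ])))),
        data.frame(class = cl, period = pp, model = "gwr", partition = "train",
                   t(met(dd$rate[tr], gw$fitted))),
        data.frame(class = cl, period = pp, model = "gwr", partition = "test",
                   t(met(dd$rate[te],
                         predict(gw, dd[te, ], d[te, c("x", "y")])))))
      details[[key]] <- m
      pick <- function(model) m[m$model == model & m$partition == partition, ]
      rows[[key]] <- data.frame(
        class = cl, period = pp, n = nrow(dd),
        mse_gwr = pick("gwr")$mse, mse_rf = pick("rf")$mse,
        adjr2_gwr = pick("gwr")$adjr2, adjr2_rf = pick("rf")$adjr2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- do.call(rbind, c(details, make.row.names = FALSE))
  attr(out, "partition") <- partition
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Forest vs GWR accuracy (%s partition):\n",
              attr(x, "partition")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
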