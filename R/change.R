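#' Clock windows used to sum activity intensity per land-use class
#'
#' Each land-use class is summarised over the clock window in which its
#' characteristic activity concentrates, rather than over the full day:
#' 22:00-24:00 for residential cells (4 half-hour bins), 9:00-17:00 for
#' working cells (16 bins), 17:00-22:00 for entertainment cells (10 bins) and
#' 9:00-24:00 for mixed-use cells (30 bins). Windows are half-open
#' `[start, end)` on bin start times; 24:00 is the exclusive end of day.
#'
#' @return Named list of `c(start_hour, end_hour)` pairs.
#' @export
default_window_policy <- function() {
  list(residential = c(22, 24), working = c(9, 17),
       entertainment = c(17, 22), mixed = c(9, 24))
}

check_window_policy <- function(policy) {
  for (nm in names(policy)) {
    w <- policy[[nm]]
    if (length(w) != 2L || w[1] < 0 || w[2] > 24 || w[1] >= w[2])
      stop("window for '", nm, "' must be a nonempty interval within [0, 24]")
  }
  invisible(policy)
}

# 0-based bin indices whose start time lies in [start, end); bin b covers
# [b/2, (b+1)/2) hours.
window_bins <- function(window) {
  starts <- (0:47) / 2
  which(starts >= window[1] & starts < window[2])  # 1-based R indices
}

#' Sum a day's intensity over the class window
#'
#' @param bins Numeric vector of 48 nonnegative half-hourly intensities
#'   (bin `b` covers `[b/2, (b+1)/2)` hours, `b = 0..47`), or a matrix with 48
#'   columns (rows = cells/days).
#' @param label Land-use class label(s) selecting the window; must be present
#'   in `policy`. Recycled against matrix rows.
#' @param policy Window policy, default [default_window_policy()].
#' @return Scalar window sum, or a vector for matrix input.
#' @examples
#' window_sum(rep(1, 48), "residential")  # 4 bins
#' @export
window_sum <- function(bins, label, policy = default_window_policy()) {
  check_window_policy(policy)
  unknown <- setdiff(unique(label), names(policy))
  if (length(unknown))
    stop("no window for label(s): ", paste(unknown, collapse = ", "))
  if (is.matrix(bins)) {
    if (ncol(bins) != 48L) stop("intensity matrices need 48 columns")
    if (length(label) == 1L) label <- rep(label, nrow(bins))
    return(vapply(seq_len(nrow(bins)), function(i)
      sum(bins[i, window_bins(policy[[label[i]]])]), numeric(1)))
  }
  if (length(bins) != 48L) stop("an intensity day has exactly 48 bins")
  if (any(bins < 0)) stop("intensity bins must be nonnegative")
  sum(bins[window_bins(policy[[label]])])
}

#' Three-period change rates from four daily window sums
#'
#' Given per-day window sums for the baseline day (day 1) and the three
#' observation days, the change rate of period `k` is
#' `(day_{k+1} - day_1) / day_1 * 100`, in percent; all three periods share
#' day 1 as the baseline. Period 1 is the lockdown stage, period 2 the first
#' stage of work resuming, period 3 total work resuming. Cells with a zero
#' baseline have undefined rates (`NA`, `defined = FALSE`) and are excluded
#' from summaries with a logged count.
#'
#' @param day1,day2,day3,day4 Nonnegative window sums (vectors of equal
#'   length, one element per cell).
#' @param cell_id Optional cell ids; default sequential.
#' @return Data frame: `cell_id`, `period1..period3` (percent), `defined`.
#' @examples
#' change_rates(100, 75, 90, 95)
#' @export
change_rates <- function(day1, day2, day3, day4, cell_id = seq_along(day1)) {
  if (any(c(day1, day2, day3, day4) < 0, na.rm = TRUE))
    stop("window sums must be nonnegative")
  n <- length(day1)
  stopifnot(length(day2) == n, length(day3) == n, length(day4) == n)
  defined <- is.finite(day1) & day1 > 0
  rate <- function(dk) ifelse(defined, (dk - day1) / day1 * 100, NA_real_)
  data.frame(cell_id = cell_id,
             period1 = rate(day2), period2 = rate(day3), period3 = rate(day4),
             defined = defined)
}

#' Per-cell change rates from a long intensity table
#'
#' Computes window sums per cell and day under the cell's land-use window,
#' then the three period change rates. The window of a cell is fixed by its
#' label for all four days.
#'
#' @param intensity Long data frame: columns `cell_id`, `day`
#'   (`"day1".."day4"`) and `bin_0 .. bin_47`.
#' @param classification Data frame with `cell_id` and `label` (from
#'   [classify_grid()]). Cells labelled `other` / `non_human_activity` are
#'   dropped (no window is defined for them) and counted in the
#'   `n_unclassified` attribute.
#' @param policy Window policy.
#' @return A [change_rates()] data frame, one row per classified cell, with
#'   attribute `n_unclassified`.
#' @export
compute_changes <- function(intensity, classification,
                            policy = default_window_policy()) {
  bin_cols <- paste0("bin_", 0:47)
  if (!all(bin_cols %in% names(intensity)))
    stop("intensity must have columns bin_0 .. bin_47")
  lab <- stats::setNames(classification$label, classification$cell_id)
  keep_labels <- names(policy)
  cells <- classification$cell_id[classification$label %in% keep_labels]
  n_unclassified <- sum(!classification$label %in% keep_labels)
  sums <- matrix(NA_real_, length(cells), 4,
                 dimnames = list(cells, paste0("day", 1:4)))
  bm <- as.matrix(intensity[, bin_cols])
  idx <- split(seq_len(nrow(intensity)),
               list(intensity$cell_id, intensity$day), drop = TRUE)
  for (key in names(idx)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cid <- parts[1]; day <- parts[2]
    if (!cid %in% rownames(sums)) next
    rows <- idx[[key]]
    sums[cid, day] <- window_sum(colSums(bm[rows, , drop = FALSE]),
                                 lab[[cid]], policy)
  }
  out <- change_rates(sums[, 1], sums[, 2], sums[, 3], sums[, 4],
                      cell_id = as.integer(rownames(sums)))
  attr(out, "n_unclassified") <- n_unclassified
  out
}

group_mean <- function(x, g) {
  ok <- !is.na(x)
  n <- tapply(ok, g, sum)
  m <- tapply(ifelse(ok, x, 0), g, sum) / ifelse(n > 0, n, NA)
  list(mean = as.numeric(m), n = as.integer(n), group = names(m))
}

#' Summary tables of change rates
#'
#' Produces the standard summaries: mean change per land-use class and
#' period; mean change per sector and period; the count and share of cells
#' with negative change per period; and east/west means per period when a
#' side vector is supplied. Means are unweighted over cells; cells with an
#' undefined rate are excluded pairwise per period and the exclusion counts
#' reported. Empty groups are reported absent (no row), never as silent NaN.
#'
#' @param changes [change_rates()] output (or [compute_changes()]).
#' @param classification Data frame with `cell_id`, `label` and optionally
#'   `sector_label`.
#' @param sides Optional named vector (names = cell ids) or data frame
#'   (`cell_id`, `side`) of `"east_side"`/`"west_side"` from [side_of_line()].
#' @return List of data frames: `by_class`, `by_sector` (if sector labels
#'   exist), `negative_share`, `by_side` (if sides given), and `exclusions`
#'   (per-period counts of undefined cells).
#' @export
summarize_changes <- function(changes, classification, sides = NULL) {
  cls <- classification[match(changes$cell_id, classification$cell_id), ]
  periods <- c("period1", "period2", "period3")
  long <- do.call(rbind, lapply(periods, function(p)
    data.frame(cell_id = changes$cell_id, period = p, rate = changes[[p]],
               label = cls$label,
               sector = if ("sector_label" %in% names(cls)) cls$sector_label
                        else NA_character_)))

  mk <- function(sub, by) {
    sub <- sub[!is.na(sub[[by]]) & !is.na(sub$rate), ]
    if (!nrow(sub)) return(data.frame())
    key <- interaction(sub[[by]], sub$period, drop = TRUE, sep = "\r")
    gm <- group_mean(sub$rate, key)
    parts <- do.call(rbind, strsplit(gm$group, "\r", fixed = TRUE))
    out <- data.frame(group = parts[, 1], period = parts[, 2],
                      mean_change = gm$mean, n_cells = gm$n)
    names(out)[1] <- by
    out[order(out[[by]], out$period), , drop = FALSE]
  }

  by_class <- mk(long, "label")
  by_sector <- mk(long[long$label %in% c("working", "entertainment"), ],
                  "sector")
  if (nrow(by_sector)) {
    cls_of <- stats::setNames(long$label, long$sector)
    by_sector$class <- cls_of[by_sector$sector]
    by_sector <- by_sector[, c("class", "sector", "period",
                               "mean_change", "n_cells")]
  }

  neg <- do.call(rbind, lapply(periods, function(p) {
    r <- changes[[p]]
    ok <- !is.na(r)
    data.frame(period = p, n_negative = sum(r[ok] < 0), n_defined = sum(ok),
               share_negative = if (sum(ok)) sum(r[ok] < 0) / sum(ok) * 100
                                else NA_real_)
  }))

  by_side <- NULL
  if (!is.null(sides)) {
    if (is.data.frame(sides))
      sides <- stats::setNames(sides$side, sides$cell_id)
    long$side <- sides[as.character(long$cell_id)]
    by_side <- mk(long, "side")
  }

  excl <- do.call(rbind, lapply(periods, function(p)
    data.frame(period = p, n_excluded = sum(is.na(changes[[p]])))))

  out <- list(by_class = by_class, negative_share = neg, exclusions = excl)
  if (nrow(by_sector)) out$by_sector <- by_sector
  if (!is.null(by_side)) out$by_side <- by_side
  out
}
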