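#' Default POI taxonomy for land-use classification
#'
#' Maps the three land-use classes to their first-level POI categories:
#' residential (2 categories), working (6) and entertainment (5). The working
#' and entertainment category lists double as the sub-sector schemes used by
#' [classify_sector()] (6 working sectors, 5 entertainment sectors).
#'
#' @return Named list of character vectors; names are
#'   `residential`, `working`, `entertainment`.
#' @export
default_taxonomy <- function() {
  list(
    residential = c("Residential community", "Community service"),
    working = c("Private company", "Office building", "Financial sector",
                "Legal sector", "Government institution",
                "Education institution"),
    entertainment = c("Commercial site", "Hotel", "Tourism", "Sport/gym",
                      "Catering site"))
}

check_taxonomy <- function(taxonomy) {
  if (!all(lengths(taxonomy) > 0L)) stop("each class needs >= 1 category")
  cats <- unlist(taxonomy, use.names = FALSE)
  if (anyDuplicated(cats)) stop("categories must be disjoint across classes")
  invisible(taxonomy)
}

#' Normalized POI frequency
#'
#' `F = n / N` where `n` is the per-cell category count and `N` the national
#' (study-area) total of that category. Normalizing by the national total
#' removes the influence of large differences in total counts between
#' categories (residential POIs are far rarer nationally than working or
#' entertainment POIs).
#'
#' Both arguments are recycled elementwise as usual. `N = 0` with `n > 0` is an
#' inconsistency and errors; `N = 0` with `n = 0` yields `F = 0` with a
#' message.
#'
#' @param n Per-cell count(s), `>= 0`.
#' @param N National total(s), `>= 0`.
#' @return Numeric vector of normalized frequencies.
#' @examples
#' normalized_frequency(10, 100)  # 0.1
#' @export
normalized_frequency <- function(n, N) {
  if (any(n < 0) || any(N < 0)) stop("counts must be nonnegative")
  bad <- N == 0 & n > 0
  if (any(bad)) stop("inconsistent totals: N = 0 with n > 0")
  out <- n / N           # recycles as usual
  zz <- is.nan(out)      # 0 / 0: zero national total with zero count
  if (any(zz)) {
    message(sum(zz), " zero-total categories; F set to 0")
    out[zz] <- 0
  }
  as.numeric(out)
}

#' Percentage share of each class from normalized frequencies
#'
#' `C_i = F_i / sum(F) * 100`; the shares sum to 100 whenever any `F_i > 0`.
#' When all frequencies are zero the shares are undefined and returned as
#' `NA`; the caller labels such a cell `"other"` (or `"non_human_activity"`).
#'
#' @param F Numeric vector (or matrix, rows = cells) of nonnegative
#'   normalized frequencies.
#' @return Shares in percent, same shape as `F`; all-`NA` where `sum(F) == 0`.
#' @examples
#' category_share(c(0.1, 0.1, 0.2))  # 25 25 50
#' @export
category_share <- function(F) {
  if (is.matrix(F)) {
    if (any(F < 0)) stop("frequencies must be nonnegative")
    tot <- rowSums(F)
    out <- F / ifelse(tot > 0, tot, NA) * 100
    return(out)
  }
  if (any(F < 0)) stop("frequencies must be nonnegative")
  tot <- sum(F)
  if (tot == 0) return(rep(NA_real_, length(F)))
  F / tot * 100
}

#' Dominance rule: label a cell from its class shares
#'
#' A cell is labelled class `i` iff `C_i` is the unique maximum and reaches
#' the threshold (inclusive, default 50%). If no share reaches the threshold
#' uniquely there is no dominant type and the cell is `"mixed"`. Undefined
#' shares (all `NA`: the cell has no POIs of the classified classes) give
#' `"other"`. An exact tie at the threshold (e.g. 50/50) is `"mixed"` because
#' no *unique* dominant type exists.
#'
#' @param C Numeric vector of shares in percent (typically length 3, named),
#'   or a matrix with one row per cell.
#' @param threshold Dominance threshold in percent; default 50.
#' @param classes Class names, used when `C` is unnamed.
#' @return Character label(s).
#' @examples
#' classify_cell(c(residential = 25, working = 25, entertainment = 50))
#' @export
classify_cell <- function(C, threshold = 50,
                          classes = c("residential", "working", "entertainment")) {
  if (is.matrix(C)) {
    if (is.null(colnames(C))) colnames(C) <- classes
    return(vapply(seq_len(nrow(C)),
                  function(i) classify_cell(C[i, ], threshold), ""))
  }
  if (is.null(names(C))) names(C) <- classes[seq_along(C)]
  if (all(is.na(C))) return("other")
  m <- max(C)
  winners <- names(C)[C == m]
  if (length(winners) == 1L && m >= threshold) winners else "mixed"
}

#' Classify every grid cell from POI category counts
#'
#' Applies the normalized-frequency dominance rule cell by cell: per-category
#' counts are normalized by the national totals ([normalized_frequency()]),
#' summed within each land-use class, converted to percentage shares
#' ([category_share()]) and labelled ([classify_cell()]). Cells whose
#' three-class POI count is zero but that contain POIs of other categories are
#' labelled `"other"`; cells with no POIs at all are `"non_human_activity"`.
#' Both residual classes are excluded from change-rate summaries downstream.
#'
#' @param counts Matrix of per-cell POI counts: rows = cells (rownames = cell
#'   ids), columns = first-level categories. Columns not in the taxonomy are
#'   allowed (they only affect the other/non-activity distinction).
#' @param taxonomy Class-to-category mapping, default [default_taxonomy()].
#' @param national_totals Named per-category national totals; defaults to the
#'   column sums of `counts` (the study area is "the nation").
#' @param threshold Dominance threshold in percent.
#' @return A data frame with one row per cell: `cell_id`, `F_residential`,
#'   `F_working`, `F_entertainment`, the corresponding `C_*` shares (percent),
#'   and `label`.
#' @export
classify_cells <- function(counts, taxonomy = default_taxonomy(),
                           national_totals = colSums(counts),
                           threshold = 50) {
  check_taxonomy(taxonomy)
  cats <- unlist(taxonomy, use.names = FALSE)
  missing_cats <- setdiff(cats, colnames(counts))
  if (length(missing_cats)) {
    pad <- matrix(0, nrow(counts), length(missing_cats),
                  dimnames = list(rownames(counts), missing_cats))
    counts <- cbind(counts, pad)
    national_totals <- c(national_totals,
                         stats::setNames(numeric(length(missing_cats)), missing_cats))
  }
  Fm <- sapply(names(taxonomy), function(cl) {
    cc <- taxonomy[[cl]]
    Fcat <- vapply(cc, function(cat)
      suppressMessages(normalized_frequency(counts[, cat], national_totals[[cat]])),
      numeric(nrow(counts)))
    if (is.null(dim(Fcat))) sum(Fcat) else rowSums(Fcat)
  })
  if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1, dimnames = list(NULL, names(taxonomy)))
  Cm <- category_share(Fm)
  label <- classify_cell(Cm, threshold = threshold)
  total_pois <- rowSums(counts)
  label[label == "other" & total_pois == 0] <- "non_human_activity"
  out <- data.frame(
    cell_id = if (!is.null(rownames(counts))) as.integer(rownames(counts))
              else seq_len(nrow(counts)))
  for (cl in names(taxonomy)) out[[paste0("F_", cl)]] <- Fm[, cl]
  for (cl in names(taxonomy)) out[[paste0("C_", cl)]] <- Cm[, cl]
  out$label <- label
  out
}

#' Sub-sector classification of working and entertainment cells
#'
#' Re-applies the same normalized-frequency dominance machinery over the
#' sub-categories of the cell's class: the 6 working sectors or the 5
#' entertainment sectors (the first-level categories of the class double as
#' its sectors). A cell with no unique sub-share reaching the threshold is
#' `"mixed_sector"`; a cell with no sub-category POIs at all gets `NA`.
#'
#' @param label Per-cell land-use labels (from [classify_cells()]); only
#'   `"working"` and `"entertainment"` cells may be classified, any other
#'   label errors.
#' @param sub_counts Per-cell count matrix over the sub-categories of the
#'   cell's class (columns = category names).
#' @param national_sub_totals Named national totals per sub-category; default
#'   column sums of `sub_counts`.
#' @param threshold Dominance threshold in percent.
#' @return Character vector of sector labels.
#' @export
classify_sector <- function(label, sub_counts,
                            national_sub_totals = colSums(sub_counts),
                            threshold = 50) {
  if (is.null(dim(sub_counts)))
    sub_counts <- matrix(sub_counts, nrow = 1,
                         dimnames = list(NULL, names(sub_counts)))
  if (length(label) == 1L) label <- rep(label, nrow(sub_counts))
  bad <- !label %in% c("working", "entertainment")
  if (any(bad))
    stop("classify_sector applies only to working/entertainment cells; got: ",
         paste(unique(label[bad]), collapse = ", "))
  subs <- colnames(sub_counts)
  Fm <- vapply(subs, function(cat)
    suppressMessages(normalized_frequency(sub_counts[, cat],
                                          national_sub_totals[[cat]])),
    numeric(nrow(sub_counts)))
  if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1, dimnames = list(NULL, subs))
  Cm <- category_share(Fm)
  out <- classify_cell(Cm, threshold = threshold)
  out[out == "mixed"] <- "mixed_sector"
  out[out == "other"] <- NA_character_
  out
}

#' Full classification pass: land-use labels plus sectors
#'
#' Convenience wrapper: classifies cells with [classify_cells()], then
#' assigns sector labels to the working and entertainment cells with
#' [classify_sector()] using the class's own first-level categories as its
#' sub-sector scheme.
#'
#' @inheritParams classify_cells
#' @return The [classify_cells()] data frame with an extra `sector_label`
#'   column (`NA` for residential/mixed/other cells).
#' @export
classify_grid <- function(counts, taxonomy = default_taxonomy(),
                          national_totals = colSums(counts),
                          threshold = 50) {
  res <- classify_cells(counts, taxonomy, national_totals, threshold)
  res$sector_label <- NA_character_
  for (cl in c("working", "entertainment")) {
    idx <- which(res$label == cl)
    if (!length(idx)) next
    subs <- intersect(taxonomy[[cl]], colnames(counts))
    res$sector_label[idx] <- classify_sector(
      rep(cl, length(idx)), counts[idx, subs, drop = FALSE],
      national_sub_totals = colSums(counts[, subs, drop = FALSE]),
      threshold = threshold)
  }
  res
}
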