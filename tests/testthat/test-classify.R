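test_that("normalized frequency is count over national total", {
  expect_equal(normalized_frequency(10, 100), 0.1)
  expect_equal(normalized_frequency(0, 57), 0)
  # vector case agrees with the elementwise scalar computation
  set.seed(2)
  n <- rpois(50, 20); N <- n + rpois(50, 500)
  expect_equal(normalized_frequency(n, N),
               vapply(1:50, function(i) normalized_frequency(n[i], N[i]), 0))
  expect_error(normalized_frequency(3, 0), "inconsistent")
  expect_message(out <- normalized_frequency(c(0, 5), c(0, 10)), "zero-total")
  expect_equal(out, c(0, 0.5))
})

test_that("category shares are percentages summing to 100", {
  expect_equal(category_share(c(0.1, 0.1, 0.2)), c(25, 25, 50))
  expect_equal(category_share(c(0.3, 0, 0)), c(100, 0, 0))
  expect_true(all(is.na(category_share(c(0, 0, 0)))))
  set.seed(9)
  for (i in 1:1000) {
    F <- rexp(3)
    expect_equal(sum(category_share(F)), 100)
  }
})

test_that("the dominance rule labels cells as the classifier oracle does", {
  expect_equal(classify_cell(c(residential = 25, working = 25,
                               entertainment = 50)), "entertainment")
  expect_equal(classify_cell(c(residential = 50, working = 50,
                               entertainment = 0)), "mixed")  # no unique max
  expect_equal(classify_cell(c(NA_real_, NA_real_, NA_real_)), "other")

  # exhaustive-condition oracle over random share vectors
  oracle <- function(C) {
    if (all(is.na(C))) return("other")
    best <- which(C == max(C))
    if (length(best) == 1 && C[best] >= 50)
      c("residential", "working", "entertainment")[best]
    else "mixed"
  }
  set.seed(31)
  for (i in 1:2000) {
    F <- rexp(3) * rbinom(3, 1, 0.8)
    C <- category_share(F)
    expect_identical(unname(classify_cell(C)), oracle(C))
  }
})

test_that("labels are invariant to rescaling all counts and totals", {
  set.seed(12)
  counts <- matrix(rpois(60, 15), 20, 3,
                   dimnames = list(1:20, c("Residential community",
                                           "Private company", "Hotel")))
  totals <- colSums(counts)
  base <- classify_cells(counts, national_totals = totals)
  scaled <- classify_cells(counts * 7, national_totals = totals * 7)
  expect_identical(base$label, scaled$label)
})

test_that("increasing the winning type's count never changes the label away", {
  tax <- default_taxonomy()
  set.seed(14)
  for (rep in 1:50) {
    counts <- matrix(rpois(13, 30), 1, 13,
                     dimnames = list(1, unlist(tax, use.names = FALSE)))
    totals <- colSums(counts) + rpois(13, 2000)
    res <- classify_cells(counts, national_totals = totals)
    lab <- res$label
    if (!lab %in% names(tax)) next
    counts2 <- counts
    counts2[1, tax[[lab]][1]] <- counts2[1, tax[[lab]][1]] + 50
    res2 <- classify_cells(counts2, national_totals = totals)
    expect_identical(res2$label, lab)
  }
})

test_that("cells with no three-class POIs split into other vs non-activity", {
  counts <- matrix(0, 2, 3,
                   dimnames = list(1:2, c("Residential community", "Hotel",
                                          "Other")))
  counts[1, "Other"] <- 12   # other-function land: POIs, none classified
  res <- classify_cells(counts, national_totals = c(
    "Residential community" = 100, "Hotel" = 100, "Other" = 100))
  expect_equal(res$label, c("other", "non_human_activity"))
})

test_that("sector classification reuses the dominance machinery", {
  subs <- default_taxonomy()$working
  counts <- matrix(0, 1, 6, dimnames = list(1, subs))
  counts[1, "Government institution"] <- 40
  totals <- setNames(rep(1000, 6), subs)
  expect_equal(classify_sector("working", counts, totals),
               "Government institution")
  # equal normalized sub-frequencies: no dominance
  counts2 <- matrix(10, 1, 6, dimnames = list(1, subs))
  expect_equal(classify_sector("working", counts2, totals), "mixed_sector")
  expect_error(classify_sector("residential", counts, totals),
               "working/entertainment")

  # agreement with the k-type classify_cell machinery on random inputs
  set.seed(8)
  for (i in 1:200) {
    cc <- matrix(rpois(6, 12), 1, 6, dimnames = list(1, subs))
    tt <- setNames(rpois(6, 800) + 1, subs)
    got <- classify_sector("working", cc, tt)
    F <- cc[1, ] / tt
    C <- category_share(F)
    want <- classify_cell(C, classes = subs)
    if (want == "mixed") want <- "mixed_sector"
    expect_identical(got, want)
  }
})

test_that("near-even compositions are labelled mixed almost always", {
  # cells drawing equal thirds of normalized-frequency mass, 10,000 POIs each;
  # with the matching national totals, every class share concentrates near
  # 33%, so no share reaches 50% in at least 99% of cells
  tax <- default_taxonomy()
  cats <- unlist(tax, use.names = FALSE)
  k <- lengths(tax)
  W <- reference_category_weights()[cats]
  mix <- (1 / 3) * (1 / k[rep(seq_along(tax), k)]) * W
  mix <- mix / sum(mix)
  set.seed(1)
  counts <- t(vapply(1:1000, function(i) rmultinom(1, 10000, mix)[, 1],
                     numeric(13)))
  colnames(counts) <- cats
  res <- classify_cells(counts, national_totals = setNames(mix * 1e7, cats))
  shares <- as.matrix(res[, c("C_residential", "C_working", "C_entertainment")])
  expect_gte(mean(apply(shares, 1, max) < 50), 0.99)
  expect_gte(mean(res$label == "mixed"), 0.99)
})
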