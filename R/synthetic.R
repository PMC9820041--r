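#' POI categories of the synthetic study area
#'
#' The 13 first-level categories of the land-use taxonomy plus a residual
#' `"Other"` category (parks, transport, farmland...) used for cells planted
#' as other-function land. `reference_category_weights()` gives the
#' generator's canonical relative national abundance of each category
#' (catering and commercial POIs are numerous, legal-sector POIs rare);
#' normalized to sum 1.
#'
#' @return Character vector / named numeric vector.
#' @export
poi_categories <- function() c(unlist(default_taxonomy(), use.names = FALSE),
                               "Other")

#' @rdname poi_categories
#' @export
reference_category_weights <- function() {
  w <- c("Residential community" = 6, "Community service" = 4,
         "Private company" = 10, "Office building" = 5,
         "Financial sector" = 2, "Legal sector" = 0.8,
         "Government institution" = 2.5, "Education institution" = 3,
         "Commercial site" = 9, "Hotel" = 5, "Tourism" = 2,
         "Sport/gym" = 1.5, "Catering site" = 12, "Other" = 8)
  w / sum(w)
}

#' Configuration of a synthetic scenario
#'
#' Defines a fully synthetic study area with planted ground truth: a regular
#' grid of cells, each with a planted land-use label (and sector, where
#' applicable), POI compositions whose *normalized-frequency* mass
#' concentrates on the planted class, smooth attribute fields, planted
#' per-period change rates linked to designated attributes, and four days of
#' half-hourly intensity whose window sums realise the planted rates up to
#' noise.
#'
#' @param n_rows,n_cols Grid dimensions; default 25 x 40 (1,000 cells).
#' @param cell_size Cell side length; nominal 5 (km).
#' @param seed Master integer seed. Each generation stage uses an
#'   independent RNG stream seeded `seed + fixed offset` (labels +1, POIs +2,
#'   attributes +3, intensity +4) so stages are independently reproducible.
#' @param pois_per_cell Expected POIs per cell (Poisson); must be > 0.
#' @param dominance Fraction of a pure cell's normalized-frequency mass
#'   placed on its planted class (0.5-1]; default 0.75.
#' @param sector_dominance Within-class F-mass fraction on the planted
#'   sector of a working/entertainment cell; default 0.7.
#' @param label_probs Named probabilities of the planted labels
#'   (`residential`, `working`, `entertainment`, `mixed`, `other`); the mix
#'   echoes a working-dominated study area.
#' @param composition_profiles Optional override: named list
#'   `label -> named count-space category mixture` (weights summing to 1 over
#'   known categories). `NULL` derives mixtures from `dominance` and the
#'   reference category weights.
#' @param effect_spec Named list `period1..period3`, each
#'   `list(intercept =, effects = c(attribute = slope))`: the planted change
#'   rate (percent) is `intercept + sum(slope * zscore(attribute))`. The
#'   defaults put the signal on GDP and junction density, with per-period
#'   intercepts of -28, -12 and -9 percent.
#' @param rate_noise_sd SD (percent) of cell-level noise added to the
#'   planted rate on top of the attribute link; 0 makes the link exact.
#' @param noise_sd SD (fractional, e.g. 0.05 = 5 percentage points) of the
#'   noise applied to the window scaling factor when intensities are
#'   generated, so `realized - planted` change rates (as fractions) have SD
#'   `noise_sd`. Applied to the factor, not per bin, so planted rates are
#'   exactly invertible at `noise_sd = 0`.
#' @param city_block Side length, in cells, of the square "city" blocks used
#'   to broadcast a city-level cumulative case count to member cells.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_rows = 25, n_cols = 40, cell_size = 5,
                            seed = 1, pois_per_cell = 120,
                            dominance = 0.75, sector_dominance = 0.7,
                            label_probs = c(residential = 0.15,
                                            working = 0.52, entertainment = 0.11,
                                            mixed = 0.17, other = 0.05),
                            composition_profiles = NULL,
                            effect_spec = default_effect_spec(),
                            rate_noise_sd = 3, noise_sd = 0.05,
                            city_block = 5) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, seed = as.integer(seed),
              pois_per_cell = pois_per_cell, dominance = dominance,
              sector_dominance = sector_dominance,
              label_probs = label_probs,
              composition_profiles = composition_profiles,
              effect_spec = effect_spec, rate_noise_sd = rate_noise_sd,
              noise_sd = noise_sd, city_block = as.integer(city_block))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) stop("grid must be at least 1 x 1")
  if (cfg$pois_per_cell <= 0) stop("zero total POIs requested")
  if (cfg$noise_sd < 0 || cfg$rate_noise_sd < 0) stop("noise SDs must be >= 0")
  if (cfg$dominance <= 0 || cfg$dominance > 1)
    stop("dominance must be in (0, 1]")
  lp <- cfg$label_probs
  if (abs(sum(lp) - 1) > 1e-8 || any(lp < 0))
    stop("label_probs must be nonnegative and sum to 1")
  bad <- setdiff(names(lp),
                 c("residential", "working", "entertainment", "mixed", "other"))
  if (length(bad)) stop("unknown planted labels: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$composition_profiles)) {
    for (nm in names(cfg$composition_profiles)) {
      p <- cfg$composition_profiles[[nm]]
      unk <- setdiff(names(p), poi_categories())
      if (length(unk))
        stop("profile '", nm, "' references unknown categories: ",
             paste(unk, collapse = ", "))
      if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
        stop("profile '", nm, "' weights must be nonnegative and sum to 1")
    }
  }
  for (pp in c("period1", "period2", "period3")) {
    es <- cfg$effect_spec[[pp]]
    if (is.null(es) || is.null(es$intercept))
      stop("effect_spec must define intercept for ", pp)
    if (es$intercept <= -100)
      stop("planted mean rate <= -100% would force negative intensities")
  }
  invisible(cfg)
}

#' Default attribute-to-change-rate link of the synthetic scenario
#'
#' Planted rates depend on GDP (strongest) and road junction density, with
#' per-period intercepts at lockdown / first work resuming / total work
#' resuming magnitudes. Slopes are percent per standard deviation of the
#' attribute.
#'
#' @return Named list over `period1..period3`.
#' @export
default_effect_spec <- function() {
  list(period1 = list(intercept = -28, effects = c(gdp = -7, junction_density = -3.5)),
       period2 = list(intercept = -12, effects = c(gdp = -4, junction_density = -2)),
       period3 = list(intercept = -9, effects = c(gdp = -3, junction_density = -2)))
}

scenario_grid <- function(config) {
  grid_def(config$n_rows, config$n_cols, config$cell_size)
}

#' Plant per-cell land-use labels and sectors
#'
#' Draws each cell's planted label from `label_probs`; working and
#' entertainment cells additionally get a planted sector drawn uniformly
#' from their class's sub-categories. Uses the `seed + 1` RNG stream.
#'
#' @param config A [scenario_config()].
#' @return Ground-truth data frame: `cell_id`, `label`, `sector` (`NA` where
#'   not applicable).
#' @export
generate_labels <- function(config) {
  grid <- scenario_grid(config)
  tax <- default_taxonomy()
  with_seed(config$seed + 1L, {
    lab <- sample(names(config$label_probs), grid$n_cells, replace = TRUE,
                  prob = config$label_probs)
    sector <- rep(NA_character_, grid$n_cells)
    for (cl in c("working", "entertainment")) {
      idx <- which(lab == cl)
      if (length(idx))
        sector[idx] <- sample(tax[[cl]], length(idx), replace = TRUE)
    }
    data.frame(cell_id = cell_ids(grid), label = lab, sector = sector,
               stringsAsFactors = FALSE)
  })
}

# Calibrated per-label POI compositions. The planted dominance is stated in
# normalized-frequency (F) space: a pure cell must hold `dominance` of its
# F mass on its own class, a mixed cell even thirds. Because the classifier
# normalizes by the totals the cells themselves produce, count mixtures alone
# cannot hit those targets -- but the per-cell F mass of class c reduces to
# t_l * share_lc, where t_l scales with the label's expected POI count, and
# the only coupling is the per-class balance sum_l q_l share_lc = k_c
# (q_l = t_l * label frequency, k_c = categories in class c). Solving that
# balance exactly is possible once the off-diagonal (non-dominant) shares are
# allowed to lean towards the larger classes: the dominant share stays at
# exactly `dominance`, the foreign remainder is split by an iterative
# proportional fitting of the 3x3 zero-diagonal transportation problem, and
# per-label expected POI totals carry the q_l scales. Within a class, every
# category carries equal F mass (equal evidence), and category abundances are
# spread by the square root of the reference weights -- enough contrast to
# keep rare categories rare without starving their counts into noise.
scenario_composition <- function(config) {
  tax <- default_taxonomy()
  k <- lengths(tax)
  K <- sum(k)
  d <- config$dominance
  labs <- c("residential", "working", "entertainment", "mixed")
  cats3 <- unlist(tax, use.names = FALSE)
  cls <- rep(seq_along(tax), times = k)
  ut <- 1 / k[cls]
  W <- reference_category_weights()
  B <- sqrt(W[cats3] / max(W))
  p <- config$label_probs[labs]
  p[is.na(p)] <- 0
  names(p) <- labs
  g0 <- (1 - d) / 2 * (1 - diag(3)) + diag(d, 3)
  g0 <- rbind(g0, rep(1, 3) / 3)
  dimnames(g0) <- list(labs, names(tax))

  share <- g0
  t_l <- stats::setNames(rep(1, 4), labs)
  if (all(p > 0) && d < 1) {
    q_mix <- 1
    S <- K - q_mix
    q_pure <- (k * (1 - (1 - d) * S / K) - q_mix / 3) / d
    f <- (1 - d) * S * k / K
    if (all(q_pure > 0) && all(f <= (1 - d) * (sum(q_pure) - q_pure) + 1e-9)) {
      A <- matrix(1, 3, 3)
      diag(A) <- 0
      for (it in seq_len(200)) {
        A <- A * ((1 - d) * q_pure / rowSums(A))
        A <- t(t(A) * (f / colSums(A)))
      }
      share <- rbind(diag(d, 3) + A / q_pure, rep(1, 3) / 3)
      dimnames(share) <- dimnames(g0)
      t_l <- stats::setNames(c(q_pure, q_mix) / p, labs)
    }
  }
  ncount <- vapply(labs, function(l) t_l[[l]] * share[l, cls] * ut * B,
                   numeric(length(cats3)))
  # normalize so the p-weighted mean cell holds pois_per_cell POIs
  pm <- if (sum(p) > 0) sum(p / sum(p) * colSums(ncount)) else mean(colSums(ncount))
  ncount <- ncount * config$pois_per_cell / pm
  rownames(ncount) <- cats3
  list(share = share, ncount = ncount)
}

# Expected per-category counts for one cell. The sector boost reweights the
# own-class F mass towards the planted sector (fraction sector_dominance),
# which leaves the class-level F masses unchanged in expectation because
# sectors are drawn uniformly.
cell_expected_counts <- function(label, sector, config, comp) {
  cats <- poi_categories()
  mu <- stats::setNames(numeric(length(cats)), cats)
  if (!is.null(config$composition_profiles) &&
      label %in% names(config$composition_profiles)) {
    pr <- config$composition_profiles[[label]]
    mu[names(pr)] <- pr * config$pois_per_cell
    return(mu)
  }
  if (label == "other") {
    mu["Other"] <- config$pois_per_cell
    return(mu)
  }
  base <- comp$ncount[, label]
  mu[names(base)] <- base
  tax <- default_taxonomy()
  if (!is.na(sector) && label %in% c("working", "entertainment") &&
      sector %in% tax[[label]]) {
    own <- tax[[label]]
    kk <- length(own)
    w <- rep((1 - config$sector_dominance) / (kk - 1), kk)
    names(w) <- own
    w[sector] <- config$sector_dominance
    mu[own] <- mu[own] * kk * w   # F-space reweight; uniform base weight 1/kk
  }
  mu
}

#' Generate synthetic POIs with planted land-use composition
#'
#' Each cell receives a Poisson number of POIs whose categories follow the
#' cell's planted composition over the 13 first-level categories (plus
#' `"Other"`); positions are uniform within the cell. Expected totals differ
#' by label (they carry part of the dominance calibration) and average
#' `pois_per_cell` across cells. Uses the `seed + 2` RNG stream.
#'
#' @param config A [scenario_config()].
#' @param truth Ground truth from [generate_labels()]; generated if `NULL`.
#' @return List with `pois` (data frame `id`, `x`, `y`, `category`) and
#'   `truth`.
#' @export
generate_pois <- function(config, truth = NULL) {
  validate_scenario_config(config)
  grid <- scenario_grid(config)
  if (is.null(truth)) truth <- generate_labels(config)
  cents <- cell_centroids(grid)
  cats <- poi_categories()
  comp <- scenario_composition(config)
  with_seed(config$seed + 2L, {
    cells <- vector("list", grid$n_cells)
    for (i in seq_len(grid$n_cells)) {
      mu <- cell_expected_counts(truth$label[i], truth$sector[i], config, comp)
      m <- stats::rpois(1L, sum(mu))
      if (!m) next
      cells[[i]] <- list(
        cell = i,
        cat = sample.int(length(cats), m, replace = TRUE, prob = mu[cats]))
    }
    cells <- cells[!vapply(cells, is.null, TRUE)]
    cell_of <- unlist(lapply(cells, function(z) rep(z$cell, length(z$cat))))
    cat_idx <- unlist(lapply(cells, function(z) z$cat))
    n_tot <- length(cat_idx)
    half <- grid$cell_size / 2
    x <- cents$x[cell_of] + stats::runif(n_tot, -half, half)
    y <- cents$y[cell_of] + stats::runif(n_tot, -half, half)
    list(pois = data.frame(id = seq_len(n_tot), x = x, y = y,
                           category = cats[cat_idx],
                           stringsAsFactors = FALSE),
         truth = truth)
  })
}

smooth_field <- function(cents, n_bumps, scale, rng_ready = TRUE) {
  # random sum of broad Gaussian bumps -> spatially smooth surface in [~0, n]
  xr <- range(cents$x); yr <- range(cents$y)
  f <- numeric(nrow(cents))
  for (k in seq_len(n_bumps)) {
    cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
    s <- scale * stats::runif(1, 0.5, 1.5)
    a <- stats::runif(1, 0.5, 1.5)
    f <- f + a * exp(-((cents$x - cx)^2 + (cents$y - cy)^2) / (2 * s^2))
  }
  f
}

#' Generate grid-cell attributes and planted change rates
#'
#' Produces the eight per-cell attributes (GDP, population density,
#' urban/rural flag, administrative level, built-up area, bus stop density,
#' road junction density, cumulative confirmed cases) as spatially smooth
#' fields, plus the planted per-period change rates as the monotone (linear
#' in z-scores) function of the active attributes declared in
#' `config$effect_spec`, with optional cell-level noise (`rate_noise_sd`).
#' Cumulative cases are a city-level value broadcast to all member cells;
#' cities are square blocks of `city_block` x `city_block` cells. Uses the
#' `seed + 3` RNG stream.
#'
#' @param config A [scenario_config()].
#' @param truth Ground truth (labels); generated if `NULL`.
#' @return List with `attributes` (data frame, `cell_id` + 8 attribute
#'   columns), and `truth` extended with planted `period1..period3` rates
#'   (percent, floored at -95 so intensities stay realisable).
#' @export
generate_attributes <- function(config, truth = NULL) {
  validate_scenario_config(config)
  grid <- scenario_grid(config)
  if (is.null(truth)) truth <- generate_labels(config)
  cents <- cell_centroids(grid)
  with_seed(config$seed + 3L, {
    span <- max(diff(range(cents$x)), diff(range(cents$y)), grid$cell_size)
    zs <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    f1 <- smooth_field(cents, 6, span / 4)   # development gradient
    f2 <- smooth_field(cents, 6, span / 4)   # second independent gradient
    f3 <- smooth_field(cents, 8, span / 5)   # road-network gradient
    f4 <- smooth_field(cents, 8, span / 5)   # transit-service gradient
    gdp <- 50 * exp(1.2 * zs(f1))                    # currency/cell
    population <- 2000 * exp(1.0 * zs(0.8 * f1 + 0.4 * f2))  # persons
    built <- pmin(grid$cell_size^2,
                  grid$cell_size^2 * 0.6 *
                    stats::plogis(zs(f1) + 0.3 * stats::rnorm(grid$n_cells)))
    bus <- 3 * exp(0.8 * zs(0.7 * f4 + 0.3 * f1)) / grid$cell_size^2
    junction <- 8 * exp(0.8 * zs(f3)) / grid$cell_size^2
    urban <- as.integer(population > stats::quantile(population, 0.7))
    admin <- as.integer(cut(gdp, stats::quantile(gdp, c(0, .4, .7, .9, 1)),
                            include.lowest = TRUE, labels = FALSE))
    # city blocks for case broadcasting
    block_row <- (cents$row - 1L) %/% config$city_block
    block_col <- (cents$col - 1L) %/% config$city_block
    city <- block_row * (max(block_col) + 1L) + block_col + 1L
    city_pop <- tapply(population, city, sum)
    city_cases <- round(city_pop / mean(city_pop) *
                        stats::rlnorm(length(city_pop), log(200), 0.8))
    cases <- as.numeric(city_cases[as.character(city)])

    attributes <- data.frame(
      cell_id = cents$cell_id, gdp = gdp, population = population,
      urban_rural = urban, admin_level = admin, built_up_area = built,
      bus_stop_density = bus, junction_density = junction,
      cumulative_cases = cases)

    for (pp in c("period1", "period2", "period3")) {
      es <- config$effect_spec[[pp]]
      rate <- rep(es$intercept, grid$n_cells)
      for (a in names(es$effects)) {
        if (!a %in% names(attributes))
          stop("effect_spec references unknown attribute: ", a)
        rate <- rate + es$effects[[a]] * zs(attributes[[a]])
      }
      if (config$rate_noise_sd > 0)
        rate <- rate + stats::rnorm(grid$n_cells, 0, config$rate_noise_sd)
      truth[[pp]] <- pmax(rate, -95)
    }
    list(attributes = attributes, truth = truth)
  })
}

#' Default diurnal baseline shape (48 half-hour bins)
#'
#' A smooth two-peak curve (morning and evening peaks over a nonzero floor),
#' normalized to mean 1. Only window sums matter downstream, so the exact
#' shape is a free choice; it is exposed so scenarios can override it.
#'
#' @return Numeric vector of 48 positive weights.
#' @export
diurnal_shape <- function() {
  h <- (0:47) / 2 + 0.25  # bin centres in hours
  s <- 0.25 + exp(-(h - 8.75)^2 / (2 * 1.5^2)) +
       0.9 * exp(-(h - 19)^2 / (2 * 2.5^2))
  s / mean(s)
}

#' Generate four days of half-hourly intensity realising the planted rates
#'
#' Day 1 is a per-cell baseline diurnal curve (amplitude lognormal across
#' cells). Days 2-4 equal day 1 scaled *inside the cell's land-use window* by
#' `1 + rate/100 + noise`, with noise `N(0, noise_sd)` applied to the scaling
#' factor (not per bin), so the realised window-sum change rates equal the
#' planted rates exactly at `noise_sd = 0`. Bins outside the window are
#' scaled by a damped factor (60% of the planted rate) so that using the
#' wrong window is detectable. Cells labelled `other` are scaled over the
#' whole day. Uses the `seed + 4` RNG stream.
#'
#' @param config A [scenario_config()].
#' @param truth Ground truth carrying planted `period1..period3` for every
#'   cell (from [generate_attributes()]).
#' @param shape Baseline diurnal shape, 48 positive values.
#' @return Long data frame: `cell_id`, `day` (`day1..day4`),
#'   `bin_0..bin_47` (nonnegative, real-valued intensities).
#' @export
generate_intensity <- function(config, truth,
                               shape = diurnal_shape()) {
  validate_scenario_config(config)
  grid <- scenario_grid(config)
  periods <- c("period1", "period2", "period3")
  if (!all(periods %in% names(truth)))
    stop("truth must contain planted change rates for all cells")
  if (any(truth[periods] < -100))
    stop("planted rate < -100% would force negative intensities")
  stopifnot(length(shape) == 48L, all(shape > 0))
  policy <- default_window_policy()
  with_seed(config$seed + 4L, {
    amp <- stats::rlnorm(grid$n_cells, log(500), 0.5)
    base <- outer(amp, shape)  # cells x 48
    rows <- vector("list", 4L)
    day_mat <- base
    rows[[1]] <- data.frame(cell_id = truth$cell_id, day = "day1", day_mat)
    for (k in 1:3) {
      rate <- truth[[periods[k]]]
      eta <- if (config$noise_sd > 0)
        stats::rnorm(grid$n_cells, 0, config$noise_sd) else 0
      fac_in <- 1 + rate / 100 + eta
      if (any(fac_in < 0)) {
        warning(sum(fac_in < 0), " window factors clamped at 0")
        fac_in <- pmax(fac_in, 0)
      }
      fac_out <- pmax(1 + 0.6 * rate / 100, 0)
      day_mat <- base
      for (i in seq_len(grid$n_cells)) {
        lab <- truth$label[i]
        inb <- if (lab %in% names(policy)) window_bins(policy[[lab]])
               else seq_len(48L)
        day_mat[i, inb] <- base[i, inb] * fac_in[i]
        outb <- setdiff(seq_len(48L), inb)
        if (length(outb)) day_mat[i, outb] <- base[i, outb] * fac_out[i]
      }
      rows[[k + 1]] <- data.frame(cell_id = truth$cell_id,
                                  day = paste0("day", k + 1), day_mat)
    }
    out <- do.call(rbind, rows)
    names(out) <- c("cell_id", "day", paste0("bin_", 0:47))
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs all generation stages in order (labels, POIs, attributes + planted
#' rates, intensity) and returns everything a pipeline run consumes,
#' together with the ground truth. Regenerating with the same config is
#' bit-identical.
#'
#' @param config A [scenario_config()].
#' @return List: `config`, `grid`, `truth`, `pois`, `attributes`,
#'   `intensity`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  validate_scenario_config(config)
  grid <- scenario_grid(config)
  truth <- generate_labels(config)
  po <- generate_pois(config, truth)
  at <- generate_attributes(config, truth)
  intensity <- generate_intensity(config, at$truth)
  list(config = config, grid = grid, truth = at$truth, pois = po$pois,
       attributes = at$attributes, intensity = intensity)
}
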