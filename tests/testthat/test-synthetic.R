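test_that("scenario generation is bit-identical under a fixed seed", {
  a <- generate_scenario(tiny_config(seed = 10))
  b <- generate_scenario(tiny_config(seed = 10))
  expect_identical(a$pois, b$pois)
  expect_identical(a$attributes, b$attributes)
  expect_identical(a$intensity, b$intensity)
  c <- generate_scenario(tiny_config(seed = 11))
  expect_false(identical(a$pois, c$pois))
})

test_that("generation stages are independently reproducible", {
  cfg <- tiny_config(seed = 5)
  full <- generate_scenario(cfg)
  # calling a stage in isolation gives the same draw as inside the pipeline
  expect_identical(generate_labels(cfg), full$truth[, c("cell_id", "label", "sector")])
  expect_identical(generate_pois(cfg)$pois, full$pois)
})

test_that("a fully dominant profile draws only its own categories", {
  cfg <- tiny_config(seed = 3, dominance = 1,
                     label_probs = c(residential = 1, working = 0,
                                     entertainment = 0, mixed = 0, other = 0))
  po <- generate_pois(cfg)
  expect_true(all(po$pois$category %in%
                  c("Residential community", "Community service")))
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(pois_per_cell = 0), "zero total POIs")
  expect_error(scenario_config(composition_profiles = list(
    residential = c("Moon base" = 1))), "unknown categories")
  expect_error(scenario_config(composition_profiles = list(
    residential = c("Hotel" = 0.7))), "sum to 1")
  expect_error(scenario_config(label_probs = c(residential = 1, farm = 0)),
               "unknown planted labels")
  expect_error(scenario_config(effect_spec = list(
    period1 = list(intercept = -150, effects = c(gdp = 0)),
    period2 = list(intercept = 0, effects = c(gdp = 0)),
    period3 = list(intercept = 0, effects = c(gdp = 0)))), "-100")
})

test_that("explicit composition profiles drive the category draw", {
  cfg <- tiny_config(seed = 6, composition_profiles = list(
    working = c("Government institution" = 0.5, "Hotel" = 0.5)),
    label_probs = c(residential = 0, working = 1, entertainment = 0,
                    mixed = 0, other = 0))
  po <- generate_pois(cfg)
  expect_setequal(unique(po$pois$category),
                  c("Government institution", "Hotel"))
})

test_that("attributes have the declared types and ranges", {
  at <- generate_attributes(tiny_config(seed = 4))
  a <- at$attributes
  expect_setequal(names(a), c("cell_id", "gdp", "population", "urban_rural",
                              "admin_level", "built_up_area",
                              "bus_stop_density", "junction_density",
                              "cumulative_cases"))
  cont <- c("gdp", "population", "built_up_area", "bus_stop_density",
            "junction_density", "cumulative_cases")
  for (v in cont) expect_true(all(a[[v]] >= 0), info = v)
  expect_true(all(a$urban_rural %in% c(0L, 1L)))
  expect_true(all(a$admin_level %in% 1:4))
  # cases are broadcast per city block: few distinct values
  expect_lt(length(unique(a$cumulative_cases)), nrow(a) / 2)
})

test_that("planted rates track the designated attribute monotonically", {
  es <- list(period1 = list(intercept = -25, effects = c(gdp = -8)),
             period2 = list(intercept = -10, effects = c(gdp = -4)),
             period3 = list(intercept = -8, effects = c(gdp = -3)))
  at <- generate_attributes(tiny_config(seed = 8, effect_spec = es,
                                        rate_noise_sd = 0))
  rho <- cor(at$attributes$gdp, at$truth$period1, method = "spearman")
  expect_gte(abs(rho), 0.9)
  expect_equal(sign(rho), -1)  # higher GDP, stronger reduction

  # all effects zero and no noise: constant planted rates
  es0 <- list(period1 = list(intercept = -20, effects = c(gdp = 0)),
              period2 = list(intercept = -5, effects = c(gdp = 0)),
              period3 = list(intercept = -2, effects = c(gdp = 0)))
  at0 <- generate_attributes(tiny_config(seed = 8, effect_spec = es0,
                                         rate_noise_sd = 0))
  expect_equal(unique(at0$truth$period1), -20)
  expect_equal(unique(at0$truth$period3), -2)
})

test_that("intensity noise lands on the scaling factor at the stated SD", {
  cfg <- recovery_config(seed = 7, noise_sd = 0.05)
  at <- generate_attributes(cfg)
  intensity <- generate_intensity(cfg, at$truth)
  ch <- compute_changes(intensity, at$truth[, c("cell_id", "label")])
  m <- merge(ch, at$truth, by = "cell_id", suffixes = c("_got", "_want"))
  resid <- (m$period1_got - m$period1_want) / 100
  expect_gt(sd(resid, na.rm = TRUE), 0.05 * 0.8)
  expect_lt(sd(resid, na.rm = TRUE), 0.05 * 1.2)
})

test_that("intensities refuse planted rates at or below -100%", {
  cfg <- tiny_config(seed = 2)
  at <- generate_attributes(cfg)
  tr <- at$truth
  tr$period2[3] <- -120
  expect_error(generate_intensity(cfg, tr), "-100")
})

test_that("POI and intensity tables have the declared shapes", {
  scn <- generate_scenario(tiny_config(seed = 9))
  expect_setequal(names(scn$pois), c("id", "x", "y", "category"))
  expect_true(all(scn$pois$category %in% poi_categories()))
  expect_equal(nrow(scn$intensity), 4 * scn$grid$n_cells)
  bins <- as.matrix(scn$intensity[, paste0("bin_", 0:47)])
  expect_true(all(bins >= 0))
  expect_setequal(unique(scn$intensity$day), paste0("day", 1:4))
})
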