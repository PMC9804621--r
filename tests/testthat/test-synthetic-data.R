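test_that("generated climate is reproducible and respects degenerate settings", {
  cfg <- synthetic_config(n_cells_x = 8, n_cells_y = 8, n_routes = 20, seed = 42)
  c1 <- generate_climate(cfg, "temperature")
  c2 <- generate_climate(cfg, "temperature")
  expect_identical(c1$values, c2$values)

  # no anomalies, no residual: every year equals the spatial gradient
  cfg0 <- synthetic_config(n_cells_x = 8, n_cells_y = 8, n_routes = 20,
                           annual_anomaly_sd = list(temperature = 0, precipitation = 0),
                           residual_sd = list(temperature = 0, precipitation = 0),
                           seed = 42)
  c0 <- generate_climate(cfg0, "temperature")
  expect_lt(max(abs(c0$values - c0$values[, 1])), 1e-12)
  d0 <- decompose_climate(c0, cfg0$study_years)
  expect_lt(max(abs(d0$temporal)), 1e-10)
  expect_lt(max(abs(d0$residual)), 1e-10)

  # residual_sd = 0 alone: decomposition returns residual == 0
  cfgr <- synthetic_config(n_cells_x = 8, n_cells_y = 8, n_routes = 20,
                           residual_sd = list(temperature = 0, precipitation = 0),
                           seed = 42)
  dr <- decompose_climate(generate_climate(cfgr, "temperature"), cfgr$study_years)
  expect_lt(max(abs(dr$residual)), 1e-10)

  # precipitation truncated at zero
  cfgp <- synthetic_config(n_cells_x = 8, n_cells_y = 8, n_routes = 20,
                           base_level = list(temperature = 10, precipitation = 5),
                           seed = 1)
  expect_true(all(generate_climate(cfgp, "precipitation")$values >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(study_years = c(1960, 2018)), "within")
  expect_error(synthetic_config(country_shares = c(0.5, 0.5, 0.5)), "summing")
  expect_error(synthetic_config(n_cells_x = 3, n_cells_y = 3, n_routes = 100),
               "exceeds")
  expect_error(
    synthetic_config(residual_sd = list(temperature = -1, precipitation = 1)),
    ">= 0")
})

test_that("route panels respect scheme start years and paired surveys", {
  cfg <- synthetic_config(n_cells_x = 12, n_cells_y = 12, n_routes = 60,
                          study_years = c(1996, 2018),
                          scheme_start_year = c(A = 2006, B = 1996, C = 2006),
                          seed = 9)
  r1 <- generate_routes(cfg)
  r2 <- generate_routes(cfg)
  expect_identical(r1, r2)

  expect_gte(min(r1$year), 1996)
  expect_gte(min(r1$year[r1$country == "A"]), 2006)
  expect_gte(min(r1$year[r1$country == "C"]), 2006)
  expect_lt(min(r1$year[r1$country == "B"]), 2006)

  # country A: two survey rows (Point + Line) sharing route id and cell
  a <- unique(r1[r1$country == "A", c("route_id", "survey_id", "cell_id", "survey")])
  per_route <- split(a, a$route_id)
  for (rt in per_route) {
    expect_setequal(rt$survey, c("Point", "Line"))
    expect_equal(length(unique(rt$cell_id)), 1L)
  }
  expect_true(all(r1$survey[r1$country != "A"] == "Line"))
  expect_true(all(r1$unit[r1$country == "B"] == "Individual"))

  # routes sit on distinct cells
  expect_false(anyDuplicated(unique(r1[c("route_id", "cell_id")])$cell_id) > 0)
})

test_that("count generation matches family moments and degenerate cases", {
  st <- small_study(31, family = "poisson", sigma_u = 0,
                    beta_count = c("(Intercept)" = log(2), temp_spatial = 0,
                                   prec_spatial = 0, temp_temporal = 0,
                                   prec_temporal = 0, temp_residual = 0,
                                   prec_residual = 0, txp_spatial = 0,
                                   txp_temporal = 0, txp_residual = 0,
                                   year_lin = 0, year_quad = 0, unitPair = 0,
                                   slope = 0))
  # all beta zero except intercept: E[count] = effort * exp(b0)
  expect_lt(abs(mean(st$counts$count / st$counts$effort) - 2), 0.1)

  # zinb with pi = 1: all counts zero
  stz <- small_study(32, family = "zinb",
                     gamma_zi = c("(Intercept)" = 30))
  expect_true(all(stz$counts$count == 0))

  # NB2 variance identity at theta = 1, mean 5: var = mean + mean^2 = 30
  set.seed(77)
  y <- rnbinom(10000, size = 1, mu = 5)
  expect_lt(abs(mean(y) - 5), 3 * sqrt(30 / 10000))
  expect_lt(abs(var(y) - 30), 3)

  # full-path NB moments via the generator (intercept-only species)
  stnb <- small_study(33, family = "nb", sigma_u = 0, theta = 1,
                      n_routes = 120, n_cells = 12,
                      study_years = c(2004, 2018),
                      beta_count = c("(Intercept)" = log(5), temp_spatial = 0,
                                     prec_spatial = 0, temp_temporal = 0,
                                     prec_temporal = 0, temp_residual = 0,
                                     prec_residual = 0, txp_spatial = 0,
                                     txp_temporal = 0, txp_residual = 0,
                                     year_lin = 0, year_quad = 0, unitPair = 0,
                                     slope = 0))
  cnt <- stnb$counts
  w <- cnt$effort == 8   # fix one effort level so mu is constant = 40
  mu <- 8 * 5
  expect_gt(sum(w), 150)
  expect_lt(abs(mean(cnt$count[w]) - mu), 3 * sqrt((mu + mu^2) / sum(w)))

  # reproducibility of the whole path
  st_a <- small_study(34)$counts
  st_b <- small_study(34)$counts
  expect_identical(st_a$count, st_b$count)
})

test_that("count generation demands a coefficient for every design column", {
  st <- small_study(35)
  bad <- st$pars
  bad$beta_count <- bad$beta_count[names(bad$beta_count) != "slope"]
  expect_error(
    generate_counts(st$counts, st$dt, st$dp, bad, seed = 1),
    "slope")
})
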