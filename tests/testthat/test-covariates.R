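test_that("land-cover pooling maps classes to the seven categories", {
  tab <- landcover_table()
  expect_equal(nrow(tab), 44L)
  expect_setequal(
    setdiff(unique(tab$pooled_category), "other_sea"),
    c("sparse_mountain", "mountain_vegetation", "deciduous_forest",
      "other_forest", "wetlands", "inland_waters", "agriculture"))

  # peat bogs -> wetlands; bare rocks -> sparse mountain; conifer -> other forest
  lookup <- function(name) tab$pooled_category[grepl(name, tab$class_name,
                                                     ignore.case = TRUE)]
  expect_equal(lookup("Peat bogs"), "wetlands")
  expect_equal(lookup("Bare rocks"), "sparse_mountain")
  expect_equal(lookup("Coniferous"), "other_forest")
  expect_equal(lookup("Broad-leaved"), "deciduous_forest")
  expect_equal(lookup("Moors"), "mountain_vegetation")

  m <- landcover_map(matrix(c(412, 332, 312, 211), 2, 2), epoch = 2006)
  pooled <- pool_landcover(m)
  expect_equal(pooled$codes[1, 1], "wetlands")
  expect_equal(pooled$codes[2, 2], "agriculture")

  expect_error(pool_landcover(landcover_map(matrix(999, 1, 1), 2012)), "999")
})

test_that("survey years match the land-cover epochs", {
  expect_equal(match_epoch(1998), 2000L)
  expect_equal(match_epoch(2003), 2000L)
  expect_equal(match_epoch(2004), 2006L)
  expect_equal(match_epoch(2011), 2012L)
  expect_equal(match_epoch(2016), 2018L)
  expect_equal(match_epoch(2018), 2018L)
  expect_equal(match_epoch(c(1996, 2009, 2015)), c(2000L, 2006L, 2012L))
  expect_error(match_epoch(1990), "outside")
})

test_that("buffer summaries match exhaustive cell enumeration", {
  # uniform numeric raster: mean is the constant
  r <- matrix(5.5, 10, 10)
  expect_equal(summarize_buffer(r, data.frame(x = 500, y = 500),
                                radius = 300, cell_size = 100), 5.5)

  # half A / half B around a point on the boundary
  codes <- matrix(311, 10, 10)
  codes[, 6:10] <- 412   # right half wetlands (columns = x)
  m <- pool_landcover(landcover_map(codes, 2012, cell_size = 100))
  pr <- summarize_buffer(m, data.frame(x = 500, y = 500), radius = 300)
  expect_equal(unname(pr["deciduous_forest"]), 0.5)
  expect_equal(unname(pr["wetlands"]), 0.5)
  expect_lte(sum(pr), 1)

  # oracle: explicit loop over all cells, center-in-circle membership
  set.seed(4)
  codes2 <- matrix(sample(c(311, 412, 512, 523), 100, replace = TRUE), 10, 10)
  m2 <- pool_landcover(landcover_map(codes2, 2012, cell_size = 100))
  geom <- data.frame(x = c(320, 660), y = c(410, 300))
  pr2 <- summarize_buffer(m2, geom, radius = 250)
  inside <- 0; n_dec <- 0
  for (i in 1:10) for (j in 1:10) {
    cx <- (j - 0.5) * 100; cy <- (i - 0.5) * 100
    memb <- any((cx - geom$x)^2 + (cy - geom$y)^2 <= 250^2)
    if (memb) {
      inside <- inside + 1
      if (codes2[i, j] == 311) n_dec <- n_dec + 1
    }
  }
  expect_equal(unname(pr2["deciduous_forest"]), n_dec / inside)
  expect_lte(sum(pr2), 1)  # sea cells dilute the seven categories

  expect_error(summarize_buffer(m2, data.frame(x = 1e6, y = 1e6), radius = 10),
               "intersect")
})

test_that("VIFs match the leave-one-out R-squared oracle", {
  set.seed(12)
  n <- 400
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X <- cbind(X, d = X[, "a"] * 0.6 + rnorm(n, 0, 0.8))
  rep <- compute_vif(X)

  # brute-force oracle via lm
  for (j in seq_len(ncol(X))) {
    o <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_lt(abs(rep$vif[j] - 1 / (1 - o)), 1e-10)
  }

  # mutually orthogonal (and intercept-orthogonal) columns: VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50, 3))))[, -1]
  expect_equal(compute_vif(Q)$vif, rep(1, 3), tolerance = 1e-10)

  # duplicated column: flagged non-finite, not a crash
  dup <- compute_vif(cbind(x = X[, 1], y = X[, 2], x2 = X[, 1]))
  expect_true(all(!is.finite(dup$vif[c(1, 3)])))
  expect_true(all(dup$flagged[c(1, 3)]))

  # noise tuned so R^2 = 0.75 gives VIF close to 4
  set.seed(99)
  x1 <- rnorm(5000)
  e <- rnorm(5000)
  e <- residuals(lm(e ~ x1))               # exactly orthogonal noise
  x2 <- x1 + e * sd(x1) / sd(e) / sqrt(3)  # var ratio 3:1 -> R^2 = 0.75
  v <- compute_vif(cbind(x1, x2))$vif[2]
  expect_lt(abs(v - 4), 0.01)
})

test_that("design assembly produces the documented columns and scalings", {
  st <- small_study(61, standardize = TRUE)
  md <- st$md
  expect_equal(md$offset, log(md$frame_raw$effort))
  for (col in c("temp_spatial", "prec_temporal", "slope")) {
    expect_lt(abs(mean(md$X[, col])), 1e-12)
    expect_lt(abs(sd(md$X[, col]) - 1), 1e-12)
  }
  expect_equal(md$X[, "txp_spatial"],
               md$X[, "temp_spatial"] * md$X[, "prec_spatial"],
               ignore_attr = TRUE)
  # zi design drops the survey-protocol contrasts only
  expect_setequal(setdiff(colnames(md$X), colnames(md$Xzi)),
                  intersect(c("surveyPoint", "unitPair"), colnames(md$X)))

  expect_error(assemble_design(transform(st$counts, effort = 0), st$dt, st$dp),
               "effort")
  broken <- st$counts; broken$slope[3] <- NA
  expect_error(assemble_design(broken, st$dt, st$dp),
               broken$route_id[3])
})

test_that("lagged designs read the previous year's anomalies", {
  st <- small_study(62)
  # centering reaches back before the study period, so nothing is dropped
  mdl <- assemble_design(st$counts, st$dt, st$dp, lag = 1L,
                         habitat = st$pars$habitat, standardize = FALSE)
  expect_equal(mdl$info$dropped, 0L)
  expect_true(min(st$counts$year) %in% mdl$frame_raw$year)
  # each row's temporal covariate equals last year's component value
  full_t <- decompose_climate(
    generate_climate(st$cfg, "temperature"), range(st$cfg$centering_years))
  for (i in c(1L, 10L, nrow(mdl$X))) {
    yr <- mdl$frame_raw$year[i]
    expect_equal(unname(mdl$X[i, "temp_temporal"]),
                 unname(full_t$temporal[as.character(yr - 1)]))
  }

  # decomposition starting at the study years: lag drops the first year
  cube <- random_cube(6, 5, 97)
  d <- decompose_climate(cube)
  routes <- data.frame(route_id = "r1", cell_id = cube$cells$cell_id[1],
                       survey = "Line", unit = "Pair", year = cube$years,
                       effort = 4, slope = 1)
  expect_message(
    md2 <- assemble_design(routes, d, d, lag = 1L, habitat = "slope"),
    "dropped")
  expect_false(min(cube$years) %in% md2$frame_raw$year)
})
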