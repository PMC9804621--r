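test_that("decomposition reproduces hand-worked toys", {
  # additively separable input: residual vanishes
  cube <- climate_cube(matrix(c(1, 5, 3, 7), 2, 2),
                       data.frame(cell_id = c("a", "b"), x = 1, y = 1:2),
                       years = 2000:2001)
  d <- decompose_climate(cube)
  expect_equal(d$global_mean, 4)
  expect_equal(unname(d$spatial), c(-2, 2))
  expect_equal(unname(d$temporal), c(-1, 1))
  expect_true(all(abs(d$residual) < 1e-12))

  # non-separable input
  cube2 <- climate_cube(matrix(c(1, 5, 3, 6), 2, 2),
                        data.frame(cell_id = c("a", "b"), x = 1, y = 1:2),
                        years = 2000:2001)
  d2 <- decompose_climate(cube2)
  expect_equal(d2$global_mean, 3.75)
  expect_equal(unname(d2$spatial), c(-1.75, 1.75))
  expect_equal(unname(d2$temporal), c(-0.75, 0.75))
  expect_equal(unname(d2$residual),
               matrix(c(-0.25, 0.25, 0.25, -0.25), 2, 2))
})

test_that("decomposition identities hold and match the brute-force oracle", {
  for (seed in 1:25) {
    n_cells <- sample(2:20, 1)
    n_years <- sample(3:10, 1)
    cube <- random_cube(n_cells, n_years, seed)
    sy <- c(cube$years[sample(seq_len(n_years - 1), 1)], max(cube$years))
    d <- decompose_climate(cube, sy)

    # identities
    expect_lt(abs(sum(d$spatial)), 1e-8 * n_cells)
    expect_true(all(abs(colMeans(d$residual)) < 1e-10))
    expect_lt(max(abs(reconstruct(d) - cube$values[, match(
      seq(sy[1], sy[2]), cube$years)])), 1e-10)

    # oracle equivalence
    o <- oracle_decompose(cube$values, cube$years, cube$centering_years, sy)
    expect_lt(abs(d$global_mean - o$global_mean), 1e-12)
    expect_lt(max(abs(unname(d$spatial) - o$spatial)), 1e-12)
    expect_lt(max(abs(unname(d$temporal) - o$temporal)), 1e-12)
    expect_lt(max(abs(unname(d$residual) - o$residual)), 1e-12)
  }
})

test_that("decompose is linear in its input", {
  c1 <- random_cube(12, 6, 101)
  c2 <- random_cube(12, 6, 102)
  a <- 2.5; b <- -1.25
  mix <- c1
  mix$values <- a * c1$values + b * c2$values
  d1 <- decompose_climate(c1); d2 <- decompose_climate(c2)
  dm <- decompose_climate(mix)
  expect_equal(dm$global_mean, a * d1$global_mean + b * d2$global_mean)
  expect_equal(dm$spatial, a * d1$spatial + b * d2$spatial)
  expect_equal(dm$temporal, a * d1$temporal + b * d2$temporal)
  expect_equal(dm$residual, a * d1$residual + b * d2$residual)
})

test_that("missing values inside the centering window are a hard error", {
  cube <- random_cube(6, 5, 7)
  cube$missing[2, 3] <- TRUE
  expect_error(decompose_climate(cube), "missing")
  expect_error(decompose_climate(list(a = 1)), "climate_cube")
})

test_that("lagged views shift the temporal and residual components", {
  cube <- random_cube(9, 8, 11)
  sy <- c(cube$years[3], max(cube$years))
  d <- decompose_climate(cube, sy)

  expect_identical(lag_components(d, 0L), d)

  dl <- lag_components(d, 1L)
  expect_equal(dl$spatial, d$spatial)
  years <- seq(sy[1], sy[2])
  full <- decompose_climate(cube, range(cube$years))
  for (t in years) {
    expect_equal(unname(dl$temporal[as.character(t)]),
                 unname(full$temporal[as.character(t - 1)]))
    expect_equal(unname(dl$residual[, as.character(t)]),
                 unname(full$residual[, as.character(t - 1)]))
  }

  # components starting at the first study year: first year flagged absent
  d_first <- decompose_climate(random_cube(4, 5, 3))  # study = all years
  dl2 <- lag_components(d_first, 1L)
  expect_equal(attr(dl2, "dropped_years"), 1L)
  expect_equal(as.integer(names(dl2$temporal)[1]), d_first$study_years[1] + 1L)
})

test_that("seasonal aggregation uses means for temperature, sums for precipitation", {
  daily <- expand.grid(cell_id = "c1", year = 2000:2001,
                       month = 1:12, day = 1:28, KEEP.OUT.ATTRS = FALSE)
  daily$x <- 1; daily$y <- 1
  daily$value <- 10
  cube <- seasonal_aggregate(daily, "may-jul", "mean")
  expect_equal(as.vector(cube$values), c(10, 10))

  daily$value <- 1
  cube2 <- seasonal_aggregate(daily, "may-jul", "sum")
  expect_equal(as.vector(cube2$values), c(84, 84))  # 3 months x 28 records

  # july warmer: may-jun mean below may-jul mean
  daily$value <- ifelse(daily$month == 7, 20, 10)
  mj <- seasonal_aggregate(daily, "may-jul", "mean")
  mj2 <- seasonal_aggregate(daily, "may-jun", "mean")
  expect_true(all(mj2$values < mj$values))

  # incomplete coverage errors with the offending cell-year
  expect_error(
    seasonal_aggregate(daily[!(daily$month == 6 & daily$year == 2001), ],
                       "may-jul", "mean"),
    "c1/2001")
})

test_that("climate cubes round-trip through long CSV", {
  cube <- random_cube(6, 4, 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(cube, path)
  back <- read_climate_csv(path, variable = cube$variable,
                           centering_years = cube$centering_years)
  expect_equal(back$values, cube$values, ignore_attr = TRUE)
  expect_equal(back$years, cube$years)
  d1 <- decompose_climate(cube); d2 <- decompose_climate(back)
  expect_equal(d1$spatial, d2$spatial)
})

test_that("decomposition components write as CSV with a JSON header", {
  d <- decompose_climate(random_cube(5, 4, 23))
  dir <- withr::local_tempdir()
  write_decomposition(d, dir)
  sp <- read.csv(file.path(dir, "spatial.csv"))
  expect_equal(sp$value, unname(d$spatial))
  hd <- jsonlite::read_json(file.path(dir, "header.json"))
  expect_equal(hd$global_mean, d$global_mean)
})
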