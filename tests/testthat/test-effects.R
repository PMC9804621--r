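# construct an abundance_fit object directly from coefficients, so grid
# behaviour can be checked without sampling error
manual_fit <- function(md, beta_named, family = "poisson") {
  beta <- setNames(rep(0, ncol(md$X)), colnames(md$X))
  beta[names(beta_named)] <- beta_named
  structure(
    list(family = family, beta = beta, gamma = NULL, theta = NULL,
         sigma_u = 0.1, u_modes = setNames(rep(0, nlevels(md$route)),
                                           levels(md$route)),
         loglik = 0, k = length(beta), aic = 0, vcov = NULL,
         se = rep(NA_real_, length(beta)), convergence = TRUE,
         order = 7, info = md$info, route_levels = levels(md$route),
         n_obs = nrow(md$X)),
    class = "abundance_fit")
}

test_that("spearman matches average-rank hand computations and conventions", {
  expect_equal(spearman_rs(1:3, c(2, 4, 6)), 1)
  expect_equal(spearman_rs(1:3, c(6, 4, 2)), -1)
  # ties averaged: ranks (1.5, 1.5, 3) vs (1, 2, 3) -> 0.866
  r <- spearman_rs(c(1, 1, 2), c(1, 2, 3))
  expect_equal(r, sqrt(3) / 2, tolerance = 1e-12)
  # explicit average-rank Pearson oracle
  a <- c(3, 1, 4, 1, 5, 9, 2, 6); b <- c(2, 7, 1, 8, 2, 8, 1, 8)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_rs(a, b), oracle, tolerance = 1e-12)
  # zero variance -> undefined
  expect_true(is.na(spearman_rs(c(1, 1, 1), 1:3)))
  expect_error(spearman_rs(1:3, 1:4), "length")
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- spearman_rs(a, b)
    expect_equal(spearman_rs(exp(a), b), r0)
    expect_equal(spearman_rs(a, 3 * atan(b) - 2), r0)
    expect_equal(spearman_rs(-a, b), -r0)
  }
})

test_that("effect grids span observed ranges and respond monotonically", {
  st <- small_study(301, family = "poisson", standardize = TRUE)
  md <- st$md
  # positive spatial temperature effect only
  fit <- manual_fit(md, c("(Intercept)" = 1, temp_spatial = 0.8))
  g <- component_grid(fit, md, "spatial")
  expect_equal(dim(g$abundance), c(10L, 10L))
  expect_equal(g$temp_levels[c(1, 10)], md$info$ranges$temp$spatial)
  expect_equal(diff(range(diff(g$temp_levels))), 0)  # evenly spaced
  # monotone increasing in temperature at every precipitation level
  for (j in 1:10) expect_true(all(diff(g$abundance[, j]) > 0))
  # constant across precipitation (no precipitation effect)
  for (i in 1:10) expect_lt(diff(range(g$abundance[i, ])), 1e-9)
  expect_true(all(g$abundance >= 0))

  # all temporal coefficients zero: temporal grid constant over all combos
  g_t <- component_grid(fit, md, "temporal")
  expect_lt(diff(range(g_t$abundance)), 1e-9)

  # grid levels for [-3, 3] are the 10-point linspace
  expect_equal(seq(-3, 3, length.out = 10)[2], -3 + 6 / 9)
})

test_that("component correlations follow the sign structure of coefficients", {
  st <- small_study(302, family = "poisson", standardize = TRUE)
  md <- st$md
  coefs_eq <- c("(Intercept)" = 1, temp_spatial = -0.6, prec_spatial = 0.3,
                temp_temporal = -0.6, prec_temporal = 0.3,
                temp_residual = -0.6, prec_residual = 0.3)
  fit_eq <- manual_fit(md, coefs_eq)
  grids <- lapply(setNames(nm = c("spatial", "temporal", "residual")),
                  function(cmp) component_grid(fit_eq, md, cmp))
  s <- correlate_components(grids)
  # identical coefficient signs: joint r_s = 1 exactly for every pair
  expect_true(all(s$r_s[s$gradient == "temperature"] == 1))
  expect_true(all(s$class == "both-retained"))

  # temporal = -spatial: rank reversal on the temperature gradient
  coefs_op <- coefs_eq
  coefs_op["temp_temporal"] <- 0.6
  coefs_op["prec_temporal"] <- -0.3
  fit_op <- manual_fit(md, coefs_op)
  grids_op <- lapply(setNames(nm = c("spatial", "temporal", "residual")),
                     function(cmp) component_grid(fit_op, md, cmp))
  s_op <- correlate_components(grids_op)
  expect_equal(s_op$r_s[s_op$pair == "spatial-temporal" &
                          s_op$gradient == "temperature"], -1)

  # absent-component conventions
  fit_abs <- manual_fit(md, c("(Intercept)" = 1, temp_spatial = -0.6))
  grids_abs <- lapply(setNames(nm = c("spatial", "temporal", "residual")),
                      function(cmp) component_grid(fit_abs, md, cmp))
  s_abs <- correlate_components(grids_abs)
  st_row <- s_abs[s_abs$pair == "spatial-temporal", ]
  # temporal component absent: r_s = 0 where the spatial one has an
  # association (joint, temperature), r_s = 1 where neither does
  # (precipitation: the species only responds to temperature)
  expect_equal(st_row$r_s[st_row$gradient == "joint"], 0)
  expect_equal(st_row$r_s[st_row$gradient == "temperature"], 0)
  expect_equal(st_row$class[st_row$gradient == "temperature"], "one-absent")
  expect_equal(st_row$r_s[st_row$gradient == "precipitation"], 1)
  tr_row <- s_abs[s_abs$pair == "temporal-residual", ]
  expect_true(all(tr_row$r_s == 1))
  expect_true(all(tr_row$class == "both-absent"))
})

test_that("species are classified by the spatial-temporal temperature correlation", {
  st <- small_study(303, family = "poisson", standardize = TRUE)
  md <- st$md
  mk <- function(tt) {
    fit <- manual_fit(md, c("(Intercept)" = 1, temp_spatial = -0.6,
                            temp_temporal = tt))
    grids <- lapply(setNames(nm = c("spatial", "temporal", "residual")),
                    function(cmp) component_grid(fit, md, cmp))
    classify_response(correlate_components(grids), grids$spatial)
  }
  cons <- mk(-0.4)
  expect_equal(cons$response, "consistent")
  expect_equal(cons$baseline, "cold")   # negative temp effect: cold baseline
  expect_equal(cons$label, "consistent-cold")
  opp <- mk(0.4)
  expect_equal(opp$response, "opposite")
  expect_equal(mk(0)$response, "one-absent")
})

test_that("performance screening separates informative from permuted fits", {
  st <- small_study(304, family = "nb", n_routes = 80,
                    country_shares = c(0.3, 0.4, 0.3))
  fit <- fit_abundance(st$md, "nb")
  perf <- performance_pearson(fit, st$md)
  expect_setequal(perf$group, c("A", "B", "C", "pooled"))
  expect_true(all(perf$r > 0.3))

  # perfect fit: r = 1 in every group
  pf <- perf
  obs_md <- st$md
  fitv <- predict_mean(fit, st$md, include_random = TRUE)
  obs_md$y <- as.integer(round(fitv))
  fit2 <- fit  # same predictions, observations equal to predictions
  perf_perfect <- performance_pearson(fit2, obs_md)
  expect_true(all(perf_perfect$r > 0.99))

  # permuted observations: near-zero correlation, screen fails
  set.seed(1)
  perm_md <- st$md
  perm_md$y <- sample(perm_md$y)
  perf_null <- performance_pearson(fit, perm_md)
  expect_true(abs(perf_null$r[perf_null$group == "pooled"]) < 0.1)
  expect_false(attr(perf_null, "pass_all"))
})

test_that("Moran's I matches hand computation and the brute-force oracle", {
  # two antisymmetric points with unit weights: I = -1
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  m <- morans_i(c(1, -1), weights = w, nperm = 9)
  expect_equal(m$I, -1)

  # brute-force double-sum oracle on 20 random points
  set.seed(8)
  xy <- matrix(runif(40), 20, 2)
  v <- rnorm(20)
  m2 <- morans_i(v, coords = xy, nperm = 9)
  D <- as.matrix(dist(xy)); W <- 1 / D; diag(W) <- 0
  z <- v - mean(v)
  num <- 0
  for (i in 1:20) for (j in 1:20) num <- num + W[i, j] * z[i] * z[j]
  I_oracle <- (20 / sum(W)) * num / sum(z^2)
  expect_lt(abs(m2$I - I_oracle), 1e-12)
  expect_equal(m2$expected, -1 / 19)

  # smooth spatial gradient: strong positive autocorrelation
  grid <- expand.grid(x = 1:10, y = 1:10)
  grad <- grid$x + grid$y
  mg <- morans_i(grad, coords = grid, nperm = 999, seed = 1)
  expect_gt(mg$I, 0.3)
  expect_lte(mg$p_value, 0.01)

  expect_error(morans_i(rep(1, 5), coords = cbind(1:5, 1:5)), "constant")
})

test_that("Moran's I agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(21)
  xy <- matrix(runif(60), 30, 2)
  v <- rnorm(30) + xy[, 1]
  W <- 1 / as.matrix(dist(xy)); diag(W) <- 0
  W <- W / rowSums(W)          # ape row-normalizes internally
  ours <- morans_i(v, weights = W, nperm = 9)
  ref <- ape::Moran.I(v, W)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-12)
})

test_that("leave-one-year-out CV refits once per year", {
  st <- small_study(305, family = "poisson", n_routes = 40, sigma_u = 0.2,
                    study_years = c(2016, 2018))
  cv <- loyo_cv(st$md, "poisson")
  expect_equal(nrow(cv), 3L)
  expect_equal(cv$year, sort(unique(st$md$frame_raw$year)))
  expect_true(all(is.finite(cv$r)))
  expect_error(loyo_cv(md_subset(st$md, st$md$frame_raw$year == 2016),
                       "poisson"), "3 years")
})
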