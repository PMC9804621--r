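# Shared fixture builders. All synthetic, generated at test time.

# small random climate cube (no structure constraints beyond completeness)
random_cube <- function(n_cells, n_years, seed, first_year = 1971) {
  set.seed(seed)
  years <- seq(first_year, first_year + n_years - 1L)
  nx <- ceiling(sqrt(n_cells))
  climate_cube(
    matrix(rnorm(n_cells * n_years, 10, 3), n_cells, n_years),
    data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
               x = ((seq_len(n_cells) - 1L) %% nx) + 1L,
               y = ((seq_len(n_cells) - 1L) %/% nx) + 1L),
    years)
}

# brute-force decomposition oracle: explicit double loops over the
# defining sums, independent of the vectorized implementation
oracle_decompose <- function(values, years, centering_years, study_years) {
  ci <- which(years %in% seq(centering_years[1], centering_years[2]))
  si <- which(years %in% seq(study_years[1], study_years[2]))
  N <- nrow(values); Tc <- length(ci)
  gm <- 0
  for (i in seq_len(N)) for (t in ci) gm <- gm + values[i, t]
  gm <- gm / (N * Tc)
  cc <- values - gm
  spatial <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (t in ci) s <- s + cc[i, t]
    spatial[i] <- s / Tc
  }
  temporal <- numeric(length(si))
  for (k in seq_along(si)) {
    s <- 0
    for (i in seq_len(N)) s <- s + cc[i, si[k]]
    temporal[k] <- s / N
  }
  residual <- matrix(0, N, length(si))
  for (i in seq_len(N)) for (k in seq_along(si))
    residual[i, k] <- cc[i, si[k]] - spatial[i] - temporal[k]
  list(global_mean = gm, spatial = spatial, temporal = temporal,
       residual = residual)
}

# complete small synthetic study: climate, decomposition, counts, design
small_study <- function(seed, family = "nb", n_routes = 60, n_cells = 12,
                        study_years = c(2011, 2018), theta = 1.5,
                        sigma_u = 0.3, beta_count = NULL, gamma_zi = NULL,
                        standardize = FALSE, country_shares = c(0, .5, .5),
                        visit_prob = 1, lag = 0L) {
  cfg <- synthetic_config(
    n_cells_x = n_cells, n_cells_y = n_cells, n_routes = n_routes,
    study_years = study_years, country_shares = country_shares,
    scheme_start_year = c(A = study_years[1], B = study_years[1], C = study_years[1]),
    visit_prob = visit_prob, seed = seed)
  ct <- generate_climate(cfg, "temperature")
  cp <- generate_climate(cfg, "precipitation")
  dt <- decompose_climate(ct, cfg$study_years)
  dp <- decompose_climate(cp, cfg$study_years)
  pars <- default_true_parameters(family, theta = theta, sigma_u = sigma_u,
                                  beta_count = beta_count, gamma_zi = gamma_zi)
  counts <- generate_counts(generate_routes(cfg), dt, dp, pars,
                            seed = seed + 1000L, lag = lag)
  md <- assemble_design(counts, dt, dp, lag = lag, habitat = pars$habitat,
                        standardize = standardize)
  list(cfg = cfg, dt = dt, dp = dp, pars = pars, counts = counts, md = md)
}

# tiny hand-assembled model_data for likelihood-level tests
tiny_md <- function(seed = 1, n_routes = 6, per_route = 5, beta = c(0.5, 0.4),
                    family = "poisson", theta = 1, sigma_u = 0.5,
                    offset = 0.2) {
  set.seed(seed)
  n <- n_routes * per_route
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n))
  route <- factor(rep(seq_len(n_routes), each = per_route))
  u <- rnorm(n_routes, 0, sigma_u)
  eta <- drop(X %*% beta) + offset + u[route]
  y <- if (family == "poisson") rpois(n, exp(eta))
  else rnbinom(n, size = theta, mu = exp(eta))
  structure(list(y = y, X = X, Xzi = X, offset = rep(offset, n),
                 route = route,
                 frame_raw = data.frame(route_id = route, year = rep(1, n)),
                 info = NULL),
            class = "model_data")
}
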