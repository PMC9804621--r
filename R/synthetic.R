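#' Configuration for the synthetic survey-and-climate generator
#'
#' Bundles the ground-truth structure the generator emulates: a smooth
#' north-south climate gradient, annual anomalies shared by all cells,
#' cell-by-year residual variation, and an unbalanced route x year survey
#' panel across three countries with differing scheme start years. Country 1
#' mimics a scheme recording the same route with both point counts and line
#' transects (two survey rows per route); country 2 starts a decade earlier
#' than the other two.
#'
#' Defaults mirror the structure of a Fennoscandian breeding-bird study:
#' centering period 1971-2018 (48 years) versus study period 1996-2018
#' (23 years), country survey shares roughly 0.27/0.41/0.32 with scheme
#' starts 2006/1996/2006, breeding-season temperature around a 10.7 degree C
#' global mean and precipitation around 193 mm.
#'
#' @param n_cells_x,n_cells_y grid dimensions (>= 2; 1-km cell semantics).
#' @param centering_years,study_years inclusive year ranges; the study range
#'   must lie within the centering range.
#' @param base_level named list, overall mean level per variable
#'   (temperature degrees C, precipitation mm).
#' @param spatial_gradient_amplitude named list, peak-to-peak amplitude of
#'   the deterministic spatial gradient per variable (temperature runs
#'   south-north along the y axis, precipitation west-east along x).
#' @param annual_anomaly_sd named list, SD of the year anomaly shared by all
#'   cells.
#' @param residual_sd named list, SD of the cell x year residual noise.
#' @param residual_smooth spatial smoothing length of the residual field in
#'   cells (0 = iid noise).
#' @param temp_precip_correlation correlation in [-1, 1] between the
#'   temperature and precipitation anomaly/residual draws.
#' @param n_routes number of survey routes (each on its own grid cell).
#' @param country_shares three fractions summing to 1.
#' @param scheme_start_year named integer vector `c(A=, B=, C=)`: first survey
#'   year per country.
#' @param effort_range inclusive integer range of per-visit survey effort
#'   (transect length units or point-station counts).
#' @param visit_prob probability a route is surveyed in a given eligible year
#'   (panels are unbalanced, as in real schemes).
#' @param seed master integer seed; per-stage streams are derived from it.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells_x = 20, n_cells_y = 20,
                             centering_years = c(1971, 2018),
                             study_years = c(1996, 2018),
                             base_level = list(temperature = 10.7, precipitation = 193),
                             spatial_gradient_amplitude = list(temperature = 6, precipitation = 120),
                             annual_anomaly_sd = list(temperature = 0.8, precipitation = 25),
                             residual_sd = list(temperature = 0.5, precipitation = 15),
                             residual_smooth = 0,
                             temp_precip_correlation = -0.3,
                             n_routes = 150,
                             country_shares = c(0.27, 0.41, 0.32),
                             scheme_start_year = c(A = 2006, B = 1996, C = 2006),
                             effort_range = c(4L, 12L),
                             visit_prob = 0.9,
                             seed = 1L) {
  stopifnot(n_cells_x >= 2, n_cells_y >= 2)
  centering_years <- as.integer(centering_years)
  study_years <- as.integer(study_years)
  if (study_years[1] < centering_years[1] || study_years[2] > centering_years[2])
    stop("study_years must lie within centering_years")
  for (v in c("temperature", "precipitation")) {
    if (annual_anomaly_sd[[v]] < 0 || residual_sd[[v]] < 0)
      stop("SDs must be >= 0")
  }
  if (abs(temp_precip_correlation) > 1)
    stop("temp_precip_correlation must be in [-1, 1]")
  if (length(country_shares) != 3L || abs(sum(country_shares) - 1) > 1e-12)
    stop("country_shares must be three fractions summing to 1")
  if (n_routes > n_cells_x * n_cells_y)
    stop("n_routes exceeds the number of grid cells")
  effort_range <- as.integer(effort_range)
  stopifnot(all(effort_range >= 1L), effort_range[1] <= effort_range[2])
  structure(
    list(n_cells_x = as.integer(n_cells_x), n_cells_y = as.integer(n_cells_y),
         centering_years = centering_years, study_years = study_years,
         base_level = base_level,
         spatial_gradient_amplitude = spatial_gradient_amplitude,
         annual_anomaly_sd = annual_anomaly_sd, residual_sd = residual_sd,
         residual_smooth = residual_smooth,
         temp_precip_correlation = temp_precip_correlation,
         n_routes = as.integer(n_routes), country_shares = country_shares,
         scheme_start_year = scheme_start_year, effort_range = effort_range,
         visit_prob = visit_prob, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Deterministic per-stage seed stream derived from the master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * offset) %% 2147483629)
}

# correlated standard-normal pair columns; column picked by variable
.cor_pair <- function(n, rho, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  z[, 2L] <- rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L]
  z
}

# separable box smoothing of a cells x years matrix on the nx x ny grid,
# rescaled to preserve the marginal SD
.smooth_field <- function(mat, nx, ny, len) {
  if (len <= 0) return(mat)
  k <- 2L * as.integer(ceiling(len)) + 1L
  out <- mat
  for (j in seq_len(ncol(mat))) {
    f <- matrix(mat[, j], nx, ny)
    f <- t(apply(f, 1L, function(r) stats::filter(r, rep(1 / k, k), circular = TRUE)))
    f <- apply(f, 2L, function(r) stats::filter(r, rep(1 / k, k), circular = TRUE))
    out[, j] <- as.vector(f)
  }
  s0 <- stats::sd(mat); s1 <- stats::sd(out)
  if (s1 > 0) out <- out * (s0 / s1)
  out
}

#' Generate a synthetic gridded climate cube
#'
#' Builds cell x year breeding-season values as a deterministic spatial
#' gradient (south-north for temperature, west-east for precipitation, plus
#' smooth low-frequency terms) + a year anomaly shared by all cells +
#' cell x year residual noise.
#' Temperature and precipitation draws share underlying streams so their
#' anomalies and residuals carry the configured cross-variable correlation.
#' Precipitation is truncated at zero.
#'
#' @param config a [synthetic_config()].
#' @param variable `"temperature"` or `"precipitation"`.
#' @param season_window window label recorded on the cube.
#' @return A [climate_cube()] spanning the centering years.
#' @export
generate_climate <- function(config, variable = c("temperature", "precipitation"),
                             season_window = "may-jul") {
  stopifnot(inherits(config, "synthetic_config"))
  variable <- match.arg(variable)
  vcol <- if (variable == "temperature") 1L else 2L
  nx <- config$n_cells_x; ny <- config$n_cells_y
  n_cells <- nx * ny
  years <- seq(config$centering_years[1], config$centering_years[2])
  n_years <- length(years)

  xg <- rep(seq_len(nx), times = ny)
  yg <- rep(seq_len(ny), each = nx)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)), x = xg, y = yg)

  # deterministic gradient plus low-frequency smooth terms; temperature runs
  # south-north (grid y, latitude proxy), precipitation west-east (grid x,
  # oceanicity proxy) so the two spatial covariates are not collinear
  amp <- config$spatial_gradient_amplitude[[variable]]
  set.seed(derive_seed(config$seed, 11L + vcol))
  ph <- stats::runif(2L, 0, 2 * pi)
  main_axis <- if (variable == "temperature")
    (yg - mean(yg)) / max(1, ny - 1)
  else
    -(xg - mean(xg)) / max(1, nx - 1)
  grad <- main_axis +
    0.15 * sin(2 * pi * xg / nx + ph[1L]) +
    0.10 * sin(2 * pi * yg / ny + ph[2L])
  grad <- amp * (grad - mean(grad))

  anom <- .cor_pair(n_years, config$temp_precip_correlation,
                    derive_seed(config$seed, 23L))[, vcol] *
    config$annual_anomaly_sd[[variable]]
  resid <- matrix(
    .cor_pair(n_cells * n_years, config$temp_precip_correlation,
              derive_seed(config$seed, 37L))[, vcol],
    n_cells, n_years) * config$residual_sd[[variable]]
  resid <- .smooth_field(resid, nx, ny, config$residual_smooth)

  values <- config$base_level[[variable]] + grad +
    matrix(anom, n_cells, n_years, byrow = TRUE) + resid
  if (variable == "precipitation") values <- pmax(values, 0)

  climate_cube(values, cells, years, variable = variable,
               season_window = season_window,
               centering_years = config$centering_years)
}

#' Generate a synthetic survey-route table
#'
#' Places routes on distinct grid cells and emits one row per route-survey
#' and year: country (A/B/C), survey type (Point/Line), count unit
#' (Individual/Pair), per-year effort, and route-level habitat covariates
#' (slope, solar radiation, and proportions of seven pooled land-cover
#' categories). Country A routes are recorded by two spatially dependent
#' surveys (Point and Line rows sharing the route id and cell); countries B
#' and C contribute Line rows only, country B counting individuals and the
#' others pairs. Route-years before a country's scheme start are absent, and
#' eligible years are visited with probability `visit_prob`.
#'
#' @param config a [synthetic_config()].
#' @return Data frame with columns `route_id`, `survey_id`, `cell_id`, `x`,
#'   `y`, `country`, `survey`, `unit`, `year`, `effort`, `slope`, `solar`,
#'   and `lc_*` proportions.
#' @export
generate_routes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_cells <- config$n_cells_x * config$n_cells_y
  n <- config$n_routes
  if (n > n_cells) stop("n_routes exceeds the number of grid cells")
  set.seed(derive_seed(config$seed, 53L))

  xg <- rep(seq_len(config$n_cells_x), times = config$n_cells_y)
  yg <- rep(seq_len(config$n_cells_y), each = config$n_cells_x)
  cell_ids <- sprintf("c%04d", seq_len(n_cells))
  pick <- sample.int(n_cells, n)

  n_c <- floor(config$country_shares * n)
  rem <- n - sum(n_c)
  if (rem > 0) {
    extra <- order(config$country_shares * n - n_c, decreasing = TRUE)[seq_len(rem)]
    n_c[extra] <- n_c[extra] + 1L
  }
  country <- rep(c("A", "B", "C"), times = n_c)

  lc_names <- paste0("lc_", c("sparse_mountain", "mountain_vegetation",
                              "deciduous_forest", "other_forest", "wetlands",
                              "inland_waters", "agriculture"))
  lc <- matrix(stats::rgamma(n * 7L, shape = 0.8), n, 7L)
  lc <- lc / rowSums(lc) * stats::runif(n, 0.85, 1)  # remainder = other/sea
  colnames(lc) <- lc_names

  routes <- data.frame(
    route_id = sprintf("r%03d", seq_len(n)),
    cell_id = cell_ids[pick], x = xg[pick], y = yg[pick],
    country = country,
    unit = ifelse(country == "B", "Individual", "Pair"),
    slope = pmax(0, stats::rnorm(n, 5, 3)),
    solar = stats::rnorm(n, 100, 15))
  routes <- cbind(routes, as.data.frame(lc))

  # country A: Point + Line rows per route; B, C: Line only
  with_survey <- function(df, s) { df$survey <- rep(s, nrow(df)); df }
  surveys <- rbind(
    with_survey(routes[routes$country == "A", , drop = FALSE], "Point"),
    with_survey(routes[routes$country == "A", , drop = FALSE], "Line"),
    with_survey(routes[routes$country != "A", , drop = FALSE], "Line"))
  surveys$survey_id <- paste0(surveys$route_id, "_", surveys$survey)

  years <- seq(config$study_years[1], config$study_years[2])
  long <- merge(surveys, data.frame(year = years), by = NULL)
  long <- long[long$year >= config$scheme_start_year[long$country], , drop = FALSE]
  keep <- stats::runif(nrow(long)) < config$visit_prob
  long <- long[keep, , drop = FALSE]
  eff_vals <- seq(config$effort_range[1], config$effort_range[2])
  long$effort <- eff_vals[sample.int(length(eff_vals), nrow(long), replace = TRUE)]
  rownames(long) <- NULL
  cols <- c("route_id", "survey_id", "cell_id", "x", "y", "country", "survey",
            "unit", "year", "effort", "slope", "solar", lc_names)
  long[order(long$route_id, long$survey_id, long$year), cols]
}

#' Ground-truth parameters for count generation
#'
#' Named coefficient vectors on the scale of the unstandardized design built
#' by [assemble_design()]: an intercept, six climate main effects
#' (spatial/temporal/residual x temperature/precipitation), three
#' component-wise temperature x precipitation interactions, the two year
#' polynomial terms, Survey and Unit contrasts, and habitat covariates. The
#' default climate effects describe a cold-adapted mountain species: more
#' abundant at colder sites and in colder years (negative temperature
#' coefficients), mildly favoured by wetter conditions.
#'
#' @param family `"poisson"`, `"nb"`, `"zip"`, or `"zinb"`.
#' @param beta_count named replacement values merged over the defaults.
#' @param gamma_zi named zero-inflation coefficients (logit scale); used by
#'   zip/zinb only.
#' @param theta NB dispersion (> 0; variance mu + mu^2/theta).
#' @param sigma_u route random-intercept SD (>= 0).
#' @param habitat character vector of habitat covariate names included in the
#'   design (must have coefficients in `beta_count`).
#' @return A `true_parameters` list.
#' @export
default_true_parameters <- function(family = c("nb", "poisson", "zip", "zinb"),
                                    beta_count = NULL, gamma_zi = NULL,
                                    theta = 1.5, sigma_u = 0.4,
                                    habitat = "slope") {
  family <- match.arg(family)
  beta <- c("(Intercept)" = 0.2,
            temp_spatial = -0.35, prec_spatial = 0.004,
            temp_temporal = -0.20, prec_temporal = 0.003,
            temp_residual = -0.12, prec_residual = 0.002,
            txp_spatial = 8e-4, txp_temporal = -8e-4, txp_residual = 5e-4,
            year_lin = 0.05, year_quad = -0.03,
            surveyPoint = -0.5, unitPair = -0.2,
            slope = -0.05, solar = 0.0,
            lc_sparse_mountain = 0.3, lc_mountain_vegetation = 0.4,
            lc_deciduous_forest = 0.0, lc_other_forest = -0.3,
            lc_wetlands = 0.2, lc_inland_waters = 0.0, lc_agriculture = -0.4)
  if (!is.null(beta_count)) beta[names(beta_count)] <- beta_count
  gamma <- beta * 0
  gamma <- gamma[setdiff(names(gamma), c("surveyPoint", "unitPair"))]
  gamma[c("(Intercept)", "temp_spatial", "prec_spatial")] <- c(-1.5, 0.2, -0.003)
  if (!is.null(gamma_zi)) gamma[names(gamma_zi)] <- gamma_zi
  if (family %in% c("nb", "zinb") && theta <= 0) stop("theta must be > 0")
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  structure(list(beta_count = beta, gamma_zi = gamma, theta = theta,
                 sigma_u = sigma_u, family = family, habitat = habitat),
            class = "true_parameters")
}

#' Generate counts from the ground-truth abundance model
#'
#' For each route-survey-year, forms the linear predictor
#' eta = x'beta + u_r + log(effort) on the unstandardized design (see
#' [assemble_design()]), draws the route intercept u_r once per route from
#' N(0, sigma_u^2), and draws the count from the configured family. For
#' zip/zinb the structural-zero probability comes from the zero-inflation
#' linear predictor through a logit link.
#'
#' @param routes route table from [generate_routes()].
#' @param decomp_temp,decomp_prec `decomposed_climate` objects for
#'   temperature and precipitation.
#' @param params a `true_parameters` object.
#' @param seed integer seed for the count draws.
#' @param lag years of climate lag wired into the design (0 or 1).
#' @return `routes` with a `count` column appended; the unstandardized model
#'   data used for generation is attached as attribute `"model_data"`.
#' @export
generate_counts <- function(routes, decomp_temp, decomp_prec, params,
                            seed = 1L, lag = 0L) {
  stopifnot(inherits(params, "true_parameters"))
  md <- assemble_design(routes, decomp_temp, decomp_prec, lag = lag,
                        habitat = params$habitat, standardize = FALSE)
  X <- md$X
  beta <- params$beta_count
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss) > 0)
    stop("no true coefficient for design column(s): ", paste(miss, collapse = ", "))
  eta_fix <- drop(X %*% beta[colnames(X)]) + md$offset

  set.seed(seed)
  routes_u <- levels(md$route)
  u <- stats::rnorm(length(routes_u), 0, params$sigma_u)
  eta <- eta_fix + u[as.integer(md$route)]
  mu <- exp(eta)

  n <- length(mu)
  y <- switch(params$family,
    poisson = stats::rpois(n, mu),
    nb = stats::rnbinom(n, size = params$theta, mu = mu),
    zip = , zinb = {
      Z <- md$Xzi
      gm <- params$gamma_zi
      missz <- setdiff(colnames(Z), names(gm))
      if (length(missz) > 0)
        stop("no true zi coefficient for design column(s): ",
             paste(missz, collapse = ", "))
      pi_str <- stats::plogis(drop(Z %*% gm[colnames(Z)]))
      base <- if (params$family == "zip") stats::rpois(n, mu) else
        stats::rnbinom(n, size = params$theta, mu = mu)
      ifelse(stats::runif(n) < pi_str, 0L, base)
    })

  out <- md$frame_raw
  out$count <- as.integer(y)
  attr(out, "model_data") <- md
  attr(out, "true_u") <- stats::setNames(u, routes_u)
  out
}
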