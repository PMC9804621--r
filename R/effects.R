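#' Prediction grid isolating one climate component's effect
#'
#' Builds a 10 x 10 grid of temperature x precipitation values for the chosen
#' climate component, evenly spaced between the component's observed minimum
#' and maximum, predicts the expected count at every route for each
#' combination with all other covariates fixed at typical values, and sums
#' the predictions over routes. For the spatial component the temporal and
#' residual components are set to zero while spatial temperature and
#' precipitation are varied; for the temporal and residual components the
#' spatial component is held at each route's observed value, the other
#' anomaly component is set to zero, and the target component is varied.
#'
#' Typical values: median of continuous covariates, Line/Pair factor levels,
#' median year, and the mean log-effort as a common offset for every route.
#' Random effects are excluded (the population-level effect is the target).
#'
#' @param fit an `abundance_fit` (possibly after block selection).
#' @param md the `model_data` the fit was built from (supplies routes, raw
#'   component values, scaling constants and observed ranges).
#' @param component `"spatial"`, `"temporal"`, or `"residual"`.
#' @param n_levels number of grid levels per variable (default 10).
#' @return An `effect_grid`: list with `component`, `temp_levels`,
#'   `prec_levels` (raw units), `abundance` (n_levels x n_levels matrix,
#'   temperature in rows), and `retained` (FALSE when every term of the
#'   component was dropped from the model, in which case the grid is
#'   constant).
#' @export
component_grid <- function(fit, md, component = c("spatial", "temporal", "residual"),
                           n_levels = 10L) {
  component <- match.arg(component)
  stopifnot(inherits(fit, "abundance_fit"), inherits(md, "model_data"))
  if (!fit$convergence) stop("refusing to build grids from a non-converged fit")
  info <- md$info
  rng_t <- info$ranges$temp[[component]]
  rng_p <- info$ranges$prec[[component]]
  temp_levels <- seq(rng_t[1], rng_t[2], length.out = n_levels)
  prec_levels <- seq(rng_p[1], rng_p[2], length.out = n_levels)

  fr <- md$frame_raw
  # one prediction row per line-transect route (falls back to all routes)
  line <- fr[fr$survey == "Line", , drop = FALSE]
  if (nrow(line) == 0L) line <- fr
  routes <- line[!duplicated(line$route_id), , drop = FALSE]
  n_r <- nrow(routes)

  # raw climate values per route under the component scheme
  raw0 <- matrix(0, n_r, 6,
                 dimnames = list(NULL, info$climate_cols))
  if (component != "spatial") {
    raw0[, "temp_spatial"] <- .route_raw(md, routes, "temp_spatial")
    raw0[, "prec_spatial"] <- .route_raw(md, routes, "prec_spatial")
  }
  tcol <- paste0("temp_", component)
  pcol <- paste0("prec_", component)

  sc <- info$scaling
  z <- function(col, v) (v - sc$mean[[col]]) / sc$sd[[col]]
  yb <- sc$year_basis
  y_med <- stats::median(fr$year)
  y1 <- (y_med - yb$mean) / yb$sd
  y2 <- (y1^2 - yb$q_mean) / yb$q_sd
  hab_typ <- vapply(info$habitat,
                    function(h) z(h, stats::median(fr[[h]])), numeric(1))
  offset_typ <- mean(log(fr$effort))

  cols <- names(fit$beta)
  comp_cols <- c(tcol, pcol, paste0("txp_", component))
  retained <- any(comp_cols %in% cols)

  abundance <- matrix(0, n_levels, n_levels,
                      dimnames = list(signif(temp_levels, 6), signif(prec_levels, 6)))
  zi <- fit$family %in% c("zip", "zinb")
  for (i in seq_len(n_levels)) {
    for (j in seq_len(n_levels)) {
      raw <- raw0
      raw[, tcol] <- temp_levels[i]
      raw[, pcol] <- prec_levels[j]
      Z <- raw
      for (cc in info$climate_cols) Z[, cc] <- z(cc, raw[, cc])
      Xfull <- cbind(
        "(Intercept)" = 1,
        Z,
        txp_spatial = Z[, "temp_spatial"] * Z[, "prec_spatial"],
        txp_temporal = Z[, "temp_temporal"] * Z[, "prec_temporal"],
        txp_residual = Z[, "temp_residual"] * Z[, "prec_residual"],
        year_lin = y1, year_quad = y2,
        surveyPoint = 0, unitPair = 1)
      if (length(hab_typ) > 0)
        Xfull <- cbind(Xfull, matrix(hab_typ, n_r, length(hab_typ), byrow = TRUE,
                                     dimnames = list(NULL, info$habitat)))
      X <- Xfull[, cols, drop = FALSE]
      mu <- exp(drop(X %*% fit$beta) + offset_typ)
      if (zi) {
        Xz <- Xfull[, names(fit$gamma), drop = FALSE]
        mu <- (1 - stats::plogis(drop(Xz %*% fit$gamma))) * mu
      }
      abundance[i, j] <- sum(mu)
    }
  }
  structure(list(component = component, temp_levels = temp_levels,
                 prec_levels = prec_levels, abundance = abundance,
                 retained = retained, n_routes = n_r),
            class = "effect_grid")
}

# raw (unstandardized) per-route value of a climate column
.route_raw <- function(md, routes, col) {
  fr <- md$frame_raw
  idx <- match(routes$route_id, fr$route_id)
  sc <- md$info$scaling
  md$X[idx, col] * sc$sd[[col]] + sc$mean[[col]]
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Undefined (zero rank variance in either argument) yields `NA`.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or `NA_real_` when undefined.
#' @export
spearman_rs <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths")
  if (length(a) < 3L) stop("need at least 3 values")
  ra <- unname(rank(a)); rb <- unname(rank(b))
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  # identical or exactly reversed rankings give +-1 by rank arithmetic,
  # without floating-point round-off from the correlation formula
  if (identical(ra, rb)) return(1)
  if (identical(ra, length(rb) + 1 - rb)) return(-1)
  stats::cor(ra, rb)
}

#' Rank correlations between the effects of climate components
#'
#' Compares the predicted-abundance surfaces of the three climate components
#' pairwise with Spearman's rank correlation, for three gradient sets:
#' jointly over all 100 temperature x precipitation combinations, along the
#' temperature gradient with precipitation fixed, and along the
#' precipitation gradient with temperature fixed. The fixed level is the
#' grid level nearest zero (components are centered, so for the spatial
#' component this is also the level nearest its all-cell mean).
#'
#' A component is treated as absent for a given gradient when its terms were
#' dropped from the model or its predicted-abundance profile is flat along
#' that gradient (e.g. a component retained only through precipitation shows
#' no temperature association). For a pair with exactly one absent component
#' no agreement in direction can be established and the correlation is
#' reported as 0; when both are absent the models agree that neither
#' component has an effect and it is reported as 1. These conventions are
#' flagged in the `class` column.
#'
#' @param grids named list with `spatial`, `temporal`, `residual`
#'   [component_grid()]s from the same fitted model.
#' @return Data frame of class `correlation_summary`: columns `pair`,
#'   `gradient` (`joint`/`temperature`/`precipitation`), `r_s`, `class`
#'   (`both-retained`, `one-absent`, `both-absent`).
#' @export
correlate_components <- function(grids) {
  stopifnot(all(c("spatial", "temporal", "residual") %in% names(grids)))
  ref_idx <- function(levels) which.min(abs(levels - 0))
  profile <- function(g, gradient) {
    switch(gradient,
           joint = as.vector(g$abundance),
           temperature = g$abundance[, ref_idx(g$prec_levels)],
           precipitation = g$abundance[ref_idx(g$temp_levels), ])
  }
  # absence is judged per gradient: a component dropped from the model, or
  # whose predicted-abundance profile is flat along the inspected gradient,
  # shows no association there
  absent <- function(g, gradient)
    !g$retained || stats::sd(profile(g, gradient)) == 0
  pairs <- list(c("spatial", "temporal"), c("spatial", "residual"),
                c("temporal", "residual"))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("joint", "temperature", "precipitation"), function(gr) {
      ab <- c(absent(grids[[pr[1]]], gr), absent(grids[[pr[2]]], gr))
      if (all(ab)) {
        r <- 1; cls <- "both-absent"
      } else if (any(ab)) {
        r <- 0; cls <- "one-absent"
      } else {
        r <- spearman_rs(profile(grids[[pr[1]]], gr), profile(grids[[pr[2]]], gr))
        cls <- "both-retained"
      }
      data.frame(pair = paste(pr, collapse = "-"), gradient = gr,
                 r_s = r, class = cls)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "absent") <- vapply(grids, function(g)
    !g$retained || stats::sd(as.vector(g$abundance)) == 0, logical(1))
  class(out) <- c("correlation_summary", class(out))
  out
}

#' Classify a species' space-versus-time climate response
#'
#' Applies the rank-correlation rule to the spatial-temporal comparison
#' along the temperature gradient: `consistent` when r_s > 0.5 (the species
#' responds in the same direction to spatial and temporal temperature
#' variation), `opposite` when r_s < -0.5, `complex/none` in between,
#' `one-absent`/`both-absent` when a component was dropped, and
#' `indeterminate` when the correlation is undefined. A `cold`/`warm`
#' spatial-baseline label records whether the spatial grid's maximum
#' predicted abundance falls in the lower or upper half of the temperature
#' levels; cold-baseline consistent species are the set expected to be
#' immediately vulnerable to warming, cold-baseline opposite species the
#' initially resilient set.
#'
#' @param summary a `correlation_summary` from [correlate_components()].
#' @param spatial_grid the spatial [component_grid()].
#' @param threshold absolute rank-correlation threshold (default 0.5).
#' @return List of class `response_class`: `response`, `baseline`, `label`,
#'   and the `r_s` used.
#' @export
classify_response <- function(summary, spatial_grid, threshold = 0.5) {
  stopifnot(inherits(summary, "correlation_summary"),
            inherits(spatial_grid, "effect_grid"),
            spatial_grid$component == "spatial")
  row <- summary[summary$pair == "spatial-temporal" &
                   summary$gradient == "temperature", , drop = FALSE]
  r <- row$r_s
  response <- if (row$class == "one-absent") "one-absent"
  else if (row$class == "both-absent") "both-absent"
  else if (is.na(r)) "indeterminate"
  else if (r > threshold) "consistent"
  else if (r < -threshold) "opposite"
  else "complex/none"

  amax <- which(spatial_grid$abundance == max(spatial_grid$abundance),
                arr.ind = TRUE)[1L, ]
  baseline <- if (amax["row"] <= length(spatial_grid$temp_levels) / 2)
    "cold" else "warm"
  structure(list(response = response, baseline = baseline,
                 label = paste(response, baseline, sep = "-"), r_s = r),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("<response_class> %s (r_s = %s)\n", x$label,
              if (is.na(x$r_s)) "NA" else signif(x$r_s, 3)))
  invisible(x)
}

#' Within-sample predictive performance by country
#'
#' Pearson correlation between fitted local abundances (conditional modes
#' included) and observed counts, per country and pooled, with pass flags at
#' the screening thresholds (default r >= 0.4 in every country and r >= 0.5
#' pooled). Groups with zero count variance get `NA` and fail the screen.
#'
#' @param fit an `abundance_fit`.
#' @param md the `model_data` it was fitted to (with `country` in
#'   `frame_raw`).
#' @param threshold_country,threshold_pooled screening thresholds.
#' @return Data frame of class `performance_report`: `group`, `n`, `r`,
#'   `pass`; attribute `"pass_all"` gives the overall screen.
#' @export
performance_pearson <- function(fit, md, threshold_country = 0.4,
                                threshold_pooled = 0.5) {
  pred <- predict_mean(fit, md, include_random = TRUE)
  obs <- md$y
  grp <- md$frame_raw$country
  one <- function(idx, g, thr) {
    r <- if (stats::sd(obs[idx]) == 0 || stats::sd(pred[idx]) == 0) NA_real_
    else stats::cor(pred[idx], obs[idx])
    data.frame(group = g, n = sum(idx), r = r, pass = !is.na(r) && r >= thr)
  }
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g)
    one(grp == g, g, threshold_country)))
  out <- rbind(out, one(rep(TRUE, length(obs)), "pooled", threshold_pooled))
  attr(out, "pass_all") <- all(out$pass)
  class(out) <- c("performance_report", class(out))
  out
}

#' Leave-one-year-out cross-validation
#'
#' Refits the model once per survey year with that year held out and
#' computes the Pearson correlation between held-out counts and predictions.
#' Random effects enter at the conditional modes estimated from the training
#' years; routes absent from training predict at u = 0 (the population-level
#' prediction). Non-convergent refits are skipped with a warning.
#'
#' @param md `model_data` with response (>= 3 years).
#' @param family count family.
#' @param ... passed to [fit_abundance()].
#' @return Data frame `year`, `n`, `r`; attributes `"median_r"` and
#'   `"range_r"`.
#' @export
loyo_cv <- function(md, family, ...) {
  years <- sort(unique(md$frame_raw$year))
  if (length(years) < 3L) stop("need at least 3 years for leave-one-year-out CV")
  rows <- lapply(years, function(yr) {
    test <- md$frame_raw$year == yr
    fit <- tryCatch(fit_abundance(md_subset(md, !test), family = family,
                                  drop_aliased = TRUE, ...),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$convergence) {
      warning("refit without year ", yr, " failed; year skipped")
      return(NULL)
    }
    mdt <- md_subset(md, test)
    pred <- predict_mean(fit, mdt, include_random = TRUE)
    r <- if (stats::sd(mdt$y) == 0 || stats::sd(pred) == 0) NA_real_
    else stats::cor(pred, mdt$y)
    data.frame(year = yr, n = sum(test), r = r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no leave-one-year-out refit succeeded")
  attr(out, "median_r") <- stats::median(out$r, na.rm = TRUE)
  attr(out, "range_r") <- range(out$r, na.rm = TRUE)
  out
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}
#' {\sum_i z_i^2}, \quad z_i = x_i - \bar x, \; w_{ii} = 0,} with the
#' p-value from random permutations of the values over locations.
#'
#' @param values numeric vector (non-constant, length >= 2).
#' @param coords two-column matrix or data frame of coordinates, or a
#'   precomputed square weight matrix via `weights`.
#' @param weights optional weight matrix (diagonal ignored); otherwise
#'   inverse-distance weights 1/d with an optional `cutoff` beyond which
#'   weights are zero.
#' @param cutoff distance beyond which inverse-distance weights are zero.
#' @param nperm number of permutations (default 999).
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"`, or `"two.sided"`.
#' @param seed optional seed for the permutation draw.
#' @return List of class `morans_i`: `I`, `expected` (-1/(n-1)), `p_value`,
#'   `nperm`.
#' @export
morans_i <- function(values, coords = NULL, weights = NULL, cutoff = Inf,
                     nperm = 999L, alternative = c("greater", "less", "two.sided"),
                     seed = NULL) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 2L) stop("need at least 2 locations")
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  if (is.null(weights)) {
    if (is.null(coords)) stop("supply coords or weights")
    coords <- as.matrix(coords)
    D <- as.matrix(stats::dist(coords))
    if (any(D[upper.tri(D)] == 0))
      stop("duplicate coordinates give infinite inverse-distance weights")
    W <- 1 / D
    W[D > cutoff] <- 0
    diag(W) <- 0
  } else {
    W <- as.matrix(weights)
    stopifnot(nrow(W) == n, ncol(W) == n)
    diag(W) <- 0
  }
  s0 <- sum(W)
  if (s0 == 0) stop("all weights are zero")
  stat <- function(x) {
    z <- x - mean(x)
    (n / s0) * drop(crossprod(z, W %*% z)) / sum(z^2)
  }
  I <- stat(values)
  if (!is.null(seed)) set.seed(seed)
  Ip <- vapply(seq_len(nperm), function(i) stat(sample(values)), numeric(1))
  p <- switch(alternative,
              greater = (1 + sum(Ip >= I)) / (nperm + 1),
              less = (1 + sum(Ip <= I)) / (nperm + 1),
              two.sided = {
                e <- -1 / (n - 1)
                (1 + sum(abs(Ip - e) >= abs(I - e))) / (nperm + 1)
              })
  structure(list(I = I, expected = -1 / (n - 1), p_value = p, nperm = nperm),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), permutation p = %.4g (%d perms)\n",
              x$I, x$expected, x$p_value, x$nperm))
  invisible(x)
}

#' Write effect grids and correlations as tidy CSV
#'
#' @param grids named list of [component_grid()]s.
#' @param summary a `correlation_summary`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_assessment <- function(grids, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- do.call(rbind, lapply(grids, function(g) {
    data.frame(component = g$component,
               temperature = rep(g$temp_levels, times = length(g$prec_levels)),
               precipitation = rep(g$prec_levels, each = length(g$temp_levels)),
               abundance = as.vector(g$abundance),
               retained = g$retained)
  }))
  utils::write.csv(tidy, file.path(dir, "effect_grids.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(summary), file.path(dir, "component_correlations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
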