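#' Decompose a climate cube into spatial, temporal and residual components
#'
#' Splits centered breeding-season climate into three additive components.
#' With cells \eqn{i = 1, \dots, N} and centering years \eqn{t = 1, \dots, T}:
#' the global mean is the average of the raw values over all cells and
#' centering years; the centered value is \eqn{CC_{i,t} = C_{i,t} - }global
#' mean; the spatial component is the per-cell long-term mean
#' \eqn{CCSpace_i = \sum_t CC_{i,t} / T}; the temporal component is the
#' per-year all-cell mean \eqn{CCTime_t = \sum_i CC_{i,t} / N}, exposed for
#' the study years; and the residual (spatiotemporal) component is
#' \eqn{CCResidual_{i,t} = CC_{i,t} - CCSpace_i - CCTime_t}, again for the
#' study years. Centering over the full period makes the spatial component
#' sum to zero over cells and the residual average to zero over cells within
#' each year.
#'
#' @param cube a [climate_cube()]; all values inside the centering window must
#'   be observed (missing cells there are an error, no imputation is done).
#' @param study_years inclusive length-2 year range for which the temporal and
#'   residual components are returned; must lie within the cube's years.
#'   Defaults to the cube's centering years.
#'
#' @return An object of class `decomposed_climate` with elements
#'   `global_mean` (scalar, variable units), `spatial` (named per-cell
#'   vector), `temporal` (named per-study-year vector), `residual`
#'   (cell x study-year matrix), `study_years`, `centering_years`, `cells`,
#'   `variable`, and `season_window`. The full centered matrix over all cube
#'   years is kept in `centered_all` so that lagged views ([lag_components()])
#'   can reach years before the study period.
#' @export
decompose_climate <- function(cube, study_years = cube$centering_years) {
  stopifnot(inherits(cube, "climate_cube"))
  study_years <- as.integer(study_years)
  if (length(study_years) != 2L || study_years[1] > study_years[2])
    stop("`study_years` must be an increasing length-2 range")
  sy <- seq(study_years[1], study_years[2])
  if (!all(sy %in% cube$years)) stop("study_years outside the cube's years")
  cy <- seq(cube$centering_years[1], cube$centering_years[2])
  cidx <- match(cy, cube$years)
  if (any(cube$missing[, cidx]))
    stop("missing values inside the centering window; the decomposition ",
         "requires a complete grid there")

  vals_c <- cube$values[, cidx, drop = FALSE]
  global_mean <- mean(vals_c)
  centered_all <- cube$values - global_mean
  spatial <- rowMeans(vals_c) - global_mean
  names(spatial) <- cube$cells$cell_id

  temporal_all <- colMeans(centered_all)          # per cube year
  names(temporal_all) <- cube$years
  sidx <- match(sy, cube$years)
  temporal <- temporal_all[sidx]
  names(temporal) <- sy

  residual <- centered_all[, sidx, drop = FALSE] -
    outer(spatial, rep(1, length(sy))) -
    outer(rep(1, length(spatial)), temporal)
  dimnames(residual) <- list(cube$cells$cell_id, sy)

  structure(
    list(global_mean = global_mean, spatial = spatial, temporal = temporal,
         residual = residual, study_years = study_years,
         centering_years = cube$centering_years, cells = cube$cells,
         variable = cube$variable, season_window = cube$season_window,
         lag = 0L, centered_all = centered_all, all_years = cube$years,
         temporal_all = temporal_all),
    class = "decomposed_climate")
}

#' @export
print.decomposed_climate <- function(x, ...) {
  cat(sprintf(
    "<decomposed_climate> %s [%s], %d cells, study %d-%d, lag %d\n  global mean %.4g; spatial range [%.3g, %.3g]; temporal sd %.3g\n",
    x$variable, x$season_window, length(x$spatial),
    x$study_years[1], x$study_years[2], x$lag,
    x$global_mean, min(x$spatial), max(x$spatial), stats::sd(x$temporal)))
  invisible(x)
}

#' Reconstruct raw climate values from a decomposition
#'
#' Inverse of [decompose_climate()] on the study years: global mean +
#' spatial + temporal + residual.
#'
#' @param d a `decomposed_climate` object.
#' @return cell x study-year matrix of raw values.
#' @export
reconstruct <- function(d) {
  stopifnot(inherits(d, "decomposed_climate"))
  sy <- seq(d$study_years[1], d$study_years[2])
  out <- d$global_mean +
    outer(d$spatial, rep(1, length(sy))) +
    outer(rep(1, length(d$spatial)), d$temporal) +
    d$residual
  dimnames(out) <- dimnames(d$residual)
  out
}

#' Lagged view of a climate decomposition
#'
#' Returns a decomposition in which the temporal and residual components read
#' from `lag` years earlier, so that a route-year (r, t) is paired with the
#' anomalies of year t - lag (settlement and recruitment may track the
#' previous season's conditions). The spatial component, a long-term mean, is
#' unchanged. Study years whose lagged source year is unavailable are dropped
#' and their count recorded in attribute `"dropped_years"`.
#'
#' @param d a `decomposed_climate` object with `lag == 0`.
#' @param lag non-negative integer number of years.
#' @return A `decomposed_climate` whose `temporal`/`residual` entries for year
#'   t hold the values of year t - lag. `lag = 0` returns `d` unchanged.
#' @export
lag_components <- function(d, lag = 1L) {
  stopifnot(inherits(d, "decomposed_climate"))
  lag <- as.integer(lag)
  if (lag < 0L) stop("`lag` must be >= 0")
  if (lag == 0L) return(d)
  if (d$lag != 0L) stop("`d` is already lagged")
  sy <- seq(d$study_years[1], d$study_years[2])
  src <- sy - lag
  ok <- src %in% d$all_years
  dropped <- sum(!ok)
  if (!any(ok)) stop("no study year has lagged data available")
  sy <- sy[ok]; src <- src[ok]

  si <- match(src, d$all_years)
  temporal <- d$temporal_all[si]
  names(temporal) <- sy
  residual <- d$centered_all[, si, drop = FALSE] -
    outer(d$spatial, rep(1, length(sy))) -
    outer(rep(1, length(d$spatial)), d$temporal_all[si])
  dimnames(residual) <- list(d$cells$cell_id, sy)

  out <- d
  out$temporal <- temporal
  out$residual <- residual
  out$study_years <- range(sy)
  out$lag <- lag
  attr(out, "dropped_years") <- dropped
  out
}

#' Write decomposition components as CSV plus a JSON header
#'
#' Writes `spatial.csv` (cell_id, value), `temporal.csv` (year, value),
#' `residual.csv` (cell_id, year, value) and `header.json` (global mean,
#' variable, windows) under `dir`.
#'
#' @param d a `decomposed_climate`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(d, dir) {
  stopifnot(inherits(d, "decomposed_climate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(cell_id = names(d$spatial), value = unname(d$spatial)),
                   file.path(dir, "spatial.csv"), row.names = FALSE)
  utils::write.csv(data.frame(year = as.integer(names(d$temporal)),
                              value = unname(d$temporal)),
                   file.path(dir, "temporal.csv"), row.names = FALSE)
  res <- data.frame(
    cell_id = rep(rownames(d$residual), times = ncol(d$residual)),
    year = rep(as.integer(colnames(d$residual)), each = nrow(d$residual)),
    value = as.vector(d$residual))
  utils::write.csv(res, file.path(dir, "residual.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(variable = d$variable, season_window = d$season_window,
         global_mean = d$global_mean,
         centering_years = d$centering_years, study_years = d$study_years,
         lag = d$lag),
    file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
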