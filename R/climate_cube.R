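#' Construct a gridded seasonal climate cube
#'
#' A climate cube holds one breeding-season value per grid cell and year for a
#' single climate variable, together with the metadata needed to decompose it:
#' cell coordinates, the season window the values summarize, and the year
#' range used for long-term centering.
#'
#' @param values numeric matrix, cells in rows and years in columns. Row names
#'   (if any) are ignored; cells are identified through `cells$cell_id`.
#' @param cells data frame with columns `cell_id`, `x`, `y` (grid coordinates,
#'   1-km cell semantics). One row per row of `values`.
#' @param years integer vector of years, one per column of `values`, strictly
#'   increasing.
#' @param variable `"temperature"` (degrees C) or `"precipitation"` (mm).
#' @param season_window label of the seasonal aggregation window, e.g.
#'   `"may-jul"` or `"may-jun"`.
#' @param centering_years length-2 integer vector, inclusive year range over
#'   which the global mean and the per-cell long-term means are computed.
#'   Must be a subset of `years`. Defaults to the full range of `years`.
#' @param missing optional logical matrix marking cells-years to be treated as
#'   missing. Values outside the mask must be finite.
#'
#' @return An object of class `climate_cube`.
#' @seealso [decompose_climate()], [seasonal_aggregate()], [generate_climate()]
#' @export
climate_cube <- function(values, cells, years,
                         variable = c("temperature", "precipitation"),
                         season_window = "may-jul",
                         centering_years = range(years),
                         missing = NULL) {
  variable <- match.arg(variable)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (nrow(cells) != nrow(values))
    stop("`cells` must have one row per row of `values`")
  if (!all(c("cell_id", "x", "y") %in% names(cells)))
    stop("`cells` needs columns cell_id, x, y")
  if (anyDuplicated(cells$cell_id)) stop("duplicated cell_id")
  years <- as.integer(years)
  if (length(years) != ncol(values)) stop("one year per column required")
  if (is.unsorted(years, strictly = TRUE)) stop("`years` must be strictly increasing")
  centering_years <- as.integer(centering_years)
  if (length(centering_years) != 2L || centering_years[1] > centering_years[2])
    stop("`centering_years` must be an increasing length-2 range")
  cy <- seq(centering_years[1], centering_years[2])
  if (!all(cy %in% years))
    stop("centering_years must lie within the cube's years")
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(values), ncol(values))
  } else {
    missing <- as.matrix(missing)
    stopifnot(identical(dim(missing), dim(values)))
  }
  if (any(!is.finite(values[!missing])))
    stop("non-finite values outside the missing mask")
  structure(
    list(values = values, cells = as.data.frame(cells), years = years,
         variable = variable, season_window = season_window,
         centering_years = centering_years, missing = missing),
    class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  cat(sprintf("<climate_cube> %s [%s], %d cells x %d years (%d-%d), centering %d-%d\n",
              x$variable, x$season_window, nrow(x$values), length(x$years),
              min(x$years), max(x$years),
              x$centering_years[1], x$centering_years[2]))
  invisible(x)
}

#' Aggregate daily climate series to breeding-season values
#'
#' Collapses per-cell daily climate records to one value per cell and year:
#' the mean over the window for temperature and the cumulative sum for
#' precipitation, following the usual treatment of breeding-season climate.
#'
#' @param daily data frame with columns `cell_id`, `x`, `y`, `year`, `month`,
#'   `value` holding daily (or any sub-seasonal) records. Multiple rows per
#'   cell-year-month are allowed and enter the statistic individually.
#' @param window month window, `"may-jul"` (months 5-7) or `"may-jun"` (5-6).
#' @param statistic `"mean"` (temperature) or `"sum"` (precipitation).
#' @param variable variable label for the resulting cube; defaults to
#'   `"temperature"` for `statistic = "mean"` and `"precipitation"` otherwise.
#' @param centering_years passed to [climate_cube()]; defaults to all years
#'   present.
#'
#' @details Every cell must cover every month of the window in every year it
#'   appears in; incomplete coverage is an error listing the offending
#'   cell-years (no silent imputation).
#'
#' @return A [climate_cube()].
#' @export
seasonal_aggregate <- function(daily, window = c("may-jul", "may-jun"),
                               statistic = c("mean", "sum"),
                               variable = NULL, centering_years = NULL) {
  window <- match.arg(window)
  statistic <- match.arg(statistic)
  months <- if (window == "may-jul") 5:7 else 5:6
  need <- c("cell_id", "x", "y", "year", "month", "value")
  if (!all(need %in% names(daily))) stop("`daily` needs columns ", paste(need, collapse = ", "))
  d <- daily[daily$month %in% months, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records inside the requested window")

  # every cell-year must cover all window months
  cov <- unique(d[c("cell_id", "year", "month")])
  n_m <- stats::aggregate(month ~ cell_id + year, cov, FUN = length)
  bad <- n_m[n_m$month < length(months), , drop = FALSE]
  if (nrow(bad) > 0L)
    stop("incomplete window coverage for cell-years: ",
         paste(sprintf("%s/%d", bad$cell_id[seq_len(min(5, nrow(bad)))],
                       bad$year[seq_len(min(5, nrow(bad)))]), collapse = ", "),
         if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5L) else "")

  agg <- stats::aggregate(value ~ cell_id + year, d,
                          FUN = if (statistic == "mean") mean else sum)
  cells <- unique(d[c("cell_id", "x", "y")])
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  years <- sort(unique(agg$year))
  values <- matrix(NA_real_, nrow(cells), length(years),
                   dimnames = list(NULL, years))
  ri <- match(agg$cell_id, cells$cell_id)
  ci <- match(agg$year, years)
  values[cbind(ri, ci)] <- agg$value
  miss <- is.na(values)
  if (is.null(variable))
    variable <- if (statistic == "mean") "temperature" else "precipitation"
  if (is.null(centering_years)) centering_years <- range(years)
  climate_cube(ifelse(miss, 0, values), cells, years, variable = variable,
               season_window = window, centering_years = centering_years,
               missing = miss)
}

#' Read or write a climate cube as long-format CSV
#'
#' The on-disk format is one row per cell and year with columns
#' `cell_id, x, y, year, value`.
#'
#' @param path CSV file path.
#' @param ... metadata passed on to [climate_cube()] (`variable`,
#'   `season_window`, `centering_years`).
#' @return `read_climate_csv()` returns a [climate_cube()];
#'   `write_climate_csv()` returns `path` invisibly.
#' @export
read_climate_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "x", "y", "year", "value")
  if (!all(need %in% names(d))) stop("CSV needs columns ", paste(need, collapse = ", "))
  cells <- unique(d[c("cell_id", "x", "y")])
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  years <- sort(unique(d$year))
  values <- matrix(NA_real_, nrow(cells), length(years))
  values[cbind(match(d$cell_id, cells$cell_id), match(d$year, years))] <- d$value
  miss <- is.na(values)
  climate_cube(ifelse(miss, 0, values), cells, years, missing = miss, ...)
}

#' @rdname read_climate_csv
#' @param cube a [climate_cube()].
#' @export
write_climate_csv <- function(cube, path) {
  stopifnot(inherits(cube, "climate_cube"))
  long <- data.frame(
    cell_id = rep(cube$cells$cell_id, times = length(cube$years)),
    x = rep(cube$cells$x, times = length(cube$years)),
    y = rep(cube$cells$y, times = length(cube$years)),
    year = rep(cube$years, each = nrow(cube$values)),
    value = as.vector(cube$values))
  long <- long[!as.vector(cube$missing), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
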