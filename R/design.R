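#' Assemble model-ready design matrices from routes and decomposed climate
#'
#' Joins the six decomposed climate covariates (spatial/temporal/residual x
#' temperature/precipitation) onto the route-year table, adds the three
#' component-wise temperature x precipitation interactions, a second-order
#' year polynomial (centered and scaled for numerical stability), the Survey
#' (Point vs Line) and Unit (Pair vs Individual) contrasts, habitat
#' covariates, and the log-effort offset. The zero-inflation design is
#' identical except that it omits Survey and Unit, which affect how many
#' birds are counted but not whether zeros are recorded.
#'
#' Continuous covariates (climate and habitat) are z-scored by default and
#' the constants stored so that prediction grids can be expressed on the
#' original scale; interactions are products of the standardized mains.
#'
#' @param routes route(-survey)-year table as produced by [generate_routes()]
#'   (optionally with a `count` column, carried into the result as the
#'   response).
#' @param decomp_temp,decomp_prec `decomposed_climate` objects (unlagged).
#' @param lag 0 or 1: with `lag = 1` the temporal and residual components for
#'   a route-year (r, t) are read from year t - 1; route-years whose lagged
#'   year is unavailable are dropped and counted.
#' @param habitat character vector of habitat covariate column names in
#'   `routes` to include (e.g. `"slope"`, `"lc_wetlands"`).
#' @param standardize z-score climate and habitat covariates (default TRUE).
#' @param scaling optional stored scaling constants from a previous assembly
#'   (list of `mean`/`sd` per column), reused instead of recomputing; used
#'   when predicting onto new data.
#'
#' @return An object of class `model_data`: list with `y` (counts or NULL),
#'   `X` (count-part design), `Xzi` (zero-inflation design), `offset`
#'   (log effort), `route` (factor; paired Point/Line surveys of one route
#'   share a level), `frame_raw` (the retained input rows), and `info`
#'   (climate column names and raw component ranges, scaling constants, year
#'   basis, lag, number of dropped route-years).
#' @export
assemble_design <- function(routes, decomp_temp, decomp_prec, lag = 0L,
                            habitat = "slope", standardize = TRUE,
                            scaling = NULL) {
  stopifnot(inherits(decomp_temp, "decomposed_climate"),
            inherits(decomp_prec, "decomposed_climate"))
  need <- c("route_id", "cell_id", "survey", "unit", "year", "effort")
  if (!all(need %in% names(routes)))
    stop("routes needs columns ", paste(need, collapse = ", "))
  if (!all(habitat %in% names(routes)))
    stop("habitat covariate(s) not in routes: ",
         paste(setdiff(habitat, names(routes)), collapse = ", "))
  if (any(routes$effort <= 0)) stop("zero or negative survey effort")

  dt <- if (lag > 0) lag_components(decomp_temp, lag) else decomp_temp
  dp <- if (lag > 0) lag_components(decomp_prec, lag) else decomp_prec

  avail_years <- as.integer(names(dt$temporal))
  keep <- routes$year %in% avail_years
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " route-year(s) dropped: no lagged climate available")
  fr <- routes[keep, , drop = FALSE]
  if (nrow(fr) == 0L) stop("no route-years with climate available")

  climate_of <- function(d, prefix) {
    ci <- match(fr$cell_id, names(d$spatial))
    if (anyNA(ci)) {
      bad <- fr[is.na(ci), c("route_id", "year")]
      stop("no ", prefix, " climate for route-year(s): ",
           paste(sprintf("%s/%d", bad$route_id, bad$year)[seq_len(min(5, nrow(bad)))],
                 collapse = ", "))
    }
    yi <- match(as.character(fr$year), colnames(d$residual))
    out <- data.frame(
      spatial = unname(d$spatial[ci]),
      temporal = unname(d$temporal[match(as.character(fr$year), names(d$temporal))]),
      residual = d$residual[cbind(ci, yi)])
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  ct <- climate_of(dt, "temp")
  cp <- climate_of(dp, "prec")

  climate_cols <- c("temp_spatial", "temp_temporal", "temp_residual",
                    "prec_spatial", "prec_temporal", "prec_residual")
  raw <- cbind(ct, cp)[climate_cols]
  hab <- fr[, habitat, drop = FALSE]
  cont <- cbind(raw, hab)
  if (any(!is.finite(as.matrix(cont)))) {
    bad <- which(!stats::complete.cases(cont) |
                   !apply(is.finite(as.matrix(cont)), 1, all))[1]
    stop("missing covariate for route-year ", fr$route_id[bad], "/", fr$year[bad])
  }

  # year polynomial basis: centered/scaled year, then centered/scaled square
  if (is.null(scaling)) {
    ym <- mean(fr$year); ys <- stats::sd(fr$year); if (is.na(ys) || ys == 0) ys <- 1
    y1 <- (fr$year - ym) / ys
    q <- y1^2
    qm <- mean(q); qs <- stats::sd(q); if (is.na(qs) || qs == 0) qs <- 1
    year_basis <- list(mean = ym, sd = ys, q_mean = qm, q_sd = qs)
  } else {
    year_basis <- scaling$year_basis
    y1 <- (fr$year - year_basis$mean) / year_basis$sd
    q <- y1^2
  }
  y2 <- (q - year_basis$q_mean) / year_basis$q_sd

  # z-scoring of climate + habitat
  if (is.null(scaling)) {
    if (standardize) {
      mns <- colMeans(cont)
      sds <- apply(cont, 2, stats::sd)
      sds[!is.finite(sds) | sds == 0] <- 1
    } else {
      mns <- stats::setNames(rep(0, ncol(cont)), names(cont))
      sds <- stats::setNames(rep(1, ncol(cont)), names(cont))
    }
  } else {
    mns <- scaling$mean; sds <- scaling$sd
    standardize <- scaling$standardize
  }
  Z <- sweep(sweep(as.matrix(cont), 2, mns[names(cont)], "-"),
             2, sds[names(cont)], "/")

  inter <- cbind(
    txp_spatial = Z[, "temp_spatial"] * Z[, "prec_spatial"],
    txp_temporal = Z[, "temp_temporal"] * Z[, "prec_temporal"],
    txp_residual = Z[, "temp_residual"] * Z[, "prec_residual"])

  X <- cbind("(Intercept)" = 1, Z[, climate_cols, drop = FALSE], inter,
             year_lin = y1, year_quad = y2)
  if (length(unique(fr$survey)) > 1L)
    X <- cbind(X, surveyPoint = as.numeric(fr$survey == "Point"))
  if (length(unique(fr$unit)) > 1L)
    X <- cbind(X, unitPair = as.numeric(fr$unit == "Pair"))
  if (length(habitat) > 0)
    X <- cbind(X, Z[, habitat, drop = FALSE])

  zi_cols <- setdiff(colnames(X), c("surveyPoint", "unitPair"))
  Xzi <- X[, zi_cols, drop = FALSE]

  ranges <- list(
    temp = list(spatial = range(dt$spatial), temporal = range(dt$temporal),
                residual = range(dt$residual)),
    prec = list(spatial = range(dp$spatial), temporal = range(dp$temporal),
                residual = range(dp$residual)))

  structure(
    list(y = if ("count" %in% names(fr)) fr$count else NULL,
         X = X, Xzi = Xzi, offset = log(fr$effort),
         route = factor(fr$route_id), frame_raw = fr,
         info = list(climate_cols = climate_cols, habitat = habitat,
                     scaling = list(mean = mns, sd = sds,
                                    standardize = standardize,
                                    year_basis = year_basis),
                     ranges = ranges, lag = lag, dropped = dropped)),
    class = "model_data")
}

#' @export
print.model_data <- function(x, ...) {
  cat(sprintf("<model_data> %d route-years, %d routes, %d count-part columns%s\n",
              nrow(x$X), nlevels(x$route), ncol(x$X),
              if (is.null(x$y)) " (no response)" else ""))
  invisible(x)
}

#' Row subset of assembled model data
#'
#' Used by cross-validation to split an assembled design without
#' recomputing standardization constants (the training constants stay in
#' force for held-out predictions).
#'
#' @param md a `model_data` object.
#' @param idx logical or integer row index.
#' @return A `model_data` with the selected rows; route factor levels are
#'   kept so train/test splits share the random-effect indexing.
#' @export
md_subset <- function(md, idx) {
  stopifnot(inherits(md, "model_data"))
  out <- md
  out$y <- md$y[idx]
  out$X <- md$X[idx, , drop = FALSE]
  out$Xzi <- md$Xzi[idx, , drop = FALSE]
  out$offset <- md$offset[idx]
  out$route <- md$route[idx]   # levels preserved
  out$frame_raw <- md$frame_raw[idx, , drop = FALSE]
  out
}
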