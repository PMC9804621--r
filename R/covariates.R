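#' Land-cover class pooling table
#'
#' Returns the editable mapping from the 44 European land-cover classes to
#' the seven pooled habitat categories used as covariates (sparsely vegetated
#' mountain areas; mountain vegetation; deciduous forest; other forest;
#' wetlands; inland waters; agriculture) plus `other_sea` for everything
#' else. Shipped as a CSV under `extdata` so users can supply their own.
#'
#' @param path optional path to an alternative mapping CSV with columns
#'   `class_code`, `class_name`, `pooled_category`.
#' @return Data frame with one row per land-cover class.
#' @export
landcover_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "corine_pooling.csv", package = "climdecomp")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Construct a categorical land-cover raster
#'
#' @param codes integer matrix of land-cover class codes (rows = y, cols = x).
#' @param epoch map epoch year, one of 2000, 2006, 2012, 2018.
#' @param cell_size cell edge length in metres.
#' @return A `landcover_map` object.
#' @export
landcover_map <- function(codes, epoch, cell_size = 100) {
  if (!epoch %in% c(2000, 2006, 2012, 2018))
    stop("epoch must be one of 2000, 2006, 2012, 2018")
  structure(list(codes = as.matrix(codes), epoch = as.integer(epoch),
                 cell_size = cell_size, pooled = FALSE),
            class = "landcover_map")
}

#' Pool land-cover classes into the seven habitat categories
#'
#' Replaces class codes by pooled category labels using [landcover_table()].
#' Every code must map to exactly one category; an unmapped code is an error
#' naming the code.
#'
#' @param map a [landcover_map()].
#' @param table mapping table, defaults to [landcover_table()].
#' @return A `landcover_map` whose `codes` matrix holds category labels.
#' @export
pool_landcover <- function(map, table = landcover_table()) {
  stopifnot(inherits(map, "landcover_map"))
  if (map$pooled) return(map)
  codes <- map$codes
  idx <- match(codes, table$class_code)
  if (anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop("unmapped land-cover code(s): ", paste(bad, collapse = ", "))
  }
  out <- map
  out$codes <- matrix(table$pooled_category[idx], nrow(codes), ncol(codes))
  out$pooled <- TRUE
  out
}

#' Match a survey year to a land-cover map epoch
#'
#' Survey years are assigned to the nearest land-cover mapping epoch:
#' 1996-2003 to the 2000 map, 2004-2009 to 2006, 2010-2015 to 2012, and
#' 2016-2018 to 2018.
#'
#' @param year survey year (vectorized).
#' @param range_years allowed inclusive year range.
#' @return Integer vector of epoch years.
#' @export
match_epoch <- function(year, range_years = c(1996, 2018)) {
  year <- as.integer(year)
  if (any(year < range_years[1] | year > range_years[2]))
    stop("year outside ", range_years[1], "-", range_years[2])
  epoch <- ifelse(year <= 2003, 2000L,
           ifelse(year <= 2009, 2006L,
           ifelse(year <= 2015, 2012L, 2018L)))
  epoch
}

#' Summarize a raster within buffers around route geometry
#'
#' Computes per-route summaries within circular buffers of radius `radius`
#' around each geometry point (point-count stations, or the cell centers of a
#' transect line). Membership is by cell center falling inside the union of
#' the buffers (no partial-cell area weighting). A numeric raster is
#' summarized by its mean; a pooled categorical land-cover raster by the
#' proportion of member cells in each of the seven habitat categories
#' (proportions sum to at most 1; `other_sea` cells count in the denominator
#' only).
#'
#' @param map a [landcover_map()] (pooled, for proportions) or a numeric
#'   matrix (with `cell_size` attr or the `cell_size` argument) for means.
#'   Cell (i, j) has its center at ((j - 0.5), (i - 0.5)) * cell_size.
#' @param geometry data frame with columns `x`, `y` in metres.
#' @param radius buffer radius in metres (default 300).
#' @param cell_size cell size for plain-matrix input.
#' @return For categorical input, a named numeric vector of the seven
#'   category proportions; for numeric input, the buffer mean.
#' @export
summarize_buffer <- function(map, geometry, radius = 300, cell_size = NULL) {
  if (inherits(map, "landcover_map")) {
    if (!map$pooled) stop("pool the land-cover map first (pool_landcover)")
    vals <- map$codes
    cs <- map$cell_size
    categorical <- TRUE
  } else {
    vals <- as.matrix(map)
    cs <- if (!is.null(cell_size)) cell_size else attr(map, "cell_size")
    if (is.null(cs)) stop("cell_size required for matrix input")
    categorical <- is.character(vals)
  }
  if (!all(c("x", "y") %in% names(geometry))) stop("geometry needs x and y")
  nr <- nrow(vals); nc <- ncol(vals)
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * cs
  cy <- (rep(seq_len(nr), times = nc) - 0.5) * cs
  member <- rep(FALSE, nr * nc)
  for (k in seq_len(nrow(geometry))) {
    member <- member |
      ((cx - geometry$x[k])^2 + (cy - geometry$y[k])^2 <= radius^2)
  }
  if (!any(member)) stop("buffer does not intersect the raster")
  v <- as.vector(vals)[member]
  if (!categorical) return(mean(v))
  cats <- c("sparse_mountain", "mountain_vegetation", "deciduous_forest",
            "other_forest", "wetlands", "inland_waters", "agriculture")
  prop <- vapply(cats, function(cat) mean(v == cat), numeric(1))
  prop
}

#' Variance inflation factors for a set of design columns
#'
#' Regresses each covariate on all the others and reports
#' VIF_j = 1 / (1 - R^2_j). Exactly collinear columns get an infinite VIF and
#' a flag rather than an error, matching the screening use (covariates with
#' VIF at or above the threshold are flagged for removal; the conventional
#' screen keeps all VIFs below 4).
#'
#' @param X numeric matrix or data frame of covariates (>= 2 columns, more
#'   rows than columns).
#' @param threshold flagging threshold (default 4).
#' @return Data frame of class `collinearity_report` with columns
#'   `covariate`, `vif`, `flagged`.
#' @export
compute_vif <- function(X, threshold = 4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least two covariates")
  if (nrow(X) <= ncol(X)) stop("need more observations than covariates")
  p <- ncol(X)
  vif <- numeric(p)
  for (j in seq_len(p)) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Zj, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) { vif[j] <- Inf; next }
    r2 <- 1 - ssr / sst
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out <- data.frame(covariate = colnames(X), vif = vif,
                    flagged = !is.finite(vif) | vif >= threshold)
  class(out) <- c("collinearity_report", class(out))
  attr(out, "threshold") <- threshold
  out
}
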