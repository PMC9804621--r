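# parameter packing: beta | gamma (zi) | log_theta (nb) | log_sigma (ranef)
.unpack <- function(par, p, q, nb, ranef) {
  i <- p
  beta <- par[seq_len(p)]
  gamma <- NULL; log_theta <- NULL; log_sigma <- NULL
  if (q > 0) { gamma <- par[i + seq_len(q)]; i <- i + q }
  if (nb) { log_theta <- par[i + 1L]; i <- i + 1L }
  if (ranef) log_sigma <- par[i + 1L]
  list(beta = beta, gamma = gamma, log_theta = log_theta, log_sigma = log_sigma)
}

#' Fit a count mixed model by maximum marginal likelihood
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood
#' ([marginal_loglik()]) over the count-part coefficients, the
#' zero-inflation coefficients (zip/zinb), log dispersion (nb/zinb) and the
#' log route random-intercept SD, using quasi-Newton (BFGS) with analytic
#' gradients on the unconstrained transforms, warm-started conditional
#' modes, and jittered restarts on failure. Standard errors come from the
#' numerically differentiated Hessian at the optimum.
#'
#' @param md a `model_data` with response ([assemble_design()]).
#' @param family `"poisson"`, `"nb"`, `"zip"`, or `"zinb"`.
#' @param order quadrature order (default 7; 1 = Laplace).
#' @param sigma_fixed optional fixed value for the random-intercept SD;
#'   `sigma_fixed = 0` drops the random effect entirely (fixed-effect GLM).
#' @param start optional named list of starting values (`beta`, `gamma`,
#'   `theta`, `sigma_u`).
#' @param restarts maximum number of jittered restarts after a failed fit.
#' @param control passed to [stats::optim()] (merged over defaults).
#' @param drop_aliased drop exactly collinear design columns (QR pivoting)
#'   instead of erroring; used by resampling loops where a subset can lose a
#'   level or alias the year polynomial.
#' @param hessian compute the Hessian-based covariance and standard errors
#'   (skipped by the AIC-only selection loops).
#' @return An object of class `abundance_fit`: coefficient vectors `beta`
#'   and `gamma`, `theta`, `sigma_u`, per-route conditional modes `u_modes`,
#'   `loglik`, `aic`, parameter count `k`, `vcov` and `se` for all fitted
#'   parameters, and a `convergence` flag. Downstream functions refuse
#'   non-converged fits unless overridden.
#' @export
fit_abundance <- function(md, family = c("poisson", "nb", "zip", "zinb"),
                          order = 7L, sigma_fixed = NULL, start = NULL,
                          restarts = 5L, control = list(),
                          drop_aliased = FALSE, hessian = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(md, "model_data"))
  if (is.null(md$y)) stop("model_data has no response")
  y <- md$y
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  qrX <- qr(md$X)
  if (qrX$rank < ncol(md$X)) {
    if (!drop_aliased)
      stop("count-part design is rank deficient (collinear or duplicated columns)")
    keep <- colnames(md$X)[qrX$pivot[seq_len(qrX$rank)]]
    md <- .md_drop_cols(md, setdiff(colnames(md$X), keep))
  }
  X <- md$X; Xzi <- md$Xzi
  zi <- family %in% .zi_families
  nb <- family %in% .nb_families
  ranef <- is.null(sigma_fixed)
  if (!ranef && sigma_fixed != 0)
    stop("only sigma_fixed = 0 (no random effect) is supported")
  if (ranef && nlevels(md$route) < 2L) stop("need >= 2 routes for a random intercept")
  p <- ncol(X); q <- if (zi) ncol(Xzi) else 0L

  # starting values: Poisson IRLS for beta; moment-style theta; small sigma
  b0 <- if (!is.null(start$beta)) start$beta else {
    g <- suppressWarnings(stats::glm.fit(X, y, offset = md$offset,
                                         family = stats::poisson()))
    co <- g$coefficients; co[!is.finite(co)] <- 0
    co
  }
  par <- b0
  if (zi) {
    g0 <- if (!is.null(start$gamma)) start$gamma else {
      mu0 <- exp(drop(X %*% b0) + md$offset)
      excess <- max(0.02, min(0.9, mean(y == 0) - mean(exp(-mu0))))
      c(stats::qlogis(excess), rep(0, q - 1L))
    }
    par <- c(par, g0)
  }
  if (nb) {
    th0 <- if (!is.null(start$theta)) start$theta else {
      mu0 <- exp(drop(X %*% b0) + md$offset)
      ex <- mean((y - mu0)^2 - mu0)
      if (is.finite(ex) && ex > 0) max(0.1, min(20, mean(mu0^2) / ex)) else 1
    }
    par <- c(par, log(th0))
  }
  if (ranef) par <- c(par, log(if (!is.null(start$sigma_u)) start$sigma_u else 0.3))

  u_cache <- new.env(parent = emptyenv())
  u_cache$u <- NULL
  fn <- function(pv) {
    pl <- .unpack(pv, p, q, nb, ranef)
    r <- tryCatch(.marginal_core(pl, md, family, order, u0 = u_cache$u,
                                 want_grad = FALSE),
                  error = function(e) NULL)
    if (is.null(r) || !is.finite(r$nll)) return(1e10)
    u_cache$u <- r$u
    r$nll
  }
  gr <- function(pv) {
    pl <- .unpack(pv, p, q, nb, ranef)
    r <- tryCatch(.marginal_core(pl, md, family, order, u0 = u_cache$u,
                                 want_grad = TRUE),
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r$grad))) return(rep(0, length(pv)))
    u_cache$u <- r$u
    r$grad
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  best <- NULL
  converged <- FALSE
  set.seed(sum(utils::head(y, 100)) %% 100000L + 7L)  # deterministic jitter
  for (attempt in 0:restarts) {
    pv <- if (attempt == 0) par else par + stats::rnorm(length(par), 0, 0.25)
    u_cache$u <- NULL
    opt <- tryCatch(stats::optim(pv, fn, gr, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (opt$convergence == 0) { best <- if (opt$value <= best$value) opt else best
      converged <- TRUE; break }
  }
  if (is.null(best)) stop("all optimizer attempts failed for family ", family)

  pl <- .unpack(best$par, p, q, nb, ranef)
  final <- .marginal_core(pl, md, family, order, want_grad = TRUE)
  H <- if (hessian)
    tryCatch(stats::optimHess(best$par, fn, gr), error = function(e) NULL)
  else NULL
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(best$par))

  nm <- colnames(X)
  nmz <- if (zi) paste0("zi_", colnames(Xzi)) else character()
  pn <- c(nm, nmz, if (nb) "log_theta" else NULL, if (ranef) "log_sigma" else NULL)
  names(best$par) <- pn
  if (!is.null(vc)) dimnames(vc) <- list(pn, pn)
  names(se) <- pn

  k <- length(best$par)
  loglik <- -best$value
  structure(
    list(family = family,
         beta = stats::setNames(pl$beta, nm),
         gamma = if (zi) stats::setNames(pl$gamma, colnames(Xzi)) else NULL,
         theta = if (nb) exp(pl$log_theta) else NULL,
         sigma_u = if (ranef) exp(pl$log_sigma) else 0,
         u_modes = stats::setNames(final$u, levels(md$route)),
         loglik = loglik, k = k, aic = -2 * loglik + 2 * k,
         vcov = vc, se = se, par = best$par,
         convergence = converged, optim = best[c("convergence", "counts")],
         order = order, info = md$info, route_levels = levels(md$route),
         n_obs = length(y)),
    class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("<abundance_fit> %s, %d obs, %d routes; logLik %.2f, AIC %.2f%s\n",
              x$family, x$n_obs, length(x$u_modes), x$loglik, x$aic,
              if (!x$convergence) " [NOT CONVERGED]" else ""))
  cat("  sigma_u =", signif(x$sigma_u, 4),
      if (!is.null(x$theta)) paste(" theta =", signif(x$theta, 4)) else "", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
logLik.abundance_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
AIC.abundance_fit <- function(object, ..., k = 2) -2 * object$loglik + k * object$k

#' Expected counts from a fitted abundance model
#'
#' Computes \eqn{\mu = \exp(x'\hat\beta + \hat u_r + \textrm{offset})} and,
#' for zero-inflated families, the unconditional mean
#' \eqn{(1 - \hat\pi)\mu}. Random-effect modes are matched by route id;
#' routes unseen at fit time get u = 0 (the population-level prediction).
#'
#' @param fit an `abundance_fit`.
#' @param md `model_data` whose design columns match the fit (build with the
#'   stored scaling constants for new data).
#' @param include_random add the conditional modes of the route intercepts.
#' @return Vector of expected counts.
#' @export
predict_mean <- function(fit, md, include_random = FALSE) {
  stopifnot(inherits(fit, "abundance_fit"), inherits(md, "model_data"))
  if (!identical(colnames(md$X), names(fit$beta))) {
    if (all(names(fit$beta) %in% colnames(md$X))) {
      md <- .md_drop_cols(md, setdiff(colnames(md$X), names(fit$beta)))
      if (!is.null(fit$gamma))
        md$Xzi <- md$Xzi[, names(fit$gamma), drop = FALSE]
    } else {
      stop("design columns do not match the fitted model ",
           "(unseen factor level or different covariate set)")
    }
  }
  eta <- drop(md$X %*% fit$beta) + md$offset
  if (include_random) {
    u <- fit$u_modes[as.character(md$route)]
    u[is.na(u)] <- 0
    eta <- eta + u
  }
  mu <- exp(eta)
  if (fit$family %in% .zi_families) {
    pi_hat <- stats::plogis(drop(md$Xzi %*% fit$gamma))
    mu <- (1 - pi_hat) * mu
  }
  mu
}

#' Select the count error family by AIC
#'
#' Fits the model with identical covariates under Poisson, NB, ZIP and ZINB
#' error structures and returns the AIC ranking; the family with the lowest
#' AIC wins, with ties (delta AIC below 1e-6) broken toward fewer
#' parameters. Non-convergent families are excluded with a warning; if all
#' fail, an error is raised.
#'
#' @param md `model_data` with response.
#' @param families candidate families.
#' @param force_family optional family name that short-circuits selection
#'   (fallback for species whose zero-inflated fits fail).
#' @param ... passed to [fit_abundance()].
#' @return List with `table` (family, k, loglik, aic, converged), `best`
#'   (family name), and `fits` (named list of `abundance_fit`s).
#' @export
select_family <- function(md, families = c("poisson", "nb", "zip", "zinb"),
                          force_family = NULL, ...) {
  if (!is.null(force_family)) families <- force_family
  fits <- list()
  for (f in families) {
    ft <- tryCatch(fit_abundance(md, family = f, hessian = FALSE, ...),
                   error = function(e) NULL)
    if (is.null(ft)) { warning("family ", f, " failed to fit"); next }
    if (!ft$convergence) { warning("family ", f, " did not converge; excluded"); next }
    fits[[f]] <- ft
  }
  if (length(fits) == 0L) stop("no family converged")
  tab <- data.frame(
    family = names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    row.names = NULL)
  tab <- tab[order(tab$aic, tab$k), , drop = FALSE]
  best <- tab$family[tab$aic <= tab$aic[1] + 1e-6]
  best <- best[which.min(tab$k[match(best, tab$family)])]
  list(table = tab, best = best, fits = fits)
}

# drop design columns (count and zi parts) from a model_data
.md_drop_cols <- function(md, cols) {
  out <- md
  out$X <- md$X[, setdiff(colnames(md$X), cols), drop = FALSE]
  out$Xzi <- md$Xzi[, setdiff(colnames(md$Xzi), cols), drop = FALSE]
  out
}

# design columns implied by a set of retained climate blocks
.block_cols <- function(blocks_in) {
  comps <- c("spatial", "temporal", "residual")
  mains <- c(outer(c("temp_", "prec_"), comps, paste0))
  keep <- blocks_in
  drop <- setdiff(mains, keep)
  for (cmp in comps) {
    if (!(paste0("temp_", cmp) %in% keep && paste0("prec_", cmp) %in% keep))
      drop <- c(drop, paste0("txp_", cmp))
  }
  drop
}

#' Backward block selection of climate components
#'
#' Starting from the full model, repeatedly drops the component-by-variable
#' climate block (spatial/temporal/residual x temperature/precipitation)
#' whose removal lowers AIC the most; an interaction term is only retained
#' while both of its main effects are. Stops when no drop improves AIC.
#'
#' @param md `model_data` with response.
#' @param family count family (fix it first with [select_family()]).
#' @param ... passed to [fit_abundance()].
#' @return List with `fit` (final `abundance_fit`), `retained` (character
#'   vector of retained blocks), `retention` (named logical over all six
#'   blocks), and `path` (data frame of steps and AICs).
#' @export
select_covariates <- function(md, family, ...) {
  comps <- c("spatial", "temporal", "residual")
  blocks <- c(outer(c("temp_", "prec_"), comps, paste0))
  blocks <- blocks[blocks %in% colnames(md$X)]
  refit <- function(keep, warm = NULL) {
    md_k <- .md_drop_cols(md, .block_cols(keep))
    start <- if (!is.null(warm)) {
      list(beta = ifelse(colnames(md_k$X) %in% names(warm$beta),
                         warm$beta[colnames(md_k$X)], 0),
           gamma = if (!is.null(warm$gamma))
             ifelse(colnames(md_k$Xzi) %in% names(warm$gamma),
                    warm$gamma[colnames(md_k$Xzi)], 0),
           theta = warm$theta, sigma_u = max(warm$sigma_u, 0.01))
    }
    fit_abundance(md_k, family = family, hessian = FALSE, start = start, ...)
  }
  current <- refit(blocks)
  kept <- blocks
  path <- data.frame(step = "full", aic = current$aic)
  repeat {
    if (length(kept) == 0L) break
    cand <- lapply(kept, function(b) {
      tryCatch(refit(setdiff(kept, b), warm = current), error = function(e) NULL)
    })
    aics <- vapply(cand, function(f) if (is.null(f) || !f$convergence) Inf else f$aic,
                   numeric(1))
    j <- which.min(aics)
    if (aics[j] >= current$aic) break
    current <- cand[[j]]
    path <- rbind(path, data.frame(step = paste("drop", kept[j]), aic = aics[j]))
    kept <- kept[-j]
  }
  retention <- stats::setNames(blocks %in% kept, blocks)
  list(fit = current, retained = kept, retention = retention, path = path)
}

#' Serialize a fitted model to JSON
#'
#' @param fit an `abundance_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "abundance_fit"))
  jsonlite::write_json(
    list(family = fit$family, beta = as.list(fit$beta),
         gamma = if (!is.null(fit$gamma)) as.list(fit$gamma) else NULL,
         theta = fit$theta, sigma_u = fit$sigma_u,
         se = as.list(fit$se), loglik = fit$loglik, aic = fit$aic,
         k = fit$k, convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
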