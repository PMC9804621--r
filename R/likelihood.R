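#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-z^2} g(z) dz \approx \sum_k w_k
#' g(z_k)} by the Golub-Welsch eigenvalue method on the Jacobi matrix of the
#' (physicists') Hermite polynomials.
#'
#' @param n number of nodes (>= 1).
#' @return List with `nodes` and `weights`, nodes ascending.
#' @export
gauss_hermite <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L) / 2)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# log(exp(a) + exp(b)), elementwise, -Inf safe
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  r[m == -Inf] <- -Inf
  r
}

.zi_families <- c("zip", "zinb")
.nb_families <- c("nb", "zinb")

#' Conditional log-likelihood of counts
#'
#' Log probability mass of observed counts given the linear predictor
#' (including offset and any random-effect value). Families: Poisson;
#' negative binomial (NB2, variance \eqn{\mu + \mu^2/\theta}); and their
#' zero-inflated versions, which mix a structural zero with probability
#' \eqn{\pi = \mathrm{logit}^{-1}(\textrm{zi\_eta})} into the count
#' distribution: \eqn{\log[\pi 1\{y=0\} + (1-\pi) f(y)]}.
#'
#' @param y non-negative integer counts.
#' @param eta linear predictor of the count part (log scale).
#' @param family `"poisson"`, `"nb"`, `"zip"`, or `"zinb"`.
#' @param theta NB dispersion (> 0), required for nb/zinb.
#' @param zi_eta zero-inflation linear predictor (logit scale), required for
#'   zip/zinb.
#' @return Vector of log-densities.
#' @export
cond_loglik <- function(y, eta, family = c("poisson", "nb", "zip", "zinb"),
                        theta = NULL, zi_eta = NULL) {
  family <- match.arg(family)
  if (any(y < 0)) stop("negative counts")
  if (any(y != round(y))) stop("non-integer counts")
  if (family %in% .nb_families) {
    if (is.null(theta) || theta <= 0) stop("theta must be > 0 for ", family)
  }
  mu <- exp(eta)
  base <- if (family %in% c("poisson", "zip"))
    stats::dpois(y, mu, log = TRUE)
  else
    stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (!family %in% .zi_families) return(base)
  if (is.null(zi_eta)) stop("zi_eta required for ", family)
  lpi <- stats::plogis(zi_eta, log.p = TRUE)          # log pi
  l1m <- stats::plogis(-zi_eta, log.p = TRUE)         # log (1 - pi)
  out <- l1m + base
  is0 <- y == 0
  out[is0] <- .lse2(lpi[is0], l1m[is0] + base[is0])
  out
}

# per-observation derivatives of the conditional log-likelihood:
# d1/d2 wrt eta, d_zi wrt zi_eta, d_lt wrt log(theta)
.cond_derivs <- function(y, eta, family, theta = NULL, zi_eta = NULL) {
  mu <- exp(eta)
  nb <- family %in% .nb_families
  if (nb) {
    r <- mu / (theta + mu)
    d1 <- y - (y + theta) * r
    d2 <- -(y + theta) * theta * mu / (theta + mu)^2
    dlt <- theta * (digamma(y + theta) - digamma(theta) +
                      log(theta / (theta + mu)) + 1 - (y + theta) / (theta + mu))
  } else {
    d1 <- y - mu
    d2 <- -mu
    dlt <- NULL
  }
  if (!family %in% .zi_families)
    return(list(d1 = d1, d2 = d2, dzi = NULL, dlt = dlt))

  lpi <- stats::plogis(zi_eta, log.p = TRUE)
  l1m <- stats::plogis(-zi_eta, log.p = TRUE)
  lf0 <- if (nb) theta * log(theta / (theta + mu)) else -mu
  ld <- .lse2(lpi, l1m + lf0)                 # log D at y = 0
  w0 <- exp(l1m + lf0 - ld)                   # weight of count component
  g1 <- if (nb) -theta * mu / (theta + mu) else -mu
  g2 <- if (nb) -theta^2 * mu / (theta + mu)^2 else -mu
  is0 <- y == 0

  d1z <- d1; d2z <- d2
  d1z[is0] <- (w0 * g1)[is0]
  d2z[is0] <- (w0 * (g2 + g1^2) - (w0 * g1)^2)[is0]

  dzi <- -exp(lpi)                            # y > 0 case: -pi
  dzi[is0] <- (exp(lpi + l1m - ld) * (1 - exp(lf0)))[is0]

  dltz <- NULL
  if (nb) {
    dlt0 <- theta * (log(theta / (theta + mu)) + mu / (theta + mu))  # y = 0 base
    dltz <- dlt
    dltz[is0] <- (w0 * dlt0)[is0]
  }
  list(d1 = d1z, d2 = d2z, dzi = dzi, dlt = dltz)
}

# group sums over routes, keeping empty groups (length R result)
.rowsum_full <- function(v, ri, R) {
  rs <- rowsum(v, ri)
  out <- numeric(R)
  out[as.integer(rownames(rs))] <- rs
  out
}

# Conditional modes of the route intercepts by damped Newton, vectorized
# over routes. Returns list(u, hess) with hess = h''(u) < 0.
.find_modes <- function(y, eta_fix, ri, n_routes, sigma, family, theta,
                        zi_eta, u0 = NULL, tol = 1e-9, maxit = 50L) {
  u <- if (is.null(u0)) numeric(n_routes) else u0
  inv_s2 <- 1 / sigma^2
  # h'' is clamped negative: zero-inflated terms can be locally convex in u
  for (it in seq_len(maxit)) {
    d <- .cond_derivs(y, eta_fix + u[ri], family, theta, zi_eta)
    g <- .rowsum_full(d$d1, ri, n_routes) - u * inv_s2
    H <- pmin(.rowsum_full(d$d2, ri, n_routes) - inv_s2, -1e-8)
    step <- g / H
    step <- pmin(pmax(step, -3), 3)
    u <- u - step
    if (max(abs(g)) < tol) break
  }
  d <- .cond_derivs(y, eta_fix + u[ri], family, theta, zi_eta)
  H <- pmin(.rowsum_full(d$d2, ri, n_routes) - inv_s2, -1e-8)
  list(u = u, hess = H)
}

# Core marginal negative log-likelihood and gradient for one parameter
# vector. md: model_data with y; pars: list(beta, gamma, log_theta,
# log_sigma). Returns list(nll, grad (same packing), u (modes)).
.marginal_core <- function(pars, md, family, order = 7L, u0 = NULL,
                           want_grad = TRUE) {
  y <- md$y
  ri <- as.integer(md$route)
  R <- nlevels(md$route)
  eta_fix <- drop(md$X %*% pars$beta) + md$offset
  zi_eta <- if (family %in% .zi_families) drop(md$Xzi %*% pars$gamma) else NULL
  # clamp theta so transient optimizer excursions cannot under/overflow
  theta <- if (family %in% .nb_families)
    min(max(exp(pars$log_theta), 1e-8), 1e12) else NULL
  sigma <- if (is.null(pars$log_sigma)) 0 else exp(pars$log_sigma)

  grad_fixed <- function(p_obs) {
    # p_obs: per-observation posterior weight multiplier (1 for sigma = 0)
    d <- attr(p_obs, "derivs")
    g_beta <- drop(crossprod(md$X, d$d1 * p_obs))
    g <- g_beta
    if (!is.null(zi_eta)) g <- c(g, drop(crossprod(md$Xzi, d$dzi * p_obs)))
    if (!is.null(theta)) g <- c(g, sum(d$dlt * p_obs))
    g
  }

  if (sigma == 0) {
    ll_obs <- cond_loglik(y, eta_fix, family, theta, zi_eta)
    nll <- -sum(ll_obs)
    grad <- NULL
    if (want_grad) {
      d <- .cond_derivs(y, eta_fix, family, theta, zi_eta)
      p <- rep(1, length(y)); attr(p, "derivs") <- d
      grad <- -grad_fixed(p)
      if (!is.null(pars$log_sigma)) grad <- c(grad, 0)
    }
    return(list(nll = nll, grad = grad, u = numeric(R)))
  }

  m <- .find_modes(y, eta_fix, ri, R, sigma, family, theta, zi_eta, u0 = u0)
  u_hat <- m$u
  tau <- 1 / sqrt(-m$hess)
  gh <- gauss_hermite(order)
  K <- length(gh$nodes)

  hk <- matrix(0, R, K)      # integrand log-values per route and node
  for (k in seq_len(K)) {
    uk <- u_hat + sqrt(2) * tau * gh$nodes[k]
    ll <- cond_loglik(y, eta_fix + uk[ri], family, theta, zi_eta)
    hk[, k] <- .rowsum_full(ll, ri, R) + stats::dnorm(uk, 0, sigma, log = TRUE)
  }
  lw <- log(gh$weights) + gh$nodes^2
  A <- sweep(hk, 2L, lw, "+")
  Amax <- apply(A, 1L, max)
  lse <- Amax + log(rowSums(exp(A - Amax)))
  ll_route <- log(sqrt(2) * tau) + lse
  nll <- -sum(ll_route)

  grad <- NULL
  if (want_grad) {
    P <- exp(A - lse)        # posterior node weights per route (rows sum to 1)
    np <- length(pars$beta) +
      (if (!is.null(zi_eta)) length(pars$gamma) else 0L) +
      (if (!is.null(theta)) 1L else 0L)
    g <- numeric(np)
    g_ls <- 0
    for (k in seq_len(K)) {
      uk <- u_hat + sqrt(2) * tau * gh$nodes[k]
      d <- .cond_derivs(y, eta_fix + uk[ri], family, theta, zi_eta)
      p <- P[ri, k]; attr(p, "derivs") <- d
      g <- g + grad_fixed(p)
      g_ls <- g_ls + sum(P[, k] * (uk^2 / sigma^2 - 1))
    }
    grad <- -c(g, g_ls)
  }
  list(nll = nll, grad = grad, u = u_hat)
}

#' Marginal log-likelihood of the route random-intercept count model
#'
#' Integrates each route's intercept out of the conditional likelihood by
#' adaptive Gauss-Hermite quadrature centered at the route's conditional
#' mode (order 1 is the Laplace approximation):
#' \deqn{\ell = \sum_r \log \int \prod_t f(y_{rt} \mid u)\,
#'   \phi(u; 0, \sigma_u^2)\, du.}
#' With `sigma_u = 0` the integral degenerates and the function returns the
#' sum of conditional log-likelihoods at u = 0.
#'
#' @param params list with `beta` (count-part coefficients, in the order of
#'   `md$X` columns), `gamma` (zi part, zip/zinb), `theta` (> 0, nb/zinb),
#'   and `sigma_u` (>= 0).
#' @param md a `model_data` with a response ([assemble_design()]).
#' @param family count family.
#' @param order quadrature order (>= 1; 1 = Laplace).
#' @return Scalar marginal log-likelihood.
#' @export
marginal_loglik <- function(params, md, family = c("poisson", "nb", "zip", "zinb"),
                            order = 7L) {
  family <- match.arg(family)
  stopifnot(inherits(md, "model_data"), !is.null(md$y))
  pars <- list(beta = params$beta,
               gamma = if (family %in% .zi_families) params$gamma else NULL,
               log_theta = if (family %in% .nb_families) log(params$theta) else NULL,
               log_sigma = if (params$sigma_u > 0) log(params$sigma_u) else NULL)
  if (params$sigma_u == 0) pars$log_sigma <- NULL
  -.marginal_core(pars, md, family, order = order, want_grad = FALSE)$nll
}
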