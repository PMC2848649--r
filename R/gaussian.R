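## Gaussian nodes (uni- and multivariate) conditioned on discrete parents.

#' Gaussian node log-density
#'
#' @param p a [gaussian_params()] object.
#' @param parents integer vector of parent states selecting the component.
#' @param x numeric value vector of length `d`.
#' @return `-(d/2) log(2 pi) - (1/2) log|Sigma| - (1/2) (x - mu)' Sigma^{-1}
#'   (x - mu)`.
#' @export
gaussian_log_density <- function(p, parents, x) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  x <- as.numeric(x)
  if (length(x) != p$d) stop("x must have length ", p$d)
  R <- p$chol[[cfg]]
  z <- backsolve(R, x - p$means[cfg, ], transpose = TRUE)
  -0.5 * (p$d * log(2 * pi) + p$logdet[cfg] + sum(z^2))
}

## Vectorized: log-densities of all rows of X under every configuration.
## Returns n x n_config matrix.
gaussian_logdens_all <- function(p, X) {
  X <- rbind(X)
  n <- nrow(X)
  out <- matrix(0, n, p$n_config)
  for (k in seq_len(p$n_config)) {
    Z <- backsolve(p$chol[[k]], t(X) - p$means[k, ], transpose = TRUE)
    out[, k] <- -0.5 * (p$d * log(2 * pi) + p$logdet[k] + colSums(Z^2))
  }
  out
}

#' Sample a Gaussian node
#'
#' Draws via the Cholesky factor of the selected component's covariance;
#' reproducible given the RNG seed.
#' @inheritParams gaussian_log_density
#' @return a numeric vector of length `d`.
#' @export
gaussian_sample <- function(p, parents) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  z <- stats::rnorm(p$d)
  as.numeric(p$means[cfg, ] + crossprod(p$chol[[cfg]], z))
}

#' Maximum-likelihood Gaussian update
#'
#' Per parent configuration, the sample mean and the (denominator `n`)
#' sample covariance plus `ridge * I`.  Configurations with fewer than
#' `d + 1` observations fall back to the pooled (within-configuration)
#' covariance plus `ridge * I`; empty configurations additionally use the
#' pooled mean.
#'
#' @param cfg integer vector of configuration indices, one per observation.
#' @param X observation matrix (`n x d`).
#' @param parent_sizes discrete-parent extents.
#' @param ridge nonnegative diagonal inflation, keeps EM stable when a
#'   hidden component momentarily owns few points.
#' @return a [gaussian_params()] object.
#' @export
gaussian_m_step <- function(cfg, X, parent_sizes = integer(), ridge = 1e-6) {
  X <- rbind(X)
  if (nrow(X) == 0L) stop("gaussian_m_step needs at least one observation")
  d <- ncol(X)
  st <- gaussian_stats(cfg, X, rep(1, nrow(X)), prod(parent_sizes), d)
  gaussian_from_stats(st, parent_sizes, d, ridge)
}

## Weighted sufficient statistics: per configuration the weight total W,
## the weighted sum Sx and the weighted outer-product sum Sxx.
gaussian_stats <- function(cfg, X, w, n_config, d) {
  W <- numeric(n_config)
  Sx <- matrix(0, n_config, d)
  Sxx <- array(0, c(d, d, n_config))
  for (k in seq_len(n_config)) {
    sel <- cfg == k
    if (!any(sel)) next
    Xk <- X[sel, , drop = FALSE]; wk <- w[sel]
    W[k] <- sum(wk)
    Sx[k, ] <- colSums(Xk * wk)
    Sxx[, , k] <- crossprod(Xk * sqrt(wk))
  }
  list(W = W, Sx = Sx, Sxx = Sxx)
}

gaussian_from_stats <- function(st, parent_sizes, d, ridge = 1e-6,
                                prev = NULL) {
  nc <- as.integer(prod(parent_sizes))
  W <- st$W
  means <- matrix(0, nc, d)
  covs <- array(0, c(d, d, nc))
  ## pooled covariance about per-configuration means
  tot <- sum(W)
  mu_all <- lapply(seq_len(nc), function(k)
    if (W[k] > 0) st$Sx[k, ] / W[k] else NULL)
  pooled <- matrix(0, d, d)
  for (k in seq_len(nc))
    if (W[k] > 0)
      pooled <- pooled + st$Sxx[, , k] - W[k] * tcrossprod(mu_all[[k]])
  pooled <- pooled / max(tot, 1)
  pooled_mean <- colSums(st$Sx) / max(tot, 1)
  for (k in seq_len(nc)) {
    if (W[k] == 0) {
      if (!is.null(prev)) {
        means[k, ] <- prev$means[k, ]; covs[, , k] <- prev$covs[, , k]
        next
      }
      means[k, ] <- pooled_mean
      covs[, , k] <- pooled + ridge * diag(d)
      next
    }
    means[k, ] <- mu_all[[k]]
    if (W[k] >= d + 1) {
      S <- st$Sxx[, , k] / W[k] - tcrossprod(mu_all[[k]])
      covs[, , k] <- (S + t(S)) / 2 + ridge * diag(d)
    } else {
      covs[, , k] <- pooled + ridge * diag(d)
    }
  }
  ## guard: pooled can be singular too when n is tiny
  for (k in seq_len(nc)) {
    ev <- eigen(covs[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      covs[, , k] <- covs[, , k] + (abs(min(ev)) + max(ridge, 1e-8)) * diag(d)
  }
  gaussian_params(means, covs, parent_sizes)
}
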