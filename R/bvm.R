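## Bivariate von Mises (cosine variant) nodes on the torus.
##
## Density: f(phi, psi) = exp{ k1 cos(phi - mu) + k2 cos(psi - nu)
##                             - k3 cos(phi - mu - psi + nu) } / C(k1, k2, k3)
## Positive k3 induces negative circular correlation between the angles.

#' Log-normalizer of the bivariate von Mises (cosine) density
#'
#' Two routes: `"quadrature"` (authoritative) reduces the torus integral to
#' one dimension, `C = int exp(k2 cos a) 2 pi I0(sqrt(k1^2 + k3^2 -
#' 2 k1 k3 cos a)) da`, and applies the periodic trapezoid rule;
#' `"series"` sums the Bessel-product expansion
#' `4 pi^2 [I0(k1) I0(k2) I0(k3) + 2 sum_p (-1)^p I_p(k1) I_p(k2) I_p(k3)]`.
#' If the series has not converged after 400 terms the quadrature value is
#' returned with a warning.
#'
#' @param kappa1,kappa2 concentrations > 0.
#' @param kappa3 interaction coefficient.
#' @param method `"quadrature"` or `"series"`.
#' @param n_grid trapezoid points for the quadrature route.
#' @return `log C(k1, k2, k3)`.
#' @export
bvm_log_normalizer <- function(kappa1, kappa2, kappa3,
                               method = c("quadrature", "series"),
                               n_grid = 1024L) {
  method <- match.arg(method)
  if (method == "quadrature")
    return(bvm_log_c_quad(kappa1, kappa2, kappa3, n_grid))
  ## series route
  x3 <- abs(kappa3)
  sgn <- if (kappa3 >= 0) -1 else 1   # (-1)^p from -k3, times sign(k3)^p
  l0 <- log(besselI(kappa1, 0, TRUE)) + log(besselI(kappa2, 0, TRUE)) +
    log(besselI(x3, 0, TRUE))
  S <- 1
  total_abs <- 1
  ok <- FALSE
  for (p in seq_len(400L)) {
    lr <- log(besselI(kappa1, p, TRUE)) + log(besselI(kappa2, p, TRUE)) +
      log(besselI(x3, p, TRUE)) - l0
    term <- 2 * sgn^p * exp(lr)
    S <- S + term
    total_abs <- total_abs + abs(term)
    if (abs(term) < 1e-17) { ok <- TRUE; break }
  }
  ## an alternating series can cancel catastrophically at strong coupling
  if (!ok || S <= 1e-8 * total_abs) {
    warning("bivariate von Mises normalizer series did not converge; ",
            "falling back to quadrature")
    return(bvm_log_c_quad(kappa1, kappa2, kappa3, n_grid))
  }
  log(4 * pi^2) + l0 + kappa1 + kappa2 + x3 + log(S)
}

bvm_log_c_quad <- function(k1, k2, k3, n_grid = 1024L) {
  a <- 2 * pi * (seq_len(n_grid) - 1L) / n_grid
  g <- sqrt(pmax(k1^2 + k3^2 - 2 * k1 * k3 * cos(a), 0))
  vals <- k2 * cos(a) + log(2 * pi) + log_bessel_i0(g)
  log_sum_exp(vals) + log(2 * pi / n_grid)
}

#' Bivariate von Mises log-density
#' @param p a [bvm_params()] object.
#' @param phi,psi angles in radians (vectorized).
#' @param parents integer vector of parent states.
#' @param n_grid quadrature size for the normalizer.
#' @export
bvm_log_density <- function(p, phi, psi, parents = integer(),
                            n_grid = 1024L) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  bvm_ld(phi, psi, p$mu[cfg], p$nu[cfg], p$kappa1[cfg], p$kappa2[cfg],
         p$kappa3[cfg], n_grid)
}

bvm_ld <- function(phi, psi, mu, nu, k1, k2, k3, n_grid = 1024L) {
  k1 * cos(phi - mu) + k2 * cos(psi - nu) - k3 * cos(phi - mu - psi + nu) -
    bvm_log_normalizer(k1, k2, k3, n_grid = n_grid)
}

#' Conditional of phi given psi
#'
#' The exponent in `phi` is `a cos(phi - mu) + b sin(phi - mu)` with
#' `a = k1 - k3 cos(psi - nu)` and `b = -k3 sin(psi - nu)`, i.e. a von
#' Mises with `kappa_c = sqrt(a^2 + b^2)` and mean `mu + atan2(b, a)`;
#' `kappa_c = 0` degenerates to the uniform conditional.
#'
#' @param p a [bvm_params()] object.
#' @param psi conditioning angle(s).
#' @param parents integer vector of parent states.
#' @return a [vm_params()] object with one entry per element of `psi`.
#' @export
bvm_conditional <- function(p, psi, parents = integer()) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  alpha <- psi - p$nu[cfg]
  a <- p$kappa1[cfg] - p$kappa3[cfg] * cos(alpha)
  b <- -p$kappa3[cfg] * sin(alpha)
  kc <- sqrt(a^2 + b^2)
  mu_c <- ifelse(kc == 0, p$mu[cfg], wrap_angle(p$mu[cfg] + atan2(b, a)))
  ## one conditional per element of psi (indexed along the config axis)
  vm_params(mu_c, kappa = kc,
            parent_sizes = if (length(mu_c) > 1L) length(mu_c) else integer())
}

## Unnormalized log marginal of alpha = psi - nu.
bvm_marg_lu <- function(alpha, k1, k2, k3) {
  g <- sqrt(pmax(k1^2 + k3^2 - 2 * k1 * k3 * cos(alpha), 0))
  k2 * cos(alpha) + log_bessel_i0(g)
}

#' Sample angle pairs from a bivariate von Mises distribution
#'
#' `psi` is drawn from its exact one-dimensional marginal by inverting a
#' grid-interpolated CDF (default 4096 points); `phi` then follows from the
#' exact von Mises conditional [bvm_conditional()].
#'
#' @param p a [bvm_params()] object.
#' @param n number of pairs.
#' @param parents integer vector of parent states.
#' @param n_grid marginal-CDF grid size.
#' @return matrix `n x 2` of `(phi, psi)` in `[0, 2*pi)`.
#' @export
bvm_sample <- function(p, n, parents = integer(), n_grid = 4096L) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  mu <- p$mu[cfg]; nu <- p$nu[cfg]
  k1 <- p$kappa1[cfg]; k2 <- p$kappa2[cfg]; k3 <- p$kappa3[cfg]
  if (n == 0L) return(matrix(numeric(), 0L, 2L,
                             dimnames = list(NULL, c("phi", "psi"))))
  alpha <- grid_icdf_sample(n, function(a) bvm_marg_lu(a, k1, k2, k3), n_grid)
  psi <- wrap_angle(nu + alpha)
  a <- k1 - k3 * cos(alpha)
  b <- -k3 * sin(alpha)
  kc <- sqrt(a^2 + b^2)
  mc <- wrap_angle(mu + atan2(b, a))
  phi <- vm_sample_vec(mc, kc)
  cbind(phi = phi, psi = psi)
}

## Inverse-CDF sampling of a periodic density on [0, 2pi) from its
## unnormalized log-density, by linear interpolation of the cumulative
## trapezoid on a uniform grid.
grid_icdf_sample <- function(n, logf, n_grid = 4096L) {
  x <- 2 * pi * (0:n_grid) / n_grid
  lf <- logf(x)
  f <- exp(lf - max(lf))
  mids <- (f[-1L] + f[-(n_grid + 1L)]) / 2
  cdf <- c(0, cumsum(mids))
  tot <- cdf[n_grid + 1L]
  u <- stats::runif(n) * tot
  j <- findInterval(u, cdf, rightmost.closed = TRUE)
  j[j < 1L] <- 1L; j[j > n_grid] <- n_grid
  frac <- (u - cdf[j]) / pmax(cdf[j + 1L] - cdf[j], .Machine$double.xmin)
  x[j] + frac * (x[j + 1L] - x[j])
}

#' Maximum-likelihood fit of a bivariate von Mises distribution
#'
#' Means from the circular means of `phi` and `psi`; concentrations by
#' maximizing the exact log-likelihood (normalizer by quadrature) from a
#' moment-based start (`A1inv` of the aligned cosine moments, `kappa3 = 0`).
#' The unimodality constraint is kept by the smooth reparameterization
#' `kappa3 = 0.95 min(kappa1, kappa2) tanh(t)`.
#'
#' @param phi,psi angle vectors (same length, n >= 5).
#' @param weights optional nonnegative observation weights.
#' @return a [bvm_params()] object with a single configuration.
#' @export
bvm_estimate <- function(phi, psi, weights = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (n < 5L) stop("bvm_estimate needs at least 5 observations")
  w <- weights %||% rep(1, n)
  st <- c(sum(w),
          sum(w * cos(phi)), sum(w * sin(phi)),
          sum(w * cos(psi)), sum(w * sin(psi)),
          sum(w * cos(phi - psi)), sum(w * sin(phi - psi)))
  bvm_from_stats(st)
}

## st: vector (W, c1, s1, c2, s2, cd, sd) of weighted trig sums, in that
## order.
bvm_from_stats <- function(st, n_grid = 512L) {
  st <- as.numeric(st)
  W <- st[1L]
  if (W <= 0) stop("bvm estimation needs observations")
  mu <- wrap_angle(atan2(st[3L], st[2L]))
  nu <- wrap_angle(atan2(st[5L], st[4L]))
  m1 <- (st[2L] * cos(mu) + st[3L] * sin(mu)) / W
  m2 <- (st[4L] * cos(nu) + st[5L] * sin(nu)) / W
  d <- mu - nu
  m3 <- (st[6L] * cos(d) + st[7L] * sin(d)) / W
  k1_0 <- min(max(A1inv(min(m1, 1 - 1e-9)), 1e-2), 1e3)
  k2_0 <- min(max(A1inv(min(m2, 1 - 1e-9)), 1e-2), 1e3)
  negll <- function(par) {
    k1 <- exp(par[1]); k2 <- exp(par[2])
    k3 <- 0.95 * min(k1, k2) * tanh(par[3])
    if (!is.finite(k1) || !is.finite(k2) || k1 > 5e3 || k2 > 5e3) return(1e10)
    -(k1 * m1 + k2 * m2 - k3 * m3 -
        bvm_log_normalizer(k1, k2, k3, n_grid = n_grid))
  }
  fit <- stats::optim(c(log(k1_0), log(k2_0), 0), negll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("bvm_estimate failed to converge (optim code ", fit$convergence,
         ", value ", format(fit$value), ")")
  k1 <- exp(fit$par[1]); k2 <- exp(fit$par[2])
  k3 <- 0.95 * min(k1, k2) * tanh(fit$par[3])
  bvm_params(mu, nu, k1, k2, k3)
}
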