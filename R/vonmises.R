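## Univariate von Mises nodes on the circle.

#' von Mises log-density
#'
#' `kappa * cos(theta - mu) - log(2 pi I0(kappa))`; at `kappa = 0` this is
#' the uniform density `1 / (2 pi)`.
#' @param p a [vm_params()] object.
#' @param theta angle(s) in radians.
#' @param parents integer vector of parent states (omit for a parentless
#'   set).
#' @return log-density, vectorized over `theta`.
#' @export
vm_log_density <- function(p, theta, parents = integer()) {
  parents <- check_parents(p, parents)
  cfg <- config_index(rbind(parents), p$psz)
  vm_ld(theta, p$mu[cfg], p$kappa[cfg])
}

vm_ld <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) - log_bessel_i0(kappa)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher wrapped-Cauchy envelope rejection; `kappa = 0` draws
#' uniformly.
#' @param n number of draws.
#' @param mu mean angle.
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 2*pi)`.
#' @export
vm_sample <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out)
}

## Vectorized over per-draw (mu, kappa); used by the bivariate sampler.
vm_sample_vec <- function(mu, kappa) {
  n <- length(mu)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- vm_sample(1L, mu[i], kappa[i])
  out
}

## Inverse of A1(kappa) = I1/I0: the standard three-regime rational
## approximation for recovering kappa from the mean resultant length.
A1inv <- function(R) {
  ifelse(R < 0.53, 2 * R + R^3 + 5 * R^5 / 6,
         ifelse(R < 0.85, -0.4 + 1.39 * R + 0.43 / (1 - R),
                1 / (R^3 - 4 * R^2 + 3 * R)))
}

#' Estimate von Mises parameters
#'
#' Circular-mean direction and concentration from the mean resultant
#' length via [A1inv()].  A resultant length at (or numerically above) 1
#' caps `kappa` at `1e4` with a warning.
#' @param theta angles in radians.
#' @return a [vm_params()] object with a single configuration.
#' @export
vm_estimate <- function(theta) {
  st <- c(sum(cos(theta)), sum(sin(theta)), length(theta))
  vm_from_stats(st[1], st[2], st[3])
}

vm_from_stats <- function(C, S, W) {
  if (W <= 0) stop("von Mises estimation needs observations")
  mu <- wrap_angle(atan2(S, C))
  R <- sqrt(C^2 + S^2) / W
  if (R >= 1 - 1e-12) {
    warning("resultant length ~ 1; capping kappa at 1e4")
    kappa <- 1e4
  } else {
    kappa <- min(A1inv(R), 1e4)
  }
  vm_params(mu, max(kappa, 1e-8))
}
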