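## Small numeric helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector (may contain -Inf).
#' @return scalar log-sum-exp.
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log-sum-exp of a matrix.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

## log I0(x) without overflow (x >= 0).
log_bessel_i0 <- function(x) {
  log(besselI(x, 0, expon.scaled = TRUE)) + x
}

## Wrap angles into [0, 2*pi).
wrap_angle <- function(x) x %% (2 * pi)

## Row-major linear index (1-based) of parent-state configurations.
## `states`: n x k matrix of 1-based states; `sizes`: extents, length k.
## k = 0 (no parents) gives all-ones.
config_index <- function(states, sizes) {
  if (length(sizes) == 0L) {
    n <- if (is.matrix(states)) nrow(states) else length(states)
    return(rep(1L, max(n, 1L)))
  }
  states <- as.matrix(states)
  stopifnot(ncol(states) == length(sizes))
  strides <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  as.integer(1L + (states - 1L) %*% strides)
}

## Inverse-CDF categorical draws, one per row of a probability matrix.
## A single uniform variate per row; ties resolved toward the lower index.
sample_rows <- function(prob) {
  n <- nrow(prob); S <- ncol(prob)
  cum <- prob %*% upper.tri(diag(S), diag = TRUE)
  u <- stats::runif(n) * cum[, S]
  as.integer(1L + rowSums(cum < u))
}

## Gauss-Legendre nodes/weights on [a, b] (thin wrapper, cached).
gauss_legendre <- local({
  cache <- list()
  function(n, a = -1, b = 1) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <<- pracma::gaussLegendre(n, -1, 1)
    gl <- cache[[key]]
    list(x = (b - a) / 2 * gl$x + (a + b) / 2, w = (b - a) / 2 * gl$w)
  }
})
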