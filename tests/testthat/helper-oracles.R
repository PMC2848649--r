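## Shared fixtures and independent oracles for the test suite.  Everything
## here is deliberately naive: enumeration, dense grids and textbook
## recursions that the fast implementation is checked against.

## A 2-node HMM spec: hidden chain of `S` states emitting a discrete
## symbol from `M`.
make_hmm_spec <- function(S = 2L, M = S) {
  dbn_spec(list(node_spec("h", "discrete", S, hidden = TRUE),
                node_spec("o", "discrete", M)),
           intra_edges = rbind(c(1L, 2L)),
           inter_edges = rbind(c(1L, 1L)))
}

## Parameters for make_hmm_spec from plain matrices.
make_hmm_params <- function(spec, pi0, Tm, Em) {
  S <- length(pi0)
  params <- dbn_params(spec, list(
    list(p = cpt_params(mdarray(c(S, S), as.vector(t(Tm)))),
         p0 = cpt_params(mdarray(S, pi0))),
    list(p = cpt_params(mdarray(dim(Em), as.vector(t(Em)))), p0 = NULL)))
  attr(params, "spec") <- spec
  params
}

random_stochastic_matrix <- function(nr, nc) {
  m <- matrix(stats::rgamma(nr * nc, 1), nr, nc)
  m / rowSums(m)
}

## Exact log P(obs) by summing over every hidden path.
enumerate_hmm_loglik <- function(pi0, Tm, Em, obs) {
  S <- length(pi0)
  L <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    h <- paths[r, ]
    p <- pi0[h[1]] * Em[h[1], obs[1]]
    if (L > 1) for (t in 2:L)
      p <- p * Tm[h[t - 1], h[t]] * Em[h[t], obs[t]]
    tot <- tot + p
  }
  log(tot)
}

## Textbook scaled forward-backward smoothing marginals (L x S).
fb_marginals <- function(pi0, Tm, Em, obs) {
  L <- length(obs); S <- length(pi0)
  a <- matrix(0, L, S); b <- matrix(1, L, S)
  a[1, ] <- pi0 * Em[, obs[1]]; a[1, ] <- a[1, ] / sum(a[1, ])
  for (t in seq_len(L)[-1L]) {
    a[t, ] <- (a[t - 1, ] %*% Tm) * Em[, obs[t]]
    a[t, ] <- a[t, ] / sum(a[t, ])
  }
  if (L > 1) for (t in (L - 1):1) {
    b[t, ] <- Tm %*% (Em[, obs[t + 1]] * b[t + 1, ])
    b[t, ] <- b[t, ] / sum(b[t, ])
  }
  g <- a * b
  g / rowSums(g)
}

## All permutations of 1..n (n! x n matrix).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

## Smallest max-entry error of (transition, emission) over hidden-state
## relabelings.
best_perm_error <- function(T_hat, E_hat, T_true, E_true) {
  P <- all_perms(nrow(T_true))
  best <- Inf
  for (r in seq_len(nrow(P))) {
    pm <- P[r, ]
    err <- max(abs(T_hat[pm, pm] - T_true), abs(E_hat[pm, ] - E_true))
    best <- min(best, err)
  }
  best
}

## Fisher-Lee circular correlation of two angle samples.
circ_cor <- function(a, b) {
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sum(sin(a - am) * sin(b - bm)) /
    sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
}

## Dense-grid integral of f(phi, psi) over the torus.
torus_integral <- function(f, n = 512L) {
  g <- 2 * pi * (seq_len(n) - 1L) / n
  sum(outer(g, g, f)) * (2 * pi / n)^2
}

## Integral of f(x) over the unit sphere: Gauss-Legendre in the polar
## cosine, trapezoid in azimuth.
sphere_integral <- function(f, n_polar = 600L, n_az = 256L) {
  gl <- pracma::gaussLegendre(n_polar, -1, 1)
  ph <- 2 * pi * (seq_len(n_az) - 1L) / n_az
  tot <- 0
  for (i in seq_len(n_polar)) {
    ct <- gl$x[i]; st <- sqrt(1 - ct^2)
    X <- cbind(st * cos(ph), st * sin(ph), ct)
    tot <- tot + gl$w[i] * sum(f(X)) * (2 * pi / n_az)
  }
  tot
}

## von Mises-Fisher log-density on the sphere (closed-form normalizer).
vmf_log_density <- function(X, mu, kappa) {
  lc <- log(4 * pi) + kappa + log1p(-exp(-2 * kappa)) - log(2) - log(kappa)
  as.numeric(X %*% mu) * kappa - lc
}

## Deterministic EM (exact expected counts via forward-backward) for the
## 2-node HMM; oracle for the MC-EM fixed-point test.
exact_em_hmm <- function(pi0, Tm, Em, obs_mat, n_iter, pseudocount = 0) {
  S <- nrow(Tm); M <- ncol(Em)
  for (it in seq_len(n_iter)) {
    pi_c <- rep(pseudocount, S)
    T_c <- matrix(pseudocount, S, S)
    E_c <- matrix(pseudocount, S, M)
    for (q in seq_len(nrow(obs_mat))) {
      obs <- obs_mat[q, ]
      L <- length(obs)
      a <- matrix(0, L, S); b <- matrix(1, L, S)
      a[1, ] <- pi0 * Em[, obs[1]]; ca <- sum(a[1, ]); a[1, ] <- a[1, ] / ca
      for (t in seq_len(L)[-1L]) {
        a[t, ] <- (a[t - 1, ] %*% Tm) * Em[, obs[t]]
        a[t, ] <- a[t, ] / sum(a[t, ])
      }
      for (t in (L - 1):1) {
        b[t, ] <- Tm %*% (Em[, obs[t + 1]] * b[t + 1, ])
        b[t, ] <- b[t, ] / sum(b[t, ])
      }
      g <- a * b; g <- g / rowSums(g)
      pi_c <- pi_c + g[1, ]
      for (t in seq_len(L - 1)) {
        xi <- outer(a[t, ], Em[, obs[t + 1]] * b[t + 1, ]) * Tm
        T_c <- T_c + xi / sum(xi)
      }
      for (t in seq_len(L)) E_c[, obs[t]] <- E_c[, obs[t]] + g[t, ]
    }
    pi0 <- pi_c / sum(pi_c)
    Tm <- T_c / rowSums(T_c)
    Em <- E_c / rowSums(E_c)
  }
  list(pi0 = pi0, Tm = Tm, Em = Em)
}

## Internal accessors (tests exercise a few unexported helpers).
cm2md <- function(m, psz, size) gibbsdbn:::config_matrix_as_md(m, psz, size)
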