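## Parameter records, one class per distribution family.  All families are
## conditioned on (zero or more) discrete parents; the parent configuration
## is flattened to a single row-major linear index ("config"), so every
## record stores one parameter set per config.

new_family_params <- function(family, psz, fields) {
  structure(c(list(family = family, psz = as.integer(psz),
                   n_config = as.integer(prod(psz))), fields),
            class = c(paste0(family, "_params"), "family_params"))
}

#' Conditional probability table parameters
#'
#' @param table an [mdarray()] (or plain array) shaped
#'   `cpt_shape(parent_sizes, node_size)`; every last-axis slice must be a
#'   probability vector.
#' @param parent_sizes,node_size extents; inferred from `table$shape` when
#'   `table` is an mdarray and these are missing.
#' @return a `discrete_params` object.
#' @export
cpt_params <- function(table, parent_sizes = NULL, node_size = NULL) {
  if (is.array(table) || (is.numeric(table) && !inherits(table, "mdarray"))) {
    if (is.null(dim(table))) dim(table) <- length(table)
    ## plain R arrays are column-major; accept via aperm to row-major flat
    table <- mdarray(dim(table), as.vector(aperm(table, rev(seq_along(dim(table))))))
  }
  shp <- table$shape
  node_size <- node_size %||% shp[length(shp)]
  parent_sizes <- parent_sizes %||% shp[-length(shp)]
  stopifnot(identical(as.integer(shp), cpt_shape(parent_sizes, node_size)))
  prob <- md_as_config_matrix(table, node_size)
  if (any(prob < 0)) stop("CPT entries must be nonnegative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-12))
    stop("every CPT row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  new_family_params("discrete", parent_sizes,
                    list(size = as.integer(node_size), prob = prob,
                         logp = log(prob)))
}

#' Multinomial node parameters
#'
#' Count-vector node: per parent configuration a probability vector over
#' `size` categories; the trial count is per observation, not a parameter.
#' @param probs matrix `n_config x size` (or mdarray shaped
#'   `c(parent_sizes, size)`); rows sum to 1.
#' @param parent_sizes discrete-parent extents.
#' @param size number of categories.
#' @export
multinomial_params <- function(probs, parent_sizes = integer(), size = NULL) {
  if (inherits(probs, "mdarray")) {
    size <- size %||% probs$shape[length(probs$shape)]
    parent_sizes <- probs$shape[-length(probs$shape)]
    probs <- md_as_config_matrix(probs, size)
  }
  probs <- rbind(probs)
  size <- size %||% ncol(probs)
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-12))
    stop("multinomial probability rows must be nonnegative and sum to 1")
  new_family_params("multinomial", parent_sizes,
                    list(size = as.integer(size), prob = probs,
                         logp = log(probs)))
}

#' Poisson node parameters
#' @param rates positive rate per parent configuration.
#' @param parent_sizes discrete-parent extents.
#' @export
poisson_params <- function(rates, parent_sizes = integer()) {
  rates <- as.numeric(rates)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("Poisson rates must be positive")
  stopifnot(length(rates) == prod(parent_sizes))
  new_family_params("poisson", parent_sizes, list(rates = rates))
}

#' Gaussian node parameters
#'
#' One mean vector and one symmetric positive-definite covariance per
#' discrete-parent configuration.
#' @param means matrix `n_config x d` (a vector is taken as a single
#'   configuration's mean).
#' @param covs array `d x d x n_config` (or a single `d x d` matrix).
#' @param parent_sizes discrete-parent extents.
#' @export
gaussian_params <- function(means, covs, parent_sizes = integer()) {
  means <- rbind(means)
  d <- ncol(means)
  if (is.matrix(covs)) covs <- array(covs, c(d, d, 1L))
  nc <- as.integer(prod(parent_sizes))
  stopifnot(nrow(means) == nc, dim(covs)[3L] == nc)
  chol_list <- vector("list", nc)
  logdet <- numeric(nc)
  for (k in seq_len(nc)) {
    S <- covs[, , k]
    if (max(abs(S - t(S))) > 1e-10)
      stop("covariance ", k, " is not symmetric")
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) stop("covariance ", k, " is not positive definite")
    chol_list[[k]] <- R
    logdet[k] <- 2 * sum(log(diag(R)))
  }
  new_family_params("gaussian", parent_sizes,
                    list(d = as.integer(d), means = means, covs = covs,
                         chol = chol_list, logdet = logdet))
}

#' Univariate von Mises parameters
#' @param mu mean angle(s) in `[0, 2*pi)`, one per parent configuration.
#' @param kappa concentration(s) > 0.
#' @param parent_sizes discrete-parent extents.
#' @export
vm_params <- function(mu, kappa, parent_sizes = integer()) {
  stopifnot(length(mu) == length(kappa),
            length(mu) == prod(parent_sizes))
  if (any(kappa < 0)) stop("von Mises concentration must be >= 0")
  new_family_params("vonmises_uni", parent_sizes,
                    list(mu = wrap_angle(as.numeric(mu)),
                         kappa = as.numeric(kappa)))
}

#' Bivariate von Mises (cosine variant) parameters
#'
#' Density on the torus proportional to
#' `exp(k1 cos(phi - mu) + k2 cos(psi - nu) - k3 cos(phi - mu - psi + nu))`.
#' Unimodality requires `k1 > |k3|` and `k2 > |k3|` (enforced by clipping
#' during estimation).
#' @param mu,nu mean angles in `[0, 2*pi)` per parent configuration.
#' @param kappa1,kappa2 concentrations > 0.
#' @param kappa3 interaction coefficient (sign controls the correlation).
#' @param parent_sizes discrete-parent extents.
#' @export
bvm_params <- function(mu, nu, kappa1, kappa2, kappa3,
                       parent_sizes = integer()) {
  nconf <- prod(parent_sizes)
  stopifnot(length(mu) == nconf, length(nu) == nconf,
            length(kappa1) == nconf, length(kappa2) == nconf,
            length(kappa3) == nconf)
  if (any(kappa1 <= 0) || any(kappa2 <= 0))
    stop("kappa1 and kappa2 must be positive")
  if (any(kappa1 <= abs(kappa3)) || any(kappa2 <= abs(kappa3)))
    stop("unimodality requires kappa1 > |kappa3| and kappa2 > |kappa3|")
  new_family_params("vonmises_bi", parent_sizes,
                    list(mu = wrap_angle(as.numeric(mu)),
                         nu = wrap_angle(as.numeric(nu)),
                         kappa1 = as.numeric(kappa1),
                         kappa2 = as.numeric(kappa2),
                         kappa3 = as.numeric(kappa3)))
}

#' Kent (FB5) parameters
#'
#' Density on the unit sphere proportional to
#' `exp(kappa * (g1 . x) + beta * ((g2 . x)^2 - (g3 . x)^2))` with
#' orthonormal axes `g1` (mean direction), `g2` (major axis), `g3` (minor
#' axis) and unimodality constraint `2 * beta < kappa`.
#' @param kappa concentration(s) > 0 per parent configuration.
#' @param beta ellipticity(ies) >= 0, `2 beta < kappa`.
#' @param gammas `3 x 3` orthogonal matrix with columns `g1, g2, g3`, or an
#'   array `3 x 3 x n_config`.
#' @param parent_sizes discrete-parent extents.
#' @export
kent_params <- function(kappa, beta, gammas, parent_sizes = integer()) {
  nconf <- as.integer(prod(parent_sizes))
  if (is.matrix(gammas)) gammas <- array(gammas, c(3L, 3L, 1L))
  stopifnot(length(kappa) == nconf, length(beta) == nconf,
            dim(gammas)[3L] == nconf)
  if (any(kappa <= 0)) stop("kent kappa must be positive")
  if (any(beta < 0)) stop("kent beta must be >= 0")
  if (any(2 * beta >= kappa))
    stop("unimodality requires 2 * beta < kappa")
  for (k in seq_len(nconf)) {
    G <- gammas[, , k]
    if (max(abs(crossprod(G) - diag(3))) > 1e-9)
      stop("gamma axes of configuration ", k, " are not orthonormal")
  }
  new_family_params("kent", parent_sizes,
                    list(kappa = as.numeric(kappa), beta = as.numeric(beta),
                         gammas = gammas))
}

## ---- per-node container -------------------------------------------------

## A node owns a tied parameter set `p` (all slices, full parent set) and,
## when it has inter parents, an initial-slice set `p0` over intra parents
## only; both are estimated jointly during EM.
node_params <- function(spec, i, p, p0 = NULL) {
  m <- spec$meta[[i]]
  if (m$has_init && is.null(p0))
    stop("node ", spec$nodes[[i]]$name, " has inter parents and needs an ",
         "initial-slice parameter set")
  stopifnot(identical(as.integer(p$psz), as.integer(m$psz)))
  if (!is.null(p0)) stopifnot(identical(as.integer(p0$psz), as.integer(m$psz0)))
  structure(list(name = spec$nodes[[i]]$name,
                 family = spec$nodes[[i]]$family,
                 size = spec$nodes[[i]]$size, p = p, p0 = p0),
            class = "node_params")
}

param_set <- function(np, initial = FALSE) {
  if (initial && !is.null(np$p0)) np$p0 else np$p
}

#' Assemble a full parameter object for a DBN
#' @param spec a [dbn_spec()].
#' @param per_node list (length = nodes) of `list(p = , p0 = )` family
#'   parameter records.
#' @return a `dbn_params` object (list of per-node containers).
#' @export
dbn_params <- function(spec, per_node) {
  stopifnot(length(per_node) == n_nodes(spec))
  out <- lapply(seq_along(per_node), function(i)
    node_params(spec, i, per_node[[i]]$p, per_node[[i]]$p0))
  structure(out, class = "dbn_params")
}

## Random parameters from documented diffuse distributions; used by the
## benchmark generators and as the EM starting point for discrete nodes.
## CPT rows ~ flat Dirichlet; Gaussian means ~ N(0,1), covariances with
## random orthogonal axes and eigenvalues ~ U(0.25, 1); von Mises means
## uniform on the circle with kappa ~ U(5, 50); kappa3 ~ U(-0.5, 0.5) *
## min(kappa1, kappa2); Kent axes from a random rotation, kappa ~ U(20, 200),
## beta ~ U(0, 0.4) * kappa / 2.
random_family_params <- function(family, size, psz) {
  nc <- as.integer(prod(psz))
  rdirich <- function(n, k) {
    g <- matrix(stats::rgamma(n * k, 1), n, k)
    g / rowSums(g)
  }
  switch(family,
    discrete = new_family_params("discrete", psz, {
      pr <- rdirich(nc, size)
      list(size = size, prob = pr, logp = log(pr))
    }),
    multinomial = new_family_params("multinomial", psz, {
      pr <- rdirich(nc, size)
      list(size = size, prob = pr, logp = log(pr))
    }),
    poisson = poisson_params(stats::runif(nc, 1, 10), psz),
    gaussian_uni = ,
    gaussian_multi = {
      d <- if (family == "gaussian_uni") 1L else size
      covs <- array(0, c(d, d, nc))
      for (k in seq_len(nc)) {
        Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
        covs[, , k] <- Q %*% diag(stats::runif(d, 0.25, 1), d) %*% t(Q)
        covs[, , k] <- (covs[, , k] + t(covs[, , k])) / 2
      }
      gaussian_params(matrix(stats::rnorm(nc * d), nc, d), covs, psz)
    },
    vonmises_uni = vm_params(stats::runif(nc, 0, 2 * pi),
                             stats::runif(nc, 5, 50), psz),
    vonmises_bi = {
      k1 <- stats::runif(nc, 5, 50); k2 <- stats::runif(nc, 5, 50)
      k3 <- stats::runif(nc, -0.5, 0.5) * pmin(k1, k2)
      bvm_params(stats::runif(nc, 0, 2 * pi), stats::runif(nc, 0, 2 * pi),
                 k1, k2, k3, psz)
    },
    kent = {
      kap <- stats::runif(nc, 20, 200)
      bet <- stats::runif(nc, 0, 0.4) * kap / 2
      gam <- array(0, c(3, 3, nc))
      for (k in seq_len(nc)) {
        G <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
        if (det(G) < 0) G[, 3] <- -G[, 3]
        gam[, , k] <- G
      }
      kent_params(kap, bet, gam, psz)
    },
    stop("unknown family: ", family))
}

#' Draw random parameters for every node of a DBN
#' @param spec a [dbn_spec()].
#' @return a `dbn_params` object; see the package vignette for the
#'   sampling distributions used per family.
#' @export
dbn_random_params <- function(spec) {
  per_node <- lapply(seq_len(n_nodes(spec)), function(i) {
    nd <- spec$nodes[[i]]; m <- spec$meta[[i]]
    list(p = random_family_params(nd$family, nd$size, m$psz),
         p0 = if (m$has_init) random_family_params(nd$family, nd$size, m$psz0))
  })
  dbn_params(spec, per_node)
}
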