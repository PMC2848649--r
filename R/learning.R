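## S-EM and MC-EM parameter learning.
##
## Both flavours share one machinery: a completed dataset (S-EM: the single
## Gibbs completion; MC-EM: each of m completions) is reduced to per-node,
## per-parameter-set sufficient statistics, and the M-step re-estimates
## every family from those statistics.  MC-EM averages the statistics over
## the m completions before the M-step.

#' EM configuration
#'
#' @param flavour `"sem"` (one Gibbs completion per iteration) or `"mcem"`
#'   (`mcem_samples` completions, sufficient statistics averaged).
#' @param n_iterations EM iterations (hard cap).
#' @param mcem_samples completions per MC-EM iteration (>= 2).
#' @param burn_in Gibbs sweeps before the first iteration only.
#' @param pseudocount per-cell CPT/multinomial smoothing in the M-step;
#'   the default 0.05 keeps zero probabilities from making hidden states
#'   unreachable during Gibbs.
#' @param ridge covariance diagonal inflation in the Gaussian M-step.
#' @param seed RNG seed (`NULL` = leave the RNG stream alone).
#' @param window,tolerance early stopping: stop when the mean
#'   completed-data log-likelihood over the last `window` iterations
#'   changes by less than `tolerance * |mean|` relative to the previous
#'   window; `tolerance = 0` disables and runs all `n_iterations`.
#' @param estimate `"average"` reports parameters re-estimated from the
#'   sufficient statistics averaged over the last `avg_window` iterations
#'   (the S-EM parameter sequence does not converge pointwise);
#'   `"last"` reports the final iterate.
#' @param avg_window iterations entering the average.
#' @param compute_forward also trace the exact forward log-likelihood
#'   (HMM-shaped models only).
#' @param n_starts independent random restarts; [train()] runs the full EM
#'   schedule from each and keeps the run with the best mean
#'   completed-data log-likelihood over its final window (the usual guard
#'   against EM local optima).
#' @return an `em_config` list.
#' @export
em_config <- function(flavour = c("sem", "mcem"), n_iterations = 100L,
                      mcem_samples = 10L, burn_in = 10L, pseudocount = 0.05,
                      ridge = 1e-6, seed = NULL, window = 10L,
                      tolerance = 0.01, estimate = c("average", "last"),
                      avg_window = 20L, compute_forward = FALSE,
                      n_starts = 1L) {
  flavour <- match.arg(flavour)
  stopifnot(n_iterations >= 1L, n_starts >= 1L)
  if (flavour == "mcem") stopifnot(mcem_samples >= 2L)
  structure(list(flavour = flavour, n_iterations = as.integer(n_iterations),
                 mcem_samples = as.integer(mcem_samples),
                 burn_in = as.integer(burn_in), pseudocount = pseudocount,
                 ridge = ridge, seed = seed, window = as.integer(window),
                 tolerance = tolerance, estimate = match.arg(estimate),
                 avg_window = as.integer(avg_window),
                 compute_forward = isTRUE(compute_forward),
                 n_starts = as.integer(n_starts)),
            class = "em_config")
}

## ---- sufficient statistics ---------------------------------------------

## Weighted per-family statistics for one parameter set of one node:
## discrete/multinomial: count tables; poisson: (W, sum k); gaussian:
## (W, sum x, sum x x'); von Mises: trig resultants; bivariate von Mises:
## the six trig sums its likelihood depends on; Kent: mean vector and
## scatter.  All keyed by the parent configuration.
empty_stats <- function(fam, n_config, size, width) {
  switch(fam,
    discrete = ,
    multinomial = list(counts = matrix(0, n_config, size)),
    poisson = list(W = numeric(n_config), Sk = numeric(n_config)),
    gaussian = list(W = numeric(n_config), Sx = matrix(0, n_config, width),
                    Sxx = array(0, c(width, width, n_config))),
    vonmises_uni = list(W = numeric(n_config), C = numeric(n_config),
                        S = numeric(n_config)),
    vonmises_bi = list(trig = matrix(0, n_config, 7L,
      dimnames = list(NULL, c("W", "c1", "s1", "c2", "s2", "cd", "sd")))),
    kent = list(W = numeric(n_config), Sx = matrix(0, n_config, 3L),
                Sxx = array(0, c(3L, 3L, n_config))),
    stop("unknown family"))
}

stats_family <- function(family) {
  if (family %in% c("gaussian_uni", "gaussian_multi")) "gaussian" else family
}

accumulate_node_stats <- function(st, fam, cfg, V, w = 1) {
  if (!length(cfg)) return(st)
  nc <- if (!is.null(st$counts)) nrow(st$counts)
        else if (!is.null(st$trig)) nrow(st$trig) else length(st$W)
  wv <- rep_len(w, length(cfg))
  switch(fam,
    discrete = {
      size <- ncol(st$counts)
      lin <- cfg + (as.integer(V[, 1L]) - 1L) * nc
      st$counts <- st$counts + matrix(tab_sum(wv, lin, nc * size), nc, size)
      st
    },
    multinomial = {
      for (k in sort(unique(cfg))) {
        sel <- cfg == k
        st$counts[k, ] <- st$counts[k, ] + colSums(V[sel, , drop = FALSE] *
                                                     wv[sel])
      }
      st
    },
    poisson = {
      st$W <- st$W + tab_sum(wv, cfg, nc)
      st$Sk <- st$Sk + tab_sum(wv * V[, 1L], cfg, nc)
      st
    },
    gaussian = {
      for (k in sort(unique(cfg))) {
        sel <- cfg == k
        Xk <- V[sel, , drop = FALSE]; wk <- wv[sel]
        st$W[k] <- st$W[k] + sum(wk)
        st$Sx[k, ] <- st$Sx[k, ] + colSums(Xk * wk)
        st$Sxx[, , k] <- st$Sxx[, , k] + crossprod(Xk * sqrt(wk))
      }
      st
    },
    vonmises_uni = {
      st$W <- st$W + tab_sum(wv, cfg, nc)
      st$C <- st$C + tab_sum(wv * cos(V[, 1L]), cfg, nc)
      st$S <- st$S + tab_sum(wv * sin(V[, 1L]), cfg, nc)
      st
    },
    vonmises_bi = {
      phi <- V[, 1L]; psi <- V[, 2L]
      m <- cbind(wv, wv * cos(phi), wv * sin(phi), wv * cos(psi),
                 wv * sin(psi), wv * cos(phi - psi), wv * sin(phi - psi))
      for (j in 1:7) st$trig[, j] <- st$trig[, j] + tab_sum(m[, j], cfg, nc)
      st
    },
    kent = {
      for (k in sort(unique(cfg))) {
        sel <- cfg == k
        Xk <- V[sel, , drop = FALSE]; wk <- wv[sel]
        st$W[k] <- st$W[k] + sum(wk)
        st$Sx[k, ] <- st$Sx[k, ] + colSums(Xk * wk)
        st$Sxx[, , k] <- st$Sxx[, , k] + crossprod(Xk * sqrt(wk))
      }
      st
    },
    stop("unknown family"))
}

tab_sum <- function(x, cfg, n) {
  out <- numeric(n)
  agg <- rowsum(x, cfg)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Sufficient statistics of a completed dataset
#'
#' Reduces a fully assigned batch to per-node, per-parameter-set weighted
#' sufficient statistics; `weight` scales every observation (used by
#' MC-EM to average over completions).
#' @param params a [dbn_params()] object (for structure only).
#' @param batch a completed [seq_batch()].
#' @param weight observation weight.
#' @param into optional statistics object to accumulate into.
#' @return a `dbn_suffstats` list: per node, `list(p = , p0 = )`.
#' @export
suff_stats <- function(params, batch, weight = 1, into = NULL) {
  spec <- batch$spec
  nn <- n_nodes(spec)
  if (is.null(into)) {
    into <- lapply(seq_len(nn), function(i) {
      nd <- spec$nodes[[i]]; m <- spec$meta[[i]]
      fam <- stats_family(nd$family)
      size <- if (fam %in% c("discrete", "multinomial")) nd$size else nd$size
      list(p = empty_stats(fam, prod(m$psz), size, nd$width),
           p0 = if (m$has_init) empty_stats(fam, prod(m$psz0), size,
                                            nd$width))
    })
    class(into) <- "dbn_suffstats"
  }
  for (i in seq_len(nn)) {
    nd <- spec$nodes[[i]]; m <- spec$meta[[i]]
    fam <- stats_family(nd$family)
    ranges <- if (m$has_init)
      list(list(ts = 1L, set = "p0"),
           list(ts = seq_len(batch$Lmax)[-1L], set = "p"))
    else list(list(ts = seq_len(batch$Lmax), set = "p"))
    for (rg in ranges) {
      for (t in rg$ts) {
        rows <- which(batch$lengths >= t)
        if (!length(rows)) next
        sp <- site_parents(spec, t, i)
        if (nrow(sp$sites)) {
          pa <- vapply(seq_len(nrow(sp$sites)), function(k)
            gather_states(batch, rows, sp$sites[k, 2L], sp$sites[k, 1L]),
            integer(length(rows)))
          cfg <- config_index(matrix(pa, nrow = length(rows)), sp$psz)
        } else cfg <- rep(1L, length(rows))
        V <- matrix(batch$values[[i]][rows, t, ], length(rows))
        into[[i]][[rg$set]] <-
          accumulate_node_stats(into[[i]][[rg$set]], fam, cfg, V, weight)
      }
    }
  }
  into
}

scale_stats <- function(st, f) {
  rapply(st, function(x) x * f, classes = c("numeric", "matrix", "array"),
         how = "replace")
}

## ---- M-step -------------------------------------------------------------

## Re-estimate one family parameter set from its statistics; `prev` breaks
## ties for empty configurations (their parameters are retained).
family_m_step <- function(fam, st, prev, psz, size, config) {
  nc <- as.integer(prod(psz))
  switch(fam,
    discrete = discrete_m_step(st$counts, config$pseudocount,
                               parent_sizes = psz, node_size = size),
    multinomial = {
      fp <- discrete_m_step(st$counts, config$pseudocount,
                            parent_sizes = psz, node_size = size)
      new_family_params("multinomial", psz,
                        list(size = size, prob = fp$prob, logp = fp$logp))
    },
    poisson = {
      rates <- ifelse(st$W > 0, st$Sk / pmax(st$W, 1e-12), prev$rates)
      poisson_params(pmax(rates, 1e-8), psz)
    },
    gaussian = gaussian_from_stats(st, psz, prev$d, config$ridge,
                                   prev = prev),
    vonmises_uni = {
      mu <- prev$mu; kappa <- prev$kappa
      for (k in seq_len(nc)) {
        if (st$W[k] <= 0) next
        fit <- vm_from_stats(st$C[k], st$S[k], st$W[k])
        mu[k] <- fit$mu; kappa[k] <- fit$kappa
      }
      vm_params(mu, kappa, psz)
    },
    vonmises_bi = {
      mu <- prev$mu; nu <- prev$nu
      k1 <- prev$kappa1; k2 <- prev$kappa2; k3 <- prev$kappa3
      for (k in seq_len(nc)) {
        if (st$trig[k, 1L] < 5) next
        fit <- bvm_from_stats(st$trig[k, ])
        mu[k] <- fit$mu; nu[k] <- fit$nu
        k1[k] <- fit$kappa1; k2[k] <- fit$kappa2; k3[k] <- fit$kappa3
      }
      bvm_params(mu, nu, k1, k2, k3, psz)
    },
    kent = {
      kap <- prev$kappa; bet <- prev$beta; gam <- prev$gammas
      for (k in seq_len(nc)) {
        if (st$W[k] < 3) next
        fit <- kent_from_stats(list(W = st$W[k], Sx = st$Sx[k, ],
                                    Sxx = st$Sxx[, , k]))
        kap[k] <- fit$kappa; bet[k] <- fit$beta
        gam[, , k] <- fit$gammas[, , 1L]
      }
      kent_params(kap, bet, gam, psz)
    },
    stop("unknown family"))
}

#' Maximum-likelihood M-step
#'
#' Dispatches to the per-family estimator for every node and parameter
#' set: CPT/multinomial count normalization (with pseudocount), Poisson
#' and Gaussian moment updates, von Mises resultant inversion, bivariate
#' von Mises likelihood maximization and Kent moment estimation.
#' Initial-slice sets are updated from slice-1 statistics only.
#' Configurations with no (or too few) observations retain their previous
#' parameters.
#'
#' @param params current [dbn_params()] (previous iterate).
#' @param stats a `dbn_suffstats` object from [suff_stats()], or a
#'   completed [seq_batch()] (statistics are computed first).
#' @param config an [em_config()].
#' @return updated [dbn_params()].
#' @export
m_step <- function(params, stats, config = em_config()) {
  if (inherits(stats, "seq_batch")) stats <- suff_stats(params, stats)
  spec <- attr(params, "spec")
  out <- params
  for (i in seq_along(params)) {
    np <- params[[i]]
    fam <- stats_family(np$family)
    upd <- tryCatch({
      p <- family_m_step(fam, stats[[i]]$p, np$p, np$p$psz, np$size, config)
      p0 <- if (!is.null(np$p0))
        family_m_step(fam, stats[[i]]$p0, np$p0, np$p0$psz, np$size, config)
      list(p = p, p0 = p0)
    }, error = function(e)
      stop("M-step failed for node ", np$name, ": ", conditionMessage(e),
           call. = FALSE))
    out[[i]]$p <- upd$p
    out[[i]]$p0 <- upd$p0
  }
  out
}

## ---- E-steps ------------------------------------------------------------

#' Stochastic-EM E-step
#'
#' Exactly one Gibbs sweep from the current assignment: the sampled hidden
#' values complete the dataset.
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()] with initialized hidden entries.
#' @return the completed batch.
#' @export
e_step_sem <- function(params, batch) {
  if (!any(vapply(batch$mask, any, TRUE))) return(batch)
  gibbs_sweep(params, batch)
}

#' Monte-Carlo-EM E-step
#'
#' Runs `m` Gibbs sweeps and averages the sufficient statistics of the
#' `m` completions.
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()] with initialized hidden entries.
#' @param m number of completions (>= 1; `m = 1` reduces to the S-EM
#'   statistics).
#' @return `list(stats = averaged dbn_suffstats, batch = final completion)`.
#' @export
e_step_mcem <- function(params, batch, m = 10L) {
  stopifnot(m >= 1L)
  pre <- precompute_emissions(batch$spec, params, batch)
  st <- NULL
  for (k in seq_len(m)) {
    if (any(vapply(batch$mask, any, TRUE)))
      batch <- gibbs_sweep(params, batch, pre)
    st <- suff_stats(params, batch, weight = 1 / m, into = st)
  }
  list(stats = st, batch = batch)
}

## ---- training loop ------------------------------------------------------

#' Train a DBN by stochastic or Monte Carlo EM
#'
#' Initializes parameters (randomly, unless `init` is given) and the
#' hidden entries (ancestral sampling), runs `burn_in` Gibbs sweeps, then
#' iterates E- and M-steps for up to `n_iterations`, tracing the
#' completed-data log-likelihood (and optionally the exact forward
#' log-likelihood for HMM-shaped models).
#'
#' @param spec a [dbn_spec()].
#' @param data a [seq_batch()] compatible with `spec`.
#' @param config an [em_config()].
#' @param init optional initial [dbn_params()].
#' @param resume a `dbn_training_state` from a previous [train()] /
#'   [load_state()]; continues exactly where it stopped (same RNG
#'   stream), ignoring `init`.
#' @return a `dbn_training_state`: final and averaged parameters, the
#'   hidden assignment, the log-likelihood trace and the RNG state.
#' @export
train <- function(spec, data, config = em_config(), init = NULL,
                  resume = NULL) {
  if (is.null(resume) && config$n_starts > 1L) {
    runs <- lapply(seq_len(config$n_starts), function(k) {
      cfg_k <- config
      cfg_k$n_starts <- 1L
      if (!is.null(cfg_k$seed)) cfg_k$seed <- cfg_k$seed + (k - 1L) * 1000L
      train(spec, data, cfg_k, init = init)
    })
    score <- vapply(runs, function(s)
      mean(utils::tail(s$trace$completed_loglik, s$config$window)), 0)
    return(runs[[which.max(score)]])
  }
  if (!is.null(resume)) {
    state <- resume
    params <- state$params
    batch <- state$batch
    assign(".Random.seed", state$rng_state, envir = globalenv())
    stats_window <- state$stats_window
    trace <- state$trace
    start_iter <- state$iteration + 1L
    config <- state$config
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    params <- init %||% dbn_random_params(spec)
    attr(params, "spec") <- spec
    batch <- init_hidden(params, data, force = TRUE)
    for (k in seq_len(config$burn_in))
      if (any(vapply(batch$mask, any, TRUE)))
        batch <- gibbs_sweep(params, batch)
    stats_window <- list()
    trace <- data.frame(iteration = integer(), completed_loglik = numeric(),
                        forward_loglik = numeric())
    start_iter <- 1L
  }
  attr(params, "spec") <- spec
  is_hmm <- !is.null(hmm_shape(spec, data))
  iters <- seq(start_iter, length.out = max(config$n_iterations -
                                              start_iter + 1L, 0L))
  for (n in iters) {
    if (config$flavour == "sem") {
      batch <- e_step_sem(params, batch)
      st <- suff_stats(params, batch)
    } else {
      es <- e_step_mcem(params, batch, config$mcem_samples)
      st <- es$stats
      batch <- es$batch
    }
    params <- m_step(params, st, config)
    attr(params, "spec") <- spec
    stats_window <- c(stats_window, list(st))
    if (length(stats_window) > config$avg_window)
      stats_window <- stats_window[-1L]
    cll <- completed_loglik(params, batch)
    fll <- if (config$compute_forward && is_hmm)
      forward_loglik(params, batch) else NA_real_
    trace <- rbind(trace, data.frame(iteration = n, completed_loglik = cll,
                                     forward_loglik = fll))
    if (config$tolerance > 0 && nrow(trace) >= 2L * config$window) {
      ll <- trace$completed_loglik
      m2 <- mean(utils::tail(ll, config$window))
      m1 <- mean(utils::tail(ll, 2L * config$window)[seq_len(config$window)])
      if (abs(m2 - m1) < config$tolerance * abs(m1)) break
    }
  }
  params_avg <- if (length(stats_window)) {
    avg <- average_stats(stats_window)
    m_step(params, avg, config)
  } else params
  final <- if (config$estimate == "average") params_avg else params
  structure(list(version = STATE_VERSION, spec = spec, config = config,
                 iteration = if (nrow(trace)) max(trace$iteration) else 0L,
                 params = params, params_avg = params_avg,
                 params_final = final, batch = batch, trace = trace,
                 stats_window = stats_window,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "dbn_training_state")
}

average_stats <- function(window) {
  m <- length(window)
  out <- window[[1L]]
  add <- function(a, b) {
    if (is.list(a)) return(mapply(add, a, b, SIMPLIFY = FALSE))
    a + b
  }
  for (k in seq_len(m)[-1L]) out <- add(out, window[[k]])
  out <- rapply(out, function(x) x / m,
                classes = c("numeric", "matrix", "array"), how = "replace")
  class(out) <- "dbn_suffstats"
  out
}

#' @export
print.dbn_training_state <- function(x, ...) {
  cat("<dbn_training_state> iteration ", x$iteration, ", final completed ",
      "log-likelihood ",
      format(utils::tail(x$trace$completed_loglik, 1L)), "\n", sep = "")
  invisible(x)
}

#' Write a training trace as delimited text
#' @param state a `dbn_training_state`.
#' @param path output file path.
#' @export
write_trace <- function(state, path) {
  utils::write.table(state$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
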