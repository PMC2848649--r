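## Gibbs sampling over hidden discrete entries of the unrolled DBN, the
## completed-data log-likelihood, and the exact forward-algorithm
## likelihood for HMM-shaped models.
##
## The sweep is a systematic scan: slices in order, nodes in slice order
## within each slice.  At every (slice, node) site the resampling is
## vectorized across sequences — sequences are independent chains, so this
## is equivalent to any per-sequence ordering of the same scan.

## log-density of every row of V (n x width) under every parameter
## configuration of a family record; returns n x n_config.
family_logdens_all <- function(fp, V) {
  n <- nrow(V)
  switch(fp$family,
    discrete = stop("family_logdens_all is for non-discrete families"),
    poisson = {
      k <- V[, 1L]
      outer(k, log(fp$rates)) -
        matrix(fp$rates, n, fp$n_config, byrow = TRUE) - lgamma(k + 1)
    },
    multinomial = {
      lp <- fp$logp
      lp[!is.finite(lp)] <- -1e300
      lgamma(rowSums(V) + 1) - rowSums(lgamma(V + 1)) + V %*% t(lp)
    },
    gaussian = gaussian_logdens_all(fp, V),
    vonmises_uni = {
      out <- matrix(0, n, fp$n_config)
      for (k in seq_len(fp$n_config))
        out[, k] <- vm_ld(V[, 1L], fp$mu[k], fp$kappa[k])
      out
    },
    vonmises_bi = {
      out <- matrix(0, n, fp$n_config)
      for (k in seq_len(fp$n_config))
        out[, k] <- bvm_ld(V[, 1L], V[, 2L], fp$mu[k], fp$nu[k],
                           fp$kappa1[k], fp$kappa2[k], fp$kappa3[k])
      out
    },
    kent = {
      out <- matrix(0, n, fp$n_config)
      for (k in seq_len(fp$n_config))
        out[, k] <- kent_ld(V, fp$kappa[k], fp$beta[k], fp$gammas[, , k])
      out
    },
    stop("unknown family"))
}

## Flatten a node's values to (n_seq * Lmax) x width, sequence index
## varying fastest (matches array linear order).
flat_values <- function(b, i) {
  v <- b$values[[i]]
  d <- dim(v)
  matrix(v, d[1L] * d[2L], d[3L])
}

## Per-sweep emission cache for non-discrete nodes: log-density of the
## observed value at every (sequence, slice) under every configuration.
## `arr`: n_seq x Lmax x n_config for the tied set; `arr0`: n_seq x
## n_config0 for the initial-slice set when the node has inter parents.
precompute_emissions <- function(spec, params, b) {
  out <- vector("list", n_nodes(spec))
  for (i in seq_len(n_nodes(spec))) {
    fam <- spec$nodes[[i]]$family
    if (fam == "discrete") next
    np <- params[[i]]
    V <- flat_values(b, i)
    ld <- family_logdens_all(np$p, V)
    arr <- array(ld, c(b$n_seq, b$Lmax, np$p$n_config))
    arr0 <- NULL
    if (!is.null(np$p0)) {
      V1 <- matrix(b$values[[i]][, 1L, ], b$n_seq)
      arr0 <- family_logdens_all(np$p0, V1)
    }
    out[[i]] <- list(arr = arr, arr0 = arr0)
  }
  out
}

## States of node j at slice t for the given rows.
gather_states <- function(b, rows, j, t) {
  s <- b$values[[j]][rows, t, 1L]
  if (anyNA(s))
    stop("hidden entries must be initialized before sweeping (node ",
         b$spec$nodes[[j]]$name, ", slice ", t, ")")
  as.integer(s)
}

## Parent (slice, node) sites of node i at slice t together with the
## matching parameter set name.
site_parents <- function(spec, t, i) {
  m <- spec$meta[[i]]
  initial <- t == 1L && m$has_init
  list(sites = parent_sites(spec, t, i), initial = initial,
       psz = if (initial) m$psz0 else m$psz)
}

## Row-major strides of a parent-size vector.
psz_strides <- function(psz) {
  if (!length(psz)) return(integer())
  md_strides(psz)
}

## log p(child value | parents with site (t,i) set to each state s).
## Returns length(rows) x S.
child_logp_matrix <- function(b, params, pre, rows, S, t, i, c_, t_c) {
  spec <- b$spec
  sp <- site_parents(spec, t_c, c_)
  strides <- psz_strides(sp$psz)
  pos <- which(sp$sites[, 1L] == t & sp$sites[, 2L] == i)
  stopifnot(length(pos) == 1L)
  base0 <- rep(0L, length(rows))
  for (k in seq_len(nrow(sp$sites))) {
    if (k == pos) next
    st <- gather_states(b, rows, sp$sites[k, 2L], sp$sites[k, 1L])
    base0 <- base0 + (st - 1L) * strides[k]
  }
  idx0 <- outer(base0, (seq_len(S) - 1L) * strides[pos], "+")
  fp <- param_set(params[[c_]], initial = sp$initial)
  if (fp$family == "discrete") {
    val <- gather_states(b, rows, c_, t_c)
    lin <- idx0 + 1L + (val - 1L) * fp$n_config
    matrix(fp$logp[as.vector(lin)], length(rows), S)
  } else {
    pc <- pre[[c_]]
    if (sp$initial) {
      lin <- rows + idx0 * b$n_seq
      matrix(pc$arr0[as.vector(lin)], length(rows), S)
    } else {
      lin <- rows + (t_c - 1L) * b$n_seq + idx0 * (b$n_seq * b$Lmax)
      matrix(pc$arr[as.vector(lin)], length(rows), S)
    }
  }
}

## Prior term log p(h = s | parents) for the given rows; length(rows) x S.
own_logp_matrix <- function(b, params, rows, t, i) {
  spec <- b$spec
  sp <- site_parents(spec, t, i)
  fp <- param_set(params[[i]], initial = sp$initial)
  if (nrow(sp$sites)) {
    pa <- vapply(seq_len(nrow(sp$sites)), function(k)
      gather_states(b, rows, sp$sites[k, 2L], sp$sites[k, 1L]),
      integer(length(rows)))
    cfg <- config_index(matrix(pa, nrow = length(rows)), sp$psz)
  } else {
    cfg <- rep(1L, length(rows))
  }
  fp$logp[cfg, , drop = FALSE]
}

#' One systematic Gibbs sweep over all hidden entries
#'
#' Every hidden entry is resampled from its full conditional
#' `p(h | Markov blanket) \propto p(h | parents) * prod_children p(child |
#' parents)`, normalized over the node's states in log space.  Scan order
#' is slice-major with nodes in slice order; within a site all sequences
#' are resampled together (sequences are independent chains).  Work per
#' entry is proportional to the node's state count, so a sweep costs
#' `O(l * s)` resample operations per hidden chain, with `l` the total
#' number of slices.
#'
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()] whose hidden entries are all initialized
#'   (see [init_hidden()]).
#' @param pre optional emission cache from `precompute_emissions()`.
#' @return the batch with hidden entries resampled; attribute `n_ops`
#'   holds the number of (entry x state) resample operations.
#' @export
gibbs_sweep <- function(params, batch, pre = NULL) {
  spec <- batch$spec
  if (is.null(pre)) pre <- precompute_emissions(spec, params, batch)
  n_ops <- 0
  for (t in seq_len(batch$Lmax)) {
    for (i in seq_len(n_nodes(spec))) {
      rows <- which(batch$mask[[i]][, t] & batch$lengths >= t)
      if (!length(rows)) next
      S <- spec$nodes[[i]]$size
      lp <- own_logp_matrix(batch, params, rows, t, i)
      m <- spec$meta[[i]]
      for (c_ in m$intra_children)
        lp <- lp + child_logp_matrix(batch, params, pre, rows, S, t, i, c_, t)
      if (length(m$inter_children)) {
        sub <- which(batch$lengths[rows] >= t + 1L)
        if (length(sub)) {
          for (c_ in m$inter_children)
            lp[sub, ] <- lp[sub, , drop = FALSE] +
              child_logp_matrix(batch, params, pre, rows[sub], S, t, i, c_,
                                t + 1L)
        }
      }
      mx <- apply(lp, 1L, max)
      if (any(!is.finite(mx)))
        stop("numerical underflow: all states have zero probability at ",
             "node ", spec$nodes[[i]]$name, ", slice ", t, ", sequence ",
             rows[which(!is.finite(mx))[1L]])
      prob <- exp(lp - mx)
      batch$values[[i]][cbind(rows, t, 1L)] <- sample_rows(prob)
      n_ops <- n_ops + length(rows) * S
    }
  }
  attr(batch, "n_ops") <- n_ops
  batch
}

#' Initialize hidden entries by ancestral sampling
#'
#' Draws every hidden entry from `p(h | parents)` under the current
#' parameters, in scan order, ignoring children — a feasible starting
#' point for the Gibbs chain.
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()].
#' @param force resample entries that already have a value?
#' @return the initialized batch.
#' @export
init_hidden <- function(params, batch, force = TRUE) {
  spec <- batch$spec
  for (t in seq_len(batch$Lmax)) {
    for (i in seq_len(n_nodes(spec))) {
      rows <- which(batch$mask[[i]][, t] & batch$lengths >= t)
      if (!force)
        rows <- rows[is.na(batch$values[[i]][rows, t, 1L])]
      if (!length(rows)) next
      lp <- own_logp_matrix(batch, params, rows, t, i)
      batch$values[[i]][cbind(rows, t, 1L)] <- sample_rows(exp(lp))
    }
  }
  batch
}

#' Approximate posterior state frequencies by Gibbs sampling
#'
#' Runs `n_burn` discarded sweeps followed by `n_samples` retained sweeps
#' and tabulates, for every hidden entry, the empirical frequency of each
#' state across the retained sweeps.
#'
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()].
#' @param n_burn discarded sweeps.
#' @param n_samples retained sweeps (>= 1).
#' @return list over nodes: for hidden nodes an array `n_seq x max_len x
#'   size` of frequencies (rows at hidden entries sum to 1), else `NULL`.
#' @export
gibbs_infer <- function(params, batch, n_burn = 100L, n_samples = 1000L) {
  stopifnot(n_samples >= 1L)
  spec <- batch$spec
  batch <- init_hidden(params, batch, force = FALSE)
  pre <- precompute_emissions(spec, params, batch)
  for (k in seq_len(n_burn)) batch <- gibbs_sweep(params, batch, pre)
  counts <- lapply(seq_len(n_nodes(spec)), function(i)
    if (any(batch$mask[[i]]))
      array(0, c(batch$n_seq, batch$Lmax, spec$nodes[[i]]$size)))
  for (k in seq_len(n_samples)) {
    batch <- gibbs_sweep(params, batch, pre)
    for (i in seq_len(n_nodes(spec))) {
      if (is.null(counts[[i]])) next
      hid <- which(batch$mask[[i]], arr.ind = TRUE)
      st <- batch$values[[i]][cbind(hid, 1L)]
      idx <- cbind(hid, st)
      counts[[i]][idx] <- counts[[i]][idx] + 1
    }
  }
  lapply(counts, function(x) if (!is.null(x)) x / n_samples)
}

## Sum of log p(value | parents) over all valid (sequence, slice) entries
## of one node, given fully assigned data.
node_loglik_sum <- function(params, b, i) {
  spec <- b$spec
  m <- spec$meta[[i]]
  np <- params[[i]]
  fam <- spec$nodes[[i]]$family
  total <- 0
  ranges <- if (m$has_init)
    list(list(ts = 1L, initial = TRUE),
         list(ts = seq_len(b$Lmax)[-1L], initial = FALSE))
  else list(list(ts = seq_len(b$Lmax), initial = FALSE))
  for (rg in ranges) {
    if (!length(rg$ts)) next
    fp <- param_set(np, initial = rg$initial)
    for (t in rg$ts) {
      rows <- which(b$lengths >= t)
      if (!length(rows)) next
      sp <- site_parents(spec, t, i)
      if (nrow(sp$sites)) {
        pa <- vapply(seq_len(nrow(sp$sites)), function(k)
          gather_states(b, rows, sp$sites[k, 2L], sp$sites[k, 1L]),
          integer(length(rows)))
        cfg <- config_index(matrix(pa, nrow = length(rows)), sp$psz)
      } else cfg <- rep(1L, length(rows))
      if (fam == "discrete") {
        val <- gather_states(b, rows, i, t)
        total <- total + sum(fp$logp[cbind(cfg, val)])
      } else {
        V <- matrix(b$values[[i]][rows, t, ], length(rows))
        ld <- family_logdens_all(fp, V)
        total <- total + sum(ld[cbind(seq_along(rows), cfg)])
      }
    }
  }
  total
}

#' Completed-data log-likelihood
#'
#' `log P(D | H, theta)`: the joint log-probability of the data with the
#' hidden entries fixed at their current assignment — the sum over all
#' sequences, slices and nodes of the node's log-density given its (fully
#' assigned) parents.  With no hidden entries this is the joint
#' log-likelihood of the observed data.
#'
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()] with all hidden entries assigned.
#' @return scalar log-probability.
#' @export
completed_loglik <- function(params, batch) {
  sum(vapply(seq_len(n_nodes(batch$spec)), function(i)
    node_loglik_sum(params, batch, i), 0))
}

## HMM-shape detection: one hidden discrete chain with a self inter edge
## and otherwise only observed intra-slice children of the chain.
hmm_shape <- function(spec, batch = NULL) {
  hid <- which(vapply(spec$nodes, `[[`, TRUE, "hidden"))
  if (length(hid) != 1L) return(NULL)
  h <- hid
  if (spec$nodes[[h]]$family != "discrete") return(NULL)
  if (nrow(spec$inter_edges) != 1L ||
      !all(spec$inter_edges[1L, ] == c(h, h))) return(NULL)
  m <- spec$meta[[h]]
  if (length(m$intra_parents)) return(NULL)
  outputs <- setdiff(seq_len(n_nodes(spec)), h)
  for (j in outputs) {
    mj <- spec$meta[[j]]
    if (!identical(mj$intra_parents, h) || length(mj$inter_parents) ||
        length(mj$intra_children) || length(mj$inter_children))
      return(NULL)
  }
  if (!is.null(batch)) {
    valid <- valid_grid(batch)
    if (!all(batch$mask[[h]][valid])) return(NULL)
    for (j in outputs) if (any(batch$mask[[j]])) return(NULL)
  }
  list(h = h, outputs = outputs)
}

#' Exact observed-data log-likelihood via the forward algorithm
#'
#' For HMM-shaped models (a single hidden discrete chain with a
#' hidden-to-hidden inter edge and observed intra-slice output children)
#' computes `log P(D | theta)` by the scaled forward recursion, summing
#' over all hidden state paths.  Any other topology is refused.
#'
#' @param params a [dbn_params()] object.
#' @param batch a [seq_batch()] with the chain fully hidden and all
#'   outputs fully observed.
#' @return scalar log-likelihood (summed over sequences).
#' @export
forward_loglik <- function(params, batch) {
  spec <- batch$spec
  shape <- hmm_shape(spec, batch)
  if (is.null(shape))
    stop("unsupported topology: the forward algorithm requires an ",
         "HMM-shaped model (one hidden discrete chain with observed ",
         "intra-slice outputs)")
  h <- shape$h
  S <- spec$nodes[[h]]$size
  lpi <- as.numeric(params[[h]]$p0$logp)      # initial distribution
  lT <- params[[h]]$p$logp                    # S x S transition, rows = prev
  ## emission log-density matrices per output node
  emis <- array(0, c(batch$n_seq, batch$Lmax, S))
  for (j in shape$outputs) {
    fam <- spec$nodes[[j]]$family
    if (fam == "discrete") {
      fp <- params[[j]]$p
      val <- matrix(batch$values[[j]][, , 1L], batch$n_seq)
      for (s in seq_len(S)) {
        lpv <- fp$logp[s, ]
        emis[, , s] <- emis[, , s] + matrix(lpv[val], batch$n_seq)
      }
    } else {
      ld <- family_logdens_all(params[[j]]$p, flat_values(batch, j))
      emis <- emis + array(ld, c(batch$n_seq, batch$Lmax, S))
    }
  }
  Tm <- exp(lT)
  total <- 0
  for (q in seq_len(batch$n_seq)) {
    L <- batch$lengths[q]
    e1 <- emis[q, 1L, ]
    la <- lpi + e1
    c1 <- log_sum_exp(la)
    a <- exp(la - c1)
    ll <- c1
    if (L > 1L) for (t in 2:L) {
      pred <- as.numeric(crossprod(Tm, a))
      la <- log(pred) + emis[q, t, ]
      ct <- log_sum_exp(la)
      a <- exp(la - ct)
      ll <- ll + ct
    }
    total <- total + ll
  }
  total
}

#' Write posterior state frequencies as delimited text
#'
#' One row per `(sequence, slice, node, state)` hidden entry with its
#' posterior frequency, as produced by [gibbs_infer()].
#' @param freq list of frequency arrays from [gibbs_infer()].
#' @param batch the [seq_batch()] the frequencies refer to.
#' @param path output file path.
#' @export
write_posterior <- function(freq, batch, path) {
  spec <- batch$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sequence\tslice\tnode\tstate\tfrequency", con)
  for (i in seq_along(freq)) {
    if (is.null(freq[[i]])) next
    hid <- which(batch$mask[[i]], arr.ind = TRUE)
    for (r in seq_len(nrow(hid))) {
      s <- hid[r, 1L]; t <- hid[r, 2L]
      for (k in seq_len(spec$nodes[[i]]$size))
        writeLines(paste(s, t, spec$nodes[[i]]$name, k,
                         fmt_num(freq[[i]][s, t, k]), sep = "\t"), con)
    }
  }
  invisible(path)
}
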