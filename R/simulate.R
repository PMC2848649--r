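## Ancestral sampling of sequences from a parameterized DBN.

## n draws from a family record, one per entry of cfg (grouped by
## configuration so samplers amortize their setup).
family_sample_vec <- function(fp, cfg, trials = 10L) {
  n <- length(cfg)
  switch(fp$family,
    discrete = matrix(sample_rows(fp$prob[cfg, , drop = FALSE]), ncol = 1L),
    poisson = matrix(stats::rpois(n, fp$rates[cfg]), ncol = 1L),
    multinomial = {
      out <- matrix(0, n, fp$size)
      for (k in sort(unique(cfg))) {
        sel <- which(cfg == k)
        out[sel, ] <- t(stats::rmultinom(length(sel), trials, fp$prob[k, ]))
      }
      out
    },
    gaussian = {
      out <- matrix(0, n, fp$d)
      for (k in sort(unique(cfg))) {
        sel <- which(cfg == k)
        Z <- matrix(stats::rnorm(length(sel) * fp$d), ncol = fp$d)
        out[sel, ] <- sweep(Z %*% fp$chol[[k]], 2L, fp$means[k, ], "+")
      }
      out
    },
    vonmises_uni = {
      out <- numeric(n)
      for (k in sort(unique(cfg))) {
        sel <- which(cfg == k)
        out[sel] <- vm_sample(length(sel), fp$mu[k], fp$kappa[k])
      }
      matrix(out, ncol = 1L)
    },
    vonmises_bi = {
      out <- matrix(0, n, 2L)
      for (k in sort(unique(cfg))) {
        sel <- which(cfg == k)
        pp <- bvm_params(fp$mu[k], fp$nu[k], fp$kappa1[k], fp$kappa2[k],
                         fp$kappa3[k])
        out[sel, ] <- bvm_sample(pp, length(sel))
      }
      out
    },
    kent = {
      out <- matrix(0, n, 3L)
      for (k in sort(unique(cfg))) {
        sel <- which(cfg == k)
        pp <- kent_params(fp$kappa[k], fp$beta[k],
                          fp$gammas[, , k, drop = FALSE])
        out[sel, ] <- kent_sample(pp, length(sel))
      }
      out
    },
    stop("unknown family"))
}

#' Sample sequences from a DBN by ancestral sampling
#'
#' Slices are generated in order; within a slice, nodes in slice order
#' (a topological order), each drawn from its conditional given the
#' already-sampled parents.  Slice 1 uses the initial-slice parameter sets
#' of nodes with inter parents.  Draws are vectorized across sequences at
#' each (slice, node) site.
#'
#' @param spec a [dbn_spec()].
#' @param params a [dbn_params()] object.
#' @param n_seq number of sequences.
#' @param n_slices slices per sequence (scalar or vector of lengths).
#' @param trials trial count used for multinomial nodes.
#' @return a fully observed [seq_batch()].
#' @export
dbn_simulate <- function(spec, params, n_seq, n_slices, trials = 10L) {
  lens <- rep_len(as.integer(n_slices), n_seq)
  Lmax <- max(lens)
  nn <- n_nodes(spec)
  values <- lapply(spec$nodes, function(nd)
    array(NA_real_, c(n_seq, Lmax, nd$width)))
  for (t in seq_len(Lmax)) {
    rows <- which(lens >= t)
    if (!length(rows)) next
    for (i in seq_len(nn)) {
      sp <- site_parents(spec, t, i)
      fp <- param_set(params[[i]], initial = sp$initial)
      if (nrow(sp$sites)) {
        pa <- vapply(seq_len(nrow(sp$sites)), function(k)
          as.integer(values[[sp$sites[k, 2L]]][rows, sp$sites[k, 1L], 1L]),
          integer(length(rows)))
        cfg <- config_index(matrix(pa, nrow = length(rows)), sp$psz)
      } else cfg <- rep(1L, length(rows))
      values[[i]][rows, t, ] <- family_sample_vec(fp, cfg, trials)
    }
  }
  mask <- lapply(spec$nodes, function(nd) matrix(FALSE, n_seq, Lmax))
  seq_batch(spec, values = values, mask = mask, lengths = lens)
}

#' Hide all entries of the hidden-flagged nodes of a batch
#'
#' Sets the mask of every `hidden = TRUE` node to `TRUE` on all valid
#' slices and clears the values (the typical training setup where a
#' latent chain is entirely unobserved).
#' @param batch a [seq_batch()].
#' @return the masked batch.
#' @export
mask_hidden_nodes <- function(batch) {
  spec <- batch$spec
  valid <- valid_grid(batch)
  for (i in seq_len(n_nodes(spec))) {
    if (!spec$nodes[[i]]$hidden) next
    batch$mask[[i]] <- valid
    batch$values[[i]][, , 1L][valid] <- NA_real_
  }
  batch
}
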