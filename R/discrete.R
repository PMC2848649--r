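## Categorical (CPT), multinomial and Poisson nodes.

check_parents <- function(p, parents) {
  parents <- as.integer(parents)
  if (length(parents) != length(p$psz))
    stop("expected ", length(p$psz), " parent states, got ", length(parents))
  if (anyNA(parents) || any(parents < 1L) || any(parents > p$psz))
    stop("parent state out of range")
  parents
}

#' Log-probability of a discrete node value
#'
#' @param p a [cpt_params()] object.
#' @param parents integer vector of parent states (1-based), one per parent.
#' @param value the node's own state (1-based).
#' @return `log(table[parents, value])`; `-Inf` for a zero entry.
#' @export
discrete_log_density <- function(p, parents, value) {
  parents <- check_parents(p, parents)
  value <- as.integer(value)
  if (is.na(value) || value < 1L || value > p$size)
    stop("value out of range")
  p$logp[config_index(rbind(parents), p$psz), value]
}

#' Sample a discrete node
#'
#' Inverse-CDF over the node's states with a single uniform variate; ties
#' break toward the lower index, so the draw is a deterministic function of
#' the RNG stream.
#' @inheritParams discrete_log_density
#' @return a state in `1:size`.
#' @export
discrete_sample <- function(p, parents) {
  parents <- check_parents(p, parents)
  row <- p$prob[config_index(rbind(parents), p$psz), , drop = FALSE]
  sample_rows(row)
}

#' Maximum-likelihood CPT update from counts
#'
#' `table[c, k] = (counts[c, k] + pseudocount) / sum_k'(counts[c, k'] +
#' pseudocount)`; rows with all-zero counts and zero pseudocount become
#' uniform.
#'
#' @param counts an [mdarray()] (or matrix `n_config x size`) of
#'   nonnegative counts shaped like the CPT.
#' @param pseudocount nonnegative per-cell smoothing constant.
#' @param parent_sizes,node_size extents when `counts` is a plain matrix.
#' @return a [cpt_params()] object.
#' @export
discrete_m_step <- function(counts, pseudocount = 0,
                            parent_sizes = NULL, node_size = NULL) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (inherits(counts, "mdarray")) {
    node_size <- counts$shape[length(counts$shape)]
    parent_sizes <- counts$shape[-length(counts$shape)]
    counts <- md_as_config_matrix(counts, node_size)
  } else {
    counts <- rbind(counts)
    node_size <- node_size %||% ncol(counts)
    parent_sizes <- parent_sizes %||% nrow(counts)
    if (prod(parent_sizes) != nrow(counts))
      stop("parent_sizes inconsistent with counts")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  m <- counts + pseudocount
  tot <- rowSums(m)
  empty <- tot == 0
  m[empty, ] <- 1
  tot[empty] <- node_size
  prob <- m / tot
  new_family_params("discrete", parent_sizes,
                    list(size = as.integer(node_size), prob = prob,
                         logp = log(prob)))
}

#' Poisson node log-probability
#' @param p a [poisson_params()] object.
#' @param parents integer vector of parent states.
#' @param k nonnegative integer count.
#' @return `k log(lambda) - lambda - log(k!)`.
#' @export
poisson_log_density <- function(p, parents, k) {
  parents <- check_parents(p, parents)
  if (any(k < 0) || any(k != round(k))) stop("k must be a nonnegative integer")
  lambda <- p$rates[config_index(rbind(parents), p$psz)]
  k * log(lambda) - lambda - lgamma(k + 1)
}

#' Multinomial node log-probability
#'
#' Multinomial pmf with per-observation trial count `n = sum(counts)`,
#' including the multinomial coefficient.
#' @param p a [multinomial_params()] object.
#' @param parents integer vector of parent states.
#' @param counts nonnegative count vector of length `size`.
#' @export
multinomial_log_density <- function(p, parents, counts) {
  parents <- check_parents(p, parents)
  if (length(counts) != p$size)
    stop("counts length ", length(counts), " does not match ", p$size,
         " categories")
  if (any(counts < 0)) stop("counts must be nonnegative")
  lp <- p$logp[config_index(rbind(parents), p$psz), ]
  pos <- counts > 0
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) +
    sum(counts[pos] * lp[pos])
}
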