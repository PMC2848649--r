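## Benchmark fixture generators: three reference architectures with
## randomly parameterized true models and ancestrally sampled training
## data, the standard testbed for S-EM/MC-EM learning at a realistic
## sequence scale (by default 200 sequences of 50 slices).

#' Describe a benchmark fixture
#'
#' Three architectures:
#' \describe{
#'   \item{`discrete_hmm`}{two discrete nodes per slice (one hidden, one
#'     output), both with 5 states.}
#'   \item{`gaussian_hmm`}{a 10-state hidden node with a 4-dimensional
#'     Gaussian output node.}
#'   \item{`complex`}{two hidden chains H (5 states) and I (3 states); H
#'     parents a 4-dimensional Gaussian node G, I parents a bivariate von
#'     Mises node V.}
#' }
#' @param name benchmark name.
#' @param n_slices slices per sequence.
#' @param n_sequences number of training sequences.
#' @param seed RNG seed for [generate_benchmark()] (`NULL` = current
#'   stream).
#' @return a `benchmark_spec` list.
#' @export
benchmark_spec <- function(name = c("discrete_hmm", "gaussian_hmm",
                                    "complex"),
                           n_slices = 50L, n_sequences = 200L, seed = NULL) {
  structure(list(name = match.arg(name), n_slices = as.integer(n_slices),
                 n_sequences = as.integer(n_sequences), seed = seed),
            class = "benchmark_spec")
}

benchmark_dbn <- function(name) {
  switch(name,
    discrete_hmm = dbn_spec(
      list(node_spec("hidden", "discrete", 5L, hidden = TRUE),
           node_spec("output", "discrete", 5L)),
      intra_edges = rbind(c(1L, 2L)),
      inter_edges = rbind(c(1L, 1L))),
    gaussian_hmm = dbn_spec(
      list(node_spec("hidden", "discrete", 10L, hidden = TRUE),
           node_spec("output", "gaussian_multi", 4L)),
      intra_edges = rbind(c(1L, 2L)),
      inter_edges = rbind(c(1L, 1L))),
    complex = dbn_spec(
      list(node_spec("H", "discrete", 5L, hidden = TRUE),
           node_spec("I", "discrete", 3L, hidden = TRUE),
           node_spec("G", "gaussian_multi", 4L),
           node_spec("V", "vonmises_bi", 2L)),
      intra_edges = rbind(c(1L, 3L), c(2L, 4L)),
      inter_edges = rbind(c(1L, 1L), c(2L, 2L))),
    stop("unknown benchmark: ", name))
}

#' A strongly identified reference HMM for parameter-recovery checks
#'
#' A 5-state hidden chain with cyclic transitions (probability 0.7 to the
#' next state, 0.2 to stay) and near-diagonal 5-symbol emissions
#' (probability 0.95 on the matching symbol), uniform initial
#' distribution.  Parameter recovery is only meaningful where the
#' estimand is well identified; this model keeps the maximum-likelihood
#' error per CPT entry well below the S-EM sampling noise at a few
#' thousand slices of data.
#'
#' @return `list(spec, params)`.
#' @export
reference_hmm <- function() {
  S <- 5L
  Tm <- matrix(0.1 / 3, S, S)
  diag(Tm) <- 0.2
  for (i in seq_len(S)) Tm[i, i %% S + 1L] <- 0.7
  Tm <- Tm / rowSums(Tm)
  Em <- matrix(0.05 / 4, S, S)
  diag(Em) <- 0.95
  spec <- benchmark_dbn("discrete_hmm")
  params <- dbn_params(spec, list(
    list(p = cpt_params(mdarray(c(S, S), as.vector(t(Tm)))),
         p0 = cpt_params(mdarray(S, rep(1 / S, S)))),
    list(p = cpt_params(mdarray(c(S, S), as.vector(t(Em)))), p0 = NULL)))
  attr(params, "spec") <- spec
  list(spec = spec, params = params)
}

#' Generate a benchmark fixture
#'
#' Builds the named architecture, draws true parameters from diffuse
#' distributions (CPT rows from a flat Dirichlet; Gaussian means standard
#' normal with random-rotation covariances; von Mises means uniform on the
#' circle with moderate concentrations — see [dbn_random_params()]),
#' ancestrally samples the sequences and masks every hidden-node entry.
#'
#' @param b a [benchmark_spec()].
#' @return `list(spec, params, data, complete)`: the architecture, the
#'   true parameters, the masked training batch and the unmasked batch.
#' @export
generate_benchmark <- function(b) {
  stopifnot(inherits(b, "benchmark_spec"))
  if (!is.null(b$seed)) set.seed(b$seed)
  spec <- benchmark_dbn(b$name)
  params <- dbn_random_params(spec)
  attr(params, "spec") <- spec
  complete <- dbn_simulate(spec, params, b$n_sequences, b$n_slices)
  data <- mask_hidden_nodes(complete)
  list(spec = spec, params = params, data = data, complete = complete)
}
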