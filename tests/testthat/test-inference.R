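test_that("the Gibbs conditional matches the enumerated posterior", {
  ## single-slice model: hidden 2-state node with one discrete child
  spec <- dbn_spec(list(node_spec("h", "discrete", 2, hidden = TRUE),
                        node_spec("o", "discrete", 3)),
                   intra_edges = rbind(c(1, 2)))
  set.seed(25)
  prior <- random_stochastic_matrix(1, 2)
  emis <- random_stochastic_matrix(2, 3)
  params <- dbn_params(spec, list(
    list(p = cpt_params(cm2md(prior, integer(), 2)), p0 = NULL),
    list(p = cpt_params(cm2md(emis, 2, 3)), p0 = NULL)))
  attr(params, "spec") <- spec
  obs <- 2L
  ## exact posterior p(h | o = 2)
  post <- prior[1, ] * emis[, obs]
  post <- post / sum(post)
  ## 100 parallel sequences x 1000 sweeps = 1e5 conditional draws
  n_chains <- 100L
  b <- seq_batch(spec, values = list(
    array(NA_real_, c(n_chains, 1, 1)),
    array(obs, c(n_chains, 1, 1))),
    mask = list(matrix(TRUE, n_chains, 1), matrix(FALSE, n_chains, 1)),
    lengths = rep(1L, n_chains))
  b <- init_hidden(params, b)
  hits <- 0
  for (k in 1:1000) {
    b <- gibbs_sweep(params, b)
    hits <- hits + sum(b$values[[1]][, 1, 1] == 1)
  }
  expect_equal(hits / (1000 * n_chains), post[1], tolerance = 0.005)
})

test_that("a deterministic emission forces the emitting state", {
  spec <- dbn_spec(list(node_spec("h", "discrete", 3, hidden = TRUE),
                        node_spec("o", "discrete", 3)),
                   intra_edges = rbind(c(1, 2)))
  emis <- diag(3)
  params <- dbn_params(spec, list(
    list(p = cpt_params(mdarray(3, rep(1 / 3, 3))), p0 = NULL),
    list(p = cpt_params(cm2md(emis, 3, 3)), p0 = NULL)))
  attr(params, "spec") <- spec
  b <- seq_batch(spec, values = list(array(NA_real_, c(5, 1, 1)),
                                     array(c(1, 2, 3, 2, 1), c(5, 1, 1))),
                 mask = list(matrix(TRUE, 5, 1), matrix(FALSE, 5, 1)),
                 lengths = rep(1L, 5))
  set.seed(26)
  b <- init_hidden(params, b)
  b <- gibbs_sweep(params, b)
  expect_equal(b$values[[1]][, 1, 1], c(1, 2, 3, 2, 1))
})

test_that("sweep cost scales linearly in slices and states", {
  set.seed(27)
  count_ops <- function(S, L, n_seq = 3) {
    spec <- make_hmm_spec(S, 2L)
    params <- make_hmm_params(spec, rep(1 / S, S),
                              random_stochastic_matrix(S, S),
                              random_stochastic_matrix(S, 2))
    d <- mask_hidden_nodes(dbn_simulate(spec, params, n_seq, L))
    d <- init_hidden(params, d)
    attr(gibbs_sweep(params, d), "n_ops")
  }
  expect_equal(count_ops(4, 20), 2 * count_ops(4, 10))
  expect_equal(count_ops(8, 10), 2 * count_ops(4, 10))
})

test_that("forward equals path enumeration and its closed forms", {
  set.seed(28)
  spec <- make_hmm_spec(2, 2)
  pi0 <- c(0.6, 0.4)
  Tm <- random_stochastic_matrix(2, 2)
  Em <- random_stochastic_matrix(2, 2)
  params <- make_hmm_params(spec, pi0, Tm, Em)
  b <- mask_hidden_nodes(dbn_simulate(spec, params, 1, 3))
  obs <- b$values[[2]][1, , 1]
  expect_equal(forward_loglik(params, b),
               enumerate_hmm_loglik(pi0, Tm, Em, obs), tolerance = 1e-10)

  ## uniform transitions and emissions over M symbols: L log(1/M)
  M <- 4L; L <- 7L
  spec_u <- make_hmm_spec(M, M)
  params_u <- make_hmm_params(spec_u, rep(1 / M, M),
                              matrix(1 / M, M, M), matrix(1 / M, M, M))
  bu <- mask_hidden_nodes(dbn_simulate(spec_u, params_u, 1, L))
  expect_equal(forward_loglik(params_u, bu), L * log(1 / M),
               tolerance = 1e-12)

  ## summing over paths can only beat any single completion
  bc <- init_hidden(params, b)
  expect_gte(forward_loglik(params, b), completed_loglik(params, bc))

  ## invariant under relabeling of the hidden states
  pm <- c(2, 1)
  params_p <- make_hmm_params(spec, pi0[pm], Tm[pm, pm], Em[pm, ])
  expect_equal(forward_loglik(params_p, b), forward_loglik(params, b),
               tolerance = 1e-12)

  ## non-HMM topology is refused
  cx <- gibbsdbn:::benchmark_dbn("complex")
  px <- dbn_random_params(cx); attr(px, "spec") <- cx
  bx <- mask_hidden_nodes(dbn_simulate(cx, px, 1, 3))
  expect_error(forward_loglik(px, bx), "topology")
})

test_that("completed log-likelihood matches brute-force factor sums", {
  ## parentless uniform 5-state node observed over 50 slices
  spec1 <- dbn_spec(list(node_spec("x", "discrete", 5)))
  p1 <- dbn_params(spec1, list(list(p = cpt_params(mdarray(5, rep(0.2, 5))),
                                    p0 = NULL)))
  attr(p1, "spec") <- spec1
  set.seed(29)
  b1 <- dbn_simulate(spec1, p1, 1, 50)
  expect_equal(completed_loglik(p1, b1), 50 * log(1 / 5), tolerance = 1e-12)

  ## random tiny model: per-factor recomputation
  spec <- make_hmm_spec(3, 4)
  pi0 <- as.numeric(random_stochastic_matrix(1, 3))
  Tm <- random_stochastic_matrix(3, 3)
  Em <- random_stochastic_matrix(3, 4)
  params <- make_hmm_params(spec, pi0, Tm, Em)
  b <- dbn_simulate(spec, params, 2, 4)
  brute <- 0
  for (q in 1:2) {
    h <- b$values[[1]][q, , 1]; o <- b$values[[2]][q, , 1]
    brute <- brute + log(pi0[h[1]]) + sum(log(Em[cbind(h, o)])) +
      sum(log(Tm[cbind(h[-4], h[-1])]))
  }
  expect_equal(completed_loglik(params, b), brute, tolerance = 1e-10)

  ## with nothing hidden this is the joint likelihood of the data
  expect_false(any(vapply(b$mask, any, TRUE)))
})

test_that("posterior frequencies match forward-backward marginals", {
  set.seed(30)
  spec <- make_hmm_spec(2, 2)
  pi0 <- c(0.5, 0.5)
  Tm <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  Em <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  params <- make_hmm_params(spec, pi0, Tm, Em)
  b <- mask_hidden_nodes(dbn_simulate(spec, params, 1, 3))
  obs <- b$values[[2]][1, , 1]
  g <- fb_marginals(pi0, Tm, Em, obs)
  freq <- gibbs_infer(params, b, n_burn = 200, n_samples = 2e4)
  emp <- freq[[1]][1, , ]
  tv <- vapply(1:3, function(t) 0.5 * sum(abs(emp[t, ] - g[t, ])), 0)
  expect_true(all(tv < 0.02))
  expect_true(all(abs(rowSums(emp) - 1) < 1e-12))
})

test_that("one retained sweep yields one-hot frequencies; symmetry holds", {
  set.seed(31)
  spec <- make_hmm_spec(2, 2)
  params <- make_hmm_params(spec, c(0.5, 0.5),
                            rbind(c(0.5, 0.5), c(0.5, 0.5)),
                            rbind(c(0.5, 0.5), c(0.5, 0.5)))
  b <- mask_hidden_nodes(dbn_simulate(spec, params, 2, 4))
  f1 <- gibbs_infer(params, b, n_burn = 5, n_samples = 1)
  expect_true(all(f1[[1]][!is.na(f1[[1]])] %in% c(0, 1)))

  ## exchangeable states with symmetric emissions: marginals 0.5 each
  f <- gibbs_infer(params, b, n_burn = 50, n_samples = 2e4)
  expect_true(all(abs(f[[1]] - 0.5) < 0.015))
})
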