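test_that("the S-EM E-step completes the data reproducibly", {
  set.seed(32)
  spec <- make_hmm_spec(3, 3)
  params <- make_hmm_params(spec, rep(1 / 3, 3),
                            random_stochastic_matrix(3, 3),
                            random_stochastic_matrix(3, 3))
  full <- dbn_simulate(spec, params, 3, 6)
  ## no hidden entries: identity
  expect_identical(e_step_sem(params, full)$values, full$values)

  b <- init_hidden(params, mask_hidden_nodes(full))
  set.seed(1); c1 <- e_step_sem(params, b)
  set.seed(1); c2 <- e_step_sem(params, b)
  expect_identical(c1$values, c2$values)
  expect_false(anyNA(c1$values[[1]][, , 1]))
})

test_that("MC-EM statistics average toward the enumerated posterior", {
  ## single-slice toy: expected count of h = posterior probability
  spec <- dbn_spec(list(node_spec("h", "discrete", 2, hidden = TRUE),
                        node_spec("o", "discrete", 2)),
                   intra_edges = rbind(c(1, 2)))
  prior <- rbind(c(0.7, 0.3))
  emis <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  params <- dbn_params(spec, list(
    list(p = cpt_params(cm2md(prior, integer(), 2)), p0 = NULL),
    list(p = cpt_params(cm2md(emis, 2, 2)), p0 = NULL)))
  attr(params, "spec") <- spec
  b <- seq_batch(spec, values = list(array(NA_real_, c(50, 1, 1)),
                                     array(1, c(50, 1, 1))),
                 mask = list(matrix(TRUE, 50, 1), matrix(FALSE, 50, 1)),
                 lengths = rep(1L, 50))
  set.seed(33)
  b <- init_hidden(params, b)
  es <- e_step_mcem(params, b, m = 1000)
  post1 <- prior[1] * emis[1, 1] / sum(prior * emis[, 1])
  expect_equal(es$stats[[1]]$p$counts[1, 1] / 50, post1, tolerance = 0.02)

  ## m = 1 reduces to the S-EM statistics of the same completion
  set.seed(34)
  es1 <- e_step_mcem(params, b, m = 1)
  expect_equal(sum(es1$stats[[1]]$p$counts), 50)
})

test_that("the M-step reproduces fully observed ML per family", {
  set.seed(35)
  spec <- make_hmm_spec(3, 4)
  params <- make_hmm_params(spec, rep(1 / 3, 3),
                            random_stochastic_matrix(3, 3),
                            random_stochastic_matrix(3, 4))
  full <- dbn_simulate(spec, params, 30, 20)
  fit <- m_step(params, full, em_config(pseudocount = 0))
  h <- full$values[[1]][, , 1]; o <- full$values[[2]][, , 1]
  emp <- t(vapply(1:3, function(s) tabulate(o[h == s], 4), numeric(4)))
  emp <- emp / rowSums(emp)
  expect_equal(fit[[2]]$p$prob, emp, tolerance = 1e-12)

  ## a Kent output node with a single observed component equals the raw
  ## moment fit
  spec_k <- dbn_spec(list(node_spec("h", "discrete", 1, hidden = TRUE),
                          node_spec("k", "kent", 3)),
                     intra_edges = rbind(c(1, 2)))
  pk <- dbn_params(spec_k, list(
    list(p = cpt_params(mdarray(1, 1)), p0 = NULL),
    list(p = kent_params(80, 20, diag(3), 1L), p0 = NULL)))
  attr(pk, "spec") <- spec_k
  bk <- dbn_simulate(spec_k, pk, 10, 40)
  fitk <- m_step(pk, bk, em_config())
  direct <- kent_estimate(matrix(aperm(bk$values[[2]], c(2, 1, 3)),
                                 ncol = 3))
  expect_equal(fitk[[2]]$p$kappa, direct$kappa, tolerance = 1e-9)
  expect_equal(abs(sum(fitk[[2]]$p$gammas[, 1, 1] *
                         direct$gammas[, 1, 1])), 1, tolerance = 1e-9)

  ## a hidden node with one state makes the child update fully observed
  expect_equal(fitk[[1]]$p$prob[1, 1], 1)
})

test_that("MC-EM with many samples tracks the exact-EM fixed point", {
  set.seed(36)
  spec <- make_hmm_spec(2, 2)
  pi_t <- c(0.5, 0.5)
  T_t <- rbind(c(0.85, 0.15), c(0.25, 0.75))
  E_t <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  truth <- make_hmm_params(spec, pi_t, T_t, E_t)
  full <- dbn_simulate(spec, truth, 40, 15)
  data <- mask_hidden_nodes(full)
  obs <- matrix(full$values[[2]][, , 1], 40)

  start <- make_hmm_params(spec, c(0.6, 0.4),
                           rbind(c(0.7, 0.3), c(0.4, 0.6)),
                           rbind(c(0.8, 0.2), c(0.35, 0.65)))
  oracle <- exact_em_hmm(c(0.6, 0.4),
                         rbind(c(0.7, 0.3), c(0.4, 0.6)),
                         rbind(c(0.8, 0.2), c(0.35, 0.65)),
                         obs, n_iter = 60)

  cfg <- em_config("mcem", n_iterations = 60, mcem_samples = 60,
                   burn_in = 20, pseudocount = 0, tolerance = 0, seed = 2,
                   estimate = "last")
  state <- train(spec, data, cfg, init = start)
  expect_lt(max(abs(state$params[[1]]$p$prob - oracle$Tm)), 0.02)
  expect_lt(max(abs(state$params[[2]]$p$prob - oracle$Em)), 0.02)
})

test_that("training keeps every parameter inside its legal domain", {
  set.seed(37)
  fx <- generate_benchmark(benchmark_spec("complex", n_slices = 15,
                                          n_sequences = 20, seed = 5))
  state <- train(fx$spec, fx$data,
                 em_config("sem", n_iterations = 25, tolerance = 0,
                           seed = 3))
  for (np in state$params) {
    if (np$family == "discrete") {
      expect_true(all(abs(rowSums(np$p$prob) - 1) < 1e-9))
      expect_true(all(np$p$prob >= 0))
    }
    if (np$family == "gaussian_multi") {
      for (k in seq_len(np$p$n_config))
        expect_gt(min(eigen(np$p$covs[, , k], symmetric = TRUE,
                            only.values = TRUE)$values), 0)
    }
    if (np$family == "vonmises_bi") {
      expect_true(all(np$p$kappa1 > abs(np$p$kappa3)))
      expect_true(all(np$p$kappa2 > abs(np$p$kappa3)))
    }
  }
  expect_equal(nrow(state$trace), 25)
})

test_that("S-EM and long MC-EM reach comparable forward likelihoods", {
  set.seed(38)
  ref <- reference_hmm()
  data <- mask_hidden_nodes(dbn_simulate(ref$spec, ref$params, 40, 30))
  sem <- train(ref$spec, data,
               em_config("sem", n_iterations = 60, tolerance = 0, seed = 4,
                         n_starts = 2))
  mcem <- train(ref$spec, data,
                em_config("mcem", n_iterations = 30, mcem_samples = 10,
                          tolerance = 0, seed = 4, n_starts = 2))
  f_sem <- forward_loglik(sem$params_final, data)
  f_mcem <- forward_loglik(mcem$params_final, data)
  expect_lt(abs(f_sem - f_mcem) / abs(f_mcem), 0.02)
})
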