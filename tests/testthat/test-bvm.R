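test_that("the normalizer has its closed forms and dual-route agreement", {
  ## independence: log[(2 pi)^2 I0(k1) I0(k2)]
  expect_equal(bvm_log_normalizer(7, 3, 0, "series"),
               log(4 * pi^2 * besselI(7, 0) * besselI(3, 0)),
               tolerance = 1e-12)
  ## uniform limit
  expect_equal(bvm_log_normalizer(1e-9, 1e-9, 0, "series"), log(4 * pi^2),
               tolerance = 1e-8)
  ## series vs quadrature
  for (k in list(c(10, 10, 5), c(1, 2, 0.5), c(20, 5, -4))) {
    expect_equal(bvm_log_normalizer(k[1], k[2], k[3], "series"),
                 bvm_log_normalizer(k[1], k[2], k[3], "quadrature",
                                    n_grid = 4096),
                 tolerance = 1e-6)
  }
  ## at strong coupling the alternating series cancels catastrophically
  ## and the quadrature value is returned with a warning
  expect_warning(s <- bvm_log_normalizer(100, 100, 49, "series"),
                 "quadrature")
  expect_equal(s, bvm_log_normalizer(100, 100, 49, "quadrature"),
               tolerance = 1e-10)
})

test_that("kappa3 = 0 factorizes into two independent von Mises densities", {
  p <- bvm_params(1, 2.5, 8, 3, 0)
  v1 <- vm_params(1, 8); v2 <- vm_params(2.5, 3)
  set.seed(14)
  phi <- runif(100, 0, 2 * pi); psi <- runif(100, 0, 2 * pi)
  expect_equal(bvm_log_density(p, phi, psi),
               vm_log_density(v1, phi) + vm_log_density(v2, psi),
               tolerance = 1e-10)
})

test_that("the density integrates to 1 on the torus and is shift-invariant", {
  lc <- function(p, phi, psi) bvm_log_density(p, phi, psi)
  p <- bvm_params(1, 2, 100, 100, 49)
  tot <- torus_integral(function(a, b) exp(lc(p, a, b)), n = 1024)
  expect_equal(tot, 1, tolerance = 1e-6)

  p1 <- bvm_params(0.5, 2, 10, 8, 3)
  p2 <- bvm_params(0.5 + 1.1, 2, 10, 8, 3)
  set.seed(15)
  phi <- runif(50, 0, 2 * pi); psi <- runif(50, 0, 2 * pi)
  expect_equal(bvm_log_density(p1, phi, psi),
               bvm_log_density(p2, phi + 1.1, psi),
               tolerance = 1e-10)
})

test_that("the conditional of phi given psi is the stated von Mises", {
  p <- bvm_params(1, 2, 10, 8, 3)
  ## kappa3 = 0: conditional is vM(mu, k1) for any psi
  p0 <- bvm_params(1, 2, 10, 8, 0)
  cnd <- bvm_conditional(p0, c(0.3, 4.2))
  expect_equal(cnd$mu, c(1, 1))
  expect_equal(cnd$kappa, c(10, 10))
  ## psi = nu: kappa_c = k1 - k3, mu_c = mu
  cnd2 <- bvm_conditional(p, 2)
  expect_equal(cnd2$kappa, 7)
  expect_equal(cnd2$mu, 1)
  ## conditional x marginal reproduces the joint
  set.seed(16)
  phi <- runif(50, 0, 2 * pi); psi <- runif(50, 0, 2 * pi)
  marg <- vapply(psi, function(ps) {
    f <- function(a) exp(bvm_log_density(p, a, rep(ps, length(a))))
    n <- 4096; g <- 2 * pi * (seq_len(n) - 1) / n
    sum(f(g)) * 2 * pi / n
  }, 0)
  cnd3 <- bvm_conditional(p, psi)
  lcond <- vapply(seq_along(phi), function(i)
    vm_log_density(cnd3, phi[i], i), 0)
  expect_equal(bvm_log_density(p, phi, psi), lcond + log(marg),
               tolerance = 1e-8)
})

test_that("sampling at the reference torus parameters behaves as expected", {
  set.seed(17)
  ## high concentration, no interaction
  S0 <- bvm_sample(bvm_params(1, 2, 100, 100, 0), 1e4)
  fit0 <- vm_estimate(S0[, 1])
  expect_lt(abs(fit0$kappa - 100) / 100, 0.1)
  expect_lt(abs(circ_cor(S0[, 1], S0[, 2])), 0.03)

  ## high concentration, negative correlation
  S1 <- bvm_sample(bvm_params(1, 2, 100, 100, 49), 1e4)
  expect_lt(circ_cor(S1[, 1], S1[, 2]), -0.3)

  ## low concentration: circular means within 3 degrees
  S2 <- bvm_sample(bvm_params(1, 2, 10, 10, 0), 1e4)
  m_phi <- atan2(mean(sin(S2[, 1])), mean(cos(S2[, 1])))
  m_psi <- atan2(mean(sin(S2[, 2])), mean(cos(S2[, 2])))
  expect_lt(abs(m_phi - 1), 3 * pi / 180)
  expect_lt(abs(m_psi - 2), 3 * pi / 180)
})

test_that("maximum likelihood recovers the interaction and equivaries", {
  set.seed(18)
  S <- bvm_sample(bvm_params(1, 2, 100, 100, 49), 1e4)
  fit <- bvm_estimate(S[, 1], S[, 2])
  expect_gt(fit$kappa3, 35); expect_lt(fit$kappa3, 63)
  expect_lt(abs(fit$kappa1 - 100) / 100, 0.15)

  ## independent von Mises data: interaction near zero
  phi <- vm_sample(1e4, 1, 10); psi <- vm_sample(1e4, 2, 10)
  fit0 <- bvm_estimate(phi, psi)
  expect_lt(abs(fit0$kappa3), 2)

  ## rotating both angles shifts the means, not the concentrations
  d <- 0.8
  fit1 <- bvm_estimate(S[, 1], S[, 2])
  fit2 <- bvm_estimate((S[, 1] + d) %% (2 * pi), (S[, 2] + d) %% (2 * pi))
  expect_equal((fit2$mu - fit1$mu) %% (2 * pi), d, tolerance = 1e-6)
  expect_equal((fit2$nu - fit1$nu) %% (2 * pi), d, tolerance = 1e-6)
  expect_equal(fit2$kappa1, fit1$kappa1, tolerance = 1e-4)
  expect_equal(fit2$kappa3, fit1$kappa3, tolerance = 1e-4)
})
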