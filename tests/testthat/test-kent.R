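test_that("the normalizer: series closed forms, approximation, monotonicity", {
  ## beta = 0 reduces to the von Mises-Fisher normalizer 4 pi sinh(k) / k
  for (k in c(1, 10, 100)) {
    vmf <- log(4 * pi) + k + log1p(-exp(-2 * k)) - log(2) - log(k)
    expect_equal(kent_log_normalizer(k, 0, "series"), vmf, tolerance = 1e-12)
  }
  ## large-kappa approximation: log(2 pi e^k / k) at beta = 0, within 1e-6
  ## relative of the closed form at kappa = 100
  appr <- kent_log_normalizer(100, 0, "approx")
  expect_equal(appr, log(2 * pi) + 100 - log(100), tolerance = 1e-12)
  vmf100 <- log(4 * pi) + 100 + log1p(-exp(-200)) - log(2) - log(100)
  expect_lt(abs(appr - vmf100) / abs(vmf100), 1e-6)
  ## approx vs series agree to 1% (log scale) for kappa >= 50
  for (kb in list(c(50, 10), c(100, 25), c(200, 50), c(1000, 499))) {
    expect_lt(abs(kent_log_normalizer(kb[1], kb[2], "approx") -
                    kent_log_normalizer(kb[1], kb[2], "series")) /
                kent_log_normalizer(kb[1], kb[2], "series"), 0.01)
  }
  ## monotone in kappa at beta = 0
  lc <- vapply(c(1, 2, 5, 10, 20), function(k)
    kent_log_normalizer(k, 0), 0)
  expect_true(all(diff(lc) > 0))
  expect_error(kent_log_normalizer(10, 5), "unimodality")
})

test_that("series normalizer matches a Monte Carlo sphere integral", {
  ## C = int exp(k g1.x + b[(g2.x)^2 - (g3.x)^2]) dx, uniform MC on the
  ## sphere at (kappa, beta) = (10, 4)
  set.seed(19)
  n <- 1e6
  z <- matrix(rnorm(3 * n), ncol = 3)
  z <- z / sqrt(rowSums(z^2))
  vals <- exp(10 * z[, 3] + 4 * (z[, 1]^2 - z[, 2]^2))
  mc <- log(mean(vals) * 4 * pi)
  expect_equal(kent_log_normalizer(10, 4, "series"), mc, tolerance = 5e-3)
})

test_that("beta = 0 reduces pointwise to the von Mises-Fisher density", {
  set.seed(20)
  G <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(G) < 0) G[, 3] <- -G[, 3]
  p <- kent_params(37, 0, G)
  X <- matrix(rnorm(300), ncol = 3)
  X <- X / sqrt(rowSums(X^2))
  expect_equal(kent_log_density(p, X), vmf_log_density(X, G[, 1], 37),
               tolerance = 1e-8)
})

test_that("the density integrates to 1 and peaks at the mean direction", {
  p <- kent_params(200, 50, diag(3))
  tot <- sphere_integral(function(X) exp(kent_log_density(p, X)),
                         n_polar = 1200, n_az = 360)
  expect_equal(tot, 1, tolerance = 1e-4)

  ## argmax over a fine grid is gamma1
  gl <- pracma::gaussLegendre(400, -1, 1)
  ph <- 2 * pi * (0:399) / 400
  best <- c(-Inf, 0, 0, 0)
  for (ct in gl$x) {
    st <- sqrt(1 - ct^2)
    X <- cbind(ct, st * cos(ph), st * sin(ph))
    ld <- kent_log_density(p, X)
    i <- which.max(ld)
    if (ld[i] > best[1]) best <- c(ld[i], X[i, ])
  }
  expect_gt(sum(best[2:4] * c(1, 0, 0)), 0.999)
})

test_that("the density is invariant under joint sign flip of the axes", {
  set.seed(21)
  G <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(G) < 0) G[, 3] <- -G[, 3]
  G2 <- G; G2[, 2] <- -G2[, 2]; G2[, 3] <- -G2[, 3]
  p1 <- kent_params(50, 20, G)
  p2 <- kent_params(50, 20, G2)
  X <- matrix(rnorm(60), ncol = 3); X <- X / sqrt(rowSums(X^2))
  expect_equal(kent_log_density(p1, X), kent_log_density(p2, X))
})

test_that("sampling at the reference sphere parameters round-trips", {
  set.seed(22)
  G <- diag(3)
  ## high concentration, high ellipticity
  e1 <- kent_estimate(kent_sample(kent_params(1000, 499, G), 5000))
  expect_lt(abs(e1$kappa - 1000) / 1000, 0.10)
  ## no ellipticity: estimated beta stays small
  e2 <- kent_estimate(kent_sample(kent_params(10, 0, G), 5000))
  expect_lt(e2$beta, 1.5)
  ## medium: kappa within [180, 220], mean direction within 2 degrees
  X3 <- kent_sample(kent_params(200, 50, G), 5000)
  e3 <- kent_estimate(X3)
  expect_gt(e3$kappa, 180); expect_lt(e3$kappa, 220)
  expect_gt(sum(e3$gammas[, 1, 1] * G[, 1]), cos(2 * pi / 180))
  ## concentration limit: the resultant length approaches 1
  Xc <- kent_sample(kent_params(1000, 0, G), 5000)
  expect_gt(sqrt(sum(colMeans(Xc)^2)), 0.998)
})

test_that("estimation handles constructed and degenerate inputs", {
  ## symmetric arc around gamma1 on a great circle
  th <- seq(-0.5, 0.5, length.out = 101)
  X <- cbind(cos(th), sin(th), 0)
  e <- suppressWarnings(kent_estimate(X))
  expect_gt(sum(e$gammas[, 1, 1] * c(1, 0, 0)), 0.999)

  ## von Mises-Fisher data: ellipticity ratio stays small
  set.seed(23)
  Xv <- kent_sample(kent_params(100, 0, diag(3)), 5000)
  ev <- kent_estimate(Xv)
  expect_lt(ev$beta / ev$kappa, 0.05)

  ## no mean direction: estimation failure
  Xd <- rbind(diag(3), -diag(3))
  expect_error(kent_estimate(Xd), "failure")
  expect_error(kent_log_density(kent_params(10, 2, diag(3)), c(1, 1, 0)),
               "unit")
})
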