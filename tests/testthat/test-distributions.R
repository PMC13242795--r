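test_that("Dirac embeddings are exact and sample exactly", {
  d <- make_dirac_continuous(c(1.0, -2.0, 0.5))
  expect_identical(drop(d$mu), c(1.0, -2.0, 0.5))
  expect_identical(d$epsilon, 0)
  d0 <- make_dirac_continuous(c(0, 0, 0))
  expect_identical(drop(d0$mu), c(0, 0, 0))
  for (seed in 1:3) {
    set.seed(seed)
    expect_identical(sample_gaussian(gaussian_params(c(1, 2, 3), 0)),
                     matrix(c(1, 2, 3), 1))
    set.seed(seed)
    expect_identical(sample_laplace(laplace_params(c(1, 1, 1), 0)),
                     matrix(c(1, 1, 1), 1))
  }
  expect_error(make_dirac_continuous(c(1, NA, 0)), "finite")

  oh <- make_dirac_discrete(3L, K = 4)
  expect_identical(drop(oh$alpha), c(0, 0, 1, 0))
  expect_identical(drop(make_dirac_discrete(1L, K = 2)$alpha), c(1, 0))
  expect_error(make_dirac_discrete(5L, K = 4), "range")
  expect_error(make_dirac_discrete(0L, K = 4), "range")
  for (seed in 1:3) {
    set.seed(seed)
    expect_identical(drop(sample_dirichlet(oh)$p), c(0, 0, 1, 0))
  }
})

test_that("continuous samplers match their distributional moments", {
  n <- 1e5
  set.seed(1)
  g <- sample_gaussian(gaussian_params(matrix(0, n, 3), 1))
  expect_true(all(abs(colMeans(g)) < 0.02))          # 3 sigma / sqrt(n) bound
  expect_true(all(abs(apply(g, 2, var) - 1) < 0.03))
  set.seed(2)
  l <- sample_laplace(laplace_params(matrix(0, n, 3), 1))
  expect_true(all(abs(apply(l, 2, var) - 2) < 0.1))  # Var(Laplace) = 2 b^2
  expect_true(all(abs(apply(l, 2, median)) < 0.02))
})

test_that("Dirichlet sampler matches moments and honors zero components", {
  n <- 1e5
  set.seed(3)
  u <- sample_dirichlet(dirichlet_params(matrix(1, n, 4)))$p
  expect_true(all(abs(colMeans(u) - 0.25) < 0.01))   # E[v_i] = alpha_i / alpha_0
  set.seed(4)
  two <- sample_dirichlet(dirichlet_params(matrix(2, n, 2)))$p
  expect_lt(abs(mean(two[, 1]) - 0.5), 0.01)
  set.seed(5)
  z <- sample_dirichlet(dirichlet_params(matrix(c(1, 0, 2), 50, 3,
                                                byrow = TRUE)))$p
  expect_true(all(z[, 2] == 0))
  expect_error(dirichlet_params(c(0, 0, 0)), "positive sum")
})

test_that("Gaussian KL matches quadrature and its 1D closed-form value", {
  expect_equal(
    kl_gaussian(gaussian_params(matrix(1), 1), gaussian_params(matrix(0), 1)),
    0.5)  # (dmu)^2 / (2 eps^2)
  p <- gaussian_params(matrix(c(1, 2, 3), 1), 0.7)
  expect_lt(kl_gaussian(p, p), 1e-14)
  set.seed(6)
  for (i in 1:25) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.2, 3); s2 <- runif(1, 0.2, 3)
    expect_equal(kl_gaussian(gaussian_params(matrix(m1), s1),
                             gaussian_params(matrix(m2), s2)),
                 kl_gaussian_quad(m1, s1, m2, s2), tolerance = 1e-6)
  }
  expect_error(kl_gaussian(p, gaussian_params(matrix(c(0, 0, 0), 1), 0)),
               "Dirac")
})

test_that("Dirichlet KL matches Beta quadrature (K=2) and Monte Carlo (K=3)", {
  expect_identical(kl_dirichlet_exact(dirichlet_params(c(1, 1, 1)),
                                      dirichlet_params(c(1, 1, 1))), 0)
  set.seed(7)
  for (i in 1:50) {
    a <- runif(2, 0.3, 5); b <- runif(2, 0.3, 5)
    expect_equal(kl_dirichlet_exact(dirichlet_params(a), dirichlet_params(b)),
                 kl_beta_quad(a[1], a[2], b[1], b[2]), tolerance = 1e-6)
  }
  expect_equal(kl_dirichlet_exact(dirichlet_params(c(2, 2)),
                                  dirichlet_params(c(1, 1))),
               kl_beta_quad(2, 2, 1, 1), tolerance = 1e-6)
  mc <- kl_dirichlet_mc(c(3, 1, 1), c(1, 1, 1))
  kl <- kl_dirichlet_exact(dirichlet_params(c(3, 1, 1)),
                           dirichlet_params(c(1, 1, 1)))
  expect_lt(abs(kl - mc$est), 3 * mc$se)
  expect_error(kl_dirichlet_exact(dirichlet_params(c(1, 0, 1) + c(0, 0, 0)),
                                  dirichlet_params(c(1, 1, 1))),
               "positive")
})

test_that("KL divergences are nonnegative and zero only at equality", {
  set.seed(8)
  for (i in 1:100) {
    p <- gaussian_params(matrix(rnorm(3), 1), runif(1, 0.1, 2))
    q <- gaussian_params(matrix(rnorm(3), 1), runif(1, 0.1, 2))
    expect_gte(kl_gaussian(p, q), 0)
    expect_lt(kl_gaussian(q, q), 1e-14)
    K <- sample(2:6, 1)
    a <- dirichlet_params(runif(K, 0.2, 4))
    b <- dirichlet_params(runif(K, 0.2, 4))
    expect_gte(kl_dirichlet_exact(a, b), 0)
    expect_equal(kl_dirichlet_exact(a, a), 0, tolerance = 1e-12)
  }
})

test_that("Gaussian sampling converges to the Dirac as epsilon shrinks", {
  for (eps in 10^-(1:6)) {
    set.seed(10)
    draws <- sample_gaussian(gaussian_params(matrix(c(1, -1, 2), 1000, 3,
                                                    byrow = TRUE), eps))
    dev <- max(abs(sweep(draws, 2, c(1, -1, 2))))
    expect_lt(dev, 5 * eps)
  }
})

test_that("samplers are bit-identical under identical seeds", {
  p <- gaussian_params(matrix(rnorm(30), 10, 3), 0.5)
  set.seed(11); a <- sample_gaussian(p)
  set.seed(11); b <- sample_gaussian(p)
  expect_identical(a, b)
  d <- dirichlet_params(matrix(runif(40, 0.2, 2), 10, 4))
  set.seed(12); a <- sample_dirichlet(d)$p
  set.seed(12); b <- sample_dirichlet(d)$p
  expect_identical(a, b)
})
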