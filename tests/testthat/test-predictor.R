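test_that("KNN graph matches brute force, clamps k, and breaks ties by index", {
  coords <- cbind(c(0, 1, 3), 0, 0)
  e <- build_knn_graph(coords, 1)
  expect_identical(e[order(e[, 1]), ],
                   cbind(from = c(1L, 2L, 3L), to = c(2L, 1L, 2L)))
  # k >= n - 1: complete digraph
  e2 <- build_knn_graph(coords, 10)
  expect_identical(nrow(e2), 6L)
  # brute force comparison on random clouds
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:12, 1); k <- sample(1:3, 1)
    xy <- matrix(rnorm(n * 3), n, 3)
    e <- build_knn_graph(xy, k)
    dm <- as.matrix(dist(xy)); diag(dm) <- Inf
    for (a in seq_len(n)) {
      want <- order(dm[a, ], seq_len(n))[seq_len(k)]
      expect_setequal(e[e[, 1] == a, 2], want)
    }
  }
  # exact duplicates: deterministic tie-break, lower index first
  dup <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(5, 5, 5))
  e3 <- build_knn_graph(dup, 1)
  expect_identical(unname(e3[e3[, 1] == 1, 2]), 2L)
})

test_that("network predictions honor the translation/permutation contract", {
  set.seed(42)
  net <- small_net()
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    coords <- matrix(rnorm(n * 3, sd = 1.5), n, 3)
    tp <- t(replicate(n, rand_simplex(4)))
    fixed <- runif(n) < 0.3
    inp <- predictor_input(coords, tp, t = runif(1), fixed = fixed)
    out <- pif_predict(net, inp)
    # simplex rows
    expect_true(all(abs(rowSums(out$alpha_hat) - 1) < 1e-6))
    expect_true(all(out$alpha_hat >= 0))
    # translation equivariance
    u <- rnorm(3)
    inp_t <- predictor_input(sweep(coords, 2, -u), tp, inp$t, fixed = fixed)
    out_t <- pif_predict(net, inp_t)
    expect_equal(out_t$mu_hat, sweep(out$mu_hat, 2, -u), tolerance = 1e-5)
    expect_equal(out_t$alpha_hat, out$alpha_hat, tolerance = 1e-8)
    # permutation equivariance
    p <- sample(n)
    inp_p <- predictor_input(coords[p, ], tp[p, ], inp$t[p], fixed = fixed[p])
    out_p <- pif_predict(net, inp_p)
    expect_equal(out_p$mu_hat, out$mu_hat[p, ], tolerance = 1e-8)
    expect_equal(out_p$alpha_hat, out$alpha_hat[p, ], tolerance = 1e-8)
  }
})

test_that("network is rotation-equivariant by construction", {
  set.seed(43)
  net <- small_net()
  n <- 7
  coords <- matrix(rnorm(n * 3), n, 3)
  tp <- t(replicate(n, rand_simplex(4)))
  inp <- predictor_input(coords, tp, t = 0.5)
  out <- pif_predict(net, inp)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  out_r <- pif_predict(net, predictor_input(coords %*% q, tp, t = 0.5))
  expect_equal(out_r$mu_hat, out$mu_hat %*% q, tolerance = 1e-8)
})

test_that("fixed atoms pass through the network verbatim", {
  set.seed(44)
  net <- small_net()
  coords <- matrix(rnorm(18), 6, 3)
  tp <- make_dirac_discrete(c(1L, 2L, 3L, 4L, 1L, 2L), 4)$alpha
  fixed <- c(TRUE, TRUE, rep(FALSE, 4))
  out <- pif_predict(net, predictor_input(coords, tp, 0.8, fixed = fixed))
  expect_identical(out$mu_hat[1:2, ], coords[1:2, ])
  expect_identical(out$alpha_hat[1:2, ], tp[1:2, ])
})

test_that("hand-derived backprop matches finite differences", {
  set.seed(45)
  net <- small_net(seed = 9)
  n <- 6
  coords <- matrix(rnorm(n * 3, sd = 1.5), n, 3)
  tp <- t(replicate(n, rand_simplex(4)))
  fixed <- c(rep(FALSE, 5), TRUE)
  inp <- predictor_input(coords, tp, t = 0.6, fixed = fixed)
  fw <- pifgen:::net_forward(net, inp, keep_cache = TRUE)
  gmu <- matrix(rnorm(n * 3), n, 3); gmu[fixed, ] <- 0
  gal <- matrix(rnorm(n * 4), n, 4); gal[fixed, ] <- 0
  grads <- pifgen:::net_backward(net, fw$cache, gmu, gal)
  lossfun <- function(nn) {
    o <- pifgen:::net_forward(nn, inp)
    sum(gmu * o$mu_hat) + sum(gal * o$alpha_hat)
  }
  eps <- 1e-6
  all_finite <- TRUE; any_nonzero <- TRUE
  for (nm in names(net$par)) {
    g <- grads[[nm]]
    all_finite <- all_finite && all(is.finite(g))
    any_nonzero <- any_nonzero && any(g != 0)   # no dead heads
    idx <- if (length(g) > 4) sample(length(g), 4) else seq_along(g)
    for (i in idx) {
      up <- net; up$par[[nm]][i] <- up$par[[nm]][i] + eps
      dn <- net; dn$par[[nm]][i] <- dn$par[[nm]][i] - eps
      fd <- (lossfun(up) - lossfun(dn)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
  expect_true(all_finite)
  expect_true(any_nonzero)
})

test_that("oracle predictor reproduces data parameters regardless of input", {
  mols <- make_ligand_dataset(chain_template(), 3, seed = 5)
  oracle <- oracle_predictor(mols)
  mol <- mols$mol_2
  n <- nrow(mol$coords)
  for (t in c(0.1, 0.5, 0.9)) {
    set.seed(floor(100 * t))
    noisy <- matrix(rnorm(n * 3), n, 3)
    tp <- t(replicate(n, rand_simplex(4)))
    out <- pif_predict(oracle, predictor_input(noisy, tp, t,
                                               instance = "mol_2"))
    expect_identical(out$mu_hat, mol$coords)
    expect_identical(out$alpha_hat, make_dirac_discrete(mol$types, 4)$alpha)
  }
  expect_error(pif_predict(oracle, predictor_input(matrix(0, 1, 3),
                                                   matrix(0.25, 1, 4), 0,
                                                   instance = "nope")),
               "unknown oracle instance")
})
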