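test_that("oracle-driven sampling reproduces data exactly for every prior and schedule", {
  mols <- make_ligand_dataset(chain_template(), 2, seed = 61)
  mols$ring <- make_ligand(molecule_template("ring", 6L), seed = 62)
  oracle <- oracle_predictor(mols)
  for (fam in c("gaussian", "laplace")) {
    for (kind in c("exponential", "linear", "quadratic")) {
      prior <- pif_prior(fam, K = 4)
      sch <- pif_schedule(kind)
      for (id in names(mols)) {
        out <- sample_denovo(oracle, nrow(mols[[id]]$coords), n_steps = 100,
                             schedule = sch, prior = prior, seed = 63,
                             instance = id)
        expect_lt(max(abs(out$coords - mols[[id]]$coords)), 1e-12)
        expect_identical(out$types, mols[[id]]$types)
      }
    }
  }
})

test_that("single refinement step lands on the exact interpolant of the prediction", {
  mols <- make_ligand_dataset(chain_template(5L), 1, seed = 64)
  oracle <- oracle_predictor(mols)
  prior <- pif_prior(K = 4)
  sch <- pif_schedule()
  st <- pifgen:::init_prior_state(5L, prior)
  set.seed(65)
  st1 <- step_update(st, oracle, t_next = 0.99, sch, prior, instance = "mol_1")
  f <- schedule_value(0.99, sch)
  expect_equal(st1$coord$mu, f * mols$mol_1$coords, tolerance = 1e-14)
  expect_equal(st1$coord$epsilon, rep((1 - f) * prior$eps0, 5),
               tolerance = 1e-14)
  expect_equal(st1$type$alpha,
               f * make_dirac_discrete(mols$mol_1$types, 4)$alpha + (1 - f) / 4,
               tolerance = 1e-14)
  # a step to f = 0 resets generated atoms to the prior regardless of model
  st0 <- pifgen:::init_prior_state(5L, prior)
  st0$t <- 0
  stz <- step_update(st0, oracle, t_next = 1e-12, pif_schedule("linear"),
                     prior, instance = "mol_1")
  expect_equal(max(abs(stz$coord$mu)), 0, tolerance = 1e-10)
  expect_equal(stz$coord$epsilon, rep(prior$eps0, 5), tolerance = 1e-10)
})

test_that("spread anneals monotonically along the trajectory", {
  mols <- make_ligand_dataset(chain_template(5L), 1, seed = 66)
  oracle <- oracle_predictor(mols)
  for (kind in c("exponential", "linear", "quadratic")) {
    prior <- pif_prior(K = 4)
    sch <- pif_schedule(kind)
    st <- pifgen:::init_prior_state(5L, prior)
    set.seed(67)
    eps_trace <- st$coord$epsilon[1]
    for (k in 1:20) {
      st <- step_update(st, oracle, k / 20, sch, prior, instance = "mol_1")
      eps_trace <- c(eps_trace, st$coord$epsilon[1])
    }
    expect_true(all(diff(eps_trace) <= 0))
  }
})

test_that("de novo sampling is seed-deterministic and n_steps=1 degenerates to one shot", {
  net <- small_net(seed = 3)
  a <- sample_denovo(net, 6, n_steps = 20, seed = 68, prior = pif_prior(K = 4))
  b <- sample_denovo(net, 6, n_steps = 20, seed = 68, prior = pif_prior(K = 4))
  expect_identical(a$coords, b$coords)
  expect_identical(a$types, b$types)
  c2 <- sample_denovo(net, 6, n_steps = 20, seed = 69, prior = pif_prior(K = 4))
  expect_false(isTRUE(all.equal(a$coords, c2$coords)))
  one <- sample_denovo(net, 6, n_steps = 1, seed = 68, prior = pif_prior(K = 4))
  expect_identical(nrow(one$coords), 6L)
})

test_that("conditional sampling preserves fixed atoms bit-exactly", {
  mols <- make_ligand_dataset(chain_template(8L), 1, seed = 70)
  mol <- mols$mol_1
  keep <- 1:3
  sub <- pif_molecule(mol$coords[keep, ], mol$types[keep], mol$K)
  # the oracle speaks the sampler's conditioning frame (centered on the
  # fixed substructure)
  ds <- mols
  ds$mol_1$coords <- sweep(ds$mol_1$coords, 2, colMeans(sub$coords))
  oracle <- oracle_predictor(ds)
  # zero new atoms: identity on the substructure
  expect_identical(sample_conditional(small_net(), sub, 0), sub)
  # oracle-driven completion reproduces the reference complement
  out <- sample_conditional(oracle, sub, n_new_atoms = 5, n_steps = 50,
                            prior = pif_prior(K = 4), seed = 71,
                            instance = "mol_1", atom_ids = 4:8)
  expect_identical(out$coords[1:3, ], mol$coords[keep, ])   # bit-exact
  expect_identical(out$types[1:3], mol$types[keep])
  expect_lt(max(abs(out$coords[4:8, ] - mol$coords[4:8, ])), 1e-12)
  expect_identical(out$types[4:8], mol$types[4:8])
  # a trainable net also passes fixed atoms through bit-exactly
  net <- small_net(seed = 5)
  out2 <- sample_conditional(net, sub, n_new_atoms = 3, n_steps = 10,
                             prior = pif_prior(K = 4), seed = 72)
  expect_identical(out2$coords[1:3, ], mol$coords[keep, ])
})

test_that("pocket conditioning returns output in the pocket frame", {
  pair <- make_pocket_ligand_pair(chain_template(6L), pocket_size = 6,
                                  offset = c(0, 0, 1), seed = 73)
  ds <- list(lig = pair$ligand)
  # oracle stores the ligand in the pocket-centered frame
  center <- colMeans(pair$pocket$coords)
  ds$lig$coords <- sweep(ds$lig$coords, 2, center)
  oracle <- oracle_predictor(ds)
  out <- sample_denovo(oracle, nrow(pair$ligand$coords), pocket = pair$pocket,
                       n_steps = 25, prior = pif_prior(K = 4), seed = 74,
                       instance = "lig")
  expect_equal(out$coords, pair$ligand$coords, tolerance = 1e-9)
})

test_that("simulate() draws atom counts from the training size histogram", {
  mols <- make_ligand_dataset(chain_template(c(5L, 7L)), 30, seed = 75)
  fit <- pif(mols, steps = 10, batch_size = 4, log_every = 5, seed = 1,
             hidden = 8, layers = 1)
  gen <- simulate(fit, nsim = 12, seed = 76)
  expect_length(gen, 12)
  sizes <- vapply(gen, function(m) nrow(m$coords), integer(1))
  expect_true(all(sizes >= 5 & sizes <= 7))
  gen2 <- simulate(fit, nsim = 12, seed = 76)
  expect_identical(lapply(gen, `[[`, "coords"), lapply(gen2, `[[`, "coords"))
})
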