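test_that("partition enumeration matches closed forms", {
  expect_equal(enumeratePartition(oneSite(5), 5), log(2), tolerance = 1e-12)
  two <- speciesModel("B", c(5, 5))
  expect_equal(enumeratePartition(two, 5), 2 * log(2), tolerance = 1e-12)
  # coupled pair: microstates 1 + 1 + 1 + 0.1
  expect_equal(enumeratePartition(coupledPair(), 5), log(3.1),
               tolerance = 1e-12)
  # vectorized over pH
  expect_equal(enumeratePartition(oneSite(5), c(4, 5)),
               log(1 + 10^(5 - c(4, 5))), tolerance = 1e-12)
  big <- speciesModel("big", rep(5, 21))
  expect_error(enumeratePartition(big, 5), "enumeration limit")
})

test_that("exact titration reproduces closed-form moments", {
  e <- exactTitration(oneSite(5), c(5, 6))
  expect_equal(e@nMeanTotal[2], 1 / 11, tolerance = 1e-12)
  expect_equal(e@varTotal[2], (1 / 11) * (10 / 11), tolerance = 1e-12)
  expect_equal(e@varTotal[1], 0.25, tolerance = 1e-12)
  ec <- exactTitration(coupledPair(), 5)
  expect_equal(unname(ec@nMeanSite[1, 1]), 1.1 / 3.1, tolerance = 1e-12)
  # ensemble invariants
  expect_equal(rowSums(ec@nMeanSite), ec@nMeanTotal, tolerance = 1e-13)
  expect_equal(rowSums(ec@covSiteTotal), ec@varTotal, tolerance = 1e-13)
})

test_that("fluctuation identity holds for enumerated models", {
  h <- 1e-4
  set.seed(42)
  for (seed in 1:5) {
    scen <- makeBenchmarkScenario(n_sites = 3 + seed %% 3, seed = seed)
    for (m in scen$models[c("M", "ML", "D")]) {
      for (ph in c(3, 5.5, 8)) {
        lo <- exactTitration(m, ph - h)
        hi <- exactTitration(m, ph + h)
        at <- exactTitration(m, ph)
        dtot <- (hi@nMeanTotal - lo@nMeanTotal) / (2 * h)
        expect_lt(abs(dtot + log(10) * at@varTotal), 1e-6)
        dsite <- (hi@nMeanSite - lo@nMeanSite) / (2 * h)
        expect_lt(max(abs(dsite + log(10) * at@covSiteTotal)), 1e-6)
      }
    }
  }
})

test_that("exact free-energy profiles match the closed form", {
  toy <- toyBinding()
  p <- exactFreeEnergyProfile(toy$reaction, toy$models, 3:8, ph_ref = 3)
  expect_equal(p@ddG, toyBindingExact(3:8), tolerance = 1e-12)
  expect_equal(p@ddG[6], 2.683, tolerance = 2e-4)
  expect_equal(p@ddG[1], 0)
  # identical product and reactant models -> identically zero
  same <- reactionSpec("null", c(M = 1), c(M2 = 1))
  models <- list(M = oneSite(4.7, "M"), M2 = oneSite(4.7, "M2"))
  p0 <- exactFreeEnergyProfile(same, models, 3:8)
  expect_equal(p0@ddG, rep(0, 6), tolerance = 1e-12)
  # swapping products and reactants negates the profile
  rev <- reactionSpec("rev", c(M = 1, L = 1), c(ML = 1))
  pr <- exactFreeEnergyProfile(rev, toy$models, 3:8, ph_ref = 3)
  expect_equal(pr@ddG, -p@ddG, tolerance = 1e-12)
  expect_error(exactFreeEnergyProfile(toy$reaction, toy$models[1:2], 3:8),
               "unknown species")
})

test_that("Metropolis sampling is reproducible and converges to exact means", {
  m <- oneSite(5)
  tr1 <- sampleMicrostates(m, 5, 1e5, seed = 11)
  tr2 <- sampleMicrostates(m, 5, 1e5, seed = 11)
  expect_identical(tr1@states, tr2@states)
  mean1 <- mean(tr1@states[-(1:15000), 1])
  se <- sqrt(0.25 / 85000)
  expect_lt(abs(mean1 - 0.5), 3 * se * 10)  # generous: frames correlate
  # coupled pair at pH = pKa: sampled correlation is negative (exact -0.409)
  trc <- sampleMicrostates(coupledPair(), 5, 5e4, seed = 12)
  r <- cor(trc@states[-(1:7500), 1], trc@states[-(1:7500), 2])
  expect_lt(r, -0.3)
  expect_gt(r, -0.52)
})

test_that("benchmark scenario closes its thermodynamic cycle exactly", {
  s <- makeBenchmarkScenario(seed = 3)
  cl <- s$exact$dim_holo@ddG - s$exact$dim_apo@ddG -
    s$exact$bind_D@ddG + 2 * s$exact$bind_M@ddG
  expect_lt(max(abs(cl)), 1e-9)
  # reproducible bit-for-bit
  s2 <- makeBenchmarkScenario(seed = 3)
  expect_identical(s$exact$bind_M@ddG, s2$exact$bind_M@ddG)
  # no ligand-induced shifts and no ligand-site coupling:
  # coupling profile is pH-independent
  s0 <- makeBenchmarkScenario(seed = 4, ligand_shift = 0,
                              ligand_site_coupling = 0)
  coup <- (s0$exact$dim_holo@ddG - s0$exact$dim_apo@ddG)
  expect_lt(max(abs(coup - coup[1])), 1e-9)
})

test_that("Gaussian-mixture conformation sampler honours its spec", {
  spec1 <- list(means = list(c(1, 2, 3)), covs = list(0.5), weights = 1)
  s <- sampleConformations(spec1, 4000, seed = 5)
  se <- sqrt(0.5 / 4000)
  expect_true(all(abs(colMeans(s$points) - c(1, 2, 3)) < 4 * se))
  spec3 <- list(means = list(rep(0, 2), rep(10, 2), rep(-10, 2)),
                covs = list(1, 1, 1), weights = c(0.7, 0.2, 0.1))
  s3 <- sampleConformations(spec3, 5000, seed = 6)
  cnt <- tabulate(s3$component, 3)
  # multinomial 99% bounds
  p <- c(0.7, 0.2, 0.1)
  bound <- 2.58 * sqrt(5000 * p * (1 - p))
  expect_true(all(abs(cnt - 5000 * p) < bound))
  expect_equal(nrow(sampleConformations(spec1, 0)$points), 0)
  spec_bad <- list(means = list(0), covs = list(1), weights = 0.5)
  expect_error(sampleConformations(spec_bad, 10), "sum to 1")
})
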