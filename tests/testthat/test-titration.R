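test_that("trace averaging computes replicate-pooled moments", {
  tr1 <- makeTrace(matrix(1L, 20, 1))
  tb <- averageProtonation(list(tr1), burn_in_fraction = 0)
  expect_equal(tb@meanTotal, 1)
  expect_equal(tb@varTotal, 0)
  alt <- makeTrace(matrix(rep(c(0L, 1L), 10), ncol = 1))
  tb2 <- averageProtonation(list(alt), burn_in_fraction = 0)
  expect_equal(tb2@meanTotal, 0.5)
  # burn-in discards the leading fraction
  ramp <- makeTrace(matrix(c(rep(0L, 5), rep(1L, 15)), ncol = 1))
  tb3 <- averageProtonation(list(ramp), burn_in_fraction = 0.25)
  expect_equal(tb3@meanTotal, 1)
  expect_error(averageProtonation(list(makeTrace(matrix(0L, 0, 1)))),
               "empty post-burn-in")
})

test_that("sampled single-site traces average to the exact mean", {
  trs <- lapply(1:4, function(r)
    sampleMicrostates(oneSite(5), 5, 2e4, seed = 100 + r, replicate = r))
  tb <- averageProtonation(trs)
  se <- sqrt(0.25 / (4 * 17000))
  expect_lt(abs(tb@meanTotal - 0.5), 3 * se * 10)
  expect_equal(dim(tb@repMeanTotal), c(1L, 4L))
})

test_that("fluctuation slopes follow the grand-canonical identity", {
  e <- exactTitration(oneSite(5), 5)
  sl <- fluctuationSlopes(e)
  expect_equal(sl$total, -log(10) * 0.25, tolerance = 1e-12)
  # independent sites: cov(n_i, n) = var(n_i)
  two <- speciesModel("B", c(4, 6))
  e2 <- exactTitration(two, seq(3, 8))
  ni <- e2@nMeanSite
  expect_equal(e2@covSiteTotal, ni * (1 - ni), tolerance = 1e-12)
  # site slopes sum to the total slope
  ec <- exactTitration(coupledPair(), c(4, 5, 6))
  slc <- fluctuationSlopes(ec)
  expect_equal(rowSums(slc$site), slc$total, tolerance = 1e-12)
})

test_that("Hill fitting recovers generating parameters", {
  ph <- seq(3, 8, 0.5)
  f <- hillFit(ph, 1 / (1 + 10^(1.2 * (ph - 4.5))))
  expect_true(f@converged)
  expect_equal(f@pka, 4.5, tolerance = 1e-3)
  expect_equal(f@h, 1.2, tolerance = 1e-3)
  # a single enumerated site is exactly Hill with h = 1
  e <- exactTitration(oneSite(6.2), 3:8)
  f1 <- hillFit(e@ph_grid, e@nMeanTotal)
  expect_equal(f1@pka, 6.2, tolerance = 1e-6)
  expect_equal(f1@h, 1, tolerance = 1e-6)
  expect_false(hillFit(ph, rep(0, length(ph)))@converged)
  expect_error(hillFit(c(3, 4), c(1, 0)), "at least 3")
})

test_that("isoionic point is the root of the charge curve", {
  sym <- speciesModel("S", c(4, 8), charge_class = c("acid", "base"))
  cc <- isoionicPoint(exactTitration(sym, 3:8), sym)
  expect_equal(cc@pI, 6, tolerance = 1e-6)
  acids <- speciesModel("A2", c(4, 5))
  expect_true(is.na(isoionicPoint(exactTitration(acids, 3:8), acids)@pI))
  # benchmark monomer: pI close to the root of the densely enumerated curve
  s <- makeBenchmarkScenario(seed = 9)
  M <- s$models$M
  cc2 <- isoionicPoint(exactTitration(M, 3:8), M)
  if (!is.na(cc2@pI)) {
    chg <- function(p) {
      e <- exactTitration(M, p)
      sum(e@nMeanSite[1, ]) - sum(M@sites$charge_class == "acid")
    }
    root <- uniroot(chg, c(3, 8), tol = 1e-10)$root
    expect_lt(abs(cc2@pI - root), 0.05)
  }
})

test_that("protonation correlations match enumeration and drop degenerate sites", {
  # a site against a copy of itself: r = 1
  base <- matrix(rep(c(0L, 1L, 1L, 0L, 1L), 40), ncol = 1)
  twin <- makeTrace(cbind(base, base))
  out <- protonationCorrelations(list(twin), threshold = 0.2,
                                 burn_in_fraction = 0)
  expect_equal(out$r, 1)
  # coupled pair at pH = pKa: exact r = cov/var = -0.409
  trs <- lapply(1:3, function(r)
    sampleMicrostates(coupledPair(), 5, 4e4, seed = 200 + r, replicate = r))
  oc <- protonationCorrelations(trs, threshold = 0.2)
  expect_equal(nrow(oc), 1)
  expect_equal(oc$r, -0.409, tolerance = 0.05)
  expect_true(is.finite(oc$se))
  # independent sites: |r| below the reporting threshold -> empty table
  ind <- speciesModel("I", c(5, 5))
  tri <- sampleMicrostates(ind, 5.4, 1e5, seed = 7)
  oi <- protonationCorrelations(list(tri), threshold = 0.05)
  expect_equal(nrow(oi), 0)
  # zero-variance site is dropped, not NaN
  frozen <- makeTrace(cbind(base, 0L))
  of <- protonationCorrelations(list(frozen), threshold = 0,
                                burn_in_fraction = 0)
  expect_equal(nrow(of), 0)
})

test_that("model-compound pKa calibration shifts by target minus apparent", {
  ph <- seq(3, 7, 0.25)
  curve420 <- 1 / (1 + 10^(ph - 4.20))
  cal <- calibrateModelPka(ph, curve420, 4.19, 5.0)
  expect_equal(cal$calibrated_pka, 4.99, tolerance = 1e-6)
  # curve already at target, initial equal to target -> unchanged
  curve50 <- 1 / (1 + 10^(ph - 5.0))
  expect_equal(calibrateModelPka(ph, curve50, 5.0, 5.0)$calibrated_pka, 5.0,
               tolerance = 1e-6)
  curve419 <- 1 / (1 + 10^(ph - 4.19))
  expect_equal(calibrateModelPka(ph, curve419, 4.19, 5.0)$calibrated_pka,
               5.00, tolerance = 1e-6)
  # translation covariance: shifting the simulated curve up in pKa by
  # delta lowers the calibrated value by delta (shift = target - apparent)
  delta <- 0.37
  shifted <- 1 / (1 + 10^((ph - delta) - 4.20))
  expect_equal(calibrateModelPka(ph, shifted, 4.19, 5.0)$calibrated_pka,
               4.99 - delta, tolerance = 1e-6)
})

test_that("transition counting flags exchange rates", {
  tr <- makeTrace(matrix(c(0L, 0L, 1L, 1L, 0L), ncol = 1))
  tc <- transitionCount(tr, 1)
  expect_equal(tc$transitions, 2)
  expect_equal(tc$rate, 0.5)
  expect_equal(transitionCount(makeTrace(matrix(1L, 10, 1)), 1)$rate, 0)
  expect_error(transitionCount(makeTrace(matrix(1L, 1, 1)), 1), "undefined")
  # single site at pH = pKa: every flip attempt is accepted -> rate 1
  tr1 <- sampleMicrostates(oneSite(5), 5, 2000, seed = 3)
  expect_equal(transitionCount(tr1, "site1")$rate, 1)
})
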