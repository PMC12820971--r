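test_that("thermo spline reproduces cubics and integrates in closed form", {
  # nodes of a cubic with its true derivatives: exact everywhere
  f <- function(x) 2 * x^3 - x^2 + 3 * x - 5
  fp <- function(x) 6 * x^2 - 2 * x + 3
  fpp <- function(x) 12 * x - 2
  xs <- c(3, 4.5, 6, 8)
  sp <- buildThermoSpline(xs, f(xs), fp(xs))
  xx <- seq(3, 8, 0.01)
  expect_lt(max(abs(splineEval(sp, xx) - f(xx))), 1e-9)
  Fint <- function(x) x^4 / 2 - x^3 / 3 + 3 * x^2 / 2 - 5 * x
  expect_equal(splineIntegral(sp, 3, 7.3), Fint(7.3) - Fint(3),
               tolerance = 1e-9)
  # constant segment: integral = value x width
  spc <- buildThermoSpline(c(0, 2), c(1.5, 1.5), c(0, 0))
  expect_equal(splineIntegral(spc, 0, 2), 3)
  expect_error(buildThermoSpline(c(3, 3, 4), 1:3, 1:3), "duplicate")
  expect_error(splineIntegral(spc, -1, 2), "span")
  # quintic form (with curvatures) reproduces the cubic exactly too
  spq <- buildThermoSpline(xs, f(xs), fp(xs), fpp(xs))
  expect_lt(max(abs(splineEval(spq, xx) - f(xx))), 1e-9)
  expect_equal(splineIntegral(spq, 3, 7.3), Fint(7.3) - Fint(3),
               tolerance = 1e-9)
  # and a quintic polynomial given its true derivatives
  g <- function(x) x^5 - 2 * x^3 + x
  gp <- function(x) 5 * x^4 - 6 * x^2 + 1
  gpp <- function(x) 20 * x^3 - 12 * x
  xs2 <- seq(0, 2, 0.5)
  spg <- buildThermoSpline(xs2, g(xs2), gp(xs2), gpp(xs2))
  zz <- seq(0, 2, 0.01)
  expect_lt(max(abs(splineEval(spg, zz) - g(zz))), 1e-8)
})

test_that("spline of exact single-site nodes tracks the closed-form curve", {
  e <- exactTitration(oneSite(5.3), 3:8)
  sl <- fluctuationSlopes(e)
  sp <- buildThermoSpline(3:8, e@nMeanTotal, sl$total,
                          log(10)^2 * e@thirdTotal)
  xx <- seq(3, 8, 0.01)
  truth <- 1 / (1 + 10^(xx - 5.3))
  expect_lt(max(abs(splineEval(sp, xx) - truth)), 1e-3)
})

test_that("linkage integration agrees with the enumeration oracle", {
  toy <- toyBinding()
  tabs <- lapply(toy$models, exactTitration, ph_grid = 3:8)
  p <- integrateLinkage(toy$reaction, tabs, ph_ref = 3)
  expect_equal(p@ddG[1], 0)
  expect_lt(max(abs(p@ddG - toyBindingExact(3:8))), 5e-3)
  expect_equal(p@ddG[6], 2.683, tolerance = 5e-3)
  # product = reactant species: zero at all pH
  nullrx <- reactionSpec("null", c(M = 1), c(M = 1))
  p0 <- integrateLinkage(nullrx, tabs["M"], ph_ref = 3)
  expect_equal(p0@ddG, rep(0, 6))
  # benchmark dimerization against the -RT dlnZ oracle
  s <- makeBenchmarkScenario(seed = 5)
  stabs <- lapply(s$models, exactTitration, ph_grid = 3:8)
  pd <- integrateLinkage(s$reactions$dim_apo, stabs, ligandCurve(5),
                         ph_ref = 3)
  expect_lt(max(abs(pd@ddG - s$exact$dim_apo@ddG)), 0.05)
  expect_error(integrateLinkage(toy$reaction, tabs["M"]), "missing species")
})

test_that("profiles are independent of the reference pH up to a constant", {
  toy <- toyBinding()
  tabs <- lapply(toy$models, exactTitration, ph_grid = 3:8)
  p3 <- integrateLinkage(toy$reaction, tabs, ph_ref = 3)
  p6 <- integrateLinkage(toy$reaction, tabs, ph_ref = 6)
  d3 <- p3@ddG[5] - p3@ddG[2]
  d6 <- p6@ddG[5] - p6@ddG[2]
  expect_lt(abs(d3 - d6), 1e-12)
  # total-protonation slopes are non-positive for every single species
  sl <- fluctuationSlopes(tabs$M)
  expect_true(all(sl$total <= 0))
})

test_that("site decomposition sums to the total profile", {
  toy <- toyBinding()
  tabs <- lapply(toy$models, exactTitration, ph_grid = 3:8)
  dec <- siteDecomposition(toy$reaction, tabs, ph_ref = 3)
  # single-site reaction: the one contribution is the total
  expect_equal(dec@contributions[, 1], dec@total@ddG, tolerance = 1e-12)
  s <- makeBenchmarkScenario(seed = 5)
  stabs <- lapply(s$models, exactTitration, ph_grid = 3:8)
  lig <- ligandCurve(5)
  for (nm in c("bind_M", "dim_apo", "bind_D")) {
    d <- siteDecomposition(s$reactions[[nm]], stabs, lig, ph_ref = 3)
    expect_lt(max(abs(rowSums(d@contributions) - d@total@ddG)), 1e-9)
  }
  # a bound-ligand site identical to the free-ligand curve contributes zero
  mlLike <- speciesModel("MLfix", c(4, 5), site_id = c("site1", "lig"))
  mFix <- speciesModel("M", 4)
  rxf <- reactionSpec("bindfix", c(MLfix = 1), c(M = 1, L = 1),
                      data.frame(product_site = c("site1", "lig"),
                                 ref_species = c("M", "ligand"),
                                 ref_site = c("site1", "lig"),
                                 stringsAsFactors = FALSE))
  tf <- list(MLfix = exactTitration(mlLike, 3:8),
             M = exactTitration(mFix, 3:8))
  df <- siteDecomposition(rxf, tf, ligandCurve(5), ph_ref = 3)
  expect_lt(max(abs(df@contributions[, "lig"])), 1e-9)
})

test_that("Hill integration uses the exact antiderivative", {
  # single h = 1, pKa 6 curve integrated over [3, 8]
  lig <- ligandCurve(6, 1)
  rx <- reactionSpec("one", c(X = 1), c(Y = 1),
                     data.frame(product_site = "s", ref_species = "ligand",
                                ref_site = "lig", stringsAsFactors = FALSE))
  fits <- list(X = list(s = new("HillFit", label = "s", pka = 99, h = 1,
                                residual = 0, converged = TRUE)))
  # the X site (pKa 99) is ~fully protonated: integral 5 minus ligand part
  p <- hillIntegration(rx, fits, lig, ph_grid = c(3, 8), ph_ref = 3)
  RT <- thermalRT(300)
  hillInt <- integrate(function(x) 1 / (1 + 10^(x - 6)), 3, 8,
                       rel.tol = 1e-12)$value
  expect_equal(hillInt, 2.9961, tolerance = 1e-4)
  expect_equal(p@ddG[2], log(10) * RT * (5 - hillInt), tolerance = 1e-6)
  # reaction of identical Hill curves: zero
  rx0 <- reactionSpec("zero", c(X = 1), c(Y = 1),
                      data.frame(product_site = "s", ref_species = "Y",
                                 ref_site = "s", stringsAsFactors = FALSE))
  f0 <- list(X = fits$X, Y = fits$X)
  expect_equal(hillIntegration(rx0, f0, NULL, 3:8)@ddG, rep(0, 6))
  # toy binding: single-site species are exactly Hill, so the two
  # integration routes agree
  toy <- toyBinding()
  tabs <- lapply(toy$models, exactTitration, ph_grid = 3:8)
  hf <- list(ML = fitHillSites(tabs$ML), M = fitHillSites(tabs$M))
  ph <- hillIntegration(toy$reaction, hf, NULL, 3:8, ph_ref = 3)
  ps <- integrateLinkage(toy$reaction, tabs, ph_ref = 3)
  expect_lt(max(abs(ph@ddG - ps@ddG)), 1e-3)
  # non-converged fits are refused
  fbad <- list(X = list(s = new("HillFit", label = "s", pka = NA_real_,
                                h = NA_real_, residual = NA_real_,
                                converged = FALSE)),
               Y = fits$X)
  expect_error(hillIntegration(rx0, fbad, NULL, 3:8), "non-converged")
})

test_that("anchoring is a rigid shift", {
  toy <- toyBinding()
  tabs <- lapply(toy$models, exactTitration, ph_grid = 3:8)
  p <- integrateLinkage(toy$reaction, tabs, ph_ref = 3)
  a <- anchorProfile(p, 7, -8.3)
  expect_equal(a@ddG[5], -8.3)
  expect_true(a@anchored)
  expect_equal(diff(a@ddG), diff(p@ddG), tolerance = 1e-12)
  # anchoring at ph_ref with value 0 is the identity
  a0 <- anchorProfile(p, 3, 0)
  expect_equal(a0@ddG, p@ddG, tolerance = 1e-12)
  expect_error(anchorProfile(p, 9, 0), "span")
})

test_that("replicate bootstrap produces honest bands", {
  m <- oneSite(5)
  # identical replicates: zero-width band
  trs <- unlist(lapply(c(4.5, 5), function(p) {
    tr <- sampleMicrostates(m, p, 5000, seed = 21)
    lapply(1:4, function(r) { t2 <- tr; t2@replicate <- as.integer(r); t2 })
  }), recursive = FALSE)
  tb <- averageProtonation(trs)
  rx <- reactionSpec("self", c(A = 2), c(A = 1))
  bp <- bootstrapProfile(rx, list(A = tb), B = 50, seed = 1, ph_ref = 4.5)
  expect_lt(max(bp@band[, 2] - bp@band[, 1]), 1e-12)
  # single replicate: band undefined
  tb1 <- averageProtonation(list(sampleMicrostates(m, 4.5, 5000, seed = 21),
                                 sampleMicrostates(m, 5, 5000, seed = 22)))
  expect_error(bootstrapProfile(rx, list(A = tb1), B = 10, ph_ref = 4.5),
               "replicates")
  # distinct replicates: band contains estimate, resamples stored
  toy <- toyBinding()
  trsG <- unlist(lapply(3:8, function(p) lapply(1:4, function(r)
    sampleMicrostates(m, p, 3000, seed = 40 + 10 * p + r,
                      replicate = r))), recursive = FALSE)
  tbG <- averageProtonation(trsG)
  mlG <- exactTitration(toy$models$ML, 3:8)
  lG <- exactTitration(toy$models$L, 3:8)
  bpG <- bootstrapProfile(toy$reaction, list(M = tbG, ML = mlG, L = lG),
                          B = 200, seed = 2)
  expect_true(all(bpG@band[, 1] <= bpG@ddG & bpG@ddG <= bpG@band[, 2]))
  expect_equal(dim(bpG@resamples), c(200L, 6L))
  expect_true(any(bpG@band[, 2] - bpG@band[, 1] > 0))
})
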