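test_that("superposition recovers rigid transforms and rejects reflections", {
  set.seed(1)
  ref <- matrix(rnorm(15, sd = 3), 5, 3)
  ens0 <- coordinateEnsemble(array(ref, c(1, 5, 3)))
  fitted0 <- superpose(ens0, reference = ref)
  expect_lt(rmsd(fitted0@coords[1, , ], ref), 1e-12)
  # rigidly rotated/translated copy fits back exactly
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ref %*% t(R) + matrix(c(1, -2, 3), 5, 3, byrow = TRUE)
  ens <- coordinateEnsemble(array(moved, c(1, 5, 3)))
  fit <- superpose(ens, reference = ref)
  expect_lt(rmsd(fit@coords[1, , ], ref), 1e-9)
  # mirror image: proper rotation enforced, residual stays positive and
  # matches a brute-force search over proper rotations
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.2, 1), 4, 3, byrow = TRUE)
  Pm <- P; Pm[, 3] <- -Pm[, 3]
  ensm <- coordinateEnsemble(array(Pm, c(1, 4, 3)))
  fitm <- superpose(ensm, reference = P)
  r <- rmsd(fitm@coords[1, , ], P)
  expect_gt(r, 1e-3)
  best <- Inf
  set.seed(2)
  for (i in 1:2000) {
    A <- matrix(rnorm(9), 3)
    qr_ <- qr(A); Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    ctr <- sweep(Pm, 2, colMeans(Pm))
    cand <- ctr %*% t(Q) + matrix(colMeans(P), 4, 3, byrow = TRUE)
    best <- min(best, rmsd(cand, P))
  }
  expect_lte(r, best + 1e-6)
  # collinear selection is degenerate
  line <- matrix(cbind(1:4, 0, 0), 4, 3)
  ensl <- coordinateEnsemble(array(line, c(1, 4, 3)))
  expect_error(superpose(ensl, reference = line + 0.1), "collinear")
})

test_that("PCA projection is deterministic with ordered variance", {
  set.seed(3)
  t0 <- rnorm(200)
  line <- cbind(2 * t0, -t0, 0.5 * t0)
  pl <- pcaProject(line, 2)
  expect_equal(pl$variance_explained[1], 1, tolerance = 1e-12)
  iso <- matrix(rnorm(2e4), ncol = 2)
  pi2 <- pcaProject(iso, 2)
  expect_equal(unname(pi2$variance_explained), c(0.5, 0.5), tolerance = 0.02)
  expect_identical(pcaProject(iso, 2)$scores, pi2$scores)
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(pi2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pcaProject(iso[1, , drop = FALSE], 2), "at least 2")
})

test_that("KDE energy surface follows the bandwidth rule and normalises", {
  # bandwidth: sigma (4/3N)^(1/5) = 0.2661 for sigma 1, N 1000
  expect_equal((4 / 3000)^(1 / 5), 0.2661, tolerance = 2e-4)
  set.seed(4)
  sc <- matrix(rnorm(2000), ncol = 2)
  ls <- kdeEnergySurface(sc, mesh = 0.25)
  expect_equal(min(ls@E[is.finite(ls@E)]), 0)
  expect_equal(sum(ls@P) * ls@mesh^2, 1, tolerance = 0.02)
  # E = -RT ln(P/Pmax) wherever P > 0
  pos <- ls@P > 0
  expect_equal(ls@E[pos], -ls@RT * log(ls@P[pos] / ls@Pmax),
               tolerance = 1e-12)
  cst <- cbind(rep(1, 10), 1:10)
  expect_error(kdeEnergySurface(cst, 0.5), "zero-variance")
})

test_that("basin detection separates well-separated modes", {
  set.seed(5)
  one <- matrix(rnorm(4000), ncol = 2)
  l1 <- findBasins(kdeEnergySurface(one, mesh = 0.25), 2)
  expect_equal(max(l1@basins), 1)
  s1 <- basinSummary(l1)
  expect_equal(s1$min_E, 0)
  # three Gaussians >= 8 sigma apart: exactly 3 basins at 2 RT
  mix <- sampleConformations(
    list(means = list(c(0, 0), c(10, 0), c(0, 10)),
         covs = list(1, 1, 1), weights = c(0.5, 0.3, 0.2)),
    5000, seed = 6)
  lm3 <- findBasins(kdeEnergySurface(mix$points, mesh = 0.5), 2)
  expect_equal(max(lm3@basins), 3)
  sm3 <- basinSummary(lm3)
  expect_equal(min(sm3$min_E), 0)
  # with equal-weight components the global 2 RT threshold clips every
  # mode identically, so basin shares recover the mixture weights
  mixEq <- sampleConformations(
    list(means = list(c(0, 0), c(10, 0), c(0, 10)),
         covs = list(1, 1, 1), weights = rep(1, 3) / 3),
    6000, seed = 16)
  lmEq <- findBasins(kdeEnergySurface(mixEq$points, mesh = 0.5), 2)
  smEq <- basinSummary(lmEq)
  expect_equal(nrow(smEq), 3)
  sdw <- sqrt((1 / 3) * (2 / 3) / 6000)
  expect_true(all(abs(smEq$share - 1 / 3) < pmax(3 * sdw, 0.03)))
  # cutoff -> Inf: one basin spanning all finite-energy cells
  linf <- findBasins(kdeEnergySurface(mix$points, mesh = 0.5), Inf)
  expect_equal(max(linf@basins), 1)
  expect_equal(sum(linf@basins > 0), sum(is.finite(linf@E)))
  # deterministic labels
  lm3b <- findBasins(kdeEnergySurface(mix$points, mesh = 0.5), 2)
  expect_identical(lm3@basins, lm3b@basins)
})

test_that("ion maps convert triangular-kernel densities to mM", {
  # unit lattice: density 1 / A^3, so concentration = 1.6606e6 mM;
  # bandwidth-2 triangular kernels on a unit lattice sum to 1 exactly
  g <- as.matrix(expand.grid(x = 0:14, y = 0:14, z = 0:14))
  map <- ionConcentrationMap(g, mesh = 1, bandwidth = 2)
  interior <- map$conc[map$x >= 3 & map$x <= 11,
                       map$y >= 3 & map$y <= 11,
                       map$z >= 3 & map$z <= 11]
  expect_equal(mean(interior), 1.6606e6, tolerance = 1e-9)
  expect_equal(max(abs(interior - 1.6606e6)), 0, tolerance = 1e-6)
  # empty ion set: all-zero grid
  e <- ionConcentrationMap(list(matrix(0, 0, 3)),
                           range = rep(list(c(0, 5)), 3))
  expect_true(all(e$conc == 0))
  # doubling the ions doubles the concentration
  m1 <- ionConcentrationMap(g[1:500, ], range = rep(list(c(0, 14)), 3))
  m2 <- ionConcentrationMap(rbind(g[1:500, ], g[1:500, ]),
                            range = rep(list(c(0, 14)), 3))
  expect_equal(m2$conc, 2 * m1$conc, tolerance = 1e-9)
  iso <- isoConcentrationCells(map, 1.6e6)
  expect_true(nrow(iso) > 0)
})

test_that("energy surfaces are invariant under joint rigid motion", {
  set.seed(7)
  co <- array(rnorm(20 * 6 * 3, sd = 2), c(20, 6, 3))
  ens <- coordinateEnsemble(co)
  fit <- superpose(ens, reference = co[1, , ])
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  co2 <- co
  for (f in 1:20) co2[f, , ] <- co[f, , ] %*% t(R) + 5
  ens2 <- coordinateEnsemble(co2)
  fit2 <- superpose(ens2, reference = co2[1, , ])
  p1 <- pcaProject(fit, 2)$scores
  p2 <- pcaProject(fit2, 2)$scores
  # scores agree up to component sign; align before comparing surfaces
  for (k in 1:2) if (cor(p1[, k], p2[, k]) < 0) p2[, k] <- -p2[, k]
  expect_lt(max(abs(p1 - p2)), 1e-6)
  l1 <- kdeEnergySurface(p1, 0.5)
  l2 <- kdeEnergySurface(p2, 0.5)
  ok <- is.finite(l1@E) & is.finite(l2@E)
  expect_lt(max(abs(l1@E[ok] - l2@E[ok])), 1e-6)
})
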