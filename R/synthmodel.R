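LN10 <- log(10)

#' Thermal energy in kcal/mol
#'
#' @param temperature temperature in Kelvin
#' @return RT in kcal/mol (0.59616 at the default 300 K)
#' @export
thermalRT <- function(temperature = 300) 1.9872e-3 * temperature

#' Construct a coupled-site species model
#'
#' @param label species name
#' @param pka intrinsic pKa per site
#' @param charge_class "acid" or "base" per site (recycled)
#' @param coupling symmetric coupling matrix in RT units (default: none)
#' @param site_id site labels (default site1, site2, ...)
#' @param chain chain label per site (recycled)
#' @return a \linkS4class{SpeciesModel}
#' @examples
#' m <- speciesModel("M", pka = c(4, 6.5), charge_class = c("acid", "base"))
#' enumeratePartition(m, ph = 7)
#' @export
speciesModel <- function(label, pka, charge_class = "acid", coupling = NULL,
                         site_id = NULL, chain = "A") {
  q <- length(pka)
  if (is.null(site_id))
    site_id <- if (q) paste0("site", seq_len(q)) else character()
  if (is.null(coupling)) coupling <- matrix(0, q, q)
  sites <- data.frame(site_id = as.character(site_id),
                      pka_intr = as.numeric(pka),
                      charge_class = rep_len(charge_class, q),
                      chain = rep_len(chain, q),
                      stringsAsFactors = FALSE)
  new("SpeciesModel", label = label, sites = sites,
      coupling = unname(as.matrix(coupling)))
}

#' @rdname speciesModel
#' @param object a SpeciesModel
#' @export
siteIds <- function(object) object@sites$site_id

#' @rdname speciesModel
#' @export
nSites <- function(object) nrow(object@sites)

#' Construct a reaction specification
#'
#' @param label reaction name
#' @param products,reactants named integer vectors of stoichiometric
#'   coefficients, e.g. \code{c(ML = 1)} and \code{c(M = 1, L = 1)}
#' @param site_map data.frame with columns \code{product_site},
#'   \code{ref_species}, \code{ref_site}; \code{ref_species = "ligand"}
#'   matches a product site to the free-ligand curve
#' @return a \linkS4class{ReactionSpec}
#' @export
reactionSpec <- function(label, products, reactants, site_map = NULL) {
  mk <- function(v) data.frame(species = names(v), coeff = as.integer(v),
                               stringsAsFactors = FALSE)
  if (is.null(site_map))
    site_map <- data.frame(product_site = character(),
                           ref_species = character(),
                           ref_site = character(), stringsAsFactors = FALSE)
  new("ReactionSpec", label = label, products = mk(products),
      reactants = mk(reactants), siteMap = site_map)
}

#' Free-ligand Hill titration curve
#'
#' @param pka ligand pKa (e.g. 5.0 for palmitate after model-compound
#'   calibration)
#' @param h Hill coefficient
#' @return a \linkS4class{LigandCurve}
#' @export
ligandCurve <- function(pka = 5.0, h = 1) new("LigandCurve", pka = pka, h = h)

# enumeration backbone: 2^Q microstate matrix and per-pH Boltzmann moments.
.enumStates <- function(q) {
  if (q > 20L)
    stop("enumeration limit exceeded: ", q,
         " sites (exact enumeration supports at most 20)")
  n <- bitwShiftL(1L, q)
  X <- matrix(0, n, q)
  for (b in seq_len(q))
    X[, b] <- bitwAnd(bitwShiftR(seq_len(n) - 1L, b - 1L), 1L)
  X
}

.enumMoments <- function(model, ph_grid) {
  q <- nSites(model)
  X <- .enumStates(q)
  pka <- model@sites$pka_intr
  s <- rowSums(X)
  xp <- if (q) drop(X %*% pka) else numeric(nrow(X))
  pair <- if (q) rowSums((X %*% model@coupling) * X) / 2 else numeric(nrow(X))
  np <- length(ph_grid)
  lnZ <- numeric(np)
  nms <- matrix(0, np, q)
  ntot <- numeric(np)
  vtot <- numeric(np)
  cst <- matrix(0, np, q)
  ttot <- numeric(np)
  tst <- matrix(0, np, q)
  for (k in seq_len(np)) {
    u <- LN10 * (ph_grid[k] * s - xp) + pair
    mx <- max(-u)
    lz <- mx + log(sum(exp(-u - mx)))
    p <- exp(-u - lz)
    lnZ[k] <- lz
    if (q) {
      ni <- drop(crossprod(X, p))
      tot <- sum(ni)
      ci <- drop(crossprod(X * s, p)) - ni * tot
      d2 <- (s - tot)^2
      ti <- drop(crossprod(X * d2, p)) - ni * sum(d2 * p)
      nms[k, ] <- ni
      ntot[k] <- tot
      cst[k, ] <- ci
      vtot[k] <- sum(ci)
      tst[k, ] <- ti
      ttot[k] <- sum(ti)
    }
  }
  list(lnZ = lnZ, nMeanSite = nms, nMeanTotal = ntot,
       varTotal = vtot, covSiteTotal = cst,
       thirdTotal = ttot, thirdSiteTotal = tst)
}

#' Log binding polynomial by exact microstate enumeration
#'
#' Evaluates \eqn{\ln Z(pH) = \ln \sum_x e^{-u(x; pH)}} over all
#' \eqn{2^Q} protonation microstates (log-sum-exp). This is the exact
#' oracle behind all linkage quantities: \eqn{-RT \ln Z} is the species'
#' proton-binding free energy and \eqn{-d\ln Z/dpH = \ln 10\,\bar n}.
#'
#' @param model a \linkS4class{SpeciesModel} with at most 20 sites
#' @param ph pH value(s)
#' @return ln Z, one value per pH
#' @export
enumeratePartition <- function(model, ph) {
  stopifnot(is(model, "SpeciesModel"))
  .enumMoments(model, ph)$lnZ
}

#' Exact titration statistics by enumeration
#'
#' Exact Boltzmann averages of per-site and total protonation, the total
#' variance and the site-total covariances on a pH grid. These satisfy the
#' fluctuation identities \eqn{d\bar n/dpH = -\ln 10\,\mathrm{var}(n)} and
#' \eqn{d\bar n_i/dpH = -\ln 10\,\mathrm{cov}(n_i, n)} exactly.
#'
#' @inheritParams enumeratePartition
#' @param ph_grid ordered pH values
#' @return an \linkS4class{ExactEnsemble}
#' @export
exactTitration <- function(model, ph_grid) {
  stopifnot(is(model, "SpeciesModel"))
  mo <- .enumMoments(model, ph_grid)
  colnames(mo$nMeanSite) <- colnames(mo$covSiteTotal) <-
    colnames(mo$thirdSiteTotal) <- siteIds(model)
  new("ExactEnsemble", species = model@label, ph_grid = as.numeric(ph_grid),
      lnZ = mo$lnZ, nMeanSite = mo$nMeanSite, nMeanTotal = mo$nMeanTotal,
      varTotal = pmax(mo$varTotal, 0), covSiteTotal = mo$covSiteTotal,
      thirdTotal = mo$thirdTotal, thirdSiteTotal = mo$thirdSiteTotal)
}

.reactionLnZ <- function(reaction, models, ph) {
  term <- function(tab, sgn) {
    out <- 0
    for (i in seq_len(nrow(tab))) {
      lab <- tab$species[i]
      if (!lab %in% names(models)) stop("unknown species label: ", lab)
      out <- out + sgn * tab$coeff[i] * enumeratePartition(models[[lab]], ph)
    }
    out
  }
  term(reaction@products, 1) + term(reaction@reactants, -1)
}

#' Exact relative reaction free-energy profile
#'
#' The enumeration twin of spline-based linkage integration: the relative
#' free energy of a reaction is computed directly from partition-function
#' differences, \eqn{\Delta\Delta G(pH) = -RT[\Delta\ln Z(pH) -
#' \Delta\ln Z(pH_{ref})]}, which equals \eqn{\ln 10\,RT
#' \int_{pH_{ref}}^{pH} \Delta\bar n\, dpH'} exactly.
#'
#' @param reaction a \linkS4class{ReactionSpec}
#' @param models named list of \linkS4class{SpeciesModel}s covering every
#'   species in the reaction
#' @param ph_grid evaluation pH grid
#' @param ph_ref reference pH (profile is zero there)
#' @param temperature Kelvin
#' @return a \linkS4class{FreeEnergyProfile} (method "exact")
#' @export
exactFreeEnergyProfile <- function(reaction, models, ph_grid, ph_ref = 3,
                                   temperature = 300) {
  RT <- thermalRT(temperature)
  dlnZ <- .reactionLnZ(reaction, models, ph_grid)
  dlnZ0 <- .reactionLnZ(reaction, models, ph_ref)
  new("FreeEnergyProfile", reaction = reaction@label, ph_ref = ph_ref,
      ph_grid = as.numeric(ph_grid), ddG = -RT * (dlnZ - dlnZ0),
      method = "exact", anchored = FALSE, anchor = NULL, band = NULL,
      resamples = NULL)
}

#' Metropolis sampling of protonation microstates
#'
#' Emulates a constant-pH simulation's protonation record: single-site
#' Metropolis flips (one pass per sweep) plus joint two-site moves for
#' strongly coupled pairs (|w|/ln 10 >= \code{pair_threshold} pKa units),
#' which keep anticorrelated pairs mobile. One state is recorded every
#' \code{record_every} sweeps; the full record is kept and equilibration
#' is discarded downstream (see \code{\link{averageProtonation}}).
#'
#' @inheritParams enumeratePartition
#' @param ph simulation pH
#' @param n_sweeps number of sweeps (> 0)
#' @param record_every sweeps between recorded states
#' @param seed RNG seed (trace is reproducible for a fixed seed)
#' @param replicate replicate id stored in the trace
#' @param pair_threshold coupling threshold (pKa units) for joint moves
#' @return an \linkS4class{OccupancyTrace}
#' @export
sampleMicrostates <- function(model, ph, n_sweeps, record_every = 1L,
                              seed = 1L, replicate = 1L,
                              pair_threshold = 2.0) {
  stopifnot(is(model, "SpeciesModel"), n_sweeps > 0, record_every >= 1)
  q <- nSites(model)
  strong <- which(abs(model@coupling) / LN10 >= pair_threshold &
                  upper.tri(model@coupling), arr.ind = TRUE)
  set.seed(seed)
  st <- cpp_sample_microstates(model@sites$pka_intr, model@coupling, ph,
                               as.integer(n_sweeps), as.integer(record_every),
                               matrix(as.integer(strong - 1L), ncol = 2))
  colnames(st) <- siteIds(model)
  new("OccupancyTrace", species = model@label, ph = ph,
      replicate = as.integer(replicate), seed = as.integer(seed),
      recordInterval = as.integer(record_every), states = st,
      siteIds = siteIds(model))
}

#' Synthetic benchmark scenario: monomer, ligand, complex, dimer
#'
#' Builds the five species of the ligand-binding/dimerization cycle with a
#' known ground truth: a monomer M with randomly drawn site pKa values and
#' intra-chain couplings; a one-site free ligand L; the complex ML as M
#' with binding-induced pKa shifts plus a bound-ligand site; the dimer D
#' as two copies of M with inter-chain interface couplings; and DL2
#' analogous to D with two bound ligands. All four cycle reactions
#' (2M -> D, 2ML -> DL2, M + L -> ML, D + 2L -> DL2) come with exact
#' enumeration free-energy profiles, so cycle closure holds by
#' construction.
#'
#' @param n_sites sites per monomer chain (default 4)
#' @param pka_range range from which intrinsic pKa values are drawn
#' @param coupling_range magnitude range (pKa units) of intra-chain and
#'   interface couplings; signs are random
#' @param ligand_pka free-ligand pKa (palmitate-like default 5.0)
#' @param ligand_shift maximum binding-induced pKa shift on the binding
#'   site(s); 0 with \code{ligand_site_coupling = 0} makes the allosteric
#'   coupling pH-independent
#' @param ligand_site_coupling coupling (pKa units) between the bound
#'   ligand site and its nearest protein site
#' @param ph_grid pH grid of the exact profiles
#' @param ph_ref reference pH
#' @param temperature Kelvin
#' @param seed RNG seed
#' @return list with \code{models} (M, L, ML, D, DL2),
#'   \code{reactions} (bind_M, bind_D, dim_apo, dim_holo),
#'   \code{exact} (FreeEnergyProfile per reaction) and \code{config}
#' @export
makeBenchmarkScenario <- function(n_sites = 4, pka_range = c(3.5, 7.5),
                                  coupling_range = c(0.25, 1.0),
                                  ligand_pka = 5.0, ligand_shift = 0.8,
                                  ligand_site_coupling = 0.5,
                                  ph_grid = 3:8, ph_ref = 3,
                                  temperature = 300, seed = 1) {
  set.seed(seed)
  q <- n_sites
  pka <- round(runif(q, pka_range[1], pka_range[2]), 2)
  cls <- sample(c("acid", "base"), q, replace = TRUE, prob = c(0.7, 0.3))
  # couplings are repulsive (w >= 0): in the binding-polynomial convention
  # every purely electrostatic site-site interaction is anticooperative;
  # cooperative couplings require conformational coupling, which this
  # protonation-only model excludes
  rmag <- function(n) runif(n, coupling_range[1], coupling_range[2]) * LN10
  wM <- matrix(0, q, q)
  intra <- which(upper.tri(wM), arr.ind = TRUE)
  pick <- intra[runif(nrow(intra)) < 0.5, , drop = FALSE]
  if (nrow(pick)) {
    wM[pick] <- rmag(nrow(pick))
    wM <- wM + t(wM)
  }
  M <- speciesModel("M", pka, cls, wM, chain = "A")
  L <- speciesModel("L", ligand_pka, "acid", site_id = "lig", chain = "L")

  # binding shifts the pKa of the half of the chain forming the pocket
  nshift <- max(1, floor(q / 2))
  shift <- numeric(q)
  shift[seq_len(nshift)] <- runif(nshift, -ligand_shift, ligand_shift)
  pkaML <- pka + shift
  wML <- rbind(cbind(wM, 0), 0)
  if (ligand_site_coupling != 0)
    wML[1, q + 1] <- wML[q + 1, 1] <- ligand_site_coupling * LN10
  ML <- speciesModel("ML", c(pkaML, ligand_pka), c(cls, "acid"), wML,
                     site_id = c(siteIds(M), "lig"),
                     chain = c(rep("A", q), "L"))

  # interface couplings act between protein sites only, identically in the
  # apo and holo dimers: site i of chain A pairs with site (q+1-i) of chain B
  nint <- max(1, floor(q / 2))
  wi <- rmag(nint)
  dimerize <- function(lab, w_mono, pka_mono, cls_mono, ids) {
    qq <- length(pka_mono)
    w <- matrix(0, 2 * qq, 2 * qq)
    w[seq_len(qq), seq_len(qq)] <- w_mono
    w[qq + seq_len(qq), qq + seq_len(qq)] <- w_mono
    for (k in seq_len(nint)) {
      i <- k; j <- qq + (q + 1 - k)
      w[i, j] <- w[j, i] <- wi[k]
    }
    speciesModel(lab, rep(pka_mono, 2), rep(cls_mono, 2), w,
                 site_id = c(paste0(ids, ".A"), paste0(ids, ".B")),
                 chain = rep(c("A", "B"), each = qq))
  }
  D <- dimerize("D", wM, pka, cls, siteIds(M))
  DL2 <- dimerize("DL2", wML, c(pkaML, ligand_pka), c(cls, "acid"),
                  c(siteIds(M), "lig"))

  models <- list(M = M, L = L, ML = ML, D = D, DL2 = DL2)
  mapTo <- function(prod_sites, ref_species, ref_sites)
    data.frame(product_site = prod_sites, ref_species = ref_species,
               ref_site = ref_sites, stringsAsFactors = FALSE)
  reactions <- list(
    bind_M = reactionSpec("bind_M", c(ML = 1), c(M = 1, L = 1),
      rbind(mapTo(siteIds(M), "M", siteIds(M)),
            mapTo("lig", "ligand", "lig"))),
    bind_D = reactionSpec("bind_D", c(DL2 = 1), c(D = 1, L = 2),
      rbind(mapTo(siteIds(D), "D", siteIds(D)),
            mapTo(c("lig.A", "lig.B"), "ligand", "lig"))),
    dim_apo = reactionSpec("dim_apo", c(D = 1), c(M = 2),
      mapTo(siteIds(D), "M", rep(siteIds(M), 2))),
    dim_holo = reactionSpec("dim_holo", c(DL2 = 1), c(ML = 2),
      mapTo(siteIds(DL2), "ML", rep(siteIds(ML), 2))))
  exact <- lapply(reactions, exactFreeEnergyProfile, models = models,
                  ph_grid = ph_grid, ph_ref = ph_ref,
                  temperature = temperature)
  list(models = models, reactions = reactions, exact = exact,
       config = list(n_sites = n_sites, pka_range = pka_range,
                     coupling_range = coupling_range,
                     ligand_pka = ligand_pka, ligand_shift = ligand_shift,
                     ligand_site_coupling = ligand_site_coupling,
                     ph_grid = ph_grid, ph_ref = ph_ref,
                     temperature = temperature, seed = seed))
}

#' Sample synthetic conformational ensembles from a Gaussian mixture
#'
#' Fixture generator for landscape analyses: draws flattened-coordinate
#' points from a mixture of multivariate Gaussians (component means are
#' 3N-vectors).
#'
#' @param mixture_spec list with \code{means} (list of numeric vectors),
#'   \code{covs} (list of covariance matrices, or scalar variances) and
#'   \code{weights} (summing to 1 within 1e-9)
#' @param n_points number of points to draw
#' @param seed RNG seed
#' @return list with \code{points} (n x 3N matrix) and \code{component}
#'   assignment per point
#' @export
sampleConformations <- function(mixture_spec, n_points, seed = 1) {
  w <- mixture_spec$weights
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  d <- length(mixture_spec$means[[1]])
  set.seed(seed)
  if (n_points == 0)
    return(list(points = matrix(0, 0, d), component = integer()))
  comp <- sample.int(length(w), n_points, replace = TRUE, prob = w)
  pts <- matrix(0, n_points, d)
  for (k in seq_along(w)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    S <- mixture_spec$covs[[k]]
    if (length(S) == 1) S <- diag(rep(S, d), d)
    pts[idx, ] <- MASS::mvrnorm(length(idx), mixture_spec$means[[k]], S)
  }
  list(points = pts, component = comp)
}
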