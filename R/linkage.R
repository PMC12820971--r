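# node values and fluctuation slopes of a species curve on a pH grid
.nodeData <- function(x, grid) {
  if (is(x, "LigandCurve")) {
    nn <- 1 / (1 + 10^(x@h * (grid - x@pka)))
    sl <- -LN10 * x@h * nn * (1 - nn)
    cv <- (LN10 * x@h)^2 * nn * (1 - nn) * (1 - 2 * nn)
    one <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "lig"))
    return(list(ph = grid, meanTotal = nn, slopeTotal = sl, curvTotal = cv,
                meanSite = one(nn), slopeSite = one(sl), curvSite = one(cv)))
  }
  if (is(x, "ExactEnsemble")) x <- asTitrationTable(x)
  stopifnot(is(x, "TitrationTable"))
  if (length(x@ph_grid) != length(grid) || max(abs(x@ph_grid - grid)) > 1e-9)
    stop("species '", x@species, "' is not on the shared pH grid")
  sl <- fluctuationSlopes(x)
  list(ph = grid, meanTotal = x@meanTotal, slopeTotal = sl$total,
       curvTotal = LN10^2 * x@thirdTotal,
       meanSite = x@meanSite, slopeSite = sl$site,
       curvSite = LN10^2 * x@thirdSiteTotal)
}

.speciesData <- function(label, tables, ligand_curve, grid) {
  if (label %in% names(tables)) return(.nodeData(tables[[label]], grid))
  if (!is.null(ligand_curve)) return(.nodeData(ligand_curve, grid))
  stop("missing species '", label, "' and no ligand curve supplied")
}

# stoichiometric protonation-difference curve (values and slopes)
.differenceCurve <- function(reaction, tables, ligand_curve, grid) {
  val <- slo <- cur <- numeric(length(grid))
  acc <- function(tab, sgn) {
    for (i in seq_len(nrow(tab))) {
      nd <- .speciesData(tab$species[i], tables, ligand_curve, grid)
      val <<- val + sgn * tab$coeff[i] * nd$meanTotal
      slo <<- slo + sgn * tab$coeff[i] * nd$slopeTotal
      cur <<- cur + sgn * tab$coeff[i] * nd$curvTotal
    }
  }
  acc(reaction@products, 1)
  acc(reaction@reactants, -1)
  list(values = val, slopes = slo, curvatures = cur)
}

.newProfile <- function(reaction, ph_ref, grid, ddG, method,
                        band = NULL, resamples = NULL) {
  new("FreeEnergyProfile", reaction = reaction, ph_ref = ph_ref,
      ph_grid = as.numeric(grid), ddG = ddG, method = method,
      anchored = FALSE, anchor = NULL, band = band, resamples = resamples)
}

#' Spline-integrated linkage free-energy profile
#'
#' The core linkage relation: the relative reaction free energy is
#' \deqn{\Delta\Delta G(pH) = \ln 10\, RT \int_{pH_{ref}}^{pH}
#'   \Delta\bar n\, dpH'}
#' with \eqn{\Delta\bar n} the stoichiometric difference of mean
#' protonations between products and reactants. The difference curve is
#' interpolated once with a thermodynamic spline whose node slopes combine
#' the species' fluctuation slopes with the same stoichiometry, and
#' integrated in closed form.
#'
#' @param reaction a \linkS4class{ReactionSpec}
#' @param tables named list (by species label) of
#'   \linkS4class{TitrationTable}, \linkS4class{ExactEnsemble} or
#'   \linkS4class{LigandCurve} objects, all on the same pH grid
#' @param ligand_curve \linkS4class{LigandCurve} used for any reaction
#'   species absent from \code{tables} (the free ligand, whose curve is
#'   derived from an experimental pKa)
#' @param ph_ref reference pH (default 3); must lie within the grid span
#' @param temperature Kelvin (RT fixed from it; outputs in kcal/mol)
#' @return a \linkS4class{FreeEnergyProfile} with method "spline"
#' @export
integrateLinkage <- function(reaction, tables, ligand_curve = NULL,
                             ph_ref = 3, temperature = 300) {
  grid <- NULL
  for (tb in tables)
    if (!is(tb, "LigandCurve")) { grid <- .phGridOf(tb); break }
  if (is.null(grid)) stop("no species table defines a pH grid")
  if (ph_ref < min(grid) - 1e-9 || ph_ref > max(grid) + 1e-9)
    stop("ph_ref outside the pH grid span")
  dc <- .differenceCurve(reaction, tables, ligand_curve, grid)
  sp <- buildThermoSpline(grid, dc$values, dc$slopes, dc$curvatures)
  RT <- thermalRT(temperature)
  .newProfile(reaction@label, ph_ref, grid,
              LN10 * RT * splineIntegral(sp, ph_ref, grid), "spline")
}

.phGridOf <- function(x) {
  if (is(x, "ExactEnsemble") || is(x, "TitrationTable")) x@ph_grid
  else stop("object has no pH grid")
}

#' Per-site decomposition of a linkage profile
#'
#' Integrates, for every product site, the difference between its
#' protonation curve and that of its matched reactant site (or the
#' free-ligand curve), with slopes from the per-site fluctuation relation
#' \eqn{d\bar n_i/dpH = -\ln 10\,\mathrm{cov}(n_i, n)}. By linearity of
#' the integral the site contributions sum to the total profile.
#'
#' @inheritParams integrateLinkage
#' @return a \linkS4class{SiteContributionSet}
#' @export
siteDecomposition <- function(reaction, tables, ligand_curve = NULL,
                              ph_ref = 3, temperature = 300) {
  if (nrow(reaction@products) != 1 || reaction@products$coeff[1] != 1)
    stop("site decomposition requires a single product with unit coefficient")
  sm <- reaction@siteMap
  prod <- .speciesData(reaction@products$species[1], tables, ligand_curve,
                       .phGridOf(tables[[reaction@products$species[1]]]))
  grid <- prod$ph
  if (!all(sm$product_site %in% colnames(prod$meanSite)))
    stop("site map names unknown product sites")
  if (!setequal(sm$product_site, colnames(prod$meanSite)))
    stop("site map must cover every product site")
  RT <- thermalRT(temperature)
  contrib <- matrix(0, length(grid), nrow(sm),
                    dimnames = list(NULL, sm$product_site))
  for (i in seq_len(nrow(sm))) {
    ps <- sm$product_site[i]
    if (sm$ref_species[i] == "ligand") {
      if (is.null(ligand_curve)) stop("site '", ps,
                                      "' mapped to ligand but no ligand curve")
      ref <- .nodeData(ligand_curve, grid)
      rv <- ref$meanTotal; rs <- ref$slopeTotal; rc <- ref$curvTotal
    } else {
      ref <- .speciesData(sm$ref_species[i], tables, ligand_curve, grid)
      j <- match(sm$ref_site[i], colnames(ref$meanSite))
      if (is.na(j)) stop("unmapped reference site '", sm$ref_site[i], "'")
      rv <- ref$meanSite[, j]; rs <- ref$slopeSite[, j]
      rc <- ref$curvSite[, j]
    }
    j <- match(ps, colnames(prod$meanSite))
    sp <- buildThermoSpline(grid, prod$meanSite[, j] - rv,
                            prod$slopeSite[, j] - rs,
                            prod$curvSite[, j] - rc)
    contrib[, i] <- LN10 * RT * splineIntegral(sp, ph_ref, grid)
  }
  total <- integrateLinkage(reaction, tables, ligand_curve, ph_ref,
                            temperature)
  new("SiteContributionSet", siteIds = sm$product_site,
      contributions = contrib, total = total, siteMap = sm)
}

# antiderivative of the Hill curve: F'(pH) = [1 + 10^{h(pH-pKa)}]^{-1}
.hillAnti <- function(ph, pka, h) {
  z <- h * LN10 * (ph - pka)
  # log1p(exp(z)) computed stably for large |z|
  lse <- ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  ph - lse / (h * LN10)
}

#' Hill-based linkage integration
#'
#' The closed-form alternative to spline integration: every mapped site
#' pair contributes \eqn{F_{prod} - F_{ref}} with
#' \eqn{F(pH) = pH - \ln(1 + 10^{h(pH - pKa)}) / (h \ln 10)},
#' the exact antiderivative of the Hill curve, evaluated between the
#' reference pH and each grid pH. No quadrature is involved.
#'
#' @param reaction a \linkS4class{ReactionSpec} with a complete site map
#' @param fits named list (by species label) of per-site
#'   \linkS4class{HillFit} lists, as from \code{\link{fitHillSites}}
#' @param ligand_curve \linkS4class{LigandCurve} for sites mapped to
#'   "ligand"
#' @param ph_grid evaluation grid
#' @param ph_ref reference pH
#' @param temperature Kelvin
#' @return a \linkS4class{FreeEnergyProfile} with method "hill"
#' @export
hillIntegration <- function(reaction, fits, ligand_curve = NULL,
                            ph_grid, ph_ref = 3, temperature = 300) {
  sm <- reaction@siteMap
  if (!nrow(sm)) stop("reaction has no site map")
  getF <- function(species, site) {
    if (species == "ligand") {
      if (is.null(ligand_curve)) stop("no ligand curve supplied")
      return(c(ligand_curve@pka, ligand_curve@h))
    }
    f <- fits[[species]][[site]]
    if (is.null(f)) stop("no Hill fit for ", species, ":", site)
    if (!f@converged) stop("non-converged Hill fit for ", species, ":", site)
    c(f@pka, f@h)
  }
  prodSpecies <- reaction@products$species[1]
  acc <- numeric(length(ph_grid))
  for (i in seq_len(nrow(sm))) {
    pp <- getF(prodSpecies, sm$product_site[i])
    rr <- getF(sm$ref_species[i], sm$ref_site[i])
    dF <- (.hillAnti(ph_grid, pp[1], pp[2]) - .hillAnti(ph_ref, pp[1], pp[2])) -
      (.hillAnti(ph_grid, rr[1], rr[2]) - .hillAnti(ph_ref, rr[1], rr[2]))
    acc <- acc + dF
  }
  RT <- thermalRT(temperature)
  .newProfile(reaction@label, ph_ref, ph_grid, LN10 * RT * acc, "hill")
}

# evaluate a profile at an arbitrary pH inside its span
.profileAt <- function(profile, ph) {
  g <- profile@ph_grid
  if (ph < min(g) - 1e-9 || ph > max(g) + 1e-9)
    stop("pH outside the profile's span")
  k <- which(abs(g - ph) < 1e-9)
  if (length(k)) return(profile@ddG[k[1]])
  stats::spline(g, profile@ddG, xout = ph, method = "fmm")$y
}

#' Anchor a relative profile to an absolute reference value
#'
#' pH-dependent linkage profiles are defined up to a constant; their
#' vertical placement is assigned by reference to an experimental value:
#' the whole curve (and any uncertainty band or resamples) is rigidly
#' shifted so that it passes through \code{anchor_value} at
#' \code{anchor_ph}. Curve shape and pairwise differences are unchanged.
#'
#' @param profile a \linkS4class{FreeEnergyProfile}
#' @param anchor_ph pH of the anchor (must lie within the profile span)
#' @param anchor_value absolute free energy at \code{anchor_ph} (kcal/mol)
#' @return the anchored \linkS4class{FreeEnergyProfile}
#' @export
anchorProfile <- function(profile, anchor_ph, anchor_value) {
  off <- anchor_value - .profileAt(profile, anchor_ph)
  profile@ddG <- profile@ddG + off
  if (!is.null(profile@band)) profile@band <- profile@band + off
  if (!is.null(profile@resamples)) profile@resamples <- profile@resamples + off
  profile@anchored <- TRUE
  profile@anchor <- c(anchor_ph, anchor_value)
  validObject(profile)
  profile
}

#' Replicate-bootstrap uncertainty band for a linkage profile
#'
#' Resamples replicates with replacement, independently for every
#' (species, pH) cell, recomputes the full spline-integrated profile for
#' each resample, and summarises the resample curves as either a 68%
#' central interval (the convention for protonation-derived quantities)
#' or a +/- 1 SD band. Replicates, not frames, are the resampling unit:
#' they are the independent unit of the simulation design, and frame
#' autocorrelation would bias a frame-level bootstrap.
#'
#' @inheritParams integrateLinkage
#' @param B number of bootstrap resamples (default 1000)
#' @param seed RNG seed
#' @param mode "percentile" (68% central interval) or "sd"
#' @return a \linkS4class{FreeEnergyProfile} with band and resamples
#' @export
bootstrapProfile <- function(reaction, tables, ligand_curve = NULL,
                             ph_ref = 3, temperature = 300, B = 1000,
                             seed = 1, mode = c("percentile", "sd")) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  est <- integrateLinkage(reaction, tables, ligand_curve, ph_ref, temperature)
  grid <- est@ph_grid
  RT <- thermalRT(temperature)
  involved <- unique(c(reaction@products$species, reaction@reactants$species))
  resampleable <- Filter(function(lab) lab %in% names(tables) &&
                           is(tables[[lab]], "TitrationTable") &&
                           ncol(tables[[lab]]@repMeanTotal) >= 2, involved)
  if (!length(resampleable))
    stop("bootstrap band undefined: no species has >= 2 replicates")
  coeffOf <- function(lab) {
    s <- 0
    i <- match(lab, reaction@products$species)
    if (!is.na(i)) s <- s + reaction@products$coeff[i]
    i <- match(lab, reaction@reactants$species)
    if (!is.na(i)) s <- s - reaction@reactants$coeff[i]
    s
  }
  # fixed part of the difference curve (non-resampleable species)
  fixed <- .differenceCurve(reaction, tables, ligand_curve, grid)
  for (lab in resampleable) {
    nd <- .speciesData(lab, tables, ligand_curve, grid)
    cf <- coeffOf(lab)
    fixed$values <- fixed$values - cf * nd$meanTotal
    fixed$slopes <- fixed$slopes - cf * nd$slopeTotal
    fixed$curvatures <- fixed$curvatures - cf * nd$curvTotal
  }
  set.seed(seed)
  res <- matrix(0, B, length(grid))
  for (b in seq_len(B)) {
    val <- fixed$values; slo <- fixed$slopes; cur <- fixed$curvatures
    for (lab in resampleable) {
      tb <- tables[[lab]]
      R <- ncol(tb@repMeanTotal)
      cf <- coeffOf(lab)
      for (k in seq_along(grid)) {
        idx <- sample.int(R, R, replace = TRUE)
        val[k] <- val[k] + cf * mean(tb@repMeanTotal[k, idx])
        slo[k] <- slo[k] - cf * LN10 * mean(tb@repVarTotal[k, idx])
        cur[k] <- cur[k] + cf * LN10^2 * mean(tb@repThirdTotal[k, idx])
      }
    }
    sp <- buildThermoSpline(grid, val, slo, cur)
    res[b, ] <- LN10 * RT * splineIntegral(sp, ph_ref, grid)
  }
  band <- if (mode == "percentile") {
    t(apply(res, 2, quantile, probs = c(0.16, 0.84), names = FALSE))
  } else {
    sdv <- apply(res, 2, sd)
    cbind(est@ddG - sdv, est@ddG + sdv)
  }
  # minimal widening so the band always contains the point estimate
  band[, 1] <- pmin(band[, 1], est@ddG)
  band[, 2] <- pmax(band[, 2], est@ddG)
  colnames(band) <- c("lower", "upper")
  est@band <- band
  est@resamples <- res
  est
}
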