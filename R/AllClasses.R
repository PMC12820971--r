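#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' A titratable species as coupled binary proton-binding sites
#'
#' A \code{SpeciesModel} describes one chemical species (monomer, ligand,
#' complex, dimer, ...) as an ordered set of titratable sites, each with an
#' intrinsic pKa and a charge class, plus a symmetric site-site coupling
#' matrix in RT units. The microstate energy of a protonation vector
#' \eqn{x \in \{0,1\}^Q} at a given pH is
#' \deqn{u(x; pH) = \ln 10 \sum_i x_i (pH - pKa_i) + \sum_{i<j} w_{ij} x_i x_j}
#' so an isolated site titrates as a Hill curve with h = 1.
#'
#' @slot label species name (e.g. "M", "L", "ML", "D", "DL2")
#' @slot sites data.frame with columns \code{site_id}, \code{pka_intr},
#'   \code{charge_class} ("acid" or "base") and \code{chain}
#' @slot coupling symmetric numeric matrix of pairwise couplings w_ij
#'   (RT units, zero diagonal), one row/column per site
#' @export
setClass("SpeciesModel",
  representation(label = "character", sites = "data.frame",
                 coupling = "matrix"))

setValidity("SpeciesModel", function(object) {
  s <- object@sites
  msg <- character()
  need <- c("site_id", "pka_intr", "charge_class", "chain")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(s$site_id)) msg <- c(msg, "site ids must be unique")
  if (!all(is.finite(s$pka_intr))) msg <- c(msg, "pka_intr must be finite")
  if (!all(s$charge_class %in% c("acid", "base")))
    msg <- c(msg, "charge_class must be 'acid' or 'base'")
  w <- object@coupling
  q <- nrow(s)
  if (!identical(dim(w), c(q, q)))
    msg <- c(msg, "coupling dimension must equal the number of sites")
  else if (q > 0) {
    if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "coupling must be symmetric")
    if (max(abs(diag(w))) > 0) msg <- c(msg, "coupling diagonal must be zero")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Exact Boltzmann titration statistics of a species
#'
#' Per-pH log partition values and exact protonation moments (per-site and
#' total means, total variance, site-total covariances) obtained by full
#' microstate enumeration of a \linkS4class{SpeciesModel}.
#'
#' @slot species species label
#' @slot ph_grid ordered pH values
#' @slot lnZ log binding-polynomial value per pH
#' @slot nMeanSite matrix (pH x site) of mean protonations
#' @slot nMeanTotal total mean protonation per pH
#' @slot varTotal variance of the total protonation per pH
#' @slot covSiteTotal matrix (pH x site) of cov(n_i, n)
#' @slot thirdTotal third central moment of the total protonation per pH
#' @slot thirdSiteTotal matrix (pH x site) of the joint third cumulant
#'   of (n_i, n, n), whose row sums equal \code{thirdTotal}
#' @export
setClass("ExactEnsemble",
  representation(species = "character", ph_grid = "numeric", lnZ = "numeric",
                 nMeanSite = "matrix", nMeanTotal = "numeric",
                 varTotal = "numeric", covSiteTotal = "matrix",
                 thirdTotal = "numeric", thirdSiteTotal = "matrix"))

setValidity("ExactEnsemble", function(object) {
  msg <- character()
  np <- length(object@ph_grid)
  if (length(object@lnZ) != np || length(object@nMeanTotal) != np ||
      length(object@varTotal) != np || nrow(object@nMeanSite) != np)
    msg <- c(msg, "pH dimension mismatch")
  else {
    if (max(abs(rowSums(object@nMeanSite) - object@nMeanTotal)) > 1e-12)
      msg <- c(msg, "site means must sum to the total mean")
    if (any(object@varTotal < -1e-15)) msg <- c(msg, "varTotal must be >= 0")
    if (max(abs(rowSums(object@covSiteTotal) - object@varTotal)) > 1e-12)
      msg <- c(msg, "site-total covariances must sum to varTotal")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A time-ordered protonation microstate trace
#'
#' One replicate of recorded binary protonation vectors for a species at a
#' fixed pH, the synthetic analogue of a constant-pH simulation's
#' protonation record. Rows are recorded steps, columns titratable sites;
#' 1 means protonated.
#'
#' @slot species species label
#' @slot ph simulation pH
#' @slot replicate integer replicate id
#' @slot seed integer seed used to generate the trace
#' @slot recordInterval sweeps between recorded states
#' @slot states integer matrix (frames x sites) of 0/1 occupancies
#' @slot siteIds site labels (column order of \code{states})
#' @export
setClass("OccupancyTrace",
  representation(species = "character", ph = "numeric", replicate = "integer",
                 seed = "integer", recordInterval = "integer",
                 states = "matrix", siteIds = "character"))

setValidity("OccupancyTrace", function(object) {
  st <- object@states
  if (!all(st %in% c(0L, 1L))) return("states must be binary")
  if (ncol(st) != length(object@siteIds))
    return("states columns must match siteIds")
  TRUE
})

#' Replicate-resolved titration statistics
#'
#' Per-pH mean protonations (per site and total) with the per-replicate
#' values and within-replicate (co)variances needed for fluctuation-based
#' spline slopes and replicate bootstrap resampling.
#'
#' @slot species species label
#' @slot ph_grid ordered pH values
#' @slot siteIds site labels
#' @slot meanSite pooled mean protonation, matrix (pH x site)
#' @slot meanTotal pooled total mean protonation per pH
#' @slot varTotal pooled within-replicate variance of the total per pH
#' @slot covSiteTotal pooled within-replicate cov(n_i, n), matrix (pH x site)
#' @slot thirdTotal pooled within-replicate third central moment of the
#'   total protonation per pH (spline curvature input)
#' @slot thirdSiteTotal pooled joint third cumulant of (n_i, n, n)
#' @slot repMeanSite array (pH x site x replicate) of replicate means
#' @slot repMeanTotal matrix (pH x replicate) of replicate total means
#' @slot repVarTotal matrix (pH x replicate) of replicate total variances
#' @slot repCovSiteTotal array (pH x site x replicate)
#' @slot repThirdTotal matrix (pH x replicate)
#' @slot repThirdSiteTotal array (pH x site x replicate)
#' @slot nFramesUsed matrix (pH x replicate) of post-burn-in frame counts
#' @export
setClass("TitrationTable",
  representation(species = "character", ph_grid = "numeric",
                 siteIds = "character", meanSite = "matrix",
                 meanTotal = "numeric", varTotal = "numeric",
                 covSiteTotal = "matrix", thirdTotal = "numeric",
                 thirdSiteTotal = "matrix", repMeanSite = "array",
                 repMeanTotal = "matrix", repVarTotal = "matrix",
                 repCovSiteTotal = "array", repThirdTotal = "matrix",
                 repThirdSiteTotal = "array", nFramesUsed = "matrix"))

setValidity("TitrationTable", function(object) {
  msg <- character()
  if (any(object@meanSite < -1e-12) || any(object@meanSite > 1 + 1e-12))
    msg <- c(msg, "site means must lie in [0,1]")
  if (max(abs(rowSums(object@meanSite) - object@meanTotal)) > 1e-12)
    msg <- c(msg, "site means must sum to the total mean")
  if (any(object@varTotal < -1e-15)) msg <- c(msg, "varTotal must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Hill-equation fit of a titration curve
#'
#' Parameters of the empirical curve
#' \eqn{f(pH) = [1 + 10^{h(pH - pKa)}]^{-1}} fitted by
#' Marquardt-Levenberg nonlinear least squares.
#'
#' @slot label site or total-curve label
#' @slot pka fitted pKa
#' @slot h fitted Hill coefficient
#' @slot residual residual norm of the fit
#' @slot converged whether the fit converged with h in (0, 10]
#' @export
setClass("HillFit",
  representation(label = "character", pka = "numeric", h = "numeric",
                 residual = "numeric", converged = "logical"))

setValidity("HillFit", function(object) {
  if (isTRUE(object@converged) && !isTRUE(object@h > 0))
    "h must be positive when converged" else TRUE
})

#' Net charge versus pH and the isoionic point
#'
#' @slot ph_grid pH values
#' @slot charge mean net charge (elementary charges) per pH, computed as
#'   \eqn{\sum_{acids} (\bar n_i - 1) + \sum_{bases} \bar n_i}
#' @slot pI isoionic point (root of the spline-interpolated charge curve),
#'   or \code{NA} if the curve has no sign change on the grid
#' @export
setClass("ChargeCurve",
  representation(ph_grid = "numeric", charge = "numeric", pI = "numeric"))

#' Thermodynamically constrained Hermite spline
#'
#' Piecewise-polynomial interpolant that matches the node values, the
#' node slopes and (optionally) the node curvatures. For titration curves
#' all three come from grand-canonical fluctuation relations:
#' \eqn{d\bar n/dpH = -\ln 10\,\mathrm{var}(n)} (cov(n_i, n) per site)
#' and \eqn{d^2\bar n/dpH^2 = (\ln 10)^2 \mu_3(n)}, so the interpolant
#' honours the simulation's moment information exactly. Definite
#' integrals are evaluated per segment in closed form.
#'
#' @slot x strictly increasing node positions (pH)
#' @slot y node values
#' @slot m node slopes
#' @slot c node curvatures (NULL for the cubic form)
#' @export
setClass("ThermoSpline",
  representation(x = "numeric", y = "numeric", m = "numeric",
                 c = "numericOrNULL"))

setValidity("ThermoSpline", function(object) {
  if (length(object@x) < 2) return("need at least 2 nodes")
  if (any(diff(object@x) <= 0)) return("node positions must be strictly increasing")
  if (length(object@y) != length(object@x) || length(object@m) != length(object@x))
    return("x, y, m must have equal length")
  if (!is.null(object@c) && length(object@c) != length(object@x))
    return("curvatures must match the node count")
  TRUE
})

#' A pH-dependent reaction free-energy profile
#'
#' Relative reaction free energy \eqn{\Delta\Delta G(pH)} (kcal/mol) on an
#' evaluation grid, zero at the reference pH before anchoring, optionally
#' carrying a bootstrap uncertainty band and the underlying resample curves.
#'
#' @slot reaction reaction label
#' @slot ph_ref reference pH (profile is zero there before anchoring)
#' @slot ph_grid evaluation grid
#' @slot ddG relative free energy per grid pH (kcal/mol)
#' @slot method "spline" or "hill"
#' @slot anchored whether an absolute anchor has been applied
#' @slot anchor numeric(2): anchor pH and anchor value, or NULL
#' @slot band matrix with columns lower/upper, or NULL
#' @slot resamples matrix (resample x pH) of bootstrap curves, or NULL
#' @export
setClass("FreeEnergyProfile",
  representation(reaction = "character", ph_ref = "numeric",
                 ph_grid = "numeric", ddG = "numeric", method = "character",
                 anchored = "logical", anchor = "numericOrNULL",
                 band = "matrixOrNULL", resamples = "matrixOrNULL"))

setValidity("FreeEnergyProfile", function(object) {
  msg <- character()
  if (length(object@ddG) != length(object@ph_grid))
    msg <- c(msg, "ddG length must match grid")
  if (!is.null(object@band)) {
    if (nrow(object@band) != length(object@ph_grid))
      msg <- c(msg, "band rows must match grid")
    else if (any(object@band[, 1] > object@ddG + 1e-9) ||
             any(object@band[, 2] < object@ddG - 1e-9))
      msg <- c(msg, "band must contain the point estimate")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-site decomposition of a free-energy profile
#'
#' @slot siteIds product-site labels
#' @slot contributions matrix (pH x site) of per-site free-energy curves
#' @slot total the total \linkS4class{FreeEnergyProfile}
#' @slot siteMap the site correspondence used
#' @export
setClass("SiteContributionSet",
  representation(siteIds = "character", contributions = "matrix",
                 total = "FreeEnergyProfile", siteMap = "data.frame"))

setValidity("SiteContributionSet", function(object) {
  tot <- rowSums(object@contributions)
  if (max(abs(tot - object@total@ddG)) > 1e-9)
    "site contributions must sum to the total profile" else TRUE
})

#' Reaction stoichiometry and site correspondence
#'
#' Describes a reaction (products and reactants with positive integer
#' coefficients) plus a site map matching every product site to either a
#' reactant site or the free-ligand titration curve ("ligand"). The site
#' map drives per-site free-energy decomposition.
#'
#' @slot label reaction name
#' @slot products data.frame(species, coeff)
#' @slot reactants data.frame(species, coeff)
#' @slot siteMap data.frame(product_site, ref_species, ref_site); use
#'   ref_species = "ligand" for sites matched to the free-ligand curve
#' @export
setClass("ReactionSpec",
  representation(label = "character", products = "data.frame",
                 reactants = "data.frame", siteMap = "data.frame"))

setValidity("ReactionSpec", function(object) {
  co <- c(object@products$coeff, object@reactants$coeff)
  if (!all(co == round(co)) || any(co <= 0))
    return("stoichiometric coefficients must be positive integers")
  TRUE
})

#' The ligand-binding / dimerization thermodynamic cycle
#'
#' Four free-energy profiles on a shared pH grid: apo and holo
#' dimerization and ligand binding to monomer and dimer, with the per-pH
#' closure residual dim_holo - dim_apo - bind_D + 2 bind_M.
#'
#' @slot dim_apo,dim_holo,bind_M,bind_D \linkS4class{FreeEnergyProfile}s
#' @slot closure closure residual per grid pH (kcal/mol)
#' @export
setClass("CycleProfiles",
  representation(dim_apo = "FreeEnergyProfile", dim_holo = "FreeEnergyProfile",
                 bind_M = "FreeEnergyProfile", bind_D = "FreeEnergyProfile",
                 closure = "numeric"))

#' Coordinate ensemble for landscape and structural metrics
#'
#' @slot coords numeric array (frame x atom x 3), Angstrom
#' @slot atomNames atom names
#' @slot resNames residue names per atom
#' @slot meta per-frame metadata data.frame (e.g. pH, replicate)
#' @slot reference reference coordinates (atom x 3) or NULL
#' @export
setClass("CoordinateEnsemble",
  representation(coords = "array", atomNames = "character",
                 resNames = "character", meta = "data.frame",
                 reference = "matrixOrNULL"))

setValidity("CoordinateEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3) return("coords must be frame x atom x 3")
  if (d[2] != length(object@atomNames)) return("atomNames must match atom count")
  TRUE
})

#' KDE free-energy landscape on a principal-component plane
#'
#' Gaussian-kernel density on a regular 2-D grid, converted to free energy
#' as \eqn{E = -RT \ln(P / P_{max})} so the mode sits at zero, with
#' optional basin labels from connected-component analysis under an
#' energy cutoff.
#'
#' @slot pc1,pc2 grid cell-centre coordinates along each axis
#' @slot P density matrix (pc1 x pc2)
#' @slot E free energy matrix (kcal/mol); NA where P underflows to zero
#' @slot Pmax maximum density
#' @slot RT thermal energy used (kcal/mol)
#' @slot mesh grid spacing
#' @slot basins integer matrix of basin labels (0 = not in a basin) or NULL
#' @slot cutoffRT basin cutoff in RT units (NA until basins are computed)
#' @export
setClass("EnergyLandscape",
  representation(pc1 = "numeric", pc2 = "numeric", P = "matrix", E = "matrix",
                 Pmax = "numeric", RT = "numeric", mesh = "numeric",
                 basins = "matrixOrNULL", cutoffRT = "numeric"))

setValidity("EnergyLandscape", function(object) {
  if (!identical(dim(object@P), c(length(object@pc1), length(object@pc2))))
    return("P dimensions must match the grid")
  ok <- is.finite(object@E)
  if (any(ok) && abs(min(object@E[ok])) > 1e-9)
    return("minimum finite energy must be zero")
  TRUE
})

#' Free-ligand titration curve from an experimental pKa
#'
#' A Hill curve standing in for the titration of the free ligand, used on
#' the reactant side of binding reactions when the ligand itself is not
#' simulated (the usual case: its curve is derived from an experimental
#' pKa). Slopes follow analytically: \eqn{d\bar n/dpH = -\ln 10\, h\,
#' \bar n (1 - \bar n)}.
#'
#' @slot pka ligand pKa
#' @slot h Hill coefficient (1 for a simple acid)
#' @export
setClass("LigandCurve", representation(pka = "numeric", h = "numeric"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "SpeciesModel", function(object) {
  cat("SpeciesModel '", object@label, "': ", nrow(object@sites),
      " titratable site(s)\n", sep = "")
  if (nrow(object@sites)) {
    cat("  pKa range: ", paste(round(range(object@sites$pka_intr), 2),
                               collapse = " .. "), "\n", sep = "")
    nz <- sum(object@coupling[upper.tri(object@coupling)] != 0)
    cat("  nonzero couplings: ", nz, "\n", sep = "")
  }
})

setMethod("show", "TitrationTable", function(object) {
  cat("TitrationTable '", object@species, "': ", length(object@siteIds),
      " site(s) x ", length(object@ph_grid), " pH value(s), ",
      dim(object@repMeanSite)[3], " replicate(s)\n", sep = "")
  cat("  pH ", paste(format(object@ph_grid), collapse = " "), "\n", sep = "")
  cat("  total protonation ", paste(format(round(object@meanTotal, 3)),
                                    collapse = " "), "\n", sep = "")
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat("FreeEnergyProfile '", object@reaction, "' (", object@method,
      if (object@anchored) ", anchored" else paste0(", relative to pH ",
                                                    object@ph_ref),
      ")\n", sep = "")
  cat("  pH ", paste(format(object@ph_grid), collapse = " "), "\n", sep = "")
  cat("  ddG ", paste(format(round(object@ddG, 3)), collapse = " "),
      " kcal/mol\n", sep = "")
})

setMethod("show", "EnergyLandscape", function(object) {
  cat("EnergyLandscape: ", length(object@pc1), " x ", length(object@pc2),
      " grid (mesh ", object@mesh, ")\n", sep = "")
  if (!is.null(object@basins))
    cat("  basins: ", max(object@basins), " at cutoff ", object@cutoffRT,
        " RT\n", sep = "")
})

setMethod("show", "ExactEnsemble", function(object) {
  cat("ExactEnsemble '", object@species, "': ", ncol(object@nMeanSite),
      " site(s) x ", length(object@ph_grid), " pH value(s)\n", sep = "")
})
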