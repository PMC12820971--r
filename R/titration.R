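# per-replicate protonation moments of one trace segment
.traceMoments <- function(states) {
  n <- nrow(states)
  ms <- colMeans(states)
  s <- rowSums(states)
  mt <- mean(s)
  d <- s - mt
  list(meanSite = ms, meanTotal = mt,
       varTotal = mean(d^2),
       covSiteTotal = drop(crossprod(states, d)) / n,
       thirdTotal = mean(d^3),
       thirdSiteTotal = drop(crossprod(states, d^2)) / n - ms * mean(d^2),
       n = n)
}

#' Average occupancy traces into a replicate-resolved titration table
#'
#' Discards the equilibration segment of every trace, computes per-site
#' and total mean protonations, the within-replicate variance of the total
#' and the site-total covariances per replicate, and pools them as the
#' mean over replicates (replicate-level means first, then pooling, which
#' keeps replicate bootstrap resampling well defined).
#'
#' @param traces list of \linkS4class{OccupancyTrace}s for one species,
#'   covering one or more pH values, with the same replicate count per pH
#' @param burn_in_fraction fraction of each trace discarded as
#'   equilibration (default 0.15)
#' @return a \linkS4class{TitrationTable}
#' @export
averageProtonation <- function(traces, burn_in_fraction = 0.15) {
  stopifnot(length(traces) >= 1, burn_in_fraction >= 0, burn_in_fraction < 1)
  spl <- unique(vapply(traces, function(tr) tr@species, character(1)))
  if (length(spl) != 1) stop("traces must belong to a single species")
  sids <- traces[[1]]@siteIds
  phs <- sort(unique(vapply(traces, function(tr) tr@ph, numeric(1))))
  np <- length(phs); q <- length(sids)
  byPh <- lapply(phs, function(p)
    Filter(function(tr) tr@ph == p, traces))
  nrep <- unique(vapply(byPh, length, integer(1)))
  if (length(nrep) != 1)
    stop("replicate count must be the same at every pH")
  repMeanSite <- array(0, c(np, q, nrep))
  repCov <- array(0, c(np, q, nrep))
  repThirdSite <- array(0, c(np, q, nrep))
  repMeanTotal <- matrix(0, np, nrep)
  repVarTotal <- matrix(0, np, nrep)
  repThirdTotal <- matrix(0, np, nrep)
  nFrames <- matrix(0L, np, nrep)
  for (k in seq_len(np)) {
    trs <- byPh[[k]][order(vapply(byPh[[k]], function(tr) tr@replicate,
                                  integer(1)))]
    for (r in seq_len(nrep)) {
      st <- trs[[r]]@states
      nb <- floor(burn_in_fraction * nrow(st))
      if (nb >= nrow(st)) stop("empty post-burn-in segment")
      mo <- .traceMoments(st[(nb + 1):nrow(st), , drop = FALSE])
      repMeanSite[k, , r] <- mo$meanSite
      repCov[k, , r] <- mo$covSiteTotal
      repThirdSite[k, , r] <- mo$thirdSiteTotal
      repMeanTotal[k, r] <- mo$meanTotal
      repVarTotal[k, r] <- mo$varTotal
      repThirdTotal[k, r] <- mo$thirdTotal
      nFrames[k, r] <- mo$n
    }
  }
  meanSite <- apply(repMeanSite, c(1, 2), mean)
  covSiteTotal <- apply(repCov, c(1, 2), mean)
  thirdSiteTotal <- apply(repThirdSite, c(1, 2), mean)
  dim(meanSite) <- dim(covSiteTotal) <- dim(thirdSiteTotal) <- c(np, q)
  colnames(meanSite) <- colnames(covSiteTotal) <-
    colnames(thirdSiteTotal) <- sids
  new("TitrationTable", species = spl, ph_grid = phs, siteIds = sids,
      meanSite = meanSite, meanTotal = rowSums(meanSite),
      varTotal = rowMeans(repVarTotal), covSiteTotal = covSiteTotal,
      thirdTotal = rowMeans(repThirdTotal), thirdSiteTotal = thirdSiteTotal,
      repMeanSite = repMeanSite, repMeanTotal = repMeanTotal,
      repVarTotal = repVarTotal, repCovSiteTotal = repCov,
      repThirdTotal = repThirdTotal, repThirdSiteTotal = repThirdSite,
      nFramesUsed = nFrames)
}

#' Coerce an exact ensemble to a titration table
#'
#' Wraps the exact Boltzmann statistics of an \linkS4class{ExactEnsemble}
#' as a single-replicate \linkS4class{TitrationTable} so enumeration
#' output can be fed to the same linkage machinery as sampled data.
#'
#' @param ens an \linkS4class{ExactEnsemble}
#' @return a \linkS4class{TitrationTable}
#' @export
asTitrationTable <- function(ens) {
  stopifnot(is(ens, "ExactEnsemble"))
  np <- length(ens@ph_grid); q <- ncol(ens@nMeanSite)
  sid <- colnames(ens@nMeanSite)
  if (is.null(sid)) sid <- character(q)
  new("TitrationTable", species = ens@species, ph_grid = ens@ph_grid,
      siteIds = sid, meanSite = ens@nMeanSite,
      meanTotal = ens@nMeanTotal, varTotal = ens@varTotal,
      covSiteTotal = ens@covSiteTotal, thirdTotal = ens@thirdTotal,
      thirdSiteTotal = ens@thirdSiteTotal,
      repMeanSite = array(ens@nMeanSite, c(np, q, 1)),
      repMeanTotal = matrix(ens@nMeanTotal, np, 1),
      repVarTotal = matrix(ens@varTotal, np, 1),
      repCovSiteTotal = array(ens@covSiteTotal, c(np, q, 1)),
      repThirdTotal = matrix(ens@thirdTotal, np, 1),
      repThirdSiteTotal = array(ens@thirdSiteTotal, c(np, q, 1)),
      nFramesUsed = matrix(NA_integer_, np, 1))
}

#' Fluctuation-derived slopes of titration curves
#'
#' Grand-canonical identity: the slope of the total protonation curve is
#' \eqn{-\ln 10\,\mathrm{var}(n)} (always non-positive) and the slope of
#' site i's curve is \eqn{-\ln 10\,\mathrm{cov}(n_i, n)} (any sign). Site
#' slopes sum to the total slope because the covariances sum to the
#' variance.
#'
#' @param table a \linkS4class{TitrationTable} or
#'   \linkS4class{ExactEnsemble}
#' @return list with \code{total} (per pH) and \code{site} (pH x site)
#' @export
fluctuationSlopes <- function(table) {
  if (is(table, "ExactEnsemble"))
    return(list(total = -LN10 * table@varTotal,
                site = -LN10 * table@covSiteTotal))
  stopifnot(is(table, "TitrationTable"))
  list(total = -LN10 * table@varTotal, site = -LN10 * table@covSiteTotal)
}

#' Fit a Hill curve to a titration curve
#'
#' Fits \eqn{f(pH) = [1 + 10^{h(pH - pKa)}]^{-1}} by Marquardt-Levenberg
#' nonlinear least squares. Initial guesses default to the pH of the point
#' closest to half-protonation and h = 1; h is constrained to (0, 10].
#' Degenerate (flat) data yield \code{converged = FALSE} rather than an
#' error.
#'
#' @param ph pH values (at least 3 distinct)
#' @param protonation mean protonations
#' @param label curve label stored in the fit
#' @param start optional list with elements \code{pka} and \code{h}
#' @return a \linkS4class{HillFit}
#' @export
hillFit <- function(ph, protonation, label = "total", start = NULL) {
  if (length(unique(ph)) < 3) stop("need at least 3 distinct pH points")
  bad <- new("HillFit", label = label, pka = NA_real_, h = NA_real_,
             residual = NA_real_, converged = FALSE)
  if (sd(protonation) == 0) return(bad)
  if (is.null(start))
    start <- list(pka = ph[which.min(abs(protonation - 0.5))], h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(protonation ~ 1 / (1 + 10^(h * (ph - pka))),
                      data = data.frame(ph = ph, protonation = protonation),
                      start = start,
                      lower = c(pka = -Inf, h = 1e-6),
                      upper = c(pka = Inf, h = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  cf <- coef(fit)
  conv <- isTRUE(fit$convInfo$isConv) && cf[["h"]] > 1e-6 &&
    cf[["h"]] <= 10 && all(is.finite(cf))
  new("HillFit", label = label, pka = unname(cf[["pka"]]),
      h = unname(cf[["h"]]), residual = sqrt(sum(resid(fit)^2)),
      converged = conv)
}

#' Hill fits for every site of a titration table
#'
#' @param table a \linkS4class{TitrationTable} or
#'   \linkS4class{ExactEnsemble}
#' @return named list of \linkS4class{HillFit}s, one per site
#' @export
fitHillSites <- function(table) {
  if (is(table, "ExactEnsemble")) table <- asTitrationTable(table)
  fits <- lapply(seq_along(table@siteIds), function(i)
    hillFit(table@ph_grid, table@meanSite[, i], label = table@siteIds[i]))
  setNames(fits, table@siteIds)
}

#' Charge curve and isoionic point
#'
#' Mean net charge per pH, \eqn{\sum_{acids} (\bar n_i - 1) +
#' \sum_{bases} \bar n_i}, interpolated with the thermodynamic spline
#' (its slope is the total fluctuation slope, since the class constants
#' drop out of the derivative) and searched for a root by bisection. The
#' isoionic point is absent (NA) when the charge curve has no sign change
#' on the grid.
#'
#' @param table a \linkS4class{TitrationTable} or
#'   \linkS4class{ExactEnsemble}
#' @param charge_class "acid"/"base" per site, or a
#'   \linkS4class{SpeciesModel} to take them from
#' @return a \linkS4class{ChargeCurve}
#' @export
isoionicPoint <- function(table, charge_class) {
  if (is(charge_class, "SpeciesModel"))
    charge_class <- charge_class@sites$charge_class
  if (is(table, "ExactEnsemble")) table <- asTitrationTable(table)
  stopifnot(length(charge_class) == length(table@siteIds),
            all(charge_class %in% c("acid", "base")))
  offs <- ifelse(charge_class == "acid", -1, 0)
  charge <- drop(table@meanSite %*% rep(1, length(offs))) + sum(offs)
  sp <- buildThermoSpline(table@ph_grid, charge, -LN10 * table@varTotal,
                          LN10^2 * table@thirdTotal)
  pI <- NA_real_
  iz <- which(abs(charge) < 1e-14)
  if (length(iz)) {
    pI <- table@ph_grid[iz[1]]
  } else {
    sgn <- sign(charge)
    k <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(k)) {
      k <- k[1]
      pI <- uniroot(function(p) splineEval(sp, p),
                    lower = table@ph_grid[k], upper = table@ph_grid[k + 1],
                    tol = 1e-12)$root
    }
  }
  new("ChargeCurve", ph_grid = table@ph_grid, charge = charge, pI = pI)
}

#' Pairwise protonation correlations
#'
#' Pearson correlation between the protonation series of site pairs,
#' computed on pooled post-burn-in frames per (species, pH), with a
#' replicate-bootstrap standard error. Pairs are reported when the
#' absolute correlation exceeds the threshold (default 0.2); sites with
#' zero variance are dropped rather than reported as NaN.
#'
#' @param traces list of \linkS4class{OccupancyTrace}s (one species)
#' @param threshold reporting threshold on |r|
#' @param burn_in_fraction equilibration fraction to discard
#' @param n_boot bootstrap resamples for the standard error
#' @param seed bootstrap seed
#' @return data.frame(species, ph, site_i, site_j, r, se)
#' @export
protonationCorrelations <- function(traces, threshold = 0.2,
                                    burn_in_fraction = 0.15, n_boot = 200,
                                    seed = 1) {
  phs <- sort(unique(vapply(traces, function(tr) tr@ph, numeric(1))))
  sids <- traces[[1]]@siteIds
  out <- list()
  set.seed(seed)
  for (p in phs) {
    trs <- Filter(function(tr) tr@ph == p, traces)
    segs <- lapply(trs, function(tr) {
      nb <- floor(burn_in_fraction * nrow(tr@states))
      tr@states[(nb + 1):nrow(tr@states), , drop = FALSE]
    })
    pooled <- do.call(rbind, segs)
    if (nrow(pooled) < 2) stop("need at least 2 post-burn-in frames")
    v <- apply(pooled, 2, var)
    keep <- which(v > 0)
    if (length(keep) < 2) next
    cm <- cor(pooled[, keep, drop = FALSE])
    R <- length(segs)
    boot <- if (R >= 2) {
      replicate(n_boot, {
        bo <- do.call(rbind, segs[sample.int(R, R, replace = TRUE)])
        vv <- apply(bo, 2, var)
        cb <- matrix(NA_real_, length(keep), length(keep))
        ok <- vv[keep] > 0
        if (sum(ok) >= 2)
          cb[ok, ok] <- cor(bo[, keep[ok], drop = FALSE])
        cb
      })
    } else NULL
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      if (a >= b) next
      r <- cm[a, b]
      if (abs(r) <= threshold) next
      se <- if (!is.null(boot)) sd(boot[a, b, ], na.rm = TRUE) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        species = trs[[1]]@species, ph = p,
        site_i = sids[keep[a]], site_j = sids[keep[b]],
        r = r, se = se, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(), ph = numeric(),
                      site_i = character(), site_j = character(),
                      r = numeric(), se = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Model-compound pKa calibration by pH shift
#'
#' Calibrates a titratable model compound against an experimental pKa:
#' the simulated titration curve's apparent pKa is obtained from a Hill
#' fit (h free), the pH shift needed to match the experimental curve is
#' \code{experimental_pka - apparent_pka}, and that shift is added to the
#' initial model pKa. The procedure is translation-equivariant: shifting
#' the input curve by delta in pH shifts the result by delta.
#'
#' @param ph,protonation the simulated titration curve points
#' @param initial_model_pka pKa the model compound was simulated with
#' @param experimental_pka target experimental pKa
#' @return list with \code{calibrated_pka}, \code{apparent_pka},
#'   \code{shift} and the underlying \linkS4class{HillFit}
#' @export
calibrateModelPka <- function(ph, protonation, initial_model_pka,
                              experimental_pka) {
  fit <- hillFit(ph, protonation, label = "model-compound")
  if (!fit@converged)
    stop("Hill fit of the simulated titration curve did not converge")
  shift <- experimental_pka - fit@pka
  list(calibrated_pka = initial_model_pka + shift,
       apparent_pka = fit@pka, shift = shift, fit = fit)
}

#' Proton-exchange transition rate of a site
#'
#' Number of adjacent-frame protonation changes divided by (frames - 1):
#' a per-recorded-frame exchange rate used to flag slow proton
#' exchangers.
#'
#' @param trace an \linkS4class{OccupancyTrace}
#' @param site site id or column index
#' @return list with \code{transitions} and \code{rate}
#' @export
transitionCount <- function(trace, site) {
  st <- trace@states
  if (nrow(st) < 2) stop("transition rate undefined for a single-frame trace")
  if (is.character(site)) site <- match(site, trace@siteIds)
  if (is.na(site) || site < 1 || site > ncol(st)) stop("unknown site")
  tr <- sum(abs(diff(st[, site])))
  list(transitions = tr, rate = tr / (nrow(st) - 1))
}
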