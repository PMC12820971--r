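#' Complete the binding/dimerization thermodynamic cycle
#'
#' The holo dimerization free energy follows from the other three legs of
#' the cycle:
#' \deqn{\Delta G_{dim}^{holo} = \Delta G_{dim}^{apo} + \Delta G_{bind}^D
#'   - 2\,\Delta G_{bind}^M}
#' Works on scalars (e.g. experimental anchors at one pH) or pointwise on
#' \linkS4class{FreeEnergyProfile}s sharing a pH grid. Uncertainty is
#' combined resample-wise when all three profiles carry bootstrap
#' resamples of equal count (preserving correlations), otherwise by
#' quadrature of the band half-widths.
#'
#' @param dim_apo apo dimerization free energy (scalar or profile)
#' @param bind_M ligand binding to the monomer
#' @param bind_D ligand binding (two ligands) to the dimer
#' @return the holo dimerization free energy, same type as the inputs
#' @examples
#' completeCycle(-7.16, bind_M = -8.3, bind_D = -14.5)  # -5.06 kcal/mol
#' @export
setGeneric("completeCycle", function(dim_apo, bind_M, bind_D)
  standardGeneric("completeCycle"))

#' @rdname completeCycle
setMethod("completeCycle", signature(dim_apo = "numeric"),
  function(dim_apo, bind_M, bind_D) dim_apo + bind_D - 2 * bind_M)

#' @rdname completeCycle
setMethod("completeCycle", signature(dim_apo = "FreeEnergyProfile"),
  function(dim_apo, bind_M, bind_D) {
    g <- dim_apo@ph_grid
    if (max(abs(bind_M@ph_grid - g)) > 1e-9 ||
        max(abs(bind_D@ph_grid - g)) > 1e-9)
      stop("cycle profiles must share a pH grid")
    ddG <- dim_apo@ddG + bind_D@ddG - 2 * bind_M@ddG
    rs <- list(dim_apo@resamples, bind_D@resamples, bind_M@resamples)
    band <- NULL; resamples <- NULL
    if (!any(vapply(rs, is.null, logical(1))) &&
        length(unique(vapply(rs, nrow, integer(1)))) == 1) {
      # matched resample indices keep cross-profile correlations intact
      resamples <- rs[[1]] + rs[[2]] - 2 * rs[[3]]
      band <- t(apply(resamples, 2, quantile, probs = c(0.16, 0.84),
                      names = FALSE))
      band[, 1] <- pmin(band[, 1], ddG)
      band[, 2] <- pmax(band[, 2], ddG)
    } else if (!is.null(dim_apo@band) && !is.null(bind_M@band) &&
               !is.null(bind_D@band)) {
      hw <- function(p) (p@band[, 2] - p@band[, 1]) / 2
      h <- sqrt(hw(dim_apo)^2 + hw(bind_D)^2 + 4 * hw(bind_M)^2)
      band <- cbind(ddG - h, ddG + h)
    }
    if (!is.null(band)) colnames(band) <- c("lower", "upper")
    new("FreeEnergyProfile", reaction = "dim_holo", ph_ref = dim_apo@ph_ref,
        ph_grid = g, ddG = ddG, method = dim_apo@method,
        anchored = dim_apo@anchored && bind_M@anchored && bind_D@anchored,
        anchor = NULL, band = band, resamples = resamples)
  })

#' Assemble the four cycle profiles
#'
#' @param dim_apo,dim_holo,bind_M,bind_D \linkS4class{FreeEnergyProfile}s
#'   on a shared pH grid
#' @return a \linkS4class{CycleProfiles} with the per-pH closure residual
#'   \code{dim_holo - dim_apo - bind_D + 2 bind_M}
#' @export
cycleProfiles <- function(dim_apo, dim_holo, bind_M, bind_D) {
  g <- dim_apo@ph_grid
  for (p in list(dim_holo, bind_M, bind_D))
    if (max(abs(p@ph_grid - g)) > 1e-9)
      stop("cycle profiles must share a pH grid")
  closure <- dim_holo@ddG - dim_apo@ddG - bind_D@ddG + 2 * bind_M@ddG
  new("CycleProfiles", dim_apo = dim_apo, dim_holo = dim_holo,
      bind_M = bind_M, bind_D = bind_D, closure = closure)
}

#' pH-dependent allosteric coupling between binding and dimerization
#'
#' The coupling free energy
#' \deqn{\Delta G_{coupl} = \Delta G_{dim}^{holo} - \Delta G_{dim}^{apo}
#'   = \Delta G_{bind}^D - 2\,\Delta G_{bind}^M}
#' measures how ligand binding and dimerization affect each other; it is
#' also the free energy of moving two bound ligands from two monomers
#' onto one dimer. Both expressions are evaluated and must agree within
#' \code{tol}; a larger discrepancy means the four profiles do not form a
#' consistent cycle. Positive coupling is antagonistic (binding disfavors
#' dimerization), negative agonistic.
#'
#' @param cycle a \linkS4class{CycleProfiles}
#' @param tol identity tolerance between the two expressions
#' @return data.frame(ph, coupling, lower, upper, classification)
#' @export
allostericCoupling <- function(cycle, tol = 1e-9) {
  d1 <- cycle@dim_holo@ddG - cycle@dim_apo@ddG
  d2 <- cycle@bind_D@ddG - 2 * cycle@bind_M@ddG
  if (max(abs(d1 - d2)) > tol)
    stop("inconsistent cycle: the two coupling expressions differ by up to ",
         format(max(abs(d1 - d2))))
  lower <- upper <- rep(NA_real_, length(d1))
  rs1 <- cycle@dim_holo@resamples; rs0 <- cycle@dim_apo@resamples
  if (!is.null(rs1) && !is.null(rs0) && nrow(rs1) == nrow(rs0)) {
    rc <- rs1 - rs0
    qs <- apply(rc, 2, quantile, probs = c(0.16, 0.84), names = FALSE)
    lower <- pmin(qs[1, ], d1); upper <- pmax(qs[2, ], d1)
  } else if (!is.null(cycle@dim_holo@band) && !is.null(cycle@dim_apo@band)) {
    hw1 <- (cycle@dim_holo@band[, 2] - cycle@dim_holo@band[, 1]) / 2
    hw0 <- (cycle@dim_apo@band[, 2] - cycle@dim_apo@band[, 1]) / 2
    h <- sqrt(hw1^2 + hw0^2)
    lower <- d1 - h; upper <- d1 + h
  }
  data.frame(ph = cycle@dim_apo@ph_grid, coupling = d1,
             lower = lower, upper = upper,
             classification = ifelse(d1 > 0, "antagonistic",
                                     ifelse(d1 < 0, "agonistic", "neutral")),
             stringsAsFactors = FALSE)
}
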