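#' Construct a coordinate ensemble
#'
#' @param coords numeric array (frame x atom x 3), Angstrom
#' @param atomNames atom names (default A1, A2, ...)
#' @param resNames residue name per atom
#' @param meta per-frame metadata data.frame
#' @param reference optional reference coordinates (atom x 3)
#' @return a \linkS4class{CoordinateEnsemble}
#' @export
coordinateEnsemble <- function(coords, atomNames = NULL, resNames = NULL,
                               meta = NULL, reference = NULL) {
  d <- dim(coords)
  if (is.null(atomNames)) atomNames <- paste0("A", seq_len(d[2]))
  if (is.null(resNames)) resNames <- rep("UNK", d[2])
  if (is.null(meta)) meta <- data.frame(frame = seq_len(d[1]))
  new("CoordinateEnsemble", coords = coords, atomNames = atomNames,
      resNames = resNames, meta = meta, reference = reference)
}

# Kabsch: optimal proper rotation + translation of P onto Q
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (svd(P0)$d[2] < 1e-8 * max(svd(P0)$d[1], 1))
    stop("degenerate (collinear) fit selection")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, cp = cp, cq = cq)
}

#' Rigid-body superposition of an ensemble onto a reference
#'
#' Least-squares (Kabsch) fit of each frame's fit selection onto the
#' reference structure — e.g. backbone atoms onto a crystallographic
#' structure — with the resulting proper rotation and translation applied
#' to all atoms of the frame. Reflections are excluded by the determinant
#' guard, so mirror-image frames keep a nonzero residual.
#'
#' @param ensemble a \linkS4class{CoordinateEnsemble}
#' @param reference reference coordinates (atom x 3 over the full atom
#'   set); defaults to the ensemble's stored reference or its first frame
#' @param fit_selection atom indices used for the fit (default: all);
#'   at least 3 non-collinear atoms
#' @return the fitted \linkS4class{CoordinateEnsemble} (reference stored)
#' @export
superpose <- function(ensemble, reference = NULL, fit_selection = NULL) {
  co <- ensemble@coords
  d <- dim(co)
  if (is.null(reference))
    reference <- if (!is.null(ensemble@reference)) ensemble@reference
                 else co[1, , ]
  if (is.null(fit_selection)) fit_selection <- seq_len(d[2])
  if (length(fit_selection) < 3)
    stop("fit selection needs at least 3 atoms")
  out <- co
  refSel <- reference[fit_selection, , drop = FALSE]
  for (f in seq_len(d[1])) {
    fr <- co[f, , , drop = TRUE]
    dim(fr) <- c(d[2], 3)
    tr <- .kabsch(fr[fit_selection, , drop = FALSE], refSel)
    out[f, , ] <- sweep(fr, 2, tr$cp) %*% t(tr$R) +
      matrix(tr$cq, d[2], 3, byrow = TRUE)
  }
  ensemble@coords <- out
  ensemble@reference <- reference
  ensemble
}

#' Root-mean-square deviation between two frames
#'
#' @param a,b coordinate matrices (atom x 3)
#' @return RMSD in the coordinates' units
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' PCA projection of a fitted coordinate ensemble
#'
#' Centers the flattened per-frame coordinates and projects them onto the
#' top principal components. Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making the
#' projection deterministic.
#'
#' @param x a \linkS4class{CoordinateEnsemble} or a frames-by-coordinates
#'   matrix
#' @param n_components number of components to keep
#' @return list with \code{scores} (frames x components),
#'   \code{variance_explained} (fractions, all components) and
#'   \code{loadings}
#' @export
pcaProject <- function(x, n_components = 2) {
  mat <- if (is(x, "CoordinateEnsemble")) {
    d <- dim(x@coords)
    matrix(x@coords, d[1], d[2] * 3)
  } else as.matrix(x)
  if (nrow(mat) < 2) stop("need at least 2 frames for PCA")
  pr <- prcomp(mat, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(nc), drop = FALSE]
  sc <- pr$x[, seq_len(nc), drop = FALSE]
  for (k in seq_len(nc)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) { rot[, k] <- -rot[, k]; sc[, k] <- -sc[, k] }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = sc, variance_explained = vf, loadings = rot)
}

#' KDE free-energy surface on a 2-D projection
#'
#' Gaussian kernel density on a regular mesh with the per-dimension
#' bandwidth \eqn{\sigma_d (4/(3N))^{1/5}} (\eqn{\sigma_d} the coordinate
#' standard deviation of the N points), converted to free energy as
#' \eqn{E = -RT \ln(P/P_{max})}, so the density mode sits at E = 0. The
#' grid pads the data range by \code{pad} bandwidths, which keeps the
#' cell-sum of P times cell area within ~2% of 1.
#'
#' @param scores two-column matrix of projected points
#' @param mesh grid spacing (same units as the scores; default 0.5)
#' @param temperature Kelvin
#' @param pad grid padding in bandwidths
#' @return an \linkS4class{EnergyLandscape}
#' @export
kdeEnergySurface <- function(scores, mesh = 0.5, temperature = 300,
                             pad = 4) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) >= 2)
  N <- nrow(scores)
  bw <- apply(scores, 2, sd) * (4 / (3 * N))^(1 / 5)
  if (any(bw == 0)) stop("zero-variance dimension")
  ax <- lapply(1:2, function(d)
    seq(min(scores[, d]) - pad * bw[d], max(scores[, d]) + pad * bw[d] + mesh,
        by = mesh))
  Kx <- outer(ax[[1]], scores[, 1],
              function(g, p) dnorm(g, p, bw[1]))
  Ky <- outer(ax[[2]], scores[, 2],
              function(g, p) dnorm(g, p, bw[2]))
  P <- (Kx %*% t(Ky)) / N
  Pmax <- max(P)
  RT <- thermalRT(temperature)
  E <- matrix(NA_real_, nrow(P), ncol(P))
  pos <- P > 0
  E[pos] <- -RT * log(P[pos] / Pmax)
  new("EnergyLandscape", pc1 = ax[[1]], pc2 = ax[[2]], P = P, E = E,
      Pmax = Pmax, RT = RT, mesh = mesh, basins = NULL,
      cutoffRT = NA_real_)
}

#' Detect free-energy basins under an energy cutoff
#'
#' Admissible cells are those within \code{cutoff_RT} times RT of the
#' global minimum (which is 0 by construction); basins are the
#' 8-neighbour connected components of the admissible set, labelled in
#' order of their lowest linear cell index so labels are deterministic.
#'
#' @param landscape an \linkS4class{EnergyLandscape}
#' @param cutoff_RT energy cutoff in RT units (default 2); \code{Inf}
#'   admits every finite-energy cell
#' @return the landscape with the \code{basins} label matrix filled in
#' @seealso \code{\link{basinSummary}}
#' @export
findBasins <- function(landscape, cutoff_RT = 2) {
  E <- landscape@E
  thr <- cutoff_RT * landscape@RT
  adm <- which(is.finite(E) & E <= thr + 1e-12)
  lab <- matrix(0L, nrow(E), ncol(E))
  if (length(adm)) {
    nr <- nrow(E)
    pos <- integer(length(E))
    pos[adm] <- seq_along(adm)
    edges <- integer(0)
    rc <- cbind((adm - 1L) %% nr + 1L, (adm - 1L) %/% nr + 1L)
    for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
      r2 <- rc[, 1] + sh[1]; c2 <- rc[, 2] + sh[2]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(E)
      nb <- (c2[ok] - 1L) * nr + r2[ok]
      okn <- pos[nb] > 0L
      if (any(okn))
        edges <- c(edges, rbind(pos[adm[ok][okn]], pos[nb[okn]]))
    }
    g <- igraph::make_empty_graph(n = length(adm), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    # relabel components by the lowest linear cell index they contain
    first <- vapply(seq_len(max(comp)), function(k) min(adm[comp == k]),
                    numeric(1))
    relab <- match(seq_len(max(comp)), order(first))
    lab[adm] <- relab[comp]
  }
  landscape@basins <- lab
  landscape@cutoffRT <- cutoff_RT
  landscape
}

#' Summarise detected basins
#'
#' @param landscape an \linkS4class{EnergyLandscape} after
#'   \code{\link{findBasins}}; basin population shares are fractions of
#'   the admissible-set population
#' @return data.frame(basin, n_cells, area, min_E, pc1_min, pc2_min,
#'   population, share)
#' @export
basinSummary <- function(landscape) {
  if (is.null(landscape@basins)) stop("run findBasins() first")
  lab <- landscape@basins
  nb <- max(lab)
  cellA <- landscape@mesh^2
  totP <- sum(landscape@P[lab > 0]) * cellA
  out <- lapply(seq_len(nb), function(k) {
    cells <- which(lab == k)
    Emin <- min(landscape@E[cells])
    at <- cells[which.min(landscape@E[cells])]
    r <- (at - 1L) %% nrow(lab) + 1L
    cc <- (at - 1L) %/% nrow(lab) + 1L
    pop <- sum(landscape@P[cells]) * cellA
    data.frame(basin = k, n_cells = length(cells),
               area = length(cells) * cellA, min_E = Emin,
               pc1_min = landscape@pc1[r], pc2_min = landscape@pc2[cc],
               population = pop, share = pop / totP)
  })
  do.call(rbind, out)
}

#' Sub-basin detection inside one basin
#'
#' Re-runs basin detection at a lower cutoff restricted to the cells of a
#' previously detected basin (energies re-referenced to that basin's
#' minimum).
#'
#' @param landscape an \linkS4class{EnergyLandscape} after
#'   \code{\link{findBasins}}
#' @param basin basin label to refine
#' @param cutoff_RT sub-basin cutoff in RT units
#' @return an \linkS4class{EnergyLandscape} restricted to the basin mask
#' @export
findSubBasins <- function(landscape, basin, cutoff_RT) {
  if (is.null(landscape@basins)) stop("run findBasins() first")
  mask <- landscape@basins == basin
  E <- landscape@E
  E[!mask] <- NA_real_
  E <- E - min(E[mask])
  sub <- landscape
  sub@E <- E
  sub@basins <- NULL
  sub@cutoffRT <- NA_real_
  findBasins(sub, cutoff_RT)
}

#' Ion concentration map from frame-wise ion positions
#'
#' Per-frame triangular-kernel density of ion positions on a regular 3-D
#' grid (separable kernel, bandwidth in Angstrom), averaged over frames
#' and converted to concentration via 1 M = 6.022e-4 ions per cubic
#' Angstrom, i.e. mM = density[A^-3] x 1.6606e6.
#'
#' @param positions list of per-frame ion coordinate matrices (n x 3),
#'   or a single matrix (one frame); frames must already be fitted to a
#'   common reference
#' @param mesh grid spacing in Angstrom (default 1)
#' @param bandwidth triangular kernel bandwidth in Angstrom (default 2)
#' @param range optional list of c(lo, hi) per axis; default: data range
#'   padded by the bandwidth
#' @return list with axes \code{x}, \code{y}, \code{z} and \code{conc}
#'   (3-D array, mM)
#' @export
ionConcentrationMap <- function(positions, mesh = 1, bandwidth = 2,
                                range = NULL) {
  if (is.matrix(positions)) positions <- list(positions)
  allp <- do.call(rbind, positions)
  if (is.null(range)) {
    if (is.null(allp) || nrow(allp) == 0) {
      if (is.null(range)) range <- rep(list(c(0, 0)), 3)
    } else {
      range <- lapply(1:3, function(d)
        c(floor(min(allp[, d])) - bandwidth,
          ceiling(max(allp[, d])) + bandwidth))
    }
  }
  ax <- lapply(range, function(r) seq(r[1], r[2], by = mesh))
  nx <- lengths(ax)
  dens <- array(0, nx)
  tri <- function(u) pmax(0, 1 - abs(u) / bandwidth) / bandwidth
  nF <- length(positions)
  for (fr in positions) {
    if (is.null(fr) || nrow(fr) == 0) next
    for (i in seq_len(nrow(fr))) {
      kx <- tri(ax[[1]] - fr[i, 1])
      ky <- tri(ax[[2]] - fr[i, 2])
      kz <- tri(ax[[3]] - fr[i, 3])
      ix <- which(kx > 0); iy <- which(ky > 0); iz <- which(kz > 0)
      if (!length(ix) || !length(iy) || !length(iz)) next
      patch <- outer(outer(kx[ix], ky[iy]), kz[iz])
      dens[ix, iy, iz] <- dens[ix, iy, iz] + patch
    }
  }
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]],
       conc = dens / nF * 1.6606e6, mesh = mesh, bandwidth = bandwidth)
}

#' Cells at or above an iso-concentration level
#'
#' @param map output of \code{\link{ionConcentrationMap}}
#' @param level concentration level in mM (e.g. 150)
#' @return data.frame(x, y, z, conc) of cells with conc >= level
#' @export
isoConcentrationCells <- function(map, level) {
  idx <- which(map$conc >= level, arr.ind = TRUE)
  data.frame(x = map$x[idx[, 1]], y = map$y[idx[, 2]], z = map$z[idx[, 3]],
             conc = map$conc[idx])
}
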