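#' Contact surface area between dimer partners
#'
#' \eqn{(SASA_A + SASA_B - SASA_{dimer}) / 2}: the buried surface per
#' partner. SASA values are inputs (computed externally with a
#' rolling-probe tool); a negative result flags inconsistent inputs.
#'
#' @param sasa_A,sasa_B solvent-accessible surface areas of the isolated
#'   partners (same units, e.g. nm^2)
#' @param sasa_dimer SASA of the dimer
#' @return contact area, same units; vectorized
#' @export
contactArea <- function(sasa_A, sasa_B, sasa_dimer) {
  if (any(sasa_A < 0) || any(sasa_B < 0) || any(sasa_dimer < 0))
    stop("SASA values must be non-negative")
  out <- (sasa_A + sasa_B - sasa_dimer) / 2
  if (any(out < 0))
    warning("negative contact area: inconsistent SASA inputs")
  out
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Signed dihedral angle of four points
#'
#' Standard signed torsion in (-180, 180] degrees: 180 for a planar
#' trans arrangement, 0 for cis.
#'
#' @param p1,p2,p3,p4 coordinates (length-3 vectors)
#' @return angle in degrees
#' @export
interfaceDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 * nb || sqrt(sum(n2^2)) < 1e-10 * nb)
    stop("collinear point triple: dihedral undefined")
  ang <- atan2(sum(.cross3(n1, n2) * b2 / nb), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Minimum cross-pair distance between two atom sets
#'
#' Smallest distance over all pairs (one atom from each set), e.g.
#' between a lysine side-chain nitrogen and the two carboxylate oxygens
#' of a bound fatty acid. Symmetric in the two sets and invariant to
#' within-set permutation.
#'
#' @param donors,acceptors coordinate matrices (n x 3), nonempty
#' @return minimum distance, in the coordinates' units
#' @export
minContactDistance <- function(donors, acceptors) {
  donors <- matrix(donors, ncol = 3)
  acceptors <- matrix(acceptors, ncol = 3)
  if (!nrow(donors) || !nrow(acceptors)) stop("empty atom set")
  d2 <- outer(rowSums(donors^2), rowSums(acceptors^2), "+") -
    2 * donors %*% t(acceptors)
  sqrt(max(min(d2), 0))
}

#' Gaussian KDE histogram with the (4/3N)^(1/5) bandwidth rule
#'
#' Normalised density curve of a metric series using a Gaussian kernel
#' with bandwidth \eqn{\sigma (4/(3N))^{1/5}} on a support padded by 4
#' bandwidths, so the curve integrates to 1 within 1%.
#'
#' @param values at least 2 values with nonzero spread
#' @param n_grid number of output grid points
#' @return data.frame(x, density) with attribute "bandwidth"
#' @export
kdeHistogram <- function(values, n_grid = 512) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- sd(values)
  if (s == 0) stop("zero spread: KDE bandwidth undefined")
  bw <- s * (4 / (3 * length(values)))^(1 / 5)
  d <- density(values, bw = bw, from = min(values) - 4 * bw,
               to = max(values) + 4 * bw, n = n_grid)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  out
}
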