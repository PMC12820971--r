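#' Read a coordinate ensemble from multi-model PDB or XYZ trajectory
#'
#' Multi-model PDB files are read through bio3d; XYZ trajectories (blocks
#' of natoms / comment / 'name x y z' lines) with a small built-in
#' parser. Coordinates are returned in Angstrom, frames in file order.
#'
#' @param path input file (.pdb or .xyz; content is sniffed otherwise)
#' @param selection optional list with elements \code{resname} and/or
#'   \code{atom} (character vectors); an empty match is an error
#' @return a \linkS4class{CoordinateEnsemble}
#' @export
readCoordinateEnsemble <- function(path, selection = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "" ) {
    first <- readLines(path, n = 1)
    ext <- if (grepl("^\\s*[0-9]+\\s*$", first)) "xyz" else "pdb"
  }
  ens <- if (ext == "xyz") .readXYZ(path) else .readMultiPDB(path)
  if (!is.null(selection)) {
    keep <- rep(TRUE, length(ens@atomNames))
    if (!is.null(selection$resname))
      keep <- keep & ens@resNames %in% selection$resname
    if (!is.null(selection$atom))
      keep <- keep & ens@atomNames %in% selection$atom
    if (!any(keep)) stop("selection matches no atoms")
    ens@coords <- ens@coords[, keep, , drop = FALSE]
    ens@atomNames <- ens@atomNames[keep]
    ens@resNames <- ens@resNames[keep]
    if (!is.null(ens@reference))
      ens@reference <- ens@reference[keep, , drop = FALSE]
  }
  ens
}

.readMultiPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3 * nat)
    stop("inconsistent atom counts across models")
  nf <- nrow(xyz)
  co <- array(0, c(nf, nat, 3))
  for (f in seq_len(nf))
    co[f, , ] <- matrix(xyz[f, ], nat, 3, byrow = TRUE)
  coordinateEnsemble(co, atomNames = pdb$atom$elety,
                     resNames = pdb$atom$resid)
}

.readXYZ <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); names_ref <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom count at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated XYZ frame at line ", i)
    blk <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(blk), "\\s+")
    if (any(lengths(tok) < 4)) stop("malformed XYZ atom line in frame")
    nm <- vapply(tok, `[`, character(1), 1)
    co <- t(vapply(tok, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (is.null(names_ref)) names_ref <- nm
    else if (length(nm) != length(names_ref))
      stop("inconsistent atom counts across XYZ frames")
    frames[[length(frames) + 1]] <- co
    i <- i + 2 + n
  }
  nf <- length(frames); nat <- length(names_ref)
  co <- array(0, c(nf, nat, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  coordinateEnsemble(co, atomNames = names_ref,
                     resNames = rep("UNK", nat))
}
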