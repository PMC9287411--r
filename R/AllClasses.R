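#' @import methods
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' ForceFieldTable: non-bonded parameters per (residue, atom)
#'
#' Holds partial charges q (elementary charges), Lennard-Jones well depths
#' epsilon (kcal/mol) and half minimum radii Rmin/2 (Angstrom) keyed by
#' residue and atom name. Validity requires epsilon >= 0, Rmin/2 > 0 and
#' per-residue charge sums within 0.01 e of an integer formal charge.
#'
#' @slot params data.frame with columns res, atom, q, epsilon, rmin_half.
#' @slot source character label recording where the table came from.
#' @exportClass ForceFieldTable
setClass("ForceFieldTable",
         representation(params = "data.frame", source = "character"))

setValidity("ForceFieldTable", function(object) {
  p <- object@params
  need <- c("res", "atom", "q", "epsilon", "rmin_half")
  if (!all(need %in% names(p))) {
    return(paste("params must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p) == 0) return("parameter table is empty")
  if (any(!is.finite(p$q))) return("non-finite partial charges")
  if (any(p$epsilon < 0)) return("negative Lennard-Jones well depth")
  if (any(p$rmin_half <= 0)) return("non-positive Rmin/2")
  sums <- tapply(p$q, p$res, sum)
  off <- abs(sums - round(sums)) > 0.01
  if (any(off)) {
    return(paste("residue charge sum not near-integer for:",
                 paste(names(sums)[off], collapse = ", ")))
  }
  TRUE
})

#' ParamStructure: atoms grouped into residues and chains
#'
#' A protein (or complex) structure after reading: one row per atom with
#' coordinates, residue/chain bookkeeping and, once [assignParameters()]
#' has run, non-bonded parameters. Residues are renumbered 1-based and
#' gap-free within each chain.
#'
#' @slot id character structure identifier.
#' @slot atoms data.frame with columns chain, resno, resid, elety,
#'   x, y, z, q, epsilon, rminHalf, parameterized.
#' @slot paramSource label of the force-field table applied ("" if none).
#' @slot paramReport data.frame of atoms left unparameterized.
#' @exportClass ParamStructure
setClass("ParamStructure",
         representation(id = "character", atoms = "data.frame",
                        paramSource = "character", paramReport = "data.frame"))

setValidity("ParamStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z",
            "q", "epsilon", "rminHalf", "parameterized")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a) == 0) return("structure has no atoms")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    return("non-finite atom coordinates")
  }
  if (!all(a$resid %in% STANDARD_AA)) {
    bad <- unique(a$resid[!a$resid %in% STANDARD_AA])
    return(paste("non-standard residues present:", paste(bad, collapse = ", ")))
  }
  par <- a$parameterized
  if (any(par & (a$epsilon < 0 | !is.finite(a$epsilon)))) {
    return("parameterized atom with invalid epsilon")
  }
  if (any(par & (a$rminHalf <= 0 | !is.finite(a$rminHalf)))) {
    return("parameterized atom with invalid Rmin/2")
  }
  for (ch in unique(a$chain)) {
    rn <- unique(a$resno[a$chain == ch])
    if (!identical(as.integer(rn), seq_along(rn))) {
      return(paste0("chain ", ch, ": residue numbering not 1-based gap-free"))
    }
  }
  TRUE
})

#' EnergyNetwork: weighted residue-residue interaction graph
#'
#' Edges carry the residue-pair Coulomb or Lennard-Jones energy
#' (kcal/mol) and the minimum inter-atomic distance. Vertices are rows of
#' the residue table (global residue index across chains).
#'
#' @slot id structure identifier.
#' @slot kind "C" (Coulomb) or "LJ" (Lennard-Jones).
#' @slot scope "intra" or "inter".
#' @slot edges data.frame(i, j, energy, minDist) with i < j.
#' @slot residues data.frame(index, chain, resno, resid).
#' @slot cutoff numeric minimum-distance cutoff in Angstrom (NA = none).
#' @exportClass EnergyNetwork
setClass("EnergyNetwork",
         representation(id = "character", kind = "character",
                        scope = "character", edges = "data.frame",
                        residues = "data.frame", cutoff = "numeric"))

setValidity("EnergyNetwork", function(object) {
  if (!object@kind %in% c("C", "LJ")) return("kind must be 'C' or 'LJ'")
  if (!object@scope %in% c("intra", "inter")) {
    return("scope must be 'intra' or 'inter'")
  }
  e <- object@edges
  if (nrow(e)) {
    if (any(e$i == e$j)) return("self-edges are not allowed")
    if (any(e$i >= e$j)) return("edges must be stored with i < j")
    if (anyDuplicated(paste(e$i, e$j))) return("duplicate edges")
    r <- object@residues
    if (max(e$j) > nrow(r)) return("edge endpoint outside residue table")
    if (object@scope == "inter" &&
        any(r$chain[e$i] == r$chain[e$j])) {
      return("inter-scope network contains a same-chain edge")
    }
  }
  TRUE
})

#' MolecularSurface: solvent-accessible dot surface with normals
#'
#' A point cloud sampled on the solvent-accessible surface; each point
#' carries a unit outward normal and the atom/residue that generated it.
#'
#' @slot points n x 3 matrix, Angstrom.
#' @slot normals n x 3 matrix of unit outward normals.
#' @slot atom integer index of the owning atom (row of the atom table).
#' @slot residue integer index of the owning residue.
#' @slot residues residue table of the parent structure.
#' @slot density requested point density (points per Angstrom^2).
#' @slot probe probe radius, Angstrom.
#' @exportClass MolecularSurface
setClass("MolecularSurface",
         representation(points = "matrix", normals = "matrix",
                        atom = "integer", residue = "integer",
                        residues = "data.frame",
                        density = "numeric", probe = "numeric"))

setValidity("MolecularSurface", function(object) {
  n <- nrow(object@points)
  if (nrow(object@normals) != n) return("points/normals size mismatch")
  if (length(object@atom) != n || length(object@residue) != n) {
    return("owner index length mismatch")
  }
  if (n > 0) {
    len <- sqrt(rowSums(object@normals^2))
    if (any(abs(len - 1) > 1e-6)) return("normals are not unit length")
  }
  TRUE
})

#' SurfacePatch: surface points within a sphere around a center
#'
#' @slot points n x 3 matrix (Angstrom).
#' @slot normals n x 3 unit normals.
#' @slot center sphere center (a surface point), length-3.
#' @slot radius patch radius R_s, Angstrom.
#' @exportClass SurfacePatch
setClass("SurfacePatch",
         representation(points = "matrix", normals = "matrix",
                        center = "numeric", radius = "numeric"))

setValidity("SurfacePatch", function(object) {
  if (nrow(object@points) != nrow(object@normals)) {
    return("points/normals size mismatch")
  }
  if (length(object@center) != 3) return("center must be length 3")
  if (nrow(object@points)) {
    d <- sqrt(colSums((t(object@points) - object@center)^2))
    if (any(d > object@radius + 1e-6)) {
      return("patch contains points outside its sphere")
    }
  }
  TRUE
})

#' PatchImage: unit-disk image of a projected surface patch
#'
#' Square G x G pixel grid over the unit disk; pixel values are the mean
#' distance r from the projection apex C to the patch points that landed
#' in the pixel. Pixels outside the inscribed disk, and interior pixels
#' that stayed empty after neighbour filling, are masked.
#'
#' @slot values G x G numeric matrix (Angstrom); NA where masked.
#' @slot mask G x G logical matrix, TRUE where the pixel is valid.
#' @slot apexHeight height of the apex C on the z-axis, Angstrom.
#' @slot theta cone half-angle used to place C, degrees.
#' @exportClass PatchImage
setClass("PatchImage",
         representation(values = "matrix", mask = "matrix",
                        apexHeight = "numeric", theta = "numeric"))

setValidity("PatchImage", function(object) {
  if (!identical(dim(object@values), dim(object@mask))) {
    return("values/mask dimension mismatch")
  }
  if (nrow(object@values) != ncol(object@values)) {
    return("image grid must be square")
  }
  v <- object@values[object@mask]
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("valid pixels must hold finite positive distances")
  }
  TRUE
})

#' ZernikeExpansion: 2D Zernike expansion coefficients
#'
#' Complex coefficients c_nm for 0 <= m <= n <= N with n - m even, in
#' canonical order (n ascending, then m ascending).
#'
#' @slot order maximum order N.
#' @slot n,m integer index vectors.
#' @slot coeff complex coefficient vector.
#' @exportClass ZernikeExpansion
setClass("ZernikeExpansion",
         representation(order = "integer", n = "integer", m = "integer",
                        coeff = "complex"))

setValidity("ZernikeExpansion", function(object) {
  M <- sum(floor(0:object@order / 2) + 1)
  if (length(object@coeff) != M) {
    return(sprintf("order %d expansion must hold %d coefficients",
                   object@order, M))
  }
  if (any((object@n - object@m) %% 2 != 0)) return("n - m must be even")
  TRUE
})

#' ZernikeDescriptor: rotation-invariant moduli z_nm = |c_nm|
#'
#' @slot order maximum order N.
#' @slot n,m integer index vectors (canonical order).
#' @slot values non-negative invariant vector.
#' @exportClass ZernikeDescriptor
setClass("ZernikeDescriptor",
         representation(order = "integer", n = "integer", m = "integer",
                        values = "numeric"))

setValidity("ZernikeDescriptor", function(object) {
  M <- sum(floor(0:object@order / 2) + 1)
  if (length(object@values) != M) {
    return(sprintf("order %d descriptor must have length %d",
                   object@order, M))
  }
  if (any(object@values < 0)) return("invariants must be non-negative")
  TRUE
})
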