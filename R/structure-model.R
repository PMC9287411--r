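#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (heteroatoms are discarded), resolves alternate
#' locations by keeping the highest-occupancy conformer (ties go to
#' altloc "A"), and renumbers residues 1-based and gap-free within each
#' chain so that insertion codes and numbering gaps disappear. Atoms come
#' back unparameterized; see [assignParameters()].
#'
#' @param path path to a PDB file.
#' @param modelIndex which MODEL to read from multi-model files (default 1).
#' @param id structure identifier; defaults to the file base name.
#' @return a [ParamStructure-class] with `parameterized = FALSE` atoms.
#' @export
readPDB <- function(path, modelIndex = 1L, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file: ", conditionMessage(e)))
  a <- pdb$atom
  if (modelIndex > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < modelIndex) {
      stop("model ", modelIndex, " not present in file")
    }
    xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3, byrow = TRUE)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("no standard residues: file holds no ATOM records")
  a <- a[a$resid %in% STANDARD_AA, , drop = FALSE]
  if (nrow(a) == 0) stop("no standard residues after trimming heteroatoms")
  a <- .resolveAltloc(a)
  a <- .renumberResidues(a)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  newParamStructure(id = id, chain = a$chain, resno = a$resno,
                    resid = a$resid, elety = a$elety,
                    xyz = cbind(a$x, a$y, a$z))
}

# keep, per (chain, residue, atom name), the altloc with highest
# occupancy; ties resolved in favour of altloc "A" (then alphabetically)
.resolveAltloc <- function(a) {
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -occ, alt != "A", alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a[order(as.integer(rownames(a))), , drop = FALSE]
}

# renumber residues 1..k per chain in order of appearance, removing
# insertion codes and numbering gaps
.renumberResidues <- function(a) {
  new <- integer(nrow(a))
  for (ch in unique(a$chain)) {
    sel <- which(a$chain == ch)
    key <- paste(a$resno[sel], a$insert[sel], sep = "\r")
    new[sel] <- match(key, unique(key))
  }
  a$resno <- new
  a
}

# low-level constructor shared by readPDB and the synthetic generators
newParamStructure <- function(id, chain, resno, resid, elety, xyz,
                              q = NULL, epsilon = NULL, rminHalf = NULL,
                              paramSource = "") {
  n <- length(resno)
  par <- !is.null(q)
  atoms <- data.frame(
    chain = as.character(chain), resno = as.integer(resno),
    resid = as.character(resid), elety = as.character(elety),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    q = if (par) q else rep(NA_real_, n),
    epsilon = if (par) epsilon else rep(NA_real_, n),
    rminHalf = if (par) rminHalf else rep(NA_real_, n),
    parameterized = rep(par, n), stringsAsFactors = FALSE)
  new("ParamStructure", id = id, atoms = atoms, paramSource = paramSource,
      paramReport = atoms[0, c("chain", "resno", "resid", "elety")])
}

#' Write a structure back to PDB
#'
#' Round-trip companion of [readPDB()]: coordinates, residue names and
#' (renumbered) residue indices survive a write/read cycle.
#'
#' @param structure a [ParamStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- atomTable(structure)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
    a[, c("x", "y", "z")]))), resno = a$resno, resid = a$resid,
    chain = a$chain, elety = a$elety, o = rep(1, nrow(a)),
    b = rep(0, nrow(a)))
  invisible(path)
}

#' Load a non-bonded force-field parameter table
#'
#' Reads a TSV with columns `res`, `atom`, `q` (elementary charges),
#' `epsilon` (kcal/mol) and `rmin_half` (Angstrom). `"bundled"` loads the
#' package's united-charge heavy-atom table, which covers all heavy atoms
#' of the 20 standard residues with hydrogen charges folded into their
#' bonded heavy atoms so unprotonated PDB files parameterize out of the
#' box.
#'
#' @param path a file path, or `"bundled"`.
#' @return a validated [ForceFieldTable-class].
#' @export
loadForceField <- function(path = "bundled") {
  src <- path
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "united_heavy_atom_nb.tsv",
                        package = "foldbind")
    src <- "bundled united-charge heavy-atom set"
  }
  if (!file.exists(path) || file.size(path) == 0) {
    stop("force-field table missing or empty: ", path)
  }
  p <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  tab <- new("ForceFieldTable", params = p, source = src)
  validObject(tab)
  tab
}

#' Attach non-bonded parameters to a structure
#'
#' Every atom with a matching (residue, atom-name) entry receives its
#' (q, epsilon, Rmin/2) triple and is marked `parameterized`; atoms with
#' no entry are flagged, reported via [parameterReport()], and excluded
#' from all energy sums. More than `maxUnmatched` unmatched atoms aborts,
#' which usually signals a wrong atom-naming dialect.
#'
#' @param structure a [ParamStructure-class].
#' @param table a [ForceFieldTable-class].
#' @param maxUnmatched tolerated unmatched fraction before erroring (0.2).
#' @return the structure with parameters assigned; the unmatched-atom
#'   report is available through [parameterReport()].
#' @export
assignParameters <- function(structure, table, maxUnmatched = 0.2) {
  stopifnot(is(structure, "ParamStructure"), is(table, "ForceFieldTable"))
  a <- structure@atoms
  p <- table@params
  idx <- match(paste(a$resid, a$elety), paste(p$res, p$atom))
  hit <- !is.na(idx)
  if (mean(!hit) > maxUnmatched) {
    stop(sprintf(paste0("parameter coverage too low: %d/%d atoms unmatched",
                        " (check the atom naming dialect)"),
                 sum(!hit), nrow(a)))
  }
  a$q[hit] <- p$q[idx[hit]]
  a$epsilon[hit] <- p$epsilon[idx[hit]]
  a$rminHalf[hit] <- p$rmin_half[idx[hit]]
  a$parameterized <- hit
  structure@atoms <- a
  structure@paramSource <- table@source
  structure@paramReport <- a[!hit, c("chain", "resno", "resid", "elety")]
  validObject(structure)
  structure
}

#' Minimum inter-atomic distance between two residues
#'
#' The residue-pair distance is the minimum over all atom pairs of the
#' Euclidean distance, the convention used both for the 4-Angstrom
#' contact filters and the per-edge distances of energy networks.
#'
#' @param resI,resJ atom data.frames (rows of [atomTable()]) or n x 3
#'   coordinate matrices.
#' @return distance in Angstrom.
#' @export
residueMinDistance <- function(resI, resJ) {
  ci <- .coordsOf(resI); cj <- .coordsOf(resJ)
  if (nrow(ci) == 0 || nrow(cj) == 0) stop("empty residue")
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * tcrossprod(ci, cj)
  sqrt(max(0, min(d2)))
}

.coordsOf <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x[, c("x", "y", "z")])
}

#' Combine two single-structure objects into one two-chain complex
#'
#' Chains are relabelled "A" and "B" (file order preserved); residue
#' numbering within each chain is kept.
#'
#' @param a,b [ParamStructure-class] objects.
#' @param id identifier of the combined complex.
#' @return a two-chain [ParamStructure-class].
#' @export
combineStructures <- function(a, b, id = paste(a@id, b@id, sep = ":")) {
  ta <- a@atoms; tb <- b@atoms
  ta$chain <- "A"; tb$chain <- "B"
  out <- a
  out@id <- id
  out@atoms <- rbind(ta, tb)
  out@paramReport <- rbind(a@paramReport, b@paramReport)
  validObject(out)
  out
}
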