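#' Van der Waals radii (Bondi) by element
#'
#' Elements not in the table fall back to 1.7 Angstrom with a warning.
#' @keywords internal
BONDI_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                 P = 1.80, F = 1.47, SE = 1.90)

# element symbol from a PDB heavy-atom name ("CA" -> C, "OD1" -> O, ...)
.elementOf <- function(elety) {
  first <- toupper(substr(gsub("[0-9]", "", elety), 1, 1))
  first[substr(elety, 1, 2) %in% c("SE")] <- "SE"
  first
}

.vdwRadius <- function(elety) {
  el <- .elementOf(elety)
  r <- BONDI_RADII[el]
  if (any(is.na(r))) {
    warning("unknown element radius for ",
            paste(unique(elety[is.na(r)]), collapse = ", "),
            "; falling back to 1.7 A")
    r[is.na(r)] <- 1.7
  }
  unname(r)
}

# deterministic near-uniform sphere sampling (Fibonacci spiral lattice)
.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 1 + 0.5)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Compute a solvent-accessible dot surface
#'
#' Places a deterministic spiral lattice of points on each atom's
#' solvent-accessible sphere (radius r_vdw + probe) at the requested
#' density, then removes every point that falls inside a neighbouring
#' atom's accessible sphere. Outward unit normals are the radial
#' directions from the owning atom center, which is exact for the
#' solvent-accessible surface.
#'
#' @param structure a [ParamStructure-class].
#' @param density requested point density, points per Angstrom^2.
#' @param probe water probe radius, Angstrom.
#' @return a [MolecularSurface-class].
#' @export
computeSurface <- function(structure, density = 5, probe = 1.4) {
  a <- atomTable(structure)
  rt <- residueTable(structure)
  ridx <- match(paste(a$chain, a$resno), paste(rt$chain, rt$resno))
  centers <- as.matrix(a[, c("x", "y", "z")])
  R <- .vdwRadius(a$elety) + probe
  nA <- nrow(a)
  ptL <- vector("list", nA); nrmL <- vector("list", nA)
  ownL <- vector("list", nA)
  # neighbour lists via pairwise center distances
  cd <- as.matrix(stats::dist(centers))
  for (k in seq_len(nA)) {
    npts <- max(1L, round(4 * pi * R[k]^2 * density))
    sph <- .fibonacciSphere(npts)
    pts <- sweep(sph * R[k], 2, centers[k, ], "+")
    nb <- which(cd[k, ] < R[k] + R & seq_len(nA) != k)
    keep <- rep(TRUE, npts)
    for (b in nb) {
      d2 <- (pts[, 1] - centers[b, 1])^2 + (pts[, 2] - centers[b, 2])^2 +
        (pts[, 3] - centers[b, 3])^2
      # points exactly on a neighbour's sphere belong to the
      # lower-indexed atom, so coincident atoms do not double the surface
      thr <- if (b < k) (R[b] + 1e-6)^2 else (R[b] - 1e-6)^2
      keep <- keep & d2 >= thr
      if (!any(keep)) break
    }
    if (any(keep)) {
      ptL[[k]] <- pts[keep, , drop = FALSE]
      nrmL[[k]] <- sph[keep, , drop = FALSE]
      ownL[[k]] <- rep(k, sum(keep))
    }
  }
  pts <- do.call(rbind, c(ptL, list(matrix(0, 0, 3))))
  nrm <- do.call(rbind, c(nrmL, list(matrix(0, 0, 3))))
  own <- as.integer(unlist(c(ownL, list(integer()))))
  new("MolecularSurface", points = pts, normals = nrm, atom = own,
      residue = as.integer(ridx[own]), residues = rt,
      density = density, probe = probe)
}

#' Per-residue solvent accessibility
#'
#' SASA per atom is the surviving fraction of its lattice points times
#' the area of its accessible sphere, aggregated per residue; RSA divides
#' by the residue's theoretical maximum SASA (bundled Gly-X-Gly reference
#' table).
#'
#' @param structure a [ParamStructure-class].
#' @param probe probe radius, Angstrom.
#' @param density lattice density used for the estimate.
#' @param surface optionally, a precomputed [MolecularSurface-class]
#'   (must match `probe`/`density`).
#' @param maxSasaPath TSV path for the max-SASA table, or "bundled".
#' @return data.frame(index, chain, resno, resid, sasa, maxSasa, rsa).
#' @export
residueSASA <- function(structure, probe = 1.4, density = 5,
                        surface = NULL, maxSasaPath = "bundled") {
  if (is.null(surface)) {
    surface <- computeSurface(structure, density = density, probe = probe)
  }
  a <- atomTable(structure)
  rt <- residueTable(structure)
  R <- .vdwRadius(a$elety) + surface@probe
  genPer <- pmax(1L, round(4 * pi * R^2 * surface@density))
  surv <- tabulate(surface@atom, nbins = nrow(a))
  atomSasa <- surv / genPer * 4 * pi * R^2
  ridx <- match(paste(a$chain, a$resno), paste(rt$chain, rt$resno))
  sasa <- as.numeric(tapply(atomSasa, factor(ridx, levels = rt$index), sum))
  sasa[is.na(sasa)] <- 0
  maxTab <- .loadMaxSasa(maxSasaPath)
  maxS <- maxTab$max_sasa[match(rt$resid, maxTab$res)]
  if (any(is.na(maxS))) {
    stop("residue type missing from max-SASA table: ",
         paste(unique(rt$resid[is.na(maxS)]), collapse = ", "))
  }
  data.frame(rt, sasa = sasa, maxSasa = maxS, rsa = sasa / maxS)
}

.loadMaxSasa <- function(path = "bundled") {
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "max_sasa_theoretical.tsv",
                        package = "foldbind")
  }
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Solvent-exposed residues
#'
#' Residues with relative solvent accessibility above the threshold
#' (default 0.25).
#'
#' @param structure a [ParamStructure-class].
#' @param rsaThreshold RSA cutoff.
#' @param ... passed to [residueSASA()] (e.g. a precomputed surface).
#' @return subset of the residue table.
#' @export
surfaceResidues <- function(structure, rsaThreshold = 0.25, ...) {
  acc <- residueSASA(structure, ...)
  acc[acc$rsa > rsaThreshold, , drop = FALSE]
}

#' Interface residues of a two-chain complex
#'
#' A residue is at the interface if any of its atoms lies within
#' `cutoff` Angstrom (default 4) of any atom of the partner chain.
#'
#' @param complex a two-chain [ParamStructure-class].
#' @param cutoff contact distance, Angstrom.
#' @return named list of residue-table subsets, one per chain.
#' @export
interfaceResidues <- function(complex, cutoff = 4) {
  rt <- residueTable(complex)
  chains <- unique(rt$chain)
  if (length(chains) != 2) stop("interface detection requires exactly two chains")
  a <- atomTable(complex)
  ca <- as.matrix(a[a$chain == chains[1], c("x", "y", "z")])
  cb <- as.matrix(a[a$chain == chains[2], c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                   2 * tcrossprod(ca, cb), 0))
  close <- d < cutoff
  resA <- a$resno[a$chain == chains[1]]
  resB <- a$resno[a$chain == chains[2]]
  hitA <- unique(resA[apply(close, 1, any)])
  hitB <- unique(resB[apply(close, 2, any)])
  out <- list(rt[rt$chain == chains[1] & rt$resno %in% hitA, , drop = FALSE],
              rt[rt$chain == chains[2] & rt$resno %in% hitB, , drop = FALSE])
  names(out) <- chains
  out
}

#' Binding-site points of a template surface
#'
#' Indices of template surface points whose minimum distance from any
#' point of the ligand surface is below `cutoff` Angstrom (default 3).
#' Computed block-wise; the result is identical to the full quadratic
#' scan.
#'
#' @param templateSurface,ligandSurface [MolecularSurface-class] objects
#'   (or raw point matrices).
#' @param cutoff distance cutoff, Angstrom.
#' @return integer vector of template point indices.
#' @export
bindingSitePoints <- function(templateSurface, ligandSurface, cutoff = 3) {
  tp <- if (is(templateSurface, "MolecularSurface"))
    templateSurface@points else templateSurface
  lp <- if (is(ligandSurface, "MolecularSurface"))
    ligandSurface@points else ligandSurface
  if (nrow(tp) == 0 || nrow(lp) == 0) return(integer())
  hit <- logical(nrow(tp))
  lp2 <- rowSums(lp^2)
  block <- 2000L
  for (s in seq(1L, nrow(tp), by = block)) {
    e <- min(s + block - 1L, nrow(tp))
    tb <- tp[s:e, , drop = FALSE]
    d2 <- outer(rowSums(tb^2), lp2, "+") - 2 * tcrossprod(tb, lp)
    hit[s:e] <- apply(d2, 1, min) < cutoff^2
  }
  which(hit)
}
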