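#' Vacuum Coulomb constant in kcal Angstrom / (mol e^2)
#'
#' K = e^2 N_A / (4 pi eps0), converted from SI to kcal/mol with atomic
#' charges in elementary-charge units and distances in Angstrom, with
#' relative permittivity 1 (no solvent screening). Derived once from
#' CODATA values and frozen.
#' @export
COULOMB_K <- 332.0636

#' Coulomb energy between two point charges
#'
#' E = K q_l q_m / r with K = [COULOMB_K] (vacuum, unscreened).
#'
#' @param ql,qm partial charges in elementary charges.
#' @param r inter-atomic distance, Angstrom (> 0).
#' @return energy in kcal/mol; the sign follows the charge product.
#' @export
coulombPair <- function(ql, qm, r) {
  if (any(r <= 0)) stop("coulombPair: distance must be positive")
  COULOMB_K * ql * qm / r
}

#' 12-6 Lennard-Jones energy between two atoms
#'
#' E = sqrt(eps_l eps_m) [ (R/r)^12 - 2 (R/r)^6 ] with R = Rmin_l +
#' Rmin_m. The combination uses the SUM of the two per-atom radii, so the
#' force-field table's Rmin/2 values are what is passed for `rminL` and
#' `rminR`. The minimum is -sqrt(eps_l eps_m), attained at r = R.
#'
#' @param epsL,epsM well depths, kcal/mol (>= 0).
#' @param rminL,rminR per-atom Rmin/2 values, Angstrom.
#' @param r inter-atomic distance, Angstrom (> 0).
#' @return energy in kcal/mol.
#' @export
ljPair <- function(epsL, epsM, rminL, rminR, r) {
  if (any(r <= 0)) stop("ljPair: distance must be positive")
  s6 <- ((rminL + rminR) / r)^6
  sqrt(epsL * epsM) * (s6^2 - 2 * s6)
}

#' Total non-bonded energy between two residues
#'
#' Sums the per-atom-pair Coulomb or Lennard-Jones energies over all
#' parameterized atom pairs of the two residues; unparameterized atoms
#' are skipped.
#'
#' @param resI,resJ atom data.frames (subsets of [atomTable()] rows) for
#'   two distinct residues.
#' @param kind "C" or "LJ".
#' @return energy in kcal/mol.
#' @export
residuePairEnergy <- function(resI, resJ, kind = c("C", "LJ")) {
  kind <- match.arg(kind)
  ai <- resI[resI$parameterized, , drop = FALSE]
  aj <- resJ[resJ$parameterized, , drop = FALSE]
  if (nrow(ai) == 0 && nrow(aj) == 0) {
    stop("residuePairEnergy: both residues are fully unparameterized")
  }
  if (nrow(ai) == 0 || nrow(aj) == 0) return(0)
  ci <- as.matrix(ai[, c("x", "y", "z")])
  cj <- as.matrix(aj[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(ci^2), rowSums(cj^2), "+") -
                   2 * tcrossprod(ci, cj), 0))
  l <- rep(seq_len(nrow(ai)), times = nrow(aj))
  m <- rep(seq_len(nrow(aj)), each = nrow(ai))
  if (kind == "C") {
    sum(coulombPair(ai$q[l], aj$q[m], as.numeric(d)))
  } else {
    sum(ljPair(ai$epsilon[l], aj$epsilon[m], ai$rminHalf[l],
               aj$rminHalf[m], as.numeric(d)))
  }
}

#' Build a residue-residue interaction energy network
#'
#' Computes the residue-pair Coulomb or Lennard-Jones energies of a
#' structure and stores them as a weighted graph. For `scope = "intra"`,
#' same-chain pairs with sequence separation below 2 (self and adjacent
#' residues, which share bonded terms) are excluded. For
#' `scope = "inter"` only cross-chain pairs between exactly two chains
#' enter. An optional minimum-distance cutoff keeps only residue pairs
#' closer than `distanceCutoff` Angstrom. CYS-CYS pairs whose SG-SG
#' distance is below 2.5 Angstrom (disulfide bridges, where a covalent
#' bond makes the non-bonded model unphysical) can be dropped; this is
#' the default for Lennard-Jones networks.
#'
#' @param structure a parameterized [ParamStructure-class]; for inter
#'   scope it must have exactly two chains (see [combineStructures()]).
#' @param kind "C" (Coulomb) or "LJ" (Lennard-Jones).
#' @param scope "intra" or "inter".
#' @param distanceCutoff minimum-distance cutoff in Angstrom, or NULL for
#'   all pairs.
#' @param excludeCysBridges drop disulfide-bonded CYS-CYS edges; default
#'   TRUE for LJ, FALSE for Coulomb.
#' @return an [EnergyNetwork-class].
#' @export
buildEnergyNetwork <- function(structure, kind = c("C", "LJ"),
                               scope = c("intra", "inter"),
                               distanceCutoff = NULL,
                               excludeCysBridges = NULL) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  if (is.null(excludeCysBridges)) excludeCysBridges <- kind == "LJ"
  a <- atomTable(structure)
  rt <- residueTable(structure)
  if (scope == "inter" && length(unique(rt$chain)) != 2) {
    stop("inter scope requires exactly two chains")
  }
  ridx <- match(paste(a$chain, a$resno), paste(rt$chain, rt$resno))
  pairs <- .allowedPairs(rt, scope)
  if (nrow(pairs)) {
    geom <- .pairGeometry(a, ridx, pairs, kind, excludeCysBridges)
    keep <- rep(TRUE, nrow(pairs))
    if (!is.null(distanceCutoff)) keep <- geom$minDist < distanceCutoff
    keep <- keep & !geom$cysBridge
    edges <- data.frame(i = pairs$i[keep], j = pairs$j[keep],
                        energy = geom$energy[keep],
                        minDist = geom$minDist[keep])
  } else {
    edges <- data.frame(i = integer(), j = integer(),
                        energy = numeric(), minDist = numeric())
  }
  new("EnergyNetwork", id = structure@id, kind = kind, scope = scope,
      edges = edges, residues = rt,
      cutoff = if (is.null(distanceCutoff)) NA_real_ else distanceCutoff)
}

.allowedPairs <- function(rt, scope) {
  n <- nrow(rt)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same <- rt$chain[i] == rt$chain[j]
  if (scope == "intra") {
    keep <- !same | abs(rt$resno[i] - rt$resno[j]) >= 2
  } else {
    keep <- !same
  }
  data.frame(i = i[keep], j = j[keep])
}

# per-residue-pair minimum distances, energies and disulfide flags,
# computed from one full atom-pair pass
.pairGeometry <- function(a, ridx, pairs, kind, excludeCysBridges) {
  co <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(co^2), rowSums(co^2), "+") -
                   2 * tcrossprod(co), 0))
  par <- a$parameterized
  pairKey <- paste(ridx[row(d)], ridx[col(d)])
  wanted <- paste(pairs$i, pairs$j)
  sel <- pairKey %in% wanted
  dv <- d[sel]; key <- pairKey[sel]
  minDist <- tapply(dv, key, min)
  lpar <- par[row(d)][sel] & par[col(d)][sel]
  ev <- numeric(length(dv))
  if (any(lpar)) {
    l <- row(d)[sel][lpar]; m <- col(d)[sel][lpar]
    ev[lpar] <- if (kind == "C") {
      coulombPair(a$q[l], a$q[m], dv[lpar])
    } else {
      ljPair(a$epsilon[l], a$epsilon[m], a$rminHalf[l], a$rminHalf[m],
             dv[lpar])
    }
  }
  energy <- tapply(ev, key, sum)
  ord <- match(wanted, names(minDist))
  cys <- rep(FALSE, nrow(pairs))
  if (excludeCysBridges) {
    sg <- a$resid == "CYS" & a$elety == "SG"
    if (any(sg)) {
      sgIdx <- which(sg)
      for (p in seq_len(nrow(pairs))) {
        li <- sgIdx[ridx[sgIdx] == pairs$i[p]]
        lj <- sgIdx[ridx[sgIdx] == pairs$j[p]]
        if (length(li) && length(lj) && min(d[li, lj]) < 2.5) cys[p] <- TRUE
      }
    }
  }
  list(minDist = as.numeric(minDist[ord]), energy = as.numeric(energy[ord]),
       cysBridge = cys)
}

#' Node strengths of an energy network
#'
#' The strength of residue i is s_i = sum over its incident edges of the
#' edge energy; residues with no edges get strength 0. Summed over all
#' residues the strengths equal twice the total edge energy (each edge is
#' counted in both endpoints).
#'
#' @param network an [EnergyNetwork-class].
#' @return numeric vector of strengths (kcal/mol), one per residue in
#'   [residueTable()] order.
#' @export
nodeStrengths <- function(network) {
  s <- numeric(nrow(network@residues))
  e <- network@edges
  if (nrow(e)) {
    add <- tapply(c(e$energy, e$energy), c(e$i, e$j), sum)
    s[as.integer(names(add))] <- as.numeric(add)
  }
  s
}

#' Total energy of a network
#'
#' Sum of all edge energies, optionally normalized by the structure's
#' residue count N (for complexes, the total over both chains).
#'
#' @param network an [EnergyNetwork-class].
#' @param normalizeBySize divide by the residue count.
#' @return kcal/mol (or kcal/mol per residue).
#' @export
totalEnergy <- function(network, normalizeBySize = FALSE) {
  tot <- sum(network@edges$energy)
  if (normalizeBySize) tot <- tot / nrow(network@residues)
  tot
}

#' Pooled edge-energy distribution and region probabilities
#'
#' Pools the edge energies of one or more networks, builds a density
#' histogram (unit area) and the probabilities of the four energy
#' regions: very strong favorable (E <= -100), strong favorable
#' (-100 < E < -10), weak (-10 <= E <= 10) and strong unfavorable
#' (E > 10), all in kcal/mol.
#'
#' @param networks an [EnergyNetwork-class] or list of them.
#' @param binWidth histogram bin width, kcal/mol (default 2 for Coulomb
#'   scale; use ~0.2 for Lennard-Jones).
#' @return list with `energies`, `breaks`, `density` and
#'   `regionProbabilities` (named, sums to 1).
#' @export
energyDistribution <- function(networks, binWidth = 2) {
  if (is(networks, "EnergyNetwork")) networks <- list(networks)
  e <- unlist(lapply(networks, function(n) n@edges$energy))
  if (length(e) == 0) stop("no edge energies to pool")
  rng <- range(e)
  breaks <- seq(floor(rng[1] / binWidth) * binWidth,
                ceiling(rng[2] / binWidth) * binWidth + binWidth,
                by = binWidth)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  probs <- c(very_strong_favorable = mean(e <= -100),
             strong_favorable = mean(e > -100 & e < -10),
             weak = mean(e >= -10 & e <= 10),
             strong_unfavorable = mean(e > 10))
  list(energies = e, breaks = h$breaks, density = h$density,
       regionProbabilities = probs)
}

#' Probability of a strong interaction
#'
#' The probability that an edge energy lies outside the weak band,
#' P(|E| > 10 kcal/mol), i.e. the complement of the weak-region
#' probability.
#'
#' @param distribution output of [energyDistribution()].
#' @return probability in [0, 1].
#' @export
strongInteractionProbability <- function(distribution) {
  unname(1 - distribution$regionProbabilities["weak"])
}

#' Probability of a high (strongly favorable) node strength
#'
#' Fraction of residues whose strength lies below a negative threshold
#' marking the beginning of the favorable tail.
#'
#' @param strengths numeric vector (or list of vectors) of node strengths.
#' @param threshold negative strength threshold, kcal/mol.
#' @return probability in [0, 1].
#' @export
highStrengthProbability <- function(strengths, threshold) {
  if (threshold >= 0) stop("threshold must target the favorable (negative) tail")
  s <- unlist(strengths)
  mean(s < threshold)
}

#' Data-adaptive high-strength threshold
#'
#' The favorable-tail marker used when no explicit threshold is given:
#' the 5th percentile of the pooled strength distribution.
#'
#' @param strengths numeric vector or list of vectors.
#' @param probs quantile level (default 0.05).
#' @return threshold in kcal/mol.
#' @export
strengthTailThreshold <- function(strengths, probs = 0.05) {
  unname(stats::quantile(unlist(strengths), probs = probs))
}
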