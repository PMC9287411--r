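#' Generate a parameterized toy dimer
#'
#' Builds two single-atom-per-residue chains with a controlled number of
#' cross-chain contact pairs at an exact contact distance; the remaining
#' residues of chain B sit far from chain A (beyond any contact cutoff).
#' All atoms come parameterized, so the dimer feeds directly into
#' [buildEnergyNetwork()] and [interfaceResidues()]. Deterministic for a
#' given seed.
#'
#' @param residuesPerChain residues in each chain.
#' @param contacts number of cross-chain contact pairs (<=
#'   `residuesPerChain`).
#' @param contactDistance separation of each contact pair, Angstrom.
#' @param chargesA,chargesB per-residue partial charges (recycled).
#' @param ljEpsilon,ljRminHalf LJ parameters given to every atom.
#' @param seed integer seed (controls the jitter of non-contact
#'   residues).
#' @param id identifier prefix.
#' @return list with `chainA`, `chainB` (single-chain
#'   [ParamStructure-class] objects) and `complex` (their two-chain
#'   combination).
#' @export
makeToyDimer <- function(residuesPerChain = 6, contacts = 2,
                         contactDistance = 3.32, chargesA = 0,
                         chargesB = 0, ljEpsilon = 0.1,
                         ljRminHalf = 1.9, seed = 1, id = "toy") {
  if (contacts > residuesPerChain) {
    stop("infeasible spec: more contacts than residues per chain")
  }
  if (contactDistance <= 0) stop("contact distance must be positive")
  rng <- .makeRNG(seed)
  n <- residuesPerChain
  qa <- rep_len(chargesA, n)
  qb <- rep_len(chargesB, n)
  spacing <- 8
  xa <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  yb <- ifelse(seq_len(n) <= contacts, contactDistance,
               30 + rng(n) * 5)
  xb <- cbind((seq_len(n) - 1) * spacing, yb, 0)
  mk <- function(ch, xyz, q, idc) {
    newParamStructure(id = idc, chain = rep(ch, n), resno = seq_len(n),
                      resid = rep("GLY", n), elety = rep("CA", n),
                      xyz = xyz, q = q,
                      epsilon = rep(ljEpsilon, n),
                      rminHalf = rep(ljRminHalf, n),
                      paramSource = "synthetic")
  }
  chainA <- mk("A", xa, qa, paste0(id, "_A"))
  chainB <- mk("B", xb, qb, paste0(id, "_B"))
  list(chainA = chainA, chainB = chainB,
       complex = combineStructures(chainA, chainB, id = id))
}

# small deterministic RNG wrapper: a single named generator with an
# explicit integer seed whose draws do not disturb the caller's
# .Random.seed
.makeRNG <- function(seed) {
  state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- stats::runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    out
  }
}

#' Generate a toy monomer with controlled salt bridges
#'
#' A single chain of single-atom residues along a line, with
#' `saltBridges` +1/-1 charge pairs moved to a close contact distance
#' (sequence separation 2, so the pairs enter the intramolecular
#' network). More bridges make the total Coulomb energy more negative.
#'
#' @param nResidues chain length (needs >= 3 * saltBridges + 1).
#' @param saltBridges number of charge-pair contacts.
#' @param bridgeDistance contact distance of each pair, Angstrom.
#' @param seed integer seed (jitter of non-bridge residues).
#' @param id identifier.
#' @return a single-chain [ParamStructure-class], fully parameterized.
#' @export
makeToyMonomer <- function(nResidues = 20, saltBridges = 2,
                           bridgeDistance = 3.32, seed = 1,
                           id = "toymono") {
  if (nResidues < 3 * saltBridges + 1) {
    stop("infeasible spec: chain too short for ", saltBridges, " bridges")
  }
  rng <- .makeRNG(seed)
  spacing <- 8
  xyz <- cbind((seq_len(nResidues) - 1) * spacing, 0,
               (rng(nResidues) - 0.5) * 0.2)
  q <- rep(0, nResidues)
  for (b in seq_len(saltBridges)) {
    i <- 3 * b - 2
    j <- i + 2
    q[i] <- 1; q[j] <- -1
    xyz[j, ] <- xyz[i, ] + c(0, bridgeDistance, 0)
  }
  newParamStructure(id = id, chain = rep("A", nResidues),
                    resno = seq_len(nResidues),
                    resid = rep("GLY", nResidues),
                    elety = rep("CA", nResidues), xyz = xyz, q = q,
                    epsilon = rep(0.1, nResidues),
                    rminHalf = rep(1.9, nResidues),
                    paramSource = "synthetic")
}

# sunflower spiral sampling of a disk (deterministic)
.diskSpiral <- function(n, radius) {
  k <- seq_len(n)
  r <- radius * sqrt((k - 0.5) / n)
  th <- pi * (3 - sqrt(5)) * k
  cbind(r * cos(th), r * sin(th))
}

#' Generate a surface patch with its exact complementary mold
#'
#' The base patch samples a smooth height field (paraboloid, sphere cap,
#' or a paraboloid with seeded Gaussian bumps) over a disk, with unit
#' upward normals from the analytic gradient and optional Gaussian
#' displacement noise along the normals. The mold is the base surface
#' offset by `gap` along the reversed normals — a perfect shape
#' complement. Decoys are independent draws of the bumpy family under
#' different seeds.
#'
#' @param shape "paraboloid", "sphere-cap" or "bumpy".
#' @param curvature paraboloid coefficient, or 1/R for the sphere cap.
#' @param noise Gaussian displacement sigma along the normal, Angstrom.
#' @param density points per Angstrom^2 of disk area.
#' @param gap mold offset along the reversed normals, Angstrom.
#' @param radius disk radius of the patch footprint, Angstrom.
#' @param seed integer seed (bumps + noise).
#' @param nDecoys number of decoy patches to generate.
#' @return list with `patch`, `mold` ([SurfacePatch-class]) and `decoys`
#'   (list of [SurfacePatch-class]).
#' @export
makePatchWithMold <- function(shape = c("bumpy", "paraboloid",
                                        "sphere-cap"),
                              curvature = 0.05, noise = 0, density = 5,
                              gap = 1, radius = 8, seed = 1,
                              nDecoys = 0) {
  shape <- match.arg(shape)
  if (density <= 0) stop("density must be positive")
  base <- .patchField(shape, curvature, noise, density, radius, seed)
  mold <- new("SurfacePatch",
              points = base$points - gap * base$normals,
              normals = -base$normals,
              center = colMeans(base$points - gap * base$normals),
              radius = .patchRadius(base$points - gap * base$normals))
  patch <- new("SurfacePatch", points = base$points,
               normals = base$normals, center = colMeans(base$points),
               radius = .patchRadius(base$points))
  decoys <- lapply(seq_len(nDecoys), function(k) {
    d <- .patchField("bumpy", curvature, noise, density, radius,
                     seed + 1000 * k)
    new("SurfacePatch", points = d$points, normals = d$normals,
        center = colMeans(d$points), radius = .patchRadius(d$points))
  })
  list(patch = patch, mold = mold, decoys = decoys)
}

.patchRadius <- function(pts) {
  ctr <- colMeans(pts)
  max(sqrt(colSums((t(pts) - ctr)^2))) + 1e-6
}

.patchField <- function(shape, curvature, noise, density, radius, seed) {
  rng <- .makeRNG(seed)
  n <- max(30L, round(pi * radius^2 * density))
  xy <- .diskSpiral(n, radius)
  x <- xy[, 1]; y <- xy[, 2]
  if (shape == "paraboloid") {
    z <- curvature * (x^2 + y^2)
    fx <- 2 * curvature * x
    fy <- 2 * curvature * y
  } else if (shape == "sphere-cap") {
    Rc <- 1 / max(curvature, 1e-6)
    if (Rc <= radius) stop("sphere cap radius must exceed the footprint")
    z <- Rc - sqrt(Rc^2 - (x^2 + y^2))
    fx <- x / sqrt(Rc^2 - (x^2 + y^2))
    fy <- y / sqrt(Rc^2 - (x^2 + y^2))
  } else {
    nb <- 6L
    u <- rng(nb * 4)
    cx <- (u[1:nb] - 0.5) * radius
    cy <- (u[nb + 1:nb] - 0.5) * radius
    amp <- (u[2 * nb + 1:nb] - 0.5) * 3
    wid <- 1.5 + u[3 * nb + 1:nb] * 2
    z <- curvature * (x^2 + y^2)
    fx <- 2 * curvature * x
    fy <- 2 * curvature * y
    for (b in seq_len(nb)) {
      g <- amp[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * wid[b]^2))
      z <- z + g
      fx <- fx - g * (x - cx[b]) / wid[b]^2
      fy <- fy - g * (y - cy[b]) / wid[b]^2
    }
  }
  nrm <- cbind(-fx, -fy, 1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  pts <- cbind(x, y, z)
  if (noise > 0) {
    disp <- stats::qnorm(pmin(pmax(rng(n), 1e-12), 1 - 1e-12), sd = noise)
    pts <- pts + disp * nrm
  }
  list(points = pts, normals = nrm)
}

#' Generate a labelled synthetic dataset
#'
#' Builds toy structures whose experimental-style label (melting
#' temperature or log10 dissociation constant) is a monotone function of
#' a controlled generator knob plus Gaussian noise, with the knob stored
#' as ground truth. Sign conventions match the experimental ones: more
#' cross-chain LJ contacts give lower B_a (tighter binding); more salt
#' bridges give higher T_m (more stable fold).
#'
#' @param n number of structures.
#' @param kind "affinity" (toy dimers, B_a labels) or "stability" (toy
#'   monomers, T_m labels).
#' @param seed integer seed.
#' @param noiseSd label noise standard deviation.
#' @param maxKnob largest knob value (contact pairs or salt bridges).
#' @return list with `structures` (named list; for "affinity" each entry
#'   is a `makeToyDimer()` triple, for "stability" a
#'   [ParamStructure-class]) and `manifest`
#'   (data.frame id, labelKind, label, knob).
#' @export
makeLabelledDataset <- function(n = 40, kind = c("affinity", "stability"),
                                seed = 1, noiseSd = 0.3, maxKnob = 8) {
  kind <- match.arg(kind)
  rng <- .makeRNG(seed)
  knob <- rep_len(seq_len(maxKnob), n)
  noise <- stats::qnorm(pmin(pmax(rng(n), 1e-12), 1 - 1e-12),
                        sd = noiseSd)
  structures <- vector("list", n)
  ids <- sprintf("%s%03d", ifelse(kind == "affinity", "dim", "mono"),
                 seq_len(n))
  if (kind == "affinity") {
    # contact pairs at the LJ minimum distance: each adds ~ -eps
    label <- -4 - 0.6 * knob + noise
    for (r in seq_len(n)) {
      structures[[r]] <- makeToyDimer(
        residuesPerChain = maxKnob + 2, contacts = knob[r],
        contactDistance = 2 * 1.9, seed = seed + r, id = ids[r])
    }
    labelKind <- "Ba"
  } else {
    label <- 45 + 4 * knob + noise
    for (r in seq_len(n)) {
      structures[[r]] <- makeToyMonomer(
        nResidues = 3 * maxKnob + 2, saltBridges = knob[r],
        seed = seed + r, id = ids[r])
    }
    labelKind <- "Tm"
  }
  names(structures) <- ids
  list(structures = structures,
       manifest = data.frame(id = ids, labelKind = labelKind,
                             label = label, knob = knob,
                             stringsAsFactors = FALSE))
}
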