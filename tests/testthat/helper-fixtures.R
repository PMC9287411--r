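# Shared fixture builders for the test suite.

# Format one fixed-width PDB coordinate record.
pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    occ = 1, alt = "", icode = "", record = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, nm, alt, resid, chain, resno, icode,
          x, y, z, occ, 0)
}

writePdbFixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

# Minimal parameterized structure built directly from coordinate /
# parameter vectors (bypasses file I/O and force-field assignment).
makeStructure <- function(id, chain, resno, resid, elety, xyz,
                          q = 0, epsilon = 0.1, rminHalf = 1.9) {
  n <- length(chain)
  foldbind:::newParamStructure(
    id = id, chain = chain, resno = as.integer(resno), resid = resid,
    elety = elety, xyz = xyz,
    q = rep_len(q, n), epsilon = rep_len(epsilon, n),
    rminHalf = rep_len(rminHalf, n), paramSource = "test")
}

# Two single-atom residues on one chain, a given distance apart.
twoAtomStructure <- function(r, q1 = 0, q2 = 0, eps = 0.1, rmh = 1.9,
                             chain = c("A", "A"), resno = c(1L, 2L)) {
  makeStructure("two", chain, resno, c("GLY", "GLY"), c("CA", "CA"),
                rbind(c(0, 0, 0), c(r, 0, 0)),
                q = c(q1, q2), epsilon = eps, rminHalf = rmh)
}

# Three single-atom residues on one chain; residues 1 and 3 sit `r`
# apart (sequence separation 2, so the intra scope keeps their edge),
# residue 2 is parked far away.
threeAtomStructure <- function(r, q1 = 0, q3 = 0, eps = 0.1, rmh = 1.9) {
  makeStructure("three", rep("A", 3), 1:3, rep("GLY", 3),
                rep("CA", 3),
                rbind(c(0, 0, 0), c(0, 500, 0), c(r, 0, 0)),
                q = c(q1, 0, q3), epsilon = eps, rminHalf = rmh)
}

# Brute-force residue-pair energy over all atom pairs (independent of
# the package's vectorized implementation).
bruteResiduePairEnergy <- function(ai, aj, kind) {
  e <- 0
  for (k in seq_len(nrow(ai))) for (l in seq_len(nrow(aj))) {
    r <- sqrt(sum((c(ai$x[k], ai$y[k], ai$z[k]) -
                     c(aj$x[l], aj$y[l], aj$z[l]))^2))
    e <- e + if (kind == "coulomb") {
      if (is.na(ai$q[k]) || is.na(aj$q[l])) 0 else
        foldbind::coulombPair(ai$q[k], aj$q[l], r)
    } else {
      if (is.na(ai$epsilon[k]) || is.na(aj$epsilon[l])) 0 else
        foldbind::ljPair(ai$epsilon[k], aj$epsilon[l],
                         ai$rminHalf[k], aj$rminHalf[l], r)
    }
  }
  e
}

# Brute-force minimum atom-pair distance between two atom tables.
bruteMinDistance <- function(ai, aj) {
  best <- Inf
  for (k in seq_len(nrow(ai))) for (l in seq_len(nrow(aj))) {
    d <- sqrt((ai$x[k] - aj$x[l])^2 + (ai$y[k] - aj$y[l])^2 +
                (ai$z[k] - aj$z[l])^2)
    best <- min(best, d)
  }
  best
}

# Hand-built EnergyNetwork from explicit edges (i < j, energies).
makeNetwork <- function(i, j, e, nResidues = max(j)) {
  rt <- data.frame(index = seq_len(nResidues),
                   chain = rep("A", nResidues),
                   resno = seq_len(nResidues),
                   resid = rep("GLY", nResidues))
  new("EnergyNetwork", id = "net", kind = "C", scope = "intra",
      edges = data.frame(i = as.integer(i), j = as.integer(j),
                         energy = as.numeric(e),
                         minDist = rep(1, length(i))),
      residues = rt, cutoff = NA_real_)
}

# An analytic image of Re(Z_nm) sampled on the package's polar grid.
realZernikeImage <- function(n, m, G = 101L) {
  u <- (seq_len(G) - 0.5) / G * 2 - 1
  gx <- matrix(u, G, G)
  gy <- matrix(u, G, G, byrow = TRUE)
  r <- sqrt(gx^2 + gy^2)
  phi <- atan2(gy, gx)
  Re(foldbind::radialPoly(n, m, pmin(r, 1)) * exp(1i * m * phi))
}

# Rotate a disk image by `deg` degrees via inverse nearest-neighbour
# lookup on the same grid.
rotateImage <- function(img, deg) {
  G <- nrow(img)
  u <- (seq_len(G) - 0.5) / G * 2 - 1
  gx <- matrix(u, G, G)
  gy <- matrix(u, G, G, byrow = TRUE)
  th <- deg * pi / 180
  sx <- cos(th) * gx + sin(th) * gy
  sy <- -sin(th) * gx + cos(th) * gy
  ix <- pmin(G, pmax(1L, as.integer(round((sx + 1) / 2 * G + 0.5))))
  iy <- pmin(G, pmax(1L, as.integer(round((sy + 1) / 2 * G + 0.5))))
  out <- matrix(img[cbind(as.vector(ix), as.vector(iy))], G, G)
  out
}

# Smooth radially-varying test image used for rotation-invariance
# checks: rotationally non-symmetric but band-limited.
smoothTestImage <- function(G = 101L) {
  u <- (seq_len(G) - 0.5) / G * 2 - 1
  gx <- matrix(u, G, G)
  gy <- matrix(u, G, G, byrow = TRUE)
  r <- sqrt(gx^2 + gy^2)
  phi <- atan2(gy, gx)
  1 + 0.5 * r^2 * cos(2 * phi) + 0.3 * r^3 * sin(3 * phi) +
    0.2 * r * cos(phi)
}
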