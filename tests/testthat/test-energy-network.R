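test_that("the Coulomb kernel matches the CODATA-derived constant", {
  # independent derivation of K = e^2 N_A / (4 pi eps0) in
  # kcal Angstrom / (mol e^2), from 2018 CODATA exact constants
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  NA_ <- 6.02214076e23      # 1/mol
  K <- e^2 * NA_ / (4 * pi * eps0) / 4184 * 1e10
  expect_equal(COULOMB_K, K, tolerance = 1e-6)
  expect_equal(coulombPair(1, -1, 3.320636), -100, tolerance = 1e-4)
  expect_equal(coulombPair(2, 3, 5), COULOMB_K * 6 / 5)
  expect_equal(coulombPair(0, 1, 2), 0)
  # antisymmetric in the sign of one charge
  expect_equal(coulombPair(1, 1, 4.2), -coulombPair(1, -1, 4.2))
  expect_error(coulombPair(1, 1, 0), "positive")
})

test_that("the Lennard-Jones kernel has its minimum at the radius sum", {
  eps <- c(0.12, 0.05); rmh <- c(2.0, 1.7)
  rmin <- sum(rmh)
  expect_equal(ljPair(eps[1], eps[2], rmh[1], rmh[2], rmin),
               -sqrt(prod(eps)))
  # independent transcription: 4 eps ((sigma/r)^12 - (sigma/r)^6) with
  # sigma = Rmin / 2^(1/6)
  r <- 3.0
  sigma <- rmin / 2^(1 / 6)
  expect_equal(ljPair(eps[1], eps[2], rmh[1], rmh[2], r),
               4 * sqrt(prod(eps)) * ((sigma / r)^12 - (sigma / r)^6),
               tolerance = 1e-12)
  expect_equal(ljPair(0, 0.3, 1.9, 1.9, 3), 0)
  # repulsive well inside, attractive outside the minimum
  expect_gt(ljPair(0.1, 0.1, 1.9, 1.9, 2.5), 0)
  expect_lt(ljPair(0.1, 0.1, 1.9, 1.9, 4.0), 0)
  expect_error(ljPair(0.1, 0.1, 1.9, 1.9, -1), "positive")
})

test_that("residue-pair energy equals the brute-force atom-pair double loop", {
  set.seed(7)
  xyz <- matrix(rnorm(8 * 3, sd = 3), ncol = 3)
  xyz[5:8, 1] <- xyz[5:8, 1] + 8
  s <- makeStructure("bf", rep("A", 8), rep(c(1L, 2L), each = 4),
                     rep(c("ALA", "SER"), each = 4),
                     rep(c("N", "CA", "C", "O"), 2), xyz,
                     q = round(rnorm(8, sd = 0.4), 2),
                     epsilon = runif(8, 0.02, 0.2),
                     rminHalf = runif(8, 1.4, 2.2))
  a <- atomTable(s)
  ai <- a[a$resno == 1, ]; aj <- a[a$resno == 2, ]
  expect_equal(residuePairEnergy(ai, aj, "C"),
               bruteResiduePairEnergy(ai, aj, "coulomb"))
  expect_equal(residuePairEnergy(ai, aj, "LJ"),
               bruteResiduePairEnergy(ai, aj, "lj"))
  # symmetric in the residue order
  expect_equal(residuePairEnergy(aj, ai, "C"), residuePairEnergy(ai, aj, "C"))
  expect_equal(residuePairEnergy(aj, ai, "LJ"), residuePairEnergy(ai, aj, "LJ"))
})

test_that("unparameterized atoms are skipped, fully empty pairs error", {
  s <- twoAtomStructure(3, q1 = 1, q2 = -1)
  a <- atomTable(s)
  aBlank <- a
  aBlank$parameterized <- FALSE
  expect_equal(residuePairEnergy(a[1, ], aBlank[2, ], "C"), 0)
  expect_error(residuePairEnergy(aBlank[1, ], aBlank[2, ], "C"),
               "unparameterized")
})

test_that("intra networks exclude self and sequence-adjacent pairs", {
  # 4 residues on a line: allowed intra pairs are (1,3),(1,4),(2,4)
  s <- makeStructure("line", rep("A", 4), 1:4, rep("GLY", 4),
                     rep("CA", 4), cbind(3 * (0:3), 0, 0),
                     q = c(1, 1, 1, 1))
  net <- buildEnergyNetwork(s, kind = "C", scope = "intra")
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 3)
  expect_setequal(paste(ed$i, ed$j), c("1 3", "1 4", "2 4"))
  expect_equal(ed$energy[ed$i == 1 & ed$j == 3], coulombPair(1, 1, 6))
  expect_equal(ed$minDist[ed$i == 1 & ed$j == 4], 9)
})

test_that("inter networks keep cross-chain pairs only and need two chains", {
  sA <- twoAtomStructure(3, q1 = 1, q2 = 1)
  sB <- twoAtomStructure(3, q1 = -1, q2 = -1)
  sB@atoms$y <- sB@atoms$y + 4
  cx <- combineStructures(sA, sB, id = "cx")
  net <- buildEnergyNetwork(cx, kind = "C", scope = "inter")
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 4)  # 2 x 2 cross-chain pairs
  rt <- residueTable(cx)
  expect_true(all(rt$chain[ed$i] != rt$chain[ed$j]))
  expect_error(buildEnergyNetwork(sA, kind = "C", scope = "inter"),
               "two chains")
})

test_that("the distance cutoff keeps only residue pairs within range", {
  s <- makeStructure("cut", rep("A", 4), 1:4, rep("GLY", 4),
                     rep("CA", 4), rbind(c(0, 0, 0), c(0, 500, 0),
                                         c(3.5, 0, 0), c(100, 0, 0)),
                     q = 1)
  net <- buildEnergyNetwork(s, kind = "C", scope = "intra",
                            distanceCutoff = 4)
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 1)
  expect_equal(c(ed$i, ed$j), c(1L, 3L))
  # without the cutoff the far pairs (1,4) and (2,4) are present too
  expect_equal(nrow(edgeTable(buildEnergyNetwork(s, "C", "intra"))), 3)
})

test_that("disulfide-bonded CYS pairs are dropped from LJ networks by default", {
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0),    # CYS 1: CA, SG
               c(0, 500, 0),                # GLY 2 far away
               c(3.8, 0, 0), c(2.0, 0, 0))  # CYS 3: CA, SG (SG-SG 0.2 A... )
  # place SGs 2.05 A apart: SG1 at x=1.8, SG3 at x=3.85
  xyz[5, 1] <- 3.85
  s <- makeStructure("ss", rep("A", 5), c(1L, 1L, 2L, 3L, 3L),
                     c("CYS", "CYS", "GLY", "CYS", "CYS"),
                     c("CA", "SG", "CA", "CA", "SG"), xyz,
                     q = 0, epsilon = 0.1, rminHalf = 1.9)
  lj <- buildEnergyNetwork(s, kind = "LJ", scope = "intra")
  ed <- edgeTable(lj)
  expect_false(any(ed$i == 1 & ed$j == 3))
  # Coulomb keeps the pair by default
  cc <- buildEnergyNetwork(s, kind = "C", scope = "intra")
  expect_true(any(edgeTable(cc)$i == 1 & edgeTable(cc)$j == 3))
  # and the exclusion can be forced off
  lj2 <- buildEnergyNetwork(s, kind = "LJ", scope = "intra",
                            excludeCysBridges = FALSE)
  expect_true(any(edgeTable(lj2)$i == 1 & edgeTable(lj2)$j == 3))
})

test_that("node strengths reproduce hand-computed values on a triangle", {
  # E12 = -1, E13 = -2, E23 = +4
  net <- makeNetwork(i = c(1, 1, 2), j = c(2, 3, 3), e = c(-1, -2, 4))
  s <- nodeStrengths(net)
  expect_equal(s, c(-3, 3, 2))
  expect_equal(sum(s), 2 * totalEnergy(net))
  # an isolated residue gets strength 0
  net4 <- makeNetwork(i = 1, j = 2, e = -5, nResidues = 4)
  expect_equal(nodeStrengths(net4), c(-5, -5, 0, 0))
})

test_that("strength sum equals twice the total energy on random networks", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- sample(nrow(all), sample(3:min(40, nrow(all)), 1))
    net <- makeNetwork(all[pick, 1], all[pick, 2],
                       rnorm(length(pick), sd = 50), nResidues = n)
    expect_equal(sum(nodeStrengths(net)), 2 * totalEnergy(net),
                 tolerance = 1e-10)
  }
})

test_that("total energy supports size normalization and empty networks", {
  net <- makeNetwork(i = c(1, 2), j = c(3, 4), e = c(-6, 2), nResidues = 4)
  expect_equal(totalEnergy(net), -4)
  expect_equal(totalEnergy(net, normalizeBySize = TRUE), -1)
  s <- twoAtomStructure(50)
  empty <- buildEnergyNetwork(s, "C", "intra")  # adjacent pair excluded
  expect_equal(nrow(edgeTable(empty)), 0)
  expect_equal(totalEnergy(empty), 0)
  expect_equal(nodeStrengths(empty), c(0, 0))
})

test_that("energy regions split the axis into the four documented bands", {
  net <- makeNetwork(i = c(1, 1, 1, 2), j = c(2, 3, 4, 3),
                     e = c(-200, -50, 0, 50), nResidues = 4)
  d <- energyDistribution(net)
  expect_equal(unname(d$regionProbabilities),
               c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(d$regionProbabilities), 1)
  expect_equal(names(d$regionProbabilities),
               c("very_strong_favorable", "strong_favorable", "weak",
                 "strong_unfavorable"))
  # boundary values: -100 is very strong favorable, -10 and 10 are weak
  db <- energyDistribution(makeNetwork(c(1, 1, 1), c(2, 3, 4),
                                       c(-100, -10, 10), nResidues = 4))
  expect_equal(unname(db$regionProbabilities["very_strong_favorable"]), 1 / 3)
  expect_equal(unname(db$regionProbabilities["weak"]), 2 / 3)
  # histogram integrates to one
  expect_equal(sum(d$density * diff(d$breaks)), 1)
})

test_that("strong-interaction probability is P(|E| > 10)", {
  net <- makeNetwork(i = c(1, 1, 1, 2), j = c(2, 3, 4, 3),
                     e = c(-12, -5, 1, 15), nResidues = 4)
  d <- energyDistribution(net)
  expect_equal(strongInteractionProbability(d), 0.5)
  expect_equal(strongInteractionProbability(d),
               1 - unname(d$regionProbabilities["weak"]))
})

test_that("high-strength probability counts the favorable tail", {
  expect_equal(highStrengthProbability(c(-50, -5, 0), threshold = -10), 1 / 3)
  expect_equal(highStrengthProbability(c(-50, -20, -5, 0), -10), 0.5)
  expect_error(highStrengthProbability(c(-1, 0), threshold = 5), "negative")
  # pooled-5th-percentile threshold sits below 95% of the data
  set.seed(3)
  s <- rnorm(500, mean = -5, sd = 10)
  thr <- strengthTailThreshold(s)
  expect_equal(mean(s < thr), 0.05, tolerance = 0.02)
})

test_that("networks from pooled lists match per-network pooling", {
  n1 <- makeNetwork(1, 2, -20, nResidues = 2)
  n2 <- makeNetwork(1, 2, 5, nResidues = 2)
  d <- energyDistribution(list(n1, n2))
  expect_setequal(d$energies, c(-20, 5))
  expect_error(energyDistribution(makeNetwork(integer(), integer(),
                                              numeric(), nResidues = 2)),
               "no edge")
})
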