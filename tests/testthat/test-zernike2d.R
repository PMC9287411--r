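test_that("the (n, m) index set has (floor(n/2)+1) entries per order", {
  idx <- zernikeIndices(4L)
  expect_equal(nrow(idx), 1 + 1 + 2 + 2 + 3)
  expect_true(all(idx$m >= 0 & idx$m <= idx$n))
  expect_true(all((idx$n - idx$m) %% 2 == 0))
  # N = 20 gives the 121 invariants of the standard descriptor
  expect_equal(nrow(zernikeIndices(20L)), 121)
})

test_that("radial polynomials match hand-derived closed forms", {
  r <- seq(0, 1, by = 0.125)
  expect_equal(radialPoly(0, 0, r), rep(1, length(r)))
  expect_equal(radialPoly(1, 1, r), r)
  expect_equal(radialPoly(2, 2, r), r^2)
  expect_equal(radialPoly(2, 0, r), 2 * r^2 - 1)
  expect_equal(radialPoly(2, 0, 0.5), -0.5)
  expect_equal(radialPoly(4, 2, r), 4 * r^4 - 3 * r^2)
  expect_equal(radialPoly(4, 0, r), 6 * r^4 - 6 * r^2 + 1)
  # parity and range violations are rejected
  expect_error(radialPoly(3, 2, r))
  expect_error(radialPoly(2, 3, r))
})

test_that("the numerical Gram matrix is diagonal pi/(n+1) at low order", {
  idx <- zernikeIndices(4L)
  Gm <- zernikeGramMatrix(4L, gridSize = 101L)
  target <- diag(pi / (idx$n + 1))
  expect_equal(dim(Gm), c(nrow(idx), nrow(idx)))
  expect_lt(max(Mod(Gm - target)) / (pi / 5), 0.01)
})

test_that("expansion is linear in the image", {
  set.seed(8)
  G <- 51L
  f <- smoothTestImage(G)
  g <- matrix(runif(G * G), G, G)
  cf <- zernikeExpand(f, order = 8L)@coeff
  cg <- zernikeExpand(g, order = 8L)@coeff
  cfg <- zernikeExpand(2 * f - 3 * g, order = 8L)@coeff
  expect_equal(cfg, 2 * cf - 3 * cg, tolerance = 1e-10)
})

test_that("a constant image loads only the c_00 coefficient", {
  G <- 101L
  z <- zernikeExpand(matrix(1, G, G), order = 8L)
  c00 <- z@coeff[z@n == 0 & z@m == 0]
  expect_equal(Mod(c00), 1, tolerance = 0.005)
  expect_lt(max(Mod(z@coeff[!(z@n == 0 & z@m == 0)])), 0.02)
})

test_that("a pure Re(Z_22) image is recovered with |c_22| = 1/2", {
  img <- realZernikeImage(2, 2, 101L)
  z <- zernikeExpand(img, order = 8L)
  expect_equal(Mod(z@coeff[z@n == 2 & z@m == 2]), 0.5, tolerance = 0.01)
  expect_lt(max(Mod(z@coeff[!(z@n == 2 & z@m == 2)])), 0.02)
})

test_that("invariants are unchanged by image rotation", {
  G <- 101L
  img <- smoothTestImage(G)
  z0 <- descriptorValues(zernikeInvariants(zernikeExpand(img, 8L)))
  z1 <- descriptorValues(zernikeInvariants(zernikeExpand(
    rotateImage(img, 37), 8L)))
  expect_lt(max(abs(z1 - z0)) / max(z0), 1e-3)
})

test_that("reconstruction error shrinks as the order grows", {
  G <- 51L
  # off-center Gaussian bump: smooth but not a finite Zernike polynomial
  u <- (seq_len(G) - 0.5) / G * 2 - 1
  gx <- matrix(u, G, G)
  gy <- matrix(u, G, G, byrow = TRUE)
  img <- exp(-((gx - 0.3)^2 + (gy - 0.2)^2) / 0.15)
  err <- vapply(c(2L, 4L, 8L), function(N) {
    rec <- zernikeReconstruct(zernikeExpand(img, N), gridSize = G)
    ok <- is.finite(rec) & is.finite(img)
    sqrt(mean((rec[ok] - img[ok])^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("descriptor distance is a Euclidean metric on the invariants", {
  a <- c(1, 0, 2); b <- c(0, 1, 2); cc <- c(3, 1, 0)
  expect_equal(descriptorDistance(a, a), 0)
  expect_equal(descriptorDistance(a, b), sqrt(2))
  expect_equal(descriptorDistance(a, b), descriptorDistance(b, a))
  expect_lte(descriptorDistance(a, cc),
             descriptorDistance(a, b) + descriptorDistance(b, cc))
  expect_error(descriptorDistance(a, c(1, 2)), "mismatch")
})

test_that("patch extraction keeps exactly the points inside the sphere", {
  set.seed(4)
  pts <- matrix(rnorm(200 * 3, sd = 5), ncol = 3)
  nrm <- pts / sqrt(rowSums(pts^2))
  ctr <- c(1, -1, 0.5)
  p <- extractPatch(list(points = pts, normals = nrm), ctr, radius = 4)
  inside <- sqrt(colSums((t(pts) - ctr)^2)) <= 4
  expect_equal(p@points, pts[inside, , drop = FALSE])
  expect_equal(p@normals, nrm[inside, , drop = FALSE])
  expect_equal(p@center, ctr)
})

test_that("orienting a patch sends its mean normal to the z-axis", {
  fix <- makePatchWithMold(shape = "paraboloid", seed = 3)
  # tilt the patch by an arbitrary rotation
  th <- 0.9
  Q <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tilted <- new("SurfacePatch", points = fix$patch@points %*% t(Q),
                normals = fix$patch@normals %*% t(Q),
                center = as.numeric(fix$patch@center %*% t(Q)),
                radius = fix$patch@radius)
  up <- orientPatch(tilted, "up")
  mn <- colMeans(up$normals)
  expect_equal(mn[1:2] / sqrt(sum(mn^2)), c(0, 0), tolerance = 1e-8)
  expect_gt(mn[3], 0)
  # "down" flips the axis
  dn <- orientPatch(tilted, "down")
  expect_lt(colMeans(dn$normals)[3], 0)
  # the rotation is proper orthogonal
  expect_equal(t(up$rotation) %*% up$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(up$rotation), 1, tolerance = 1e-10)
  # x/y centroid is moved to the origin
  expect_equal(colMeans(up$points)[1:2], c(x = 0, y = 0),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the cone apex of a flat disk sits at the 45-degree height", {
  pts <- cbind(foldbind:::.diskSpiral(400, 5), 0)
  flat <- list(points = pts)
  img <- projectPatch(flat, theta = 45, gridSize = 25L)
  # tan(45 deg) = 1: apex height above the plane equals the disk radius
  expect_equal(img@apexHeight, 5, tolerance = 0.02)
  v <- img@values[img@mask]
  # distances from the apex lie between h (center) and sqrt(h^2 + R^2)
  expect_gte(min(v), 5 - 0.05)
  expect_lte(max(v), sqrt(50) + 0.05)
})

test_that("projection is invariant to translation along the view axis", {
  fix <- makePatchWithMold(shape = "bumpy", seed = 6)
  up <- orientPatch(fix$patch, "up")
  shifted <- up
  shifted$points[, 3] <- shifted$points[, 3] + 7
  i1 <- projectPatch(up); i2 <- projectPatch(shifted)
  expect_equal(i2@values, i1@values, tolerance = 1e-6)
  expect_equal(i2@apexHeight, i1@apexHeight + 7, tolerance = 0.02)
})

test_that("patch descriptors are invariant to in-plane rotation", {
  fix <- makePatchWithMold(shape = "bumpy", seed = 9)
  z0 <- descriptorValues(patchDescriptor(fix$patch, "up"))
  th <- pi / 2  # maps the pixel grid onto itself
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- new("SurfacePatch", points = fix$patch@points %*% t(Q),
             normals = fix$patch@normals %*% t(Q),
             center = as.numeric(fix$patch@center %*% t(Q)),
             radius = fix$patch@radius)
  z1 <- descriptorValues(patchDescriptor(rot, "up"))
  expect_lt(max(abs(z1 - z0)) / max(z0), 1e-6)
})

test_that("a patch is closer to its mold than to decoy patches", {
  fix <- makePatchWithMold(shape = "bumpy", seed = 2, nDecoys = 3)
  zUp <- patchDescriptor(fix$patch, "up")
  dMold <- descriptorDistance(zUp, patchDescriptor(fix$mold, "down"))
  dDecoys <- vapply(fix$decoys, function(d) {
    descriptorDistance(zUp, patchDescriptor(d, "down"))
  }, numeric(1))
  expect_true(all(dMold < dDecoys))
})

test_that("the complementarity scan scores a molded complex and skips misses", {
  fix <- makePatchWithMold(shape = "paraboloid", seed = 5, gap = 2)
  tmpl <- list(points = fix$patch@points, normals = fix$patch@normals)
  lig <- list(points = fix$mold@points, normals = fix$mold@normals)
  scan <- complementarityScan(tmpl, lig, stride = 40L)
  expect_true(is.finite(scan$minimum))
  expect_gt(nrow(scan$distances), 0)
  expect_equal(scan$minimum, min(scan$distances$distance))
  # disjoint partners yield an empty scan
  farLig <- list(points = lig$points + 500, normals = lig$normals)
  empty <- complementarityScan(tmpl, farLig)
  expect_true(is.na(empty$minimum))
  expect_equal(nrow(empty$distances), 0)
})
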