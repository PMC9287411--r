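#' Canonical 2D Zernike index set
#'
#' All (n, m) with 0 <= m <= n <= N and n - m even, ordered by n
#' ascending then m ascending. For N = 20 this yields 121 index pairs.
#'
#' @param order maximum order N.
#' @return data.frame(n, m).
#' @export
zernikeIndices <- function(order) {
  out <- do.call(rbind, lapply(0:order, function(n) {
    m <- seq(n %% 2, n, by = 2)
    data.frame(n = n, m = m)
  }))
  rownames(out) <- NULL
  out
}

#' Radial Zernike polynomial R_nm(r)
#'
#' The finite alternating factorial sum
#' R_nm(r) = sum_k (-1)^k (n-k)! / (k! ((n+m)/2 - k)! ((n-m)/2 - k)!)
#' r^(n-2k), for 0 <= m <= n with n - m even.
#'
#' @param n,m integer indices.
#' @param r radius (vectorized), 0 <= r <= 1.
#' @return numeric vector of values.
#' @export
radialPoly <- function(n, m, r) {
  if (m < 0 || m > n) stop("radialPoly: need 0 <= m <= n")
  if ((n - m) %% 2 != 0) stop("radialPoly: n - m must be even")
  out <- numeric(length(r))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    out <- out + coef * r^(n - 2 * k)
  }
  out
}

# complex basis matrix: rows = sample points (r, phi), cols = canonical
# (n, m) pairs; Z_nm = R_nm(r) exp(i m phi)
.zernikeBasis <- function(r, phi, order) {
  idx <- zernikeIndices(order)
  Z <- matrix(0 + 0i, nrow = length(r), ncol = nrow(idx))
  for (k in seq_len(nrow(idx))) {
    Z[, k] <- radialPoly(idx$n[k], idx$m[k], r) *
      exp(1i * idx$m[k] * phi)
  }
  Z
}

# pixel-center polar coordinates of a G x G grid over [-1,1]^2
.gridPolar <- function(G) {
  cc <- (seq_len(G) - 0.5) / G * 2 - 1
  x <- rep(cc, times = G)
  y <- rep(cc, each = G)
  list(x = x, y = y, r = sqrt(x^2 + y^2), phi = atan2(y, x))
}

# per-pixel integrals of conj(Z_nm) over the pixel-disk intersection,
# by subdividing each pixel subdiv x subdiv; cached per (G, order)
.quadCache <- new.env(parent = emptyenv())

.pixelBasisIntegrals <- function(G, order, subdiv = 4L) {
  key <- paste(G, order, subdiv, sep = "_")
  hit <- .quadCache[[key]]
  if (!is.null(hit)) return(hit)
  cc <- (seq_len(G) - 0.5) / G * 2 - 1
  x <- rep(cc, times = G)
  y <- rep(cc, each = G)
  h <- 1 / G  # half pixel width
  off <- ((seq_len(subdiv) - 0.5) / subdiv * 2 - 1) * h
  M <- nrow(zernikeIndices(order))
  B <- matrix(0 + 0i, G * G, M)
  for (dx in off) for (dy in off) {
    xs <- x + dx; ys <- y + dy
    r <- sqrt(xs^2 + ys^2)
    inside <- r <= 1
    if (any(inside)) {
      Z <- .zernikeBasis(r[inside], atan2(ys, xs)[inside], order)
      B[inside, ] <- B[inside, ] + Conj(Z)
    }
  }
  B <- B * (2 / G)^2 / subdiv^2
  .quadCache[[key]] <- B
  B
}

# pixels with any overlap with the unit disk (positive quadrature area)
.diskMask <- function(G) {
  Re(.pixelBasisIntegrals(G, 0L)[, 1]) > 0
}

#' Numerical Gram matrix of the 2D Zernike basis
#'
#' The pairwise inner products <Z_nm | Z_n'm'> over the unit disk,
#' computed by the package's pixel quadrature on a gridSize x gridSize
#' grid. For an orthogonal basis this reproduces the analytic value
#' pi/(n+1) on the diagonal and 0 elsewhere.
#'
#' @param order maximum order N.
#' @param gridSize quadrature grid size (default 101).
#' @param subdiv per-pixel subdivision of the quadrature (default 4).
#' @return complex M x M matrix in canonical index order.
#' @export
zernikeGramMatrix <- function(order, gridSize = 101L, subdiv = 4L) {
  G <- as.integer(gridSize)
  cc <- (seq_len(G) - 0.5) / G * 2 - 1
  x <- rep(cc, times = G)
  y <- rep(cc, each = G)
  h <- 1 / G
  off <- ((seq_len(subdiv) - 0.5) / subdiv * 2 - 1) * h
  M <- nrow(zernikeIndices(order))
  Gm <- matrix(0 + 0i, M, M)
  for (dx in off) for (dy in off) {
    xs <- x + dx; ys <- y + dy
    r <- sqrt(xs^2 + ys^2)
    inside <- r <= 1
    Z <- .zernikeBasis(r[inside], atan2(ys, xs)[inside], order)
    Gm <- Gm + crossprod(Conj(Z), Z)
  }
  Gm * (2 / G)^2 / subdiv^2
}

#' Expand a patch image in the 2D Zernike basis
#'
#' Approximates c_nm = (n+1)/pi <Z_nm | f> by a Riemann sum over the
#' valid pixels of the unit-disk image, treating the image as piecewise
#' constant per pixel and integrating the basis over each pixel's
#' intersection with the disk (sub-pixel quadrature); masked pixels
#' contribute zero measure.
#'
#' @param image a [PatchImage-class] (or plain numeric matrix, taken as a
#'   fully valid image whose pixels outside the inscribed disk are
#'   masked automatically).
#' @param order maximum expansion order N (default 20).
#' @return a [ZernikeExpansion-class].
#' @export
zernikeExpand <- function(image, order = 20L) {
  im <- .asImageMatrix(image)
  G <- nrow(im$values)
  valid <- as.logical(im$mask) & .diskMask(G)
  if (!any(valid)) stop("cannot expand an all-masked image")
  B <- .pixelBasisIntegrals(G, order)
  f <- as.numeric(im$values)[valid]
  idx <- zernikeIndices(order)
  coeff <- as.complex(((idx$n + 1) / pi) *
                        as.vector(crossprod(B[valid, , drop = FALSE], f)))
  new("ZernikeExpansion", order = as.integer(order),
      n = as.integer(idx$n), m = as.integer(idx$m), coeff = coeff)
}

.asImageMatrix <- function(image) {
  if (is(image, "PatchImage")) {
    return(list(values = image@values, mask = image@mask))
  }
  if (is.matrix(image)) {
    G <- nrow(image)
    mask <- matrix(.diskMask(G), G, G) & is.finite(image)
    return(list(values = image, mask = mask))
  }
  stop("image must be a PatchImage or a numeric matrix")
}

#' Rotation-invariant Zernike descriptors
#'
#' The moduli z_nm = |c_nm| in canonical (n, m) order; invariant under
#' rotations of the image about the disk center. For N = 20 the
#' descriptor has 121 entries.
#'
#' @param expansion a [ZernikeExpansion-class].
#' @return a [ZernikeDescriptor-class].
#' @export
zernikeInvariants <- function(expansion) {
  new("ZernikeDescriptor", order = expansion@order, n = expansion@n,
      m = expansion@m, values = Mod(expansion@coeff))
}

#' Reconstruct an image from its Zernike expansion
#'
#' Evaluates the truncated expansion on a G x G grid. Input images are
#' real, so the negative-m coefficients are the conjugates of the
#' positive-m ones: the real part is taken and positive-m terms doubled.
#'
#' @param expansion a [ZernikeExpansion-class].
#' @param gridSize output grid size G.
#' @return numeric G x G matrix (NA outside the unit disk).
#' @export
zernikeReconstruct <- function(expansion, gridSize = 25L) {
  G <- as.integer(gridSize)
  gp <- .gridPolar(G)
  inside <- gp$r <= 1
  Z <- .zernikeBasis(gp$r[inside], gp$phi[inside], expansion@order)
  w <- ifelse(expansion@m == 0, 1, 2)
  vals <- Re(Z %*% (w * expansion@coeff))
  out <- rep(NA_real_, G * G)
  out[inside] <- as.numeric(vals)
  matrix(out, G, G)
}

#' Euclidean distance between two Zernike descriptors
#'
#' d_ij = sqrt(sum_k (z_i^k - z_j^k)^2); smaller distances mean more
#' similar (for equally-oriented patches) or more complementary (for
#' oppositely-oriented patches) shapes.
#'
#' @param zi,zj [ZernikeDescriptor-class] objects or plain numeric
#'   vectors of equal length.
#' @return non-negative distance.
#' @export
descriptorDistance <- function(zi, zj) {
  vi <- if (is(zi, "ZernikeDescriptor")) zi@values else zi
  vj <- if (is(zj, "ZernikeDescriptor")) zj@values else zj
  if (length(vi) != length(vj)) stop("descriptor length mismatch")
  sqrt(sum((vi - vj)^2))
}

#' Extract a spherical surface patch
#'
#' The patch is the set of surface points within `radius` (default the
#' R_s = 8 Angstrom of the complementarity protocol) of a center point.
#'
#' @param surface a [MolecularSurface-class] (or list with `points`,
#'   `normals` matrices).
#' @param center length-3 numeric center (normally a surface point).
#' @param radius patch radius R_s, Angstrom.
#' @return a [SurfacePatch-class].
#' @export
extractPatch <- function(surface, center, radius = 8) {
  pts <- if (is(surface, "MolecularSurface")) surface@points else surface$points
  nrm <- if (is(surface, "MolecularSurface")) surface@normals else surface$normals
  d2 <- colSums((t(pts) - center)^2)
  sel <- d2 <= radius^2
  new("SurfacePatch", points = pts[sel, , drop = FALSE],
      normals = nrm[sel, , drop = FALSE],
      center = as.numeric(center), radius = radius)
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
.rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis orthogonal to a for the half-turn
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Orient a patch along the z-axis
#'
#' Rigidly rotates the patch so its mean normal points along +z
#' (`direction = "up"`, solvent toward +z) or -z (`"down"`), and
#' translates the point centroid to the origin in x and y. "up"/"down"
#' is what makes two opposing patches comparable for complementarity.
#'
#' @param patch a [SurfacePatch-class].
#' @param direction "up" or "down".
#' @return list with rotated `points`, `normals` and the rotation matrix.
#' @export
orientPatch <- function(patch, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nrow(patch@points) == 0) stop("cannot orient an empty patch")
  mn <- colMeans(patch@normals)
  len <- sqrt(sum(mn^2))
  if (len < 1e-8) stop("degenerate orientation: mean normal is ~ zero")
  target <- if (direction == "up") c(0, 0, 1) else c(0, 0, -1)
  Rm <- .rotationBetween(mn / len, target)
  pts <- patch@points %*% t(Rm)
  nrm <- patch@normals %*% t(Rm)
  ctr <- colMeans(pts)
  pts[, 1] <- pts[, 1] - ctr[1]
  pts[, 2] <- pts[, 2] - ctr[2]
  list(points = pts, normals = nrm, rotation = Rm)
}

# largest apex angle (degrees, from the -z viewing axis) seen from an
# apex at height h above the patch
.maxApexAngle <- function(pts, h) {
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  max(atan2(rho, h - pts[, 3])) * 180 / pi
}

#' Project an oriented patch onto the unit disk
#'
#' Places the apex C on the z-axis (by bisection on its height) so that
#' the largest angle between the z-axis and a secant from C to any patch
#' point is `theta` degrees, then maps each point to the unit disk by
#' dividing its in-plane coordinates by the maximum in-plane radius and
#' bins the points on a G x G pixel grid; each pixel value is the mean
#' distance r from C over its points. Empty interior pixels are filled
#' by the mean of their valid 8-neighbours, iterated to closure;
#' still-empty pixels stay masked.
#'
#' @param oriented output of [orientPatch()] (list with `points`).
#' @param theta cone half-angle, degrees (default 45).
#' @param gridSize image grid size G (default 25).
#' @return a [PatchImage-class].
#' @export
projectPatch <- function(oriented, theta = 45, gridSize = 25L) {
  pts <- oriented$points
  if (nrow(pts) == 0) stop("cannot project an empty patch")
  zmax <- max(pts[, 3])
  lo <- zmax + 1e-4
  hi <- zmax + 100
  if (.maxApexAngle(pts, hi) > theta) {
    stop("projection error: cannot bracket the apex height")
  }
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (.maxApexAngle(pts, mid) > theta) lo <- mid else hi <- mid
  }
  h <- (lo + hi) / 2
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2 + (h - pts[, 3])^2)
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  Rdisk <- max(rho)
  if (Rdisk <= 0) Rdisk <- 1
  u <- pts[, 1] / Rdisk
  v <- pts[, 2] / Rdisk
  G <- as.integer(gridSize)
  ix <- pmin(G, pmax(1L, floor((u + 1) / 2 * G) + 1L))
  iy <- pmin(G, pmax(1L, floor((v + 1) / 2 * G) + 1L))
  vals <- matrix(NA_real_, G, G)
  key <- (iy - 1L) * G + ix
  agg <- tapply(r, key, mean)
  vals[as.integer(names(agg))] <- as.numeric(agg)
  insideDisk <- matrix(.diskMask(G), G, G)
  vals[!insideDisk] <- NA_real_
  vals <- .fillInterior(vals, insideDisk)
  mask <- insideDisk & is.finite(vals)
  vals[!mask] <- NA_real_
  new("PatchImage", values = vals, mask = mask, apexHeight = h,
      theta = theta)
}

# iterated 8-neighbour mean fill of empty pixels inside the disk
.fillInterior <- function(vals, inside) {
  G <- nrow(vals)
  repeat {
    empty <- which(inside & !is.finite(vals), arr.ind = TRUE)
    if (nrow(empty) == 0) break
    filled <- 0L
    newVals <- vals
    for (k in seq_len(nrow(empty))) {
      i <- empty[k, 1]; j <- empty[k, 2]
      ni <- max(1, i - 1):min(G, i + 1)
      nj <- max(1, j - 1):min(G, j + 1)
      nb <- vals[ni, nj]
      nb <- nb[is.finite(nb)]
      if (length(nb)) {
        newVals[i, j] <- mean(nb)
        filled <- filled + 1L
      }
    }
    vals <- newVals
    if (filled == 0L) break
  }
  vals
}

#' Zernike descriptor of a surface patch
#'
#' Convenience wrapper: orient, project and expand a patch, returning
#' its rotation-invariant descriptor.
#'
#' @param patch a [SurfacePatch-class].
#' @param direction "up" or "down".
#' @param order expansion order N.
#' @param theta projection cone half-angle, degrees.
#' @param gridSize image grid size.
#' @return a [ZernikeDescriptor-class].
#' @export
patchDescriptor <- function(patch, direction = "up", order = 20L,
                            theta = 45, gridSize = 25L) {
  img <- projectPatch(orientPatch(patch, direction), theta = theta,
                      gridSize = gridSize)
  zernikeInvariants(zernikeExpand(img, order = order))
}

#' Shape-complementarity scan over a binding region
#'
#' For every (optionally strided) template binding-site point, builds the
#' template patch (oriented "up") and the ligand patch (oriented "down")
#' from the same sphere center of radius `rs`, projects both to unit-disk
#' images, expands them at order N, and records the Euclidean distance
#' between the two invariant vectors. The complex's Zernike score is the
#' minimum of those distances; small scores mean high local shape
#' complementarity.
#'
#' @param templateSurface surface of the template (larger) partner.
#' @param ligandSurface surface of the ligand partner.
#' @param rs patch radius R_s, Angstrom (default 8).
#' @param order Zernike order N (default 20).
#' @param stride subsampling stride over binding-site points.
#' @param cutoff binding-site point distance cutoff, Angstrom (default 3).
#' @param gridSize image grid size.
#' @param minLigandPoints skip centers whose ligand patch has fewer
#'   points than this (default 20); skips are reported in `skipped`.
#' @return list with `distances` (data.frame point/distance), `minimum`
#'   (NA when the binding site is empty) and `skipped` point indices.
#' @export
complementarityScan <- function(templateSurface, ligandSurface, rs = 8,
                                order = 20L, stride = 1L, cutoff = 3,
                                gridSize = 25L, minLigandPoints = 20L) {
  tp <- if (is(templateSurface, "MolecularSurface"))
    templateSurface@points else templateSurface$points
  lp <- if (is(ligandSurface, "MolecularSurface"))
    ligandSurface@points else ligandSurface$points
  site <- bindingSitePoints(tp, lp, cutoff = cutoff)
  if (length(site) == 0) {
    return(list(distances = data.frame(point = integer(),
                                       distance = numeric()),
                minimum = NA_real_, skipped = integer()))
  }
  centers <- site[seq(1, length(site), by = stride)]
  res <- numeric(0); at <- integer(0); skipped <- integer(0)
  for (p in centers) {
    ctr <- tp[p, ]
    tpatch <- extractPatch(templateSurface, ctr, rs)
    lpatch <- extractPatch(ligandSurface, ctr, rs)
    if (nrow(lpatch@points) < minLigandPoints) {
      skipped <- c(skipped, p)
      next
    }
    d <- tryCatch({
      zt <- patchDescriptor(tpatch, "up", order = order,
                            gridSize = gridSize)
      zl <- patchDescriptor(lpatch, "down", order = order,
                            gridSize = gridSize)
      descriptorDistance(zt, zl)
    }, error = function(e) NA_real_)
    if (is.na(d)) { skipped <- c(skipped, p); next }
    res <- c(res, d); at <- c(at, p)
  }
  list(distances = data.frame(point = at, distance = res),
       minimum = if (length(res)) min(res) else NA_real_,
       skipped = skipped)
}
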