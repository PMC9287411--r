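#' Stratify records by melting temperature or binding affinity
#'
#' Assigns each record to the printed experimental ranges. Melting
#' temperature (label kind "Tm", Celsius): very low (< 55), low
#' [55, 60], high (60, 70], very high (> 70). Binding affinity
#' (label kind "Ba" = log10 Kd): very high affinity (< -9), high
#' [-9, -8], medium (-8, -7], low (-7, -5], very low (> -5). Shared
#' endpoints are resolved right-closed, so every value lands in exactly
#' one stratum.
#'
#' @param records data.frame with columns `labelKind` ("Tm" or "Ba") and
#'   `label`; rows with missing labels are dropped with a message.
#' @return `records` with a `stratum` column added.
#' @export
stratifyRecords <- function(records) {
  drop <- is.na(records$label)
  if (any(drop)) {
    message("dropping ", sum(drop), " record(s) with missing labels")
    records <- records[!drop, , drop = FALSE]
  }
  stratum <- character(nrow(records))
  tm <- records$labelKind == "Tm"
  ba <- records$labelKind == "Ba"
  x <- records$label
  stratum[tm] <- c("very_low", "low", "high", "very_high")[
    as.integer(cut(x[tm], c(-Inf, 55 - 1e-9, 60, 70, Inf),
                   right = TRUE))]
  stratum[ba] <- c("very_high_affinity", "high_affinity",
                   "medium_affinity", "low_affinity",
                   "very_low_affinity")[
    as.integer(cut(x[ba], c(-Inf, -9 - 1e-9, -8, -7, -5, Inf),
                   right = TRUE))]
  records$stratum <- stratum
  records
}

#' Pearson correlation with significance
#'
#' Standard Pearson r with a two-sided t-test p-value; records the
#' sample size alongside. No multiple-testing correction is applied.
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return list(r, p, n).
#' @export
correlateQuantity <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Run the fold-stability study on a monomer dataset
#'
#' For each monomer: intramolecular Coulomb and Lennard-Jones networks,
#' size-normalized totals, contact-filtered (4 Angstrom) Coulomb
#' distributions and node strengths. Reports the correlations of the
#' totals with T_m, the per-stratum Coulomb distributions, the
#' strong-interaction probability against the stratum mean T_m (with its
#' Pearson r when >= 3 strata), and high-strength tail probabilities per
#' stratum.
#'
#' @param dataset list with `structures` (named list of single-chain
#'   [ParamStructure-class]) and `manifest` (data.frame id, labelKind =
#'   "Tm", label).
#' @param distributionCutoff contact cutoff for distributions, Angstrom.
#' @return a study-report list; structures failing parameterization are
#'   listed under `excluded`.
#' @export
runStabilityStudy <- function(dataset, distributionCutoff = 4) {
  man <- dataset$manifest
  if (is.null(man) || nrow(man) == 0) stop("empty manifest")
  perStructure <- list(); excluded <- character(0)
  for (k in seq_len(nrow(man))) {
    id <- man$id[k]
    s <- dataset$structures[[id]]
    res <- tryCatch({
      netC <- buildEnergyNetwork(s, "C", "intra")
      netLJ <- buildEnergyNetwork(s, "LJ", "intra")
      netCcut <- buildEnergyNetwork(s, "C", "intra",
                                    distanceCutoff = distributionCutoff)
      list(totalC = totalEnergy(netC, normalizeBySize = TRUE),
           totalLJ = totalEnergy(netLJ, normalizeBySize = TRUE),
           cutNet = netCcut, strengths = nodeStrengths(netCcut))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("excluding ", id, ": ", conditionMessage(res))
      excluded <- c(excluded, id)
      next
    }
    perStructure[[id]] <- res
  }
  if (length(perStructure) == 0) stop("empty report: no usable structures")
  man <- stratifyRecords(man[man$id %in% names(perStructure), ,
                             drop = FALSE])
  totC <- vapply(perStructure[man$id], `[[`, 0, "totalC")
  totLJ <- vapply(perStructure[man$id], `[[`, 0, "totalLJ")
  report <- list(
    totals = data.frame(id = man$id, label = man$label,
                        stratum = man$stratum, totalC = totC,
                        totalLJ = totLJ),
    excluded = excluded)
  report$corTotalC <- tryCatch(correlateQuantity(totC, man$label),
                               error = function(e) NULL)
  report$corTotalLJ <- tryCatch(correlateQuantity(totLJ, man$label),
                                error = function(e) NULL)
  report <- c(report, .stratumStats(perStructure, man))
  report
}

# shared per-stratum machinery: pooled distributions, strong-interaction
# probability vs stratum mean label, strength-tail probabilities
.stratumStats <- function(perStructure, man) {
  strata <- split(man$id, man$stratum)
  allStrengths <- unlist(lapply(perStructure, `[[`, "strengths"))
  thr <- strengthTailThreshold(allStrengths)
  rows <- lapply(names(strata), function(st) {
    ids <- strata[[st]]
    nets <- lapply(perStructure[ids], `[[`, "cutNet")
    nets <- nets[vapply(nets, function(n) nrow(n@edges) > 0, TRUE)]
    if (length(nets) == 0) return(NULL)
    dist <- energyDistribution(nets)
    s <- unlist(lapply(perStructure[ids], `[[`, "strengths"))
    data.frame(stratum = st, n = length(ids),
               meanLabel = mean(man$label[man$id %in% ids]),
               strongProb = strongInteractionProbability(dist),
               # no favorable tail exists when the pooled 5th percentile
               # is not negative (e.g. charge-neutral structures)
               highStrengthProb = if (thr < 0)
                 highStrengthProbability(s, thr) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  out <- list(strataTable = tab, strengthThreshold = thr)
  if (!is.null(tab) && nrow(tab) >= 3) {
    out$corStrongProb <- tryCatch(
      correlateQuantity(tab$strongProb, tab$meanLabel),
      error = function(e) NULL)
  }
  out
}

#' Run the binding-affinity study on a dimer dataset
#'
#' For each complex: intermolecular Coulomb and Lennard-Jones networks
#' (raw and size-normalized totals), contact-filtered distributions and
#' strengths, interface residues, composition and hydropathy, and
#' optionally the minimum Zernike complementarity distance. Reports the
#' correlations of totals (and Zernike minima) with B_a, stratified
#' distribution statistics, per-stratum interface composition, and the
#' hydropathy-windowed correlation curve of LJ totals vs B_a.
#'
#' @param dataset list with `structures` (named list of
#'   [makeToyDimer()]-style triples or two-chain complexes) and
#'   `manifest` (id, labelKind = "Ba", label).
#' @param distributionCutoff contact cutoff for distributions, Angstrom.
#' @param hydropathyScale named H vector.
#' @param windowWidth hydropathy window width (default 0.6).
#' @param includeZernike run the per-complex complementarity scan.
#' @param zernikeStride stride for the scan.
#' @param surfaceDensity dot-surface density for the scan.
#' @return a study-report list.
#' @export
runAffinityStudy <- function(dataset, distributionCutoff = 4,
                             hydropathyScale = loadHydropathyScale(),
                             windowWidth = 0.6, includeZernike = FALSE,
                             zernikeStride = 4L, surfaceDensity = 2) {
  man <- dataset$manifest
  if (is.null(man) || nrow(man) == 0) stop("empty manifest")
  perStructure <- list(); excluded <- character(0)
  for (k in seq_len(nrow(man))) {
    id <- man$id[k]
    entry <- dataset$structures[[id]]
    cx <- if (is(entry, "ParamStructure")) entry else entry$complex
    res <- tryCatch({
      netC <- buildEnergyNetwork(cx, "C", "inter")
      netLJ <- buildEnergyNetwork(cx, "LJ", "inter")
      netCcut <- buildEnergyNetwork(cx, "C", "inter",
                                    distanceCutoff = distributionCutoff)
      iface <- interfaceResidues(cx)
      hAB <- tryCatch(
        interfaceHydropathy(cx, scale = hydropathyScale),
        error = function(e) c(NA_real_, NA_real_))
      out <- list(totalC = totalEnergy(netC),
                  totalLJ = totalEnergy(netLJ),
                  totalCnorm = totalEnergy(netC, normalizeBySize = TRUE),
                  totalLJnorm = totalEnergy(netLJ, normalizeBySize = TRUE),
                  cutNet = netCcut, strengths = nodeStrengths(netCcut),
                  ifaceResid = unlist(lapply(iface, `[[`, "resid")),
                  hA = hAB[[1]], hB = hAB[[2]])
      if (includeZernike && !is(entry, "ParamStructure")) {
        chains <- list(entry$chainA, entry$chainB)
        sizes <- vapply(chains, residueCount, 1L)
        tmpl <- if (sizes[2] > sizes[1]) 2L else 1L  # tie -> file order
        surfT <- computeSurface(chains[[tmpl]], density = surfaceDensity)
        surfL <- computeSurface(chains[[3L - tmpl]],
                                density = surfaceDensity)
        scan <- complementarityScan(surfT, surfL,
                                    stride = zernikeStride)
        out$zernikeMin <- scan$minimum
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("excluding ", id, ": ", conditionMessage(res))
      excluded <- c(excluded, id)
      next
    }
    perStructure[[id]] <- res
  }
  if (length(perStructure) == 0) stop("empty report: no usable complexes")
  man <- stratifyRecords(man[man$id %in% names(perStructure), ,
                             drop = FALSE])
  g <- function(f) vapply(perStructure[man$id], function(x)
    if (is.null(x[[f]])) NA_real_ else x[[f]], 0)
  totals <- data.frame(id = man$id, label = man$label,
                       stratum = man$stratum, totalC = g("totalC"),
                       totalLJ = g("totalLJ"),
                       totalCnorm = g("totalCnorm"),
                       totalLJnorm = g("totalLJnorm"),
                       hA = g("hA"), hB = g("hB"))
  if (includeZernike) totals$zernikeMin <- g("zernikeMin")
  report <- list(totals = totals, excluded = excluded)
  safeCor <- function(x, y) tryCatch(correlateQuantity(x, y),
                                     error = function(e) NULL)
  report$corTotalC <- safeCor(totals$totalC, man$label)
  report$corTotalLJ <- safeCor(totals$totalLJ, man$label)
  report$corTotalCnorm <- safeCor(totals$totalCnorm, man$label)
  report$corTotalLJnorm <- safeCor(totals$totalLJnorm, man$label)
  if (includeZernike) {
    report$corZernike <- safeCor(totals$zernikeMin, man$label)
  }
  report <- c(report, .stratumStats(perStructure, man))
  # interface composition per stratum
  comp <- lapply(split(man$id, man$stratum), function(ids) {
    pool <- unlist(lapply(perStructure[ids], `[[`, "ifaceResid"))
    if (length(pool) == 0) return(NULL)
    aaFrequencies(pool)
  })
  report$interfaceComposition <- comp[!vapply(comp, is.null, TRUE)]
  # hydropathy-windowed correlation curve of LJ totals vs Ba
  hrec <- data.frame(id = man$id, label = man$label,
                     totalLJ = totals$totalLJ, hA = totals$hA,
                     hB = totals$hB)
  hrec <- hrec[is.finite(hrec$hA) & is.finite(hrec$hB), , drop = FALSE]
  if (nrow(hrec) >= 3) {
    centers <- seq(min(c(hrec$hA, hrec$hB)), max(c(hrec$hA, hrec$hB)),
                   by = windowWidth / 3)
    curve <- lapply(centers, function(cc) {
      sub <- hydropathyWindowSelect(hrec, cc, width = windowWidth)
      if (nrow(sub) < 3) return(NULL)
      cr <- tryCatch(correlateQuantity(sub$totalLJ, sub$label),
                     error = function(e) NULL)
      if (is.null(cr)) return(NULL)
      data.frame(center = cc, r = cr$r, p = cr$p, n = cr$n)
    })
    curve <- do.call(rbind, curve)
    report$hydropathyWindowCurve <- curve
  }
  report
}
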