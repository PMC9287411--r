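#' Load a hydropathy scale
#'
#' Reads a TSV with columns `res` (3-letter code) and `H`. Two scales are
#' bundled: `"bundled"` — a synthetic water-affinity scale oriented with
#' H = 0.0 at the purely hydrophobic end and higher H more hydrophilic
#' (an affine rescale of Kyte-Doolittle onto [0, 3]; the 1.3/1.7 class
#' thresholds are calibrated against it) — and `"kyte-doolittle"`, the
#' raw Kyte-Doolittle indices (opposite orientation: higher = more
#' hydrophobic).
#'
#' @param path a TSV path, `"bundled"` or `"kyte-doolittle"`.
#' @return named numeric vector of H over the 20 standard residues.
#' @export
loadHydropathyScale <- function(path = "bundled") {
  file <- switch(path,
    "bundled" = system.file("extdata", "water_affinity_synthetic.tsv",
                            package = "foldbind"),
    "kyte-doolittle" = system.file("extdata", "kyte_doolittle.tsv",
                                   package = "foldbind"),
    path)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  h <- stats::setNames(tab$H, tab$res)
  missing <- setdiff(STANDARD_AA, names(h))
  if (length(missing)) {
    stop("hydropathy scale missing residues: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(h))) stop("hydropathy scale holds non-finite values")
  h
}

#' Amino-acid composition profile
#'
#' Relative abundances of the 20 standard residues over a pooled residue
#' set (pooled counts across structures, not per-structure averages).
#'
#' @param residueNames character vector (or list of vectors) of 3-letter
#'   residue codes, e.g. the `resid` column of residue-table subsets.
#' @return named numeric 20-vector summing to 1.
#' @export
aaFrequencies <- function(residueNames) {
  rn <- unlist(residueNames)
  if (length(rn) == 0) stop("empty residue pool")
  bad <- setdiff(unique(rn), STANDARD_AA)
  if (length(bad)) stop("non-standard residues in pool: ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(rn, levels = STANDARD_AA))
  stats::setNames(as.numeric(counts) / length(rn), STANDARD_AA)
}

#' Mean interface hydropathy of a complex
#'
#' Selects each chain's interface residues (any atom within `cutoff`
#' Angstrom of the partner) and averages their hydropathy indices,
#' yielding one value per chain.
#'
#' @param complex a two-chain [ParamStructure-class].
#' @param scale named H vector from [loadHydropathyScale()].
#' @param cutoff interface contact distance, Angstrom.
#' @return named numeric length-2 vector (one mean H per chain).
#' @export
interfaceHydropathy <- function(complex, scale = loadHydropathyScale(),
                                cutoff = 4) {
  iface <- interfaceResidues(complex, cutoff = cutoff)
  if (any(vapply(iface, nrow, 1L) == 0)) {
    stop("empty interface: no residue within ", cutoff, " A of the partner")
  }
  vapply(iface, function(rt) mean(scale[rt$resid]), numeric(1))
}

#' Select complexes inside a hydropathy window
#'
#' Keeps the complexes whose interface hydropathy on BOTH chains falls
#' within [center - width/2, center + width/2]; used to sweep
#' overlapping windows (default width 0.6) over the H axis.
#'
#' @param records data.frame with columns `hA` and `hB` (per-chain mean
#'   interface H).
#' @param center window center.
#' @param width window width (default 0.6).
#' @return the selected subset of `records`.
#' @export
hydropathyWindowSelect <- function(records, center, width = 0.6) {
  lo <- center - width / 2
  hi <- center + width / 2
  keep <- records$hA >= lo & records$hA <= hi &
    records$hB >= lo & records$hB <= hi
  records[keep, , drop = FALSE]
}

#' Hydropathy class of a binding region
#'
#' Classifies a mean interface hydropathy as mainly hydrophobic
#' (H < `lower`), intermediate, or mainly hydrophilic (H > `upper`);
#' defaults 1.3 and 1.7 are calibrated for the bundled scale.
#'
#' @param h mean hydropathy value(s).
#' @param lower,upper class thresholds.
#' @return character vector in {"hydrophobic", "intermediate",
#'   "hydrophilic"}.
#' @export
hydropathyClass <- function(h, lower = 1.3, upper = 1.7) {
  ifelse(h < lower, "hydrophobic",
         ifelse(h > upper, "hydrophilic", "intermediate"))
}
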