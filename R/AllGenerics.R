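#' Accessors for foldbind S4 objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setGeneric("residueCount", function(x) standardGeneric("residueCount"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))

#' @rdname accessors
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))

#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname accessors
#' @export
setGeneric("parameterReport", function(x) standardGeneric("parameterReport"))

setMethod("atomTable", "ParamStructure", function(x) x@atoms)
setMethod("structureId", "ParamStructure", function(x) x@id)
setMethod("parameterReport", "ParamStructure", function(x) x@paramReport)

setMethod("residueTable", "ParamStructure", function(x) {
  a <- x@atoms
  key <- !duplicated(paste(a$chain, a$resno))
  data.frame(index = seq_len(sum(key)), chain = a$chain[key],
             resno = a$resno[key], resid = a$resid[key],
             stringsAsFactors = FALSE)
})

setMethod("residueCount", "ParamStructure", function(x) {
  nrow(residueTable(x))
})

setMethod("residueTable", "EnergyNetwork", function(x) x@residues)
setMethod("edgeTable", "EnergyNetwork", function(x) x@edges)
setMethod("structureId", "EnergyNetwork", function(x) x@id)
setMethod("residueCount", "EnergyNetwork", function(x) nrow(x@residues))

setMethod("surfacePoints", "MolecularSurface", function(x) x@points)
setMethod("surfaceNormals", "MolecularSurface", function(x) x@normals)
setMethod("surfacePoints", "SurfacePatch", function(x) x@points)
setMethod("surfaceNormals", "SurfacePatch", function(x) x@normals)

setMethod("descriptorValues", "ZernikeDescriptor", function(x) x@values)

setMethod("show", "ParamStructure", function(object) {
  rt <- residueTable(object)
  cat("ParamStructure:", object@id, "\n",
      " chains:", paste(unique(rt$chain), collapse = ", "),
      " residues:", nrow(rt), " atoms:", nrow(object@atoms), "\n",
      " parameterized:", sum(object@atoms$parameterized), "/",
      nrow(object@atoms), "atoms",
      if (nzchar(object@paramSource)) paste0(" (", object@paramSource, ")"),
      "\n")
})

setMethod("show", "ForceFieldTable", function(object) {
  cat("ForceFieldTable:", nrow(object@params), "entries,",
      length(unique(object@params$res)), "residue types [",
      object@source, "]\n")
})

setMethod("show", "EnergyNetwork", function(object) {
  cat("EnergyNetwork:", object@id, sprintf("[%s, %s]", object@kind,
      object@scope), "\n  residues:", nrow(object@residues),
      " edges:", nrow(object@edges),
      if (!is.na(object@cutoff)) sprintf(" cutoff: %.1f A", object@cutoff),
      "\n")
})

setMethod("show", "MolecularSurface", function(object) {
  cat("MolecularSurface:", nrow(object@points), "points,",
      sprintf("density %.1f pts/A^2, probe %.1f A\n",
              object@density, object@probe))
})

setMethod("show", "SurfacePatch", function(object) {
  cat("SurfacePatch:", nrow(object@points), "points, R_s =",
      object@radius, "A\n")
})

setMethod("show", "PatchImage", function(object) {
  cat("PatchImage:", nrow(object@values), "x", ncol(object@values),
      "grid,", sum(object@mask), "valid pixels, apex at",
      round(object@apexHeight, 2), "A\n")
})

setMethod("show", "ZernikeExpansion", function(object) {
  cat("ZernikeExpansion: order", object@order, "with",
      length(object@coeff), "coefficients\n")
})

setMethod("show", "ZernikeDescriptor", function(object) {
  cat("ZernikeDescriptor: order", object@order, "with",
      length(object@values), "rotation invariants\n")
})
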