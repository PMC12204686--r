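# Accessor generics: user code never touches slots directly.

#' @name accessors
#' @title Accessors for spiroscan S4 containers
#' @param object an S4 object from this package.
#' @description Slot access for `SpiroStructure`, `Tunnel`,
#'   `LigandTrajectory`, `CompositionProfile`, `EnrichmentTable`,
#'   `MsaAlignment`, `SasaResult`, `ResidenceResult` and `RankTestResult`.
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setMethod("structureId", "SpiroStructure", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("atomData", function(object) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setMethod("atomData", "SpiroStructure", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("chainIds", function(object) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setMethod("chainIds", "SpiroStructure", function(object) sort(unique(object@atoms$chain)))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "SpiroStructure", function(object) nrow(object@atoms))

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(object) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setMethod("atomCoords", "SpiroStructure", function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  rownames(m) <- object@atoms$serial
  m
})

#' @rdname accessors
#' @export
setGeneric("residueIds", function(object) standardGeneric("residueIds"))
#' @rdname accessors
#' @export
setMethod("residueIds", "SpiroStructure", function(object) {
  a <- object@atoms
  unique(residueKey(a$chain, a$resnum, a$icode))
})

#' Residue-level table of a structure
#'
#' One row per residue with its key, chain, number, insertion code, 3-letter
#' name, heteroatom flag and whether it is one of the 20 standard amino acids.
#'
#' @param object a `SpiroStructure`.
#' @return data.frame with columns key, chain, resnum, icode, resname,
#'   hetero, standard.
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))
#' @rdname residueTable
#' @export
setMethod("residueTable", "SpiroStructure", function(object) {
  a <- object@atoms
  key <- residueKey(a$chain, a$resnum, a$icode)
  first <- !duplicated(key)
  data.frame(
    key = key[first], chain = a$chain[first], resnum = a$resnum[first],
    icode = a$icode[first], resname = a$resname[first],
    hetero = a$hetero[first],
    standard = a$resname[first] %in% names(AA3),
    stringsAsFactors = FALSE, row.names = NULL
  )
})

#' @rdname accessors
#' @export
setGeneric("tunnelCenterline", function(object) standardGeneric("tunnelCenterline"))
#' @rdname accessors
#' @export
setMethod("tunnelCenterline", "Tunnel", function(object) object@centerline)

#' @rdname accessors
#' @export
setGeneric("tunnelRadii", function(object) standardGeneric("tunnelRadii"))
#' @rdname accessors
#' @export
setMethod("tunnelRadii", "Tunnel", function(object) object@radii)

#' @rdname accessors
#' @export
setGeneric("tunnelFound", function(object) standardGeneric("tunnelFound"))
#' @rdname accessors
#' @export
setMethod("tunnelFound", "Tunnel", function(object) object@found)

#' Arc length of a tunnel centerline
#' @param object a `Tunnel`.
#' @return length in Angstrom (0 for a no-tunnel result).
#' @export
setGeneric("tunnelLength", function(object) standardGeneric("tunnelLength"))
#' @rdname tunnelLength
#' @export
setMethod("tunnelLength", "Tunnel", function(object) {
  if (!object@found || nrow(object@centerline) < 2L) return(0)
  sum(sqrt(rowSums(diff(object@centerline)^2)))
})

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "LigandTrajectory", function(object) length(object@ligandCoords))

#' @rdname accessors
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setMethod("timeStep", "LigandTrajectory", function(object) object@dt)

#' @rdname accessors
#' @export
setGeneric("ligandCoords", function(object) standardGeneric("ligandCoords"))
#' @rdname accessors
#' @export
setMethod("ligandCoords", "LigandTrajectory", function(object) object@ligandCoords)

#' Protein coordinates for a given frame
#' @param object a `LigandTrajectory`.
#' @param frame 1-based frame index.
#' @return k x 3 coordinate matrix.
#' @export
setGeneric("proteinCoords", function(object, frame = 1L) standardGeneric("proteinCoords"))
#' @rdname proteinCoords
#' @export
setMethod("proteinCoords", "LigandTrajectory", function(object, frame = 1L) {
  if (length(object@proteinCoords) == 1L) object@proteinCoords[[1L]]
  else object@proteinCoords[[frame]]
})

#' @rdname accessors
#' @export
setGeneric("aaCounts", function(object) standardGeneric("aaCounts"))
#' @rdname accessors
#' @export
setMethod("aaCounts", "CompositionProfile", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("aaFrequencies", function(object) standardGeneric("aaFrequencies"))
#' @rdname accessors
#' @export
setMethod("aaFrequencies", "CompositionProfile", function(object) object@frequencies)

#' @rdname accessors
#' @export
setGeneric("log2FoldChange", function(object) standardGeneric("log2FoldChange"))
#' @rdname accessors
#' @export
setMethod("log2FoldChange", "EnrichmentTable", function(object) object@log2fc)

#' @rdname accessors
#' @export
setGeneric("msaNames", function(object) standardGeneric("msaNames"))
#' @rdname accessors
#' @export
setMethod("msaNames", "MsaAlignment", function(object) object@names)

#' @rdname accessors
#' @export
setGeneric("msaMatrix", function(object) standardGeneric("msaMatrix"))
#' @rdname accessors
#' @export
setMethod("msaMatrix", "MsaAlignment", function(object) object@seqs)

#' @rdname accessors
#' @export
setGeneric("perAtomSasa", function(object) standardGeneric("perAtomSasa"))
#' @rdname accessors
#' @export
setMethod("perAtomSasa", "SasaResult", function(object) object@perAtom)

#' @rdname accessors
#' @export
setGeneric("totalSasa", function(object) standardGeneric("totalSasa"))
#' @rdname accessors
#' @export
setMethod("totalSasa", "SasaResult", function(object) object@total)

#' @rdname accessors
#' @export
setGeneric("residenceTimeNs", function(object) standardGeneric("residenceTimeNs"))
#' @rdname accessors
#' @export
setMethod("residenceTimeNs", "ResidenceResult", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))
#' @rdname accessors
#' @export
setMethod("isCensored", "ResidenceResult", function(object) object@censored)

#' @rdname accessors
#' @export
setGeneric("escapeFrame", function(object) standardGeneric("escapeFrame"))
#' @rdname accessors
#' @export
setMethod("escapeFrame", "ResidenceResult", function(object) object@escapeFrame)

#' @rdname accessors
#' @export
setGeneric("uStatistic", function(object) standardGeneric("uStatistic"))
#' @rdname accessors
#' @export
setMethod("uStatistic", "RankTestResult", function(object) object@U)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "RankTestResult", function(object) object@pTwoSided)

#' @rdname accessors
#' @export
setGeneric("lengthTable", function(object) standardGeneric("lengthTable"))
#' @rdname accessors
#' @export
setMethod("lengthTable", "LengthDataset", function(object) {
  data.frame(group = object@group, length_nm = object@length_nm,
             conformation = object@conformation, stringsAsFactors = FALSE)
})
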