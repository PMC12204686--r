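# Central S4 containers. Atom records live in a single data.frame per
# structure (one row per atom) rather than nested residue objects: every
# downstream computation is a vectorised scan over atoms, and residue
# identity is carried on each row (chain, resnum, icode, resname).

#' SpiroStructure: a macromolecular structure
#'
#' Holds all ATOM/HETATM records of a parsed PDB or mmCIF file (first model),
#' with author residue numbering preserved and one row per atom. Alternate
#' locations are reduced to the highest-occupancy conformer at read time.
#'
#' @slot id character identifier (file stem or supplied id).
#' @slot atoms data.frame with columns serial, name, resname, chain, resnum,
#'   icode, x, y, z, occ, element, vdw, hetero.
#' @slot metadata free-form provenance list.
#' @export
setClass("SpiroStructure",
  representation(id = "character", atoms = "data.frame", metadata = "list"),
  prototype(id = NA_character_, metadata = list())
)

setValidity("SpiroStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "chain", "resnum", "icode",
            "x", "y", "z", "occ", "element", "vdw", "hetero")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (!all(a$vdw > 0)) return("non-positive van der Waals radius")
  TRUE
})

#' SasaResult: per-atom and total solvent-accessible surface area
#'
#' @slot perAtom numeric vector of areas in squared Angstrom, named by atom serial.
#' @slot total total area in squared Angstrom.
#' @slot probeRadius probe radius in Angstrom.
#' @slot nPoints number of quadrature points per atom.
#' @export
setClass("SasaResult",
  representation(perAtom = "numeric", total = "numeric",
                 probeRadius = "numeric", nPoints = "integer")
)

setValidity("SasaResult", function(object) {
  if (any(object@perAtom < 0)) return("negative per-atom area")
  tot <- sum(object@perAtom)
  if (tot > 0 && abs(tot - object@total) > 1e-6 * tot)
    return("total does not equal sum of per-atom areas")
  TRUE
})

#' Tunnel: a probe-accessible channel through a structure
#'
#' @slot centerline numeric matrix (n x 3) of ordered centerline points.
#' @slot radii numeric clearance radius at each centerline point (Angstrom).
#' @slot gridSpacing grid spacing used by the finder (Angstrom).
#' @slot probeRadius probe radius (Angstrom).
#' @slot found logical; FALSE encodes a "no tunnel" result.
#' @export
setClass("Tunnel",
  representation(centerline = "matrix", radii = "numeric",
                 gridSpacing = "numeric", probeRadius = "numeric",
                 found = "logical")
)

setValidity("Tunnel", function(object) {
  if (!object@found) return(TRUE)
  n <- nrow(object@centerline)
  if (n < 1L) return("found tunnel with empty centerline")
  if (length(object@radii) != n) return("radii length != centerline length")
  if (n > 1L) {
    steps <- sqrt(rowSums(diff(object@centerline)^2))
    if (any(steps > sqrt(3) * object@gridSpacing + 1e-9))
      return("consecutive centerline points further apart than sqrt(3) * grid spacing")
  }
  if (any(object@radii < object@probeRadius - 1e-9))
    return("tunnel radius below probe radius")
  TRUE
})

#' LigandTrajectory: per-frame ligand and protein coordinates
#'
#' @slot dt time per frame in nanoseconds.
#' @slot ligandCoords list of per-frame ligand coordinate matrices (k x 3).
#' @slot proteinCoords list of protein coordinate matrices; length 1 means a
#'   static protein reused for every frame.
#' @slot ligandLabels,proteinLabels character atom labels for selections.
#' @export
setClass("LigandTrajectory",
  representation(dt = "numeric", ligandCoords = "list", proteinCoords = "list",
                 ligandLabels = "character", proteinLabels = "character")
)

setValidity("LigandTrajectory", function(object) {
  if (length(object@ligandCoords) < 1L) return("need at least one frame")
  if (object@dt <= 0) return("dt must be positive")
  nl <- vapply(object@ligandCoords, nrow, 1L)
  if (length(unique(nl)) != 1L) return("inconsistent ligand atom counts across frames")
  np <- vapply(object@proteinCoords, nrow, 1L)
  if (length(unique(np)) != 1L) return("inconsistent protein atom counts across frames")
  if (!length(object@proteinCoords) %in% c(1L, length(object@ligandCoords)))
    return("proteinCoords must have length 1 or n_frames")
  TRUE
})

#' ResidenceResult: ligand residence time before escape to solvent
#'
#' @slot time residence time in nanoseconds (censoring time when censored).
#' @slot censored logical; TRUE when no sustained escape occurred.
#' @slot escapeFrame 1-based first frame of the sustained excursion, NA when censored.
#' @export
setClass("ResidenceResult",
  representation(time = "numeric", censored = "logical", escapeFrame = "integer")
)

setValidity("ResidenceResult", function(object) {
  if (object@censored && !is.na(object@escapeFrame))
    return("censored result must not carry an escape frame")
  TRUE
})

#' CompositionProfile: 20-symbol amino-acid composition
#'
#' @slot counts named integer vector over the 20 one-letter codes.
#' @slot frequencies named numeric vector; sums to 1 when counts > 0.
#' @slot nonStandard number of residues excluded as non-standard.
#' @export
setClass("CompositionProfile",
  representation(counts = "integer", frequencies = "numeric", nonStandard = "integer")
)

setValidity("CompositionProfile", function(object) {
  if (!identical(names(object@counts), unname(AA3))) return("counts must cover the 20 amino acids in order")
  tot <- sum(object@counts)
  if (tot > 0 && abs(sum(object@frequencies) - 1) > 1e-9)
    return("frequencies must sum to 1")
  TRUE
})

#' EnrichmentTable: log2-fold channel-vs-protein composition change
#'
#' @slot log2fc named numeric vector over the 20 amino acids.
#' @slot alpha pseudocount used for smoothing.
#' @export
setClass("EnrichmentTable",
  representation(log2fc = "numeric", alpha = "numeric")
)

setValidity("EnrichmentTable", function(object) {
  if (object@alpha > 0 && any(!is.finite(object@log2fc)))
    return("log2 fold changes must be finite when alpha > 0")
  TRUE
})

#' MsaAlignment: a multiple sequence alignment with a reference row
#'
#' @slot names sequence names.
#' @slot seqs character matrix (rows = sequences) over amino acids and '-'.
#' @slot refIndex index of the reference row.
#' @export
setClass("MsaAlignment",
  representation(names = "character", seqs = "matrix", refIndex = "integer")
)

setValidity("MsaAlignment", function(object) {
  if (nrow(object@seqs) != length(object@names)) return("names/rows mismatch")
  if (object@refIndex < 1L || object@refIndex > nrow(object@seqs))
    return("refIndex out of range")
  if (!any(object@seqs[object@refIndex, ] != "-"))
    return("reference row is all gaps")
  TRUE
})

#' RankTestResult: Mann-Whitney U test result
#'
#' @slot U the U statistic for the first sample.
#' @slot pTwoSided two-sided p value.
#' @slot method "exact" (full enumeration) or "normal_approx".
#' @slot n1,n2 sample sizes.
#' @export
setClass("RankTestResult",
  representation(U = "numeric", pTwoSided = "numeric", method = "character",
                 n1 = "integer", n2 = "integer")
)

setValidity("RankTestResult", function(object) {
  if (object@U < -1e-9 || object@U > object@n1 * object@n2 + 1e-9)
    return("U outside [0, n1*n2]")
  if (object@pTwoSided < 0 || object@pTwoSided > 1) return("p outside [0,1]")
  TRUE
})

#' LengthDataset: spirosome length measurements
#'
#' @slot group character group label per measurement.
#' @slot length_nm positive lengths in nanometres.
#' @slot conformation optional "extended"/"compact" per measurement ("" if unknown).
#' @export
setClass("LengthDataset",
  representation(group = "character", length_nm = "numeric", conformation = "character")
)

setValidity("LengthDataset", function(object) {
  if (length(object@group) != length(object@length_nm)) return("group/length mismatch")
  if (any(object@length_nm <= 0)) return("lengths must be positive")
  if (any(object@group == "")) return("empty group label")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "SpiroStructure", function(object) {
  a <- object@atoms
  cat(sprintf("SpiroStructure '%s': %d atoms, %d residues, chains [%s]\n",
              object@id, nrow(a),
              length(unique(residueKey(a$chain, a$resnum, a$icode))),
              paste(sort(unique(a$chain)), collapse = ",")))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf("SasaResult: total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              object@total, length(object@perAtom), object@probeRadius, object@nPoints))
})

setMethod("show", "Tunnel", function(object) {
  if (!object@found) {
    cat("Tunnel: no tunnel found\n")
  } else {
    cat(sprintf("Tunnel: %d points, length %.2f A, bottleneck %.2f A, widest %.2f A (grid %.2f A)\n",
                nrow(object@centerline), tunnelLength(object),
                min(object@radii), max(object@radii), object@gridSpacing))
  }
})

setMethod("show", "LigandTrajectory", function(object) {
  cat(sprintf("LigandTrajectory: %d frames x %.3g ns, %d ligand / %d protein atoms\n",
              length(object@ligandCoords), object@dt,
              nrow(object@ligandCoords[[1]]), nrow(object@proteinCoords[[1]])))
})

setMethod("show", "ResidenceResult", function(object) {
  if (object@censored)
    cat(sprintf("ResidenceResult: censored at %.3g ns (no escape)\n", object@time))
  else
    cat(sprintf("ResidenceResult: escape at frame %d, time %.3g ns\n",
                object@escapeFrame, object@time))
})

setMethod("show", "RankTestResult", function(object) {
  cat(sprintf("Mann-Whitney U = %.4g (n1=%d, n2=%d), two-sided p = %.4g [%s]\n",
              object@U, object@n1, object@n2, object@pTwoSided, object@method))
})

setMethod("show", "MsaAlignment", function(object) {
  cat(sprintf("MsaAlignment: %d sequences x %d columns, reference '%s'\n",
              nrow(object@seqs), ncol(object@seqs), object@names[object@refIndex]))
})

setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf("CompositionProfile: %d residues (%d non-standard excluded)\n",
              sum(object@counts), object@nonStandard))
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable (alpha = %.2f): range [%.2f, %.2f] log2 units\n",
              object@alpha, min(object@log2fc), max(object@log2fc)))
})

setMethod("show", "LengthDataset", function(object) {
  cat(sprintf("LengthDataset: %d measurements in %d group(s)\n",
              length(object@length_nm), length(unique(object@group))))
})
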