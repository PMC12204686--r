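# Amino-acid composition, channel log2-fold enrichment, motif scanning and
# cross-species residue-set homology.

#' Amino-acid composition of a residue set
#'
#' Counts over the 20 one-letter codes for a set of residues of a structure.
#' Non-standard residues are excluded and reported in the `nonStandard` slot
#' (with a warning).
#'
#' @param residues character vector of residue keys ("chain:resnum"), e.g.
#'   from [liningResidues()]; duplicated keys count once.
#' @param structure a [SpiroStructure-class].
#' @return a [CompositionProfile-class].
#' @export
aaComposition <- function(residues, structure) {
  if (!length(residues)) stop("empty residue set")
  rt <- residueTable(structure)
  rows <- rt[match(unique(residues), rt$key), , drop = FALSE]
  if (anyNA(rows$key))
    stop("residue(s) not in structure: ",
         paste(unique(residues)[is.na(rows$key)], collapse = ", "))
  nonStd <- sum(!rows$standard)
  if (nonStd > 0)
    warning(nonStd, " non-standard residue(s) excluded from composition")
  std <- rows[rows$standard, , drop = FALSE]
  counts <- setNames(integer(20), unname(AA3))
  tab <- table(AA3[std$resname])
  counts[names(tab)] <- as.integer(tab)
  tot <- sum(counts)
  freq <- if (tot > 0) counts / tot else counts * 0
  new("CompositionProfile", counts = counts,
      frequencies = setNames(as.numeric(freq), names(counts)),
      nonStandard = as.integer(nonStd))
}

#' Composition of every polymer residue in a structure
#'
#' Convenience wrapper: the whole-protein background profile against which
#' channel composition is compared.
#'
#' @param structure a [SpiroStructure-class].
#' @return a [CompositionProfile-class].
#' @export
proteinComposition <- function(structure) {
  rt <- residueTable(structure)
  keys <- rt$key[!rt$hetero]
  if (!length(keys)) stop("structure has no polymer residues")
  suppressWarnings(aaComposition(keys, structure))
}

#' Log2-fold enrichment of channel composition over protein composition
#'
#' For each amino acid a,
#' `log2fc[a] = log2( ((c_a + alpha) / (C + 20 alpha)) / ((p_a + alpha) / (P + 20 alpha)) )`
#' where c/p are channel/protein counts and C/P their totals. The Jeffreys
#' pseudocount `alpha = 0.5` keeps rare amino acids (a channel with a single
#' lysine, say) finite while preserving the sign and magnitude of depletion.
#'
#' @param channel a [CompositionProfile-class] of channel-lining residues.
#' @param protein a [CompositionProfile-class] of the full protein.
#' @param alpha smoothing pseudocount (> 0).
#' @return an [EnrichmentTable-class].
#' @export
log2Enrichment <- function(channel, protein, alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be > 0")
  cc <- aaCounts(channel); pc <- aaCounts(protein)
  if (sum(pc) == 0) stop("protein profile has zero total count")
  fC <- (cc + alpha) / (sum(cc) + 20 * alpha)
  fP <- (pc + alpha) / (sum(pc) + 20 * alpha)
  new("EnrichmentTable", log2fc = setNames(log2(fC / fP), names(cc)),
      alpha = alpha)
}

#' Scan a sequence for a motif with x wildcards
#'
#' Finds all (possibly overlapping) occurrences of a motif such as
#' `"GxGxxG"` (the dinucleotide-cofactor binding fingerprint) in an
#' amino-acid sequence; `x`/`X` match any residue.
#'
#' @param sequence amino-acid string.
#' @param pattern motif string of residue letters and x wildcards.
#' @return integer vector of 1-based start positions.
#' @export
motifScan <- function(sequence, pattern) {
  if (!nchar(pattern)) stop("pattern must be non-empty")
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p); n <- length(s)
  if (n < m) return(integer(0))
  fixed <- which(p != "X")
  hits <- vapply(seq_len(n - m + 1L), function(i) {
    all(s[i - 1L + fixed] == p[fixed])
  }, logical(1))
  which(hits)
}

#' Cross-species homology of mapped residue sets
#'
#' Percent of mapped channel positions whose residues are identical across
#' two species, given a position correspondence from a pairwise alignment.
#' Positions of either set whose partner is unmapped (alignment gap) count
#' as non-identical and are reported.
#'
#' @param setA,setB integer vectors of sequence positions (1-based) of the
#'   channel residues in species A and B.
#' @param mapping data.frame with columns posA, posB, aaA, aaB: the aligned
#'   position pairs and their residues (see [alignmentMapping()]).
#' @return list with `identityPercent`, `similarityPercent` (BLOSUM62-positive
#'   pairs), `nPairs`, `nUnmapped`.
#' @export
setHomology <- function(setA, setB, mapping) {
  if (!length(setA) || !length(setB)) stop("empty residue set")
  pairKeys <- character(0); ident <- logical(0); simil <- logical(0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  addPos <- function(posVec, col) {
    for (p in posVec) {
      row <- mapping[mapping[[col]] == p, , drop = FALSE]
      if (nrow(row) == 0L) {
        pairKeys <<- c(pairKeys, paste0(col, ":", p))
        ident <<- c(ident, FALSE); simil <<- c(simil, FALSE)
      } else {
        key <- paste0(row$posA[1], "|", row$posB[1])
        if (!key %in% pairKeys) {
          pairKeys <<- c(pairKeys, key)
          same <- row$aaA[1] == row$aaB[1]
          ident <<- c(ident, same)
          sc <- tryCatch(blosum[row$aaA[1], row$aaB[1]], error = function(e) -1)
          simil <<- c(simil, same || sc > 0)
        }
      }
    }
  }
  addPos(unique(setA), "posA")
  addPos(unique(setB), "posB")
  list(identityPercent = 100 * mean(ident),
       similarityPercent = 100 * mean(simil),
       nPairs = length(ident),
       nUnmapped = sum(grepl(":", pairKeys, fixed = TRUE)))
}

#' Position correspondence from a global pairwise alignment
#'
#' Aligns two sequences (Needleman-Wunsch, BLOSUM62) and returns the mapped
#' position pairs, the input expected by [setHomology()].
#'
#' @param seqA,seqB amino-acid strings.
#' @param gapOpening,gapExtension gap penalties.
#' @return data.frame with columns posA, posB, aaA, aaB.
#' @export
alignmentMapping <- function(seqA, seqB, gapOpening = 10, gapExtension = 0.5) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- ib <- 0L
  out <- vector("list", length(pa)); k <- 0L
  for (i in seq_along(pa)) {
    if (pa[i] != "-") ia <- ia + 1L
    if (sa[i] != "-") ib <- ib + 1L
    if (pa[i] != "-" && sa[i] != "-") {
      k <- k + 1L
      out[[k]] <- c(ia, ib)
    }
  }
  m <- do.call(rbind, out[seq_len(k)])
  sA <- strsplit(seqA, "")[[1]]; sB <- strsplit(seqB, "")[[1]]
  data.frame(posA = m[, 1], posB = m[, 2],
             aaA = sA[m[, 1]], aaB = sB[m[, 2]], stringsAsFactors = FALSE)
}
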