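# Multiple sequence alignments: reading, per-column conservation relative
# to a reference row, and global pairwise identity.

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' @param path file path.
#' @param format "auto" (by content/extension), "fasta" or "clustal".
#' @param ref name or index of the reference sequence (default: first row).
#' @return an [MsaAlignment-class].
#' @export
readMsa <- function(path, format = c("auto", "fasta", "clustal"), ref = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    w <- Biostrings::width(ss)
    if (length(unique(w)) != 1L) {
      bad <- which(w != w[1])[1]
      stop(sprintf("ragged alignment: row '%s' has width %d, expected %d",
                   names(ss)[bad], w[bad], w[1]))
    }
    rows <- as.character(ss)
    nms <- names(ss)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    ss <- Biostrings::unmasked(aln)
    rows <- as.character(ss)
    nms <- names(ss)
  }
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  dimnames(mat) <- NULL
  mat[mat == "."] <- "-"
  msa <- new("MsaAlignment", names = nms, seqs = mat, refIndex = 1L)
  setMsaReference(msa, ref)
}

#' Set the reference row of an alignment
#' @param msa an [MsaAlignment-class].
#' @param ref sequence name or row index.
#' @return the updated [MsaAlignment-class].
#' @export
setMsaReference <- function(msa, ref) {
  idx <- if (is.numeric(ref)) as.integer(ref) else match(ref, msaNames(msa))
  if (is.na(idx) || idx < 1L || idx > length(msaNames(msa)))
    stop("reference sequence not found: ", ref)
  initialize(msa, refIndex = idx)
}

#' Per-column conservation relative to the reference sequence
#'
#' For every non-gap column of the reference row, the percentage of rows
#' (reference included) whose residue matches the reference residue; gaps
#' count as mismatches. Positions are reported in reference coordinates
#' (1-based over ungapped reference residues), the numbering used when
#' quoting, e.g., how conserved the ADH-site triad residues are.
#'
#' @param msa an [MsaAlignment-class].
#' @return data.frame with columns position (reference coordinate), column
#'   (alignment column), refAA, conservation (percent).
#' @export
columnConservation <- function(msa) {
  m <- msaMatrix(msa)
  refRow <- m[msa@refIndex, ]
  cols <- which(refRow != "-")
  cons <- vapply(cols, function(j) 100 * mean(m[, j] == refRow[j]), numeric(1))
  data.frame(position = seq_along(cols), column = cols,
             refAA = refRow[cols], conservation = cons,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62 by default), with identity
#' computed as identical columns divided by aligned columns excluding
#' terminal-gap columns, as a percentage. Alternative denominators (all
#' alignment columns; shorter sequence length) are returned alongside.
#'
#' @param seqA,seqB amino-acid strings.
#' @param substitutionMatrix substitution matrix name.
#' @param gapOpening,gapExtension gap penalties.
#' @return list with `identityPercent` plus `identityAllColumns`,
#'   `identityShorter`, `nIdentical`, `nColumns`.
#' @export
pairwiseIdentity <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                             gapOpening = 10, gapExtension = 0.5) {
  for (s in c(seqA, seqB)) {
    if (!nchar(s)) stop("empty sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(s)))
      stop("non-amino-acid characters in sequence")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seqA)), Biostrings::AAString(toupper(seqB)),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gapA <- a == "-"; gapB <- b == "-"
  # terminal-gap columns: leading/trailing runs where either row is gapped
  n <- length(a)
  lead <- 0L
  while (lead < n && (gapA[lead + 1L] || gapB[lead + 1L])) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && (gapA[n - trail] || gapB[n - trail])) trail <- trail + 1L
  core <- if (lead + trail >= n) integer(0) else (lead + 1L):(n - trail)
  ident <- a == b & !gapA & !gapB
  nCore <- length(core)
  list(identityPercent = if (nCore) 100 * sum(ident[core]) / nCore else 0,
       identityAllColumns = 100 * sum(ident) / n,
       identityShorter = 100 * sum(ident) / min(sum(!gapA), sum(!gapB)),
       nIdentical = sum(ident[core]), nColumns = nCore)
}
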