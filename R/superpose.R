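# Rigid-body superposition (Kabsch) and sequence-guided Calpha pairing.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' ordered point sets, using the SVD construction; the rotation determinant
#' is forced to +1 so reflections are never returned.
#'
#' @param ref n x 3 matrix of reference coordinates.
#' @param mobile n x 3 matrix of mobile coordinates (same ordering).
#' @return list with `rotation` (3 x 3, applied as `mobile %*% rotation`),
#'   `translation` (length-3), and `rmsd` in Angstrom, such that
#'   `mobile %*% rotation + translation` best fits `ref`.
#' @export
kabschSuperpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!identical(dim(ref), dim(mobile)))
    stop("ref and mobile must have identical dimensions")
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 point pairs")
  cref <- colMeans(ref); cmob <- colMeans(mobile)
  r0 <- sweep(ref, 2, cref); m0 <- sweep(mobile, 2, cmob)
  # degenerate (collinear) point sets leave the rotation about the line free
  sv_r <- svd(r0)$d
  if (sv_r[2] < 1e-8 * max(sv_r[1], 1))
    stop("degenerate geometry: reference points are collinear")
  h <- crossprod(m0, r0)               # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(rotation = rot,
       translation = as.numeric(cref - cmob %*% rot),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 rotation.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% rotation, 2, -as.numeric(translation))
}

# Paired Calpha coordinates of two chains, matched through a global
# sequence alignment (Needleman-Wunsch, BLOSUM62); gapped positions are
# dropped. Returns list(ref=, mobile=) coordinate matrices.
.pairCalpha <- function(structRef, chainRef, structMob, chainMob,
                        gapOpening = 10, gapExtension = 0.5) {
  getCa <- function(s, ch) {
    a <- atomData(selectChains(s, ch))
    a <- a[!a$hetero & a$name == "CA" & a$resname %in% names(AA3), , drop = FALSE]
    a <- a[order(a$resnum, a$icode), , drop = FALSE]
    a
  }
  ra <- getCa(structRef, chainRef)
  ma <- getCa(structMob, chainMob)
  if (nrow(ra) < 3L || nrow(ma) < 3L) stop("too few Calpha atoms to pair")
  sref <- paste(AA3[ra$resname], collapse = "")
  smob <- paste(AA3[ma$resname], collapse = "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(smob), Biostrings::AAString(sref),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  im <- ir <- 0L
  idxM <- idxR <- integer(0)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") im <- im + 1L
    if (sub[k] != "-") ir <- ir + 1L
    if (pat[k] != "-" && sub[k] != "-") {
      idxM <- c(idxM, im); idxR <- c(idxR, ir)
    }
  }
  if (length(idxR) < 3L) stop("alignment pairs fewer than 3 Calpha atoms")
  list(ref = as.matrix(ra[idxR, c("x", "y", "z")]),
       mobile = as.matrix(ma[idxM, c("x", "y", "z")]))
}

#' Superpose one chain onto another via sequence-matched Calpha atoms
#'
#' Builds the residue correspondence from a global pairwise alignment of the
#' two chain sequences (BLOSUM62), pairs the Calpha atoms of aligned
#' (ungapped) positions, and runs [kabschSuperpose()]. This is the operation
#' used to compare, e.g., an ALDH domain against a homologous deposited
#' aldehyde dehydrogenase.
#'
#' @param structRef,structMob [SpiroStructure-class] objects.
#' @param chainRef,chainMob chain identifiers.
#' @return the [kabschSuperpose()] result plus `nPaired`.
#' @export
superposeChainsCA <- function(structRef, chainRef, structMob, chainMob) {
  p <- .pairCalpha(structRef, chainRef, structMob, chainMob)
  out <- kabschSuperpose(p$ref, p$mobile)
  out$nPaired <- nrow(p$ref)
  out
}
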