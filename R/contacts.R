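# Inter-protomer salt bridges and hydrogen bonds.
#
# Chemistry tables are the definition of the detectors; geometric criteria
# (4.0 A salt bridges, 3.5 A heavy-atom hydrogen bonds with an optional
# antecedent-angle filter) follow common practice since the original
# analysis software is unspecified, and every cutoff is an argument.

# Side-chain nitrogens of basic residues (salt-bridge donors). Histidine's
# protonation is unknown in heavy-atom models; it is included by default and
# switchable via includeHis.
SALT_BASIC <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
# Side-chain carboxylate oxygens of acidic residues.
SALT_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Hydrogen-bond donor heavy atoms (N/O/S bearing a proton) with their
# antecedent atom for the optional angle criterion, and acceptor heavy atoms
# (N/O). Backbone N (except proline) donates; backbone O accepts.
HB_DONORS <- list(
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  LYS = c(NZ = "CE"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"), TRP = c(NE1 = "CD1"),
  CYS = c(SG = "CB")
)
HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2")
)

.contactAtoms <- function(atoms, table, backbone = NULL) {
  sel <- rep(FALSE, nrow(atoms))
  for (res in names(table))
    sel <- sel | (atoms$resname == res & atoms$name %in% table[[res]])
  if (!is.null(backbone)) sel <- sel | backbone(atoms)
  atoms[sel, , drop = FALSE]
}

.donorAtoms <- function(atoms) {
  bb <- atoms$name == "N" & atoms$resname != "PRO" & atoms$resname %in% names(AA3)
  side <- rep(FALSE, nrow(atoms))
  ante <- ifelse(bb, "CA", NA_character_)
  for (res in names(HB_DONORS)) {
    tab <- HB_DONORS[[res]]
    hit <- atoms$resname == res & atoms$name %in% names(tab)
    side <- side | hit
    ante[hit] <- tab[atoms$name[hit]]
  }
  out <- atoms[bb | side, , drop = FALSE]
  out$antecedent <- ante[bb | side]
  out
}

.acceptorAtoms <- function(atoms) {
  bb <- atoms$name %in% c("O", "OXT") & atoms$resname %in% names(AA3)
  .contactAtoms(atoms, HB_ACCEPTORS, backbone = function(a) bb)
}

.emptyContacts <- function() {
  data.frame(residueA = character(0), residueB = character(0),
             resnameA = character(0), resnameB = character(0),
             atomA = character(0), atomB = character(0),
             distance = numeric(0), kind = character(0),
             angle = numeric(0), stringsAsFactors = FALSE)
}

# Pair every row of atoms1 against every row of atoms2 within cutoff.
.pairsWithin <- function(atoms1, atoms2, cutoff) {
  if (!nrow(atoms1) || !nrow(atoms2)) return(NULL)
  d <- crossDist(as.matrix(atoms1[, c("x", "y", "z")]),
                 as.matrix(atoms2[, c("x", "y", "z")]))
  idx <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(i = idx[, 1], j = idx[, 2], distance = d[idx],
             stringsAsFactors = FALSE)
}

.checkGroups <- function(structure, groupA, groupB) {
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  list(a = .polymerAtoms(selectChains(structure, groupA)),
       b = .polymerAtoms(selectChains(structure, groupB)))
}

.finishContacts <- function(rows) {
  if (is.null(rows) || !nrow(rows)) return(.emptyContacts())
  rows <- rows[order(rows$residueA, rows$residueB, rows$atomA, rows$atomB), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Detect inter-group salt bridges
#'
#' A salt bridge is reported when any side-chain nitrogen of Arg/Lys/His in
#' one group lies within `cutoff` of any side-chain carboxylate oxygen of
#' Asp/Glu in the other group (either direction). One contact per residue
#' pair, at the minimum atom-atom distance.
#'
#' @param structure a [SpiroStructure-class].
#' @param groupA,groupB disjoint chain-id vectors.
#' @param cutoff distance cutoff in Angstrom.
#' @param includeHis treat histidine as a salt-bridge donor.
#' @return data.frame of contacts (residueA/B, resnameA/B, atomA/B,
#'   distance, kind), sorted deterministically.
#' @export
findSaltBridges <- function(structure, groupA, groupB, cutoff = 4.0,
                            includeHis = TRUE) {
  g <- .checkGroups(structure, groupA, groupB)
  basic <- SALT_BASIC
  if (!includeHis) basic$HIS <- NULL
  rows <- NULL
  for (dir in 1:2) {
    at1 <- .contactAtoms(if (dir == 1) g$a else g$b, basic)
    at2 <- .contactAtoms(if (dir == 1) g$b else g$a, SALT_ACIDIC)
    p <- .pairsWithin(at1, at2, cutoff)
    if (is.null(p)) next
    # orient so that residueA is always in groupA
    aSide <- if (dir == 1) at1[p$i, ] else at2[p$j, ]
    bSide <- if (dir == 1) at2[p$j, ] else at1[p$i, ]
    rows <- rbind(rows, data.frame(
      residueA = residueKey(aSide$chain, aSide$resnum, aSide$icode),
      residueB = residueKey(bSide$chain, bSide$resnum, bSide$icode),
      resnameA = aSide$resname, resnameB = bSide$resname,
      atomA = aSide$name, atomB = bSide$name,
      distance = p$distance, kind = "salt_bridge", angle = NA_real_,
      stringsAsFactors = FALSE))
  }
  if (is.null(rows)) return(.emptyContacts())
  # one ContactPair per residue pair at minimum distance
  key <- paste(rows$residueA, rows$residueB, sep = "|")
  rows <- rows[order(key, rows$distance, rows$atomA, rows$atomB), , drop = FALSE]
  rows <- rows[!duplicated(paste(rows$residueA, rows$residueB, sep = "|")), , drop = FALSE]
  .finishContacts(rows)
}

.angleDeg <- function(center, p1, p2) {
  v1 <- p1 - center; v2 <- p2 - center
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect inter-group hydrogen bonds (heavy-atom criterion)
#'
#' Donor-acceptor pairs (N/O/S donors, N/O acceptors, main-chain and
#' side-chain atoms both eligible) with heavy-atom distance <= `dMax`. With
#' `requireGeometry = TRUE` an antecedent-angle criterion is applied: the
#' angle antecedent-donor-acceptor must be >= `minAngle` degrees, rejecting
#' geometries where the acceptor sits behind the donor's bonded neighbour.
#'
#' @inheritParams findSaltBridges
#' @param dMax heavy-atom donor-acceptor distance cutoff in Angstrom.
#' @param requireGeometry apply the antecedent-angle filter.
#' @param minAngle minimum antecedent-donor-acceptor angle in degrees.
#' @return data.frame of contacts, one row per unordered atom pair.
#' @export
findHbonds <- function(structure, groupA, groupB, dMax = 3.5,
                       requireGeometry = FALSE, minAngle = 90) {
  g <- .checkGroups(structure, groupA, groupB)
  rows <- NULL
  for (dir in 1:2) {
    don <- .donorAtoms(if (dir == 1) g$a else g$b)
    acc <- .acceptorAtoms(if (dir == 1) g$b else g$a)
    p <- .pairsWithin(don, acc, dMax)
    if (is.null(p)) next
    dAt <- don[p$i, ]; aAt <- acc[p$j, ]
    ang <- rep(NA_real_, nrow(p))
    if (requireGeometry) {
      src <- if (dir == 1) g$a else g$b
      for (k in seq_len(nrow(p))) {
        antName <- dAt$antecedent[k]
        ai <- which(src$chain == dAt$chain[k] & src$resnum == dAt$resnum[k] &
                      src$icode == dAt$icode[k] & src$name == antName)
        if (length(ai) == 1L)
          ang[k] <- .angleDeg(c(dAt$x[k], dAt$y[k], dAt$z[k]),
                              c(src$x[ai], src$y[ai], src$z[ai]),
                              c(aAt$x[k], aAt$y[k], aAt$z[k]))
      }
      keep <- is.na(ang) | ang >= minAngle
      p <- p[keep, , drop = FALSE]; dAt <- dAt[keep, , drop = FALSE]
      aAt <- aAt[keep, , drop = FALSE]; ang <- ang[keep]
      if (!nrow(p)) next
    }
    aIsGroupA <- dir == 1
    rows <- rbind(rows, data.frame(
      residueA = residueKey(if (aIsGroupA) dAt$chain else aAt$chain,
                            if (aIsGroupA) dAt$resnum else aAt$resnum,
                            if (aIsGroupA) dAt$icode else aAt$icode),
      residueB = residueKey(if (aIsGroupA) aAt$chain else dAt$chain,
                            if (aIsGroupA) aAt$resnum else dAt$resnum,
                            if (aIsGroupA) aAt$icode else dAt$icode),
      resnameA = if (aIsGroupA) dAt$resname else aAt$resname,
      resnameB = if (aIsGroupA) aAt$resname else dAt$resname,
      atomA = if (aIsGroupA) dAt$name else aAt$name,
      atomB = if (aIsGroupA) aAt$name else dAt$name,
      distance = p$distance, kind = "hbond", angle = ang,
      stringsAsFactors = FALSE))
  }
  if (is.null(rows)) return(.emptyContacts())
  # an atom pair qualifying in both donor/acceptor directions counts once
  pairKey <- paste(rows$residueA, rows$atomA, rows$residueB, rows$atomB, sep = "|")
  rows <- rows[!duplicated(pairKey), , drop = FALSE]
  .finishContacts(rows)
}

#' Count unique residue pairs in a contact list
#'
#' Distinct unordered (residueA, residueB) pairs, the quantity reported per
#' structure when comparing hydrogen-bond network extent between extended
#' and compact spirosomes.
#'
#' @param contacts a contact data.frame from [findSaltBridges()] / [findHbonds()].
#' @return integer count.
#' @export
uniqueResiduePairs <- function(contacts) {
  if (!nrow(contacts)) return(0L)
  a <- pmin(contacts$residueA, contacts$residueB)
  b <- pmax(contacts$residueA, contacts$residueB)
  length(unique(paste(a, b, sep = "|")))
}
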