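# Synthetic fixtures with machine-readable ground truth. Every generator is
# a pure function of (parameters, seed); each verifies its own truth payload
# by an independent brute-force check before returning. Fixtures mimic the
# statistical and geometric structure the analyses assume, not the real
# AdhE fold or sequence.

# ---- brute-force contact oracles (simple nested scans, independent of the
# vectorised detectors) ----------------------------------------------------

.bruteSaltBridges <- function(structure, groupA, groupB, cutoff = 4.0,
                              includeHis = TRUE) {
  basic <- SALT_BASIC
  if (!includeHis) basic$HIS <- NULL
  a <- .polymerAtoms(selectChains(structure, groupA))
  b <- .polymerAtoms(selectChains(structure, groupB))
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ai <- a[i, ]; bj <- b[j, ]
    basicA <- !is.null(basic[[ai$resname]]) && ai$name %in% basic[[ai$resname]]
    acidB <- !is.null(SALT_ACIDIC[[bj$resname]]) && bj$name %in% SALT_ACIDIC[[bj$resname]]
    basicB <- !is.null(basic[[bj$resname]]) && bj$name %in% basic[[bj$resname]]
    acidA <- !is.null(SALT_ACIDIC[[ai$resname]]) && ai$name %in% SALT_ACIDIC[[ai$resname]]
    if (!((basicA && acidB) || (basicB && acidA))) next
    d <- sqrt((ai$x - bj$x)^2 + (ai$y - bj$y)^2 + (ai$z - bj$z)^2)
    if (d <= cutoff)
      hits[[length(hits) + 1L]] <- c(residueKey(ai$chain, ai$resnum, ai$icode),
                                     residueKey(bj$chain, bj$resnum, bj$icode))
  }
  if (!length(hits)) return(character(0))
  sort(unique(vapply(hits, paste, "", collapse = "|")))
}

.isDonor <- function(resname, name) {
  (name == "N" && resname != "PRO" && resname %in% names(AA3)) ||
    (!is.null(HB_DONORS[[resname]]) && name %in% names(HB_DONORS[[resname]]))
}
.isAcceptor <- function(resname, name) {
  (name %in% c("O", "OXT") && resname %in% names(AA3)) ||
    (!is.null(HB_ACCEPTORS[[resname]]) && name %in% HB_ACCEPTORS[[resname]])
}

.bruteHbonds <- function(structure, groupA, groupB, dMax = 3.5) {
  a <- .polymerAtoms(selectChains(structure, groupA))
  b <- .polymerAtoms(selectChains(structure, groupB))
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ai <- a[i, ]; bj <- b[j, ]
    ok <- (.isDonor(ai$resname, ai$name) && .isAcceptor(bj$resname, bj$name)) ||
      (.isDonor(bj$resname, bj$name) && .isAcceptor(ai$resname, ai$name))
    if (!ok) next
    d <- sqrt((ai$x - bj$x)^2 + (ai$y - bj$y)^2 + (ai$z - bj$z)^2)
    if (d <= dMax)
      hits[[length(hits) + 1L]] <- paste(
        residueKey(ai$chain, ai$resnum, ai$icode), ai$name,
        residueKey(bj$chain, bj$resnum, bj$icode), bj$name, sep = "|")
  }
  if (!length(hits)) return(character(0))
  sort(unique(unlist(hits)))
}

# ---- toy multimer ---------------------------------------------------------

#' Two-chain toy multimer with designed inter-chain contacts
#'
#' Builds a two-chain structure carrying exactly `nSaltBridges` inter-chain
#' salt bridges (Lys NZ vs Asp OD1 at `separation` Angstrom; default 3.7 so
#' a designed bridge never doubles as a hydrogen bond) and `nHbonds`
#' hydrogen bonds (Ser OG vs backbone O at 2.9 Angstrom), each on its own
#' well-separated site, with small seeded coordinate jitter. Ground truth is
#' re-derived at generation time by a brute-force all-pairs scan; a mismatch
#' with the request is an error (infeasible geometry).
#'
#' @param seed RNG seed.
#' @param nSaltBridges,nHbonds requested contact counts (>= 0).
#' @param separation salt-bridge N-O distance in Angstrom.
#' @param jitter uniform coordinate jitter half-width in Angstrom.
#' @return list with `structure` ([SpiroStructure-class]) and `truth`.
#' @export
makeToyMultimer <- function(seed, nSaltBridges = 2L, nHbonds = 3L,
                            separation = 3.7, jitter = 0.05) {
  if (nSaltBridges < 0 || nHbonds < 0) stop("contact counts must be >= 0")
  if (nSaltBridges + nHbonds < 1) stop("need at least one designed contact")
  if (separation > 4.0 + 1e-9) stop("infeasible geometry: separation exceeds the 4.0 A salt-bridge cutoff")
  withSeed(seed, {
    atomsA <- list(); atomsB <- list(); serial <- 0L
    addAtom <- function(side, name, resname, resnum, p) {
      serial <<- serial + 1L
      row <- data.frame(serial = serial, name = name, resname = resname,
                        chain = side, resnum = resnum,
                        x = p[1] + runif(1, -jitter, jitter),
                        y = p[2] + runif(1, -jitter, jitter),
                        z = p[3] + runif(1, -jitter, jitter),
                        element = substr(name, 1, 1), stringsAsFactors = FALSE)
      if (side == "A") atomsA[[length(atomsA) + 1L]] <<- row
      else atomsB[[length(atomsB) + 1L]] <<- row
    }
    site <- 0L
    for (k in seq_len(nSaltBridges)) {
      site <- site + 1L; x0 <- 12 * site
      addAtom("A", "N",  "LYS", site, c(x0, -6.0, 0))
      addAtom("A", "CA", "LYS", site, c(x0, -4.5, 0))
      addAtom("A", "CB", "LYS", site, c(x0, -3.0, 0))
      addAtom("A", "CE", "LYS", site, c(x0, -1.5, 0))
      addAtom("A", "NZ", "LYS", site, c(x0, 0, 0))
      addAtom("B", "OD1", "ASP", site, c(x0, separation, 0))
      addAtom("B", "CG",  "ASP", site, c(x0, separation + 1.3, 0))
      addAtom("B", "OD2", "ASP", site, c(x0 + 1.1, separation + 2.1, 0))
      addAtom("B", "CB",  "ASP", site, c(x0, separation + 2.8, 0))
      addAtom("B", "CA",  "ASP", site, c(x0, separation + 4.3, 0))
      addAtom("B", "N",   "ASP", site, c(x0, separation + 5.8, 0))
    }
    for (k in seq_len(nHbonds)) {
      site <- site + 1L; x0 <- 12 * site
      addAtom("A", "N",  "SER", site, c(x0, -4.4, 0))
      addAtom("A", "CA", "SER", site, c(x0, -2.9, 0))
      addAtom("A", "CB", "SER", site, c(x0, -1.43, 0))
      addAtom("A", "OG", "SER", site, c(x0, 0, 0))
      addAtom("B", "O",  "GLY", site, c(x0, 2.9, 0))
      addAtom("B", "C",  "GLY", site, c(x0, 4.1, 0))
      addAtom("B", "CA", "GLY", site, c(x0, 5.6, 0))
      addAtom("B", "N",  "GLY", site, c(x0, 7.0, 0))
    }
    atoms <- do.call(rbind, c(atomsA, atomsB))
    s <- newStructure(atoms, id = sprintf("toy_multimer_seed%d", seed))
    sbTruth <- .bruteSaltBridges(s, "A", "B")
    hbTruth <- .bruteHbonds(s, "A", "B")
    hbPairs <- sort(unique(vapply(strsplit(hbTruth, "|", fixed = TRUE),
                                  function(v) paste(v[1], v[3], sep = "|"), "")))
    if (length(sbTruth) != nSaltBridges || length(hbPairs) != nHbonds)
      stop("infeasible geometry request: designed contacts (",
           length(sbTruth), " bridges, ", length(hbPairs),
           " H-bond pairs) do not match the request")
    list(structure = s,
         truth = list(kind = "toy_multimer",
                      parameters = list(seed = seed, nSaltBridges = nSaltBridges,
                                        nHbonds = nHbonds, separation = separation,
                                        jitter = jitter),
                      saltBridgePairs = sbTruth,
                      hbondAtomPairs = hbTruth,
                      hbondResiduePairs = hbPairs))
  })
}

# ---- channel phantom ------------------------------------------------------

#' Tubular channel phantom with known centerline and radius
#'
#' Builds a pseudo-atom (carbon) shell enclosing a cylindrical lumen of the
#' requested radius along a straight or gently curved centerline, with
#' hemispherical end caps so the lumen is sealed from bulk solvent; an
#' optional side window (recorded in the truth payload) is carved out of the
#' wall, wide enough for a 1.4 Angstrom probe to pass. Every wall residue
#' lines the channel by construction. An optional mid-tube bulge programs
#' the widest point at the arc midpoint.
#'
#' @param seed RNG seed (the phantom itself is deterministic; the seed is
#'   recorded and reserved for jittered variants).
#' @param tubeLength tube length in Angstrom.
#' @param radius lumen radius in Angstrom (> probe radius).
#' @param shape "straight" or "curve" (sinusoidal bend in the xy-plane).
#' @param window NULL, or list(axialFrom, axialTo, angleFrom, angleTo):
#'   axial positions as fractions of the length, wall angles in degrees.
#' @param bulge extra lumen radius (Angstrom) of a Gaussian mid-tube bulge.
#' @param resnames residue names cycled over wall rings (programs the
#'   lining composition).
#' @return list with `structure`, `truth` (centerline, radius, lining set,
#'   window flag) and `anchors` (start/end points for [findTunnel()]).
#' @export
makeChannelPhantom <- function(seed = 1L, tubeLength = 20, radius = 3,
                               shape = c("straight", "curve"), window = NULL,
                               bulge = 0,
                               resnames = c("LEU", "PHE", "HIS", "GLY", "VAL",
                                            "ALA", "SER", "ILE", "THR", "MET")) {
  shape <- match.arg(shape)
  if (radius <= 1.4) stop("radius must exceed the probe radius")
  atomR <- 1.7
  step <- 0.5
  tt <- seq(0, tubeLength, by = step)
  centerline <- switch(shape,
    straight = cbind(tt, 0 * tt, 0 * tt),
    curve = cbind(tt, (tubeLength / 6) * sin(pi * tt / tubeLength), 0 * tt))
  # self-intersection guard
  if (nrow(centerline) > 20) {
    far <- crossDist(centerline, centerline)
    sep <- abs(outer(seq_along(tt), seq_along(tt), "-")) * step
    if (any(far[sep > 4 * (radius + atomR)] < 2 * (radius + atomR)))
      stop("self-intersecting centerline")
  }
  shellR <- function(t) radius + atomR +
    if (bulge > 0) bulge * exp(-(t - tubeLength / 2)^2 / (2 * 2^2)) else 0
  # local frames (tangent/normal in-plane, z out of plane)
  tangent <- rbind(centerline[2, ] - centerline[1, ], diff(centerline))
  tangent <- tangent / sqrt(rowSums(tangent^2))
  n1 <- cbind(-tangent[, 2], tangent[, 1], 0)
  n2 <- matrix(rep(c(0, 0, 1), each = nrow(centerline)), ncol = 3)
  ringStep <- 1.2
  ringIdx <- seq(1, nrow(centerline), by = max(1L, round(ringStep / step)))
  inWindow <- function(tfrac, angDeg) {
    if (is.null(window)) return(FALSE)
    tfrac >= window$axialFrom & tfrac <= window$axialTo &
      angDeg >= window$angleFrom & angDeg <= window$angleTo
  }
  rows <- list(); serial <- 0L; resnum <- 0L
  addRing <- function(center, u, v, r, resname, tfrac, isCap) {
    nAng <- max(8L, ceiling(2 * pi * r / 1.4))
    angs <- seq(0, 2 * pi, length.out = nAng + 1L)[-(nAng + 1L)]
    resnum <<- resnum + 1L
    for (ang in angs) {
      angDeg <- ang * 180 / pi
      if (angDeg > 180) angDeg <- angDeg - 360
      if (!isCap && inWindow(tfrac, angDeg)) next
      serial <<- serial + 1L
      p <- center + r * (cos(ang) * u + sin(ang) * v)
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = serial, name = "C", resname = resname, chain = "T",
        resnum = resnum, x = p[1], y = p[2], z = p[3], element = "C",
        stringsAsFactors = FALSE)
    }
  }
  for (i in ringIdx) {
    t <- tt[i]
    addRing(centerline[i, ], n1[i, ], n2[i, ], shellR(t),
            resnames[(length(rows) %% length(resnames)) + 1L], t / tubeLength, FALSE)
  }
  # hemispherical caps at both ends
  for (end in c(1L, nrow(centerline))) {
    dir <- if (end == 1L) -tangent[end, ] else tangent[end, ]
    r0 <- shellR(tt[end])
    for (phi in seq(75, 10, by = -15) * pi / 180) {
      ringC <- centerline[end, ] + dir * (r0 * cos(phi))
      addRing(ringC, n1[end, ], n2[end, ], r0 * sin(phi),
              resnames[1], if (end == 1L) 0 else 1, TRUE)
    }
    serial <- serial + 1L; resnum <- resnum + 1L
    tip <- centerline[end, ] + dir * r0
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "C", resname = resnames[1], chain = "T",
      resnum = resnum, x = tip[1], y = tip[2], z = tip[3], element = "C",
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  s <- newStructure(atoms, id = sprintf("phantom_%s_seed%d", shape, seed))
  lining <- sort(unique(residueKey(atoms$chain, atoms$resnum, "")))
  list(structure = s,
       truth = list(kind = "channel_phantom",
                    parameters = list(seed = seed, tubeLength = tubeLength,
                                      radius = radius, shape = shape,
                                      bulge = bulge,
                                      window = window %||% "none"),
                    centerline = centerline, radius = radius,
                    bulgePoint = if (bulge > 0) centerline[which.min(abs(tt - tubeLength / 2)), ] else NULL,
                    liningResidues = lining,
                    windowed = !is.null(window)),
       anchors = list(start = centerline[1, ], end = centerline[nrow(centerline), ]))
}

# ---- synthetic trajectories ----------------------------------------------

#' Synthetic ligand trajectories inside a recorded tube
#'
#' The ligand random-walks inside a straight tube (the phantom shell is the
#' static protein). At every frame it escapes with probability
#' `hazardPerFrame` and then departs permanently far beyond the escape
#' distance. A designated wall atom ("ACC") receives a programmed
#' Bernoulli(`occupancyP`) contact (<= 3.5 Angstrom) per pre-escape frame.
#' Truth records, per replicate, the realized escape frame (NA when the
#' escape, if any, cannot be sustained within the trajectory), the censoring
#' status and the realized contact fraction.
#'
#' @param seed RNG seed.
#' @param n number of replicate trajectories.
#' @param dt nanoseconds per frame.
#' @param hazardPerFrame per-frame escape probability in `[0, 1]`.
#' @param nFrames frames per trajectory.
#' @param occupancyP per-frame contact probability in `[0, 1]`.
#' @param sustainFrames the sustain window the truth is expressed in.
#' @return list with `trajectories`, `tunnel` (the tube as a [Tunnel-class]),
#'   `structure` (the tube shell) and `truth`.
#' @export
makeSyntheticTrajectories <- function(seed, n = 3L, dt = 0.1,
                                      hazardPerFrame = 0.01, nFrames = 2000L,
                                      occupancyP = 0.3, sustainFrames = 5L) {
  if (hazardPerFrame < 0 || hazardPerFrame > 1) stop("hazard must be in [0,1]")
  tubeLen <- 30; radius <- 3
  phantom <- makeChannelPhantom(seed = 1L, tubeLength = tubeLen, radius = radius)
  prot <- atomCoords(phantom$structure)
  # acceptor: wall atom nearest to the mid-tube wall point
  accIdx <- which.min(crossDist(prot, matrix(c(tubeLen / 2, radius + 1.7, 0), 1))[, 1])
  protLabels <- rep("SHELL", nrow(prot))
  protLabels[accIdx] <- "ACC"
  acc <- prot[accIdx, ]
  withSeed(seed, {
    trajs <- vector("list", n)
    truth <- vector("list", n)
    for (r in seq_len(n)) {
      pos <- c(2, 0, 0)
      lig <- vector("list", nFrames)
      contacts <- logical(nFrames)
      esc <- NA_integer_
      for (f in seq_len(nFrames)) {
        if (is.na(esc) && runif(1) < hazardPerFrame) esc <- f
        if (!is.na(esc)) {
          lig[[f]] <- matrix(c(200 + 5 * (f - esc), 100, 100), 1)
          next
        }
        contact <- runif(1) < occupancyP
        contacts[f] <- contact
        if (contact) {
          dir <- c(tubeLen / 2, 0, 0) - acc
          dir <- dir / sqrt(sum(dir^2))
          pos <- acc + dir * runif(1, 2.6, 3.3)
        } else {
          repeat {
            cand <- pos + rnorm(3, 0, 0.8)
            cand[1] <- min(max(cand[1], 1), tubeLen - 1)
            rad <- sqrt(cand[2]^2 + cand[3]^2)
            if (rad > radius - 0.3) cand[2:3] <- cand[2:3] * (radius - 0.3) / rad
            if (sqrt(sum((cand - acc)^2)) > 3.6) { pos <- cand; break }
          }
        }
        lig[[f]] <- matrix(pos, 1)
      }
      sustained <- !is.na(esc) && (nFrames - esc + 1L >= sustainFrames)
      trajs[[r]] <- newTrajectory(dt, lig, list(prot),
                                  ligandLabels = "LIG", proteinLabels = protLabels)
      truth[[r]] <- list(
        escapeFrame = if (sustained) esc else NA_integer_,
        censored = !sustained,
        time = if (sustained) dt * esc else dt * nFrames,
        realizedOccupancy = mean(contacts))
    }
    centers <- cbind(seq(0, tubeLen, by = 0.5), 0, 0)
    tunnel <- new("Tunnel", centerline = centers,
                  radii = rep(radius, nrow(centers)),
                  gridSpacing = 0.5, probeRadius = 1.4, found = TRUE)
    list(trajectories = trajs, tunnel = tunnel, structure = phantom$structure,
         truth = list(kind = "synthetic_trajectories",
                      parameters = list(seed = seed, n = n, dt = dt,
                                        hazardPerFrame = hazardPerFrame,
                                        nFrames = nFrames, occupancyP = occupancyP,
                                        sustainFrames = sustainFrames),
                      perTrajectory = truth))
  })
}

# ---- toy MSA --------------------------------------------------------------

#' Toy multiple sequence alignment with programmed column conservation
#'
#' The reference row is random; in column j, `round(p_j * nRows)` rows
#' (clamped to `[1, nRows]`, reference included) match the reference
#' residue and the remainder carry a different residue. Truth records the
#' realized per-column conservation, which [columnConservation()] must
#' recover exactly.
#'
#' @param seed RNG seed.
#' @param nRows number of sequences.
#' @param length alignment length.
#' @param conservationProfile numeric vector in `[0, 1]` per column
#'   (recycled); default draws each column target from U(0.5, 1).
#' @return list with `msa` ([MsaAlignment-class]) and `truth`.
#' @export
makeToyMsa <- function(seed, nRows = 10L, length = 30L,
                       conservationProfile = NULL) {
  withSeed(seed, {
    if (is.null(conservationProfile)) conservationProfile <- runif(length, 0.5, 1)
    p <- rep(conservationProfile, length.out = length)
    if (any(p < 0 | p > 1)) stop("conservation profile values must be in [0,1]")
    aa <- unname(AA3)
    refRow <- sample(aa, length, replace = TRUE)
    m <- matrix("", nRows, length)
    m[1, ] <- refRow
    realized <- numeric(length)
    for (j in seq_len(length)) {
      mj <- min(max(round(p[j] * nRows), 1L), nRows)
      match_rows <- if (mj > 1L) 1L + sample(nRows - 1L, mj - 1L) else integer(0)
      for (i in 2:nRows) {
        m[i, j] <- if (i %in% match_rows) refRow[j]
        else sample(setdiff(aa, refRow[j]), 1L)
      }
      realized[j] <- 100 * mj / nRows
    }
    msa <- new("MsaAlignment",
               names = paste0("seq", seq_len(nRows)), seqs = m, refIndex = 1L)
    list(msa = msa,
         truth = list(kind = "toy_msa",
                      parameters = list(seed = seed, nRows = nRows, length = length),
                      targetProfile = p, realizedConservation = realized))
  })
}

# ---- length samples -------------------------------------------------------

#' Two-group spirosome length samples from stated distributions
#'
#' Positive-truncated normal samples per group, emulating negative-stain
#' length measurements: defaults are a native group at 80 +/- 25 nm and an
#' exogenous-expression group at 60 +/- 25 nm (a 20 nm mean shift) with
#' n = 1250 measurements per group, the scale of the published experiment.
#'
#' @param seed RNG seed.
#' @param groupParams named list of c(mean, sd) in nm per group.
#' @param n measurements per group.
#' @return list with `data` ([LengthDataset-class]) and `truth`.
#' @export
makeLengthSamples <- function(seed,
                              groupParams = list(native = c(mean = 80, sd = 25),
                                                 exogenous = c(mean = 60, sd = 25)),
                              n = 1250L) {
  if (n < 1L) stop("n must be >= 1")
  withSeed(seed, {
    groups <- character(0); lens <- numeric(0)
    realized <- list()
    for (g in names(groupParams)) {
      pars <- groupParams[[g]]
      if (pars[["sd"]] <= 0) stop("sd must be positive")
      v <- numeric(0)
      while (base::length(v) < n) {
        draw <- rnorm(2L * n, pars[["mean"]], pars[["sd"]])
        v <- c(v, draw[draw > 0])
      }
      v <- v[seq_len(n)]
      groups <- c(groups, rep(g, n)); lens <- c(lens, v)
      realized[[g]] <- list(n = n, mean = mean(v), sd = sd(v))
    }
    list(data = newLengthDataset(groups, lens),
         truth = list(kind = "length_samples",
                      parameters = list(seed = seed, groupParams = groupParams, n = n),
                      realized = realized))
  })
}

# ---- writers for fixture files -------------------------------------------

#' Write a trajectory as an XYZ file
#' @param traj a [LigandTrajectory-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nFrames(traj)
  for (f in seq_len(n)) {
    lig <- traj@ligandCoords[[f]]
    prot <- proteinCoords(traj, f)
    all <- rbind(lig, prot)
    el <- c(rep("O", nrow(lig)), rep("C", nrow(prot)))
    writeLines(c(sprintf("%d", nrow(all)), sprintf("frame %d", f),
                 sprintf("%s %.4f %.4f %.4f", el, all[, 1], all[, 2], all[, 3])),
               con)
  }
  invisible(path)
}

#' Write an alignment as aligned FASTA
#' @param msa an [MsaAlignment-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMsaFasta <- function(msa, path) {
  m <- msaMatrix(msa)
  lines <- character(0)
  for (i in seq_len(nrow(m)))
    lines <- c(lines, paste0(">", msaNames(msa)[i]), paste(m[i, ], collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
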