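# Ligand trajectory post-processing: readers (multi-model PDB, XYZ),
# residence time before escape to solvent (censoring-aware), hydrogen-bond
# occupancy, and adherence to a tunnel path.

#' Construct a ligand trajectory from coordinate lists
#'
#' @param dt nanoseconds per frame.
#' @param ligandCoords list of per-frame ligand coordinate matrices (k x 3).
#' @param proteinCoords list of protein coordinate matrices; a length-1 list
#'   means the protein frame is static (reused for every ligand frame).
#' @param ligandLabels,proteinLabels optional atom labels.
#' @return a [LigandTrajectory-class].
#' @export
newTrajectory <- function(dt, ligandCoords, proteinCoords,
                          ligandLabels = character(0),
                          proteinLabels = character(0)) {
  asM <- function(x) { m <- as.matrix(x); storage.mode(m) <- "double"; m }
  new("LigandTrajectory", dt = dt,
      ligandCoords = lapply(ligandCoords, asM),
      proteinCoords = lapply(proteinCoords, asM),
      ligandLabels = ligandLabels, proteinLabels = proteinLabels)
}

# Parse an XYZ trajectory into a list of frames, each a data.frame with
# element, x, y, z.
.readXyzFrames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("bad XYZ atom-count line at line ", i)
    f <- f + 1L
    if (i + 1L + nat > length(lines))
      stop("truncated XYZ frame ", f, " (expected ", nat, " atoms)")
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad)) stop("bad XYZ atom line in frame ", f)
    frames[[f]] <- data.frame(
      element = vapply(toks, `[`, "", 1L),
      x = as.numeric(vapply(toks, `[`, "", 2L)),
      y = as.numeric(vapply(toks, `[`, "", 3L)),
      z = as.numeric(vapply(toks, `[`, "", 4L)),
      stringsAsFactors = FALSE)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames in XYZ file ", path)
  frames
}

# Parse a multi-model PDB into per-frame atom tables.
.readPdbFrames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    return(list(.parsePdbAtoms(lines, path)))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) stop("unterminated MODEL block in ", path)
  lapply(seq_along(starts), function(k) {
    .parsePdbAtoms(lines[(starts[k] + 1L):(ends[k] - 1L)], path)
  })
}

# Selection strings against a frame table:
#   "resname:ACD"        atoms of residue name ACD
#   "chain:A"            atoms of chain A
#   "not-resname:ACD"    complement of a resname selection
#   "name:O1"            atoms by atom name
#   integer vector       explicit atom indices
.resolveSelection <- function(frame, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("bad selection: ", selection)
  key <- parts[1]; val <- parts[2]
  idx <- switch(key,
    resname = which(frame$resname == val),
    `not-resname` = which(frame$resname != val),
    chain = which(frame$chain == val),
    name = which(frame$name == val),
    element = which(frame$element == val),
    stop("unknown selection key: ", key)
  )
  idx
}

#' Read a ligand trajectory from a multi-model PDB or XYZ file
#'
#' @param path file path.
#' @param dt nanoseconds per frame.
#' @param ligandSelection,proteinSelection selection strings
#'   ("resname:ACD", "chain:A", "name:O1", "element:C", "not-resname:ACD")
#'   or integer atom indices, resolved on the first frame and required to be
#'   consistent across frames.
#' @param format "auto" (by extension), "pdb" or "xyz".
#' @return a [LigandTrajectory-class].
#' @export
readTrajectory <- function(path, dt, ligandSelection, proteinSelection,
                           format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  frames <- if (format == "xyz") .readXyzFrames(path) else .readPdbFrames(path)
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) != 1L)
    stop("inconsistent atom count at frame ", which(nat != nat[1])[1],
         " (", nat[which(nat != nat[1])[1]], " vs ", nat[1], ")")
  li <- .resolveSelection(frames[[1]], ligandSelection)
  pi_ <- .resolveSelection(frames[[1]], proteinSelection)
  if (!length(li)) stop("ligand selection matches no atoms")
  if (!length(pi_)) stop("protein selection matches no atoms")
  lab <- function(fr, idx) {
    if (!is.null(fr$name)) paste0(fr$resname[idx], ":", fr$name[idx]) else fr$element[idx]
  }
  newTrajectory(
    dt = dt,
    ligandCoords = lapply(frames, function(fr) as.matrix(fr[li, c("x", "y", "z")])),
    proteinCoords = lapply(frames, function(fr) as.matrix(fr[pi_, c("x", "y", "z")])),
    ligandLabels = lab(frames[[1]], li),
    proteinLabels = lab(frames[[1]], pi_)
  )
}

# Per-frame minimum ligand-protein heavy-atom distance.
.minDistSeries <- function(traj) {
  n <- nFrames(traj)
  vapply(seq_len(n), function(f) {
    min(crossDist(traj@ligandCoords[[f]], proteinCoords(traj, f)))
  }, numeric(1))
}

#' Ligand residence time before sustained escape to solvent
#'
#' The escape frame is the first frame f at which the minimum ligand-protein
#' heavy-atom distance exceeds `escapeDistance` for `sustainFrames`
#' consecutive frames (f .. f+sustainFrames-1); brief excursions shorter
#' than `sustainFrames` do not count. Residence time is `dt * f` (frames
#' 1-based). When no such frame exists the result is censored at the
#' trajectory end and reported as a lower bound.
#'
#' @param traj a [LigandTrajectory-class].
#' @param escapeDistance escape threshold in Angstrom.
#' @param sustainFrames consecutive frames required beyond the threshold (>= 1).
#' @return a [ResidenceResult-class].
#' @export
residenceTime <- function(traj, escapeDistance = 10.0, sustainFrames = 5L) {
  sustainFrames <- as.integer(sustainFrames)
  if (sustainFrames < 1L) stop("sustainFrames must be >= 1")
  md <- .minDistSeries(traj)
  n <- length(md)
  beyond <- md > escapeDistance
  esc <- NA_integer_
  if (n >= sustainFrames) {
    run <- 0L
    for (f in seq_len(n)) {
      run <- if (beyond[f]) run + 1L else 0L
      if (run == sustainFrames) { esc <- f - sustainFrames + 1L; break }
    }
  }
  if (is.na(esc)) {
    new("ResidenceResult", time = traj@dt * n, censored = TRUE,
        escapeFrame = NA_integer_)
  } else {
    new("ResidenceResult", time = traj@dt * esc, censored = FALSE,
        escapeFrame = esc)
  }
}

#' Ensemble mean residence time
#'
#' Mean and sample standard deviation over replicate residence times;
#' censored entries enter at their censoring time, and when any replicate is
#' censored the mean is flagged a lower bound on the true residence time.
#'
#' @param results list of [ResidenceResult-class] objects.
#' @return list with mean, sd, n, nCensored, lowerBound.
#' @export
meanResidence <- function(results) {
  if (!length(results)) stop("need at least one residence result")
  t <- vapply(results, residenceTimeNs, numeric(1))
  cens <- vapply(results, isCensored, logical(1))
  list(mean = mean(t), sd = if (length(t) > 1) sd(t) else 0,
       n = length(t), nCensored = sum(cens), lowerBound = any(cens))
}

.selectTrajAtoms <- function(traj, frame, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  src <- parts[1]
  coords <- switch(src,
    ligand = traj@ligandCoords[[frame]],
    protein = proteinCoords(traj, frame),
    stop("selection must start with 'ligand' or 'protein': ", spec))
  if (length(parts) == 1L) return(coords)
  labels <- if (src == "ligand") traj@ligandLabels else traj@proteinLabels
  if (grepl("^[0-9,]+$", parts[2])) {
    idx <- as.integer(strsplit(parts[2], ",")[[1]])
  } else {
    if (!length(labels)) stop("trajectory has no labels for selection: ", spec)
    idx <- which(labels == parts[2])
  }
  if (!length(idx)) stop("selection matches no atoms: ", spec)
  coords[idx, , drop = FALSE]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which at least one donor-acceptor pair from the
#' selections lies within `dMax` (distance-only criterion: deposited
#' trajectories analysed at the heavy-atom level carry no hydrogens).
#'
#' @param traj a [LigandTrajectory-class].
#' @param donorSelection,acceptorSelection selection specs:
#'   "ligand", "protein", "ligand:2", "protein:1,5", or "protein:LABEL".
#' @param dMax donor-acceptor distance cutoff in Angstrom.
#' @return fraction of frames in `[0, 1]`.
#' @export
hbondOccupancy <- function(traj, donorSelection, acceptorSelection, dMax = 3.5) {
  n <- nFrames(traj)
  hit <- vapply(seq_len(n), function(f) {
    d <- crossDist(.selectTrajAtoms(traj, f, donorSelection),
                   .selectTrajAtoms(traj, f, acceptorSelection))
    any(d <= dMax)
  }, logical(1))
  mean(hit)
}

#' Fraction of pre-escape frames adhering to a tunnel path
#'
#' Fraction of frames before the escape frame in which the ligand centroid
#' lies within `cutoff` of the tunnel centerline polyline; the whole
#' trajectory is used when censored.
#'
#' @param traj a [LigandTrajectory-class].
#' @param tunnel a found [Tunnel-class].
#' @param cutoff distance cutoff in Angstrom.
#' @param escapeDistance,sustainFrames forwarded to [residenceTime()].
#' @return fraction in `[0, 1]`.
#' @export
pathAdherence <- function(traj, tunnel, cutoff = 5.0,
                          escapeDistance = 10.0, sustainFrames = 5L) {
  if (!tunnelFound(tunnel)) stop("tunnel is empty (no tunnel found)")
  res <- residenceTime(traj, escapeDistance, sustainFrames)
  last <- if (isCensored(res)) nFrames(traj) else max(escapeFrame(res) - 1L, 1L)
  centroids <- t(vapply(seq_len(last), function(f) {
    colMeans(traj@ligandCoords[[f]])
  }, numeric(3)))
  d <- distToPolyline(centroids, tunnelCenterline(tunnel))
  mean(d <= cutoff)
}
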