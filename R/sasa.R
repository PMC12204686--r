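# Shrake-Rupley solvent-accessible surface area and interface buried area.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Generalized-spiral construction (Rakhmanov/Saff-Kuijlaars). Fully
#' deterministic for a given n, so SASA values are bit-reproducible.
#'
#' @param n number of points (>= 2).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(1, pmax(-1, h)))
  phi <- numeric(n)
  for (i in 2:(n - 1))
    phi[i] <- (phi[i - 1] + 3.6 / sqrt(n * (1 - h[i]^2))) %% (2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe of radius `probeRadius` over the van der Waals surface using
#' a fixed quasi-uniform point set per atom: a surface point on the expanded
#' sphere of atom i is accessible when it lies outside every other expanded
#' sphere. Waters and non-polymer heteroatoms are excluded unless
#' `includeHetero = TRUE`. Heavy-atom treatment throughout.
#'
#' @param structure a [SpiroStructure-class].
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints quadrature points per atom (>= 92).
#' @param includeHetero include heteroatoms (waters/ligands/ions).
#' @return a [SasaResult-class].
#' @export
shrakeRupleySasa <- function(structure, probeRadius = 1.4, nPoints = 960L,
                             includeHetero = FALSE) {
  nPoints <- as.integer(nPoints)
  if (nPoints < 92L) stop("nPoints must be >= 92")
  a <- .polymerAtoms(structure, includeHetero)
  if (nrow(a) == 0L) stop("no atoms to compute SASA over (empty selection)")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rExp <- a$vdw + probeRadius
  n <- nrow(a)
  sph <- spherePoints(nPoints)
  # neighbour lists from expanded-sphere overlap; distances computed one
  # atom at a time so memory stays O(n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    di2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(di2 < (rExp[i] + rExp)^2 & seq_len(n) != i)
    pts <- sweep(sph * rExp[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      dd <- crossDist2(pts, xyz[nb, , drop = FALSE])
      buried <- rowSums(dd < matrix(rExp[nb]^2, nrow(pts), length(nb), byrow = TRUE)) > 0
      frac <- mean(!buried)
    } else frac <- 1
    area[i] <- frac * 4 * pi * rExp[i]^2
  }
  new("SasaResult",
      perAtom = setNames(area, a$serial),
      total = sum(area), probeRadius = probeRadius, nPoints = nPoints)
}

#' Interface buried surface area between two chain groups
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together), the total
#' area (both sides summed, no division by two); the per-side value is
#' total/2. Waters, ions and cofactors are excluded: interface areas are
#' protein-protein.
#'
#' @param structure a [SpiroStructure-class] containing both groups.
#' @param groupA,groupB disjoint, non-empty character vectors of chain ids.
#' @param probeRadius probe radius in Angstrom.
#' @param nPoints quadrature points per atom.
#' @param details if TRUE return a list with the component SASA totals and
#'   the per-side value; otherwise the total BSA as a scalar.
#' @return numeric total BSA in squared Angstrom (or a detail list).
#' @export
buriedSurfaceArea <- function(structure, groupA, groupB, probeRadius = 1.4,
                              nPoints = 960L, details = FALSE) {
  if (!length(groupA) || !length(groupB)) stop("both chain groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  sA <- shrakeRupleySasa(selectChains(structure, groupA), probeRadius, nPoints)
  sB <- shrakeRupleySasa(selectChains(structure, groupB), probeRadius, nPoints)
  sAB <- shrakeRupleySasa(selectChains(structure, c(groupA, groupB)), probeRadius, nPoints)
  bsa <- totalSasa(sA) + totalSasa(sB) - totalSasa(sAB)
  if (!details) return(bsa)
  list(bsaTotal = bsa, bsaPerSide = bsa / 2,
       sasaA = totalSasa(sA), sasaB = totalSasa(sB), sasaComplex = totalSasa(sAB),
       probeRadius = probeRadius, nPoints = as.integer(nPoints))
}
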