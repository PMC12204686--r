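# Shared chemistry tables and small geometry helpers.

# Bondi-style van der Waals radii (Angstrom), applied uniformly to every
# structure; metals use commonly adopted extensions. Unknown elements are a
# hard error so silent mis-sizing cannot propagate into SASA or clearance.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CU = 1.40, NI = 1.63,
  `NA` = 2.27, K = 2.75, CA = 2.31, CO = 2.00, MO = 2.10
)

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1 <- names(AA3)
names(AA1) <- unname(AA3)

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param serial optional atom serials used in the error message.
#' @return numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(element, serial = NULL) {
  el <- toupper(trimws(element))
  r <- VDW_RADII[el]
  bad <- which(is.na(r))
  if (length(bad)) {
    where <- if (!is.null(serial)) sprintf(" (atom serial %s)", paste(serial[bad], collapse = ", ")) else ""
    stop("unknown element(s): ", paste(unique(el[bad]), collapse = ", "), where)
  }
  unname(r)
}

# Squared Euclidean cross-distances between row-vector matrices a (n x 3)
# and b (m x 3), returned as an n x m matrix.
crossDist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

crossDist <- function(a, b) sqrt(pmax(crossDist2(a, b), 0))

# Minimum distance from each point (rows of p) to a polyline given as an
# ordered matrix of vertices (n x 3). Exact point-to-segment distances.
distToPolyline <- function(p, line) {
  p <- as.matrix(p); line <- as.matrix(line)
  if (nrow(line) == 1L) return(crossDist(p, line)[, 1])
  best <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-300) {
      d <- sqrt(rowSums(sweep(p, 2, a)^2))
    } else {
      t <- pmin(1, pmax(0, (sweep(p, 2, a) %*% ab) / len2))
      proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
      d <- sqrt(rowSums((p - proj)^2))
    }
    best <- pmin(best, d)
  }
  best
}

# Run code under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical residue key "chain:resnum" or "chain:resnum:icode".
residueKey <- function(chain, resnum, icode = "") {
  if (!length(chain)) return(character(0))
  ic <- ifelse(is.na(icode) | icode == "" | icode == " ", "", icode)
  paste0(chain, ":", resnum, ifelse(ic == "", "", paste0(":", ic)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
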