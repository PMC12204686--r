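# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (Monte-Carlo sampling,
# naive Dijkstra, graph components, direct enumeration), so agreement is
# evidence, not tautology.

# Monte-Carlo Shrake-Rupley oracle: random (not spiral) directions per atom.
mcSasaOracle <- function(structure, probe = 1.4, nSamples = 1e5, seed = 42) {
  a <- atomData(structure)
  a <- a[!a$hetero, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rExp <- a$vdw + probe
  set.seed(seed)
  areas <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    dirs <- matrix(rnorm(3 * nSamples), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * rExp[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, nSamples)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 + (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rExp[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * rExp[i]^2
  }
  list(perAtom = areas, total = sum(areas))
}

# Naive Dijkstra (O(V^2) with vectorised min) over the package's own grid
# edges; independent of igraph.
dijkstraOracle <- function(nNodes, from, to, edges, weights) {
  adj <- split(seq_along(edges$from), edges$from)
  adjR <- split(seq_along(edges$to), edges$to)
  dist <- rep(Inf, nNodes); dist[from] <- 0
  prev <- rep(NA_integer_, nNodes)
  done <- logical(nNodes)
  repeat {
    dist2 <- dist; dist2[done] <- Inf
    u <- which.min(dist2)
    if (!is.finite(dist2[u])) break
    done[u] <- TRUE
    if (u == to) break
    for (k in c(adj[[as.character(u)]], adjR[[as.character(u)]])) {
      v <- if (edges$from[k] == u) edges$to[k] else edges$from[k]
      alt <- dist[u] + weights[k]
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  path <- integer(0)
  if (is.finite(dist[to])) {
    v <- to
    while (!is.na(v)) { path <- c(v, path); v <- prev[v] }
  }
  list(dist = dist[to], path = path)
}

# Flood-fill reachability oracle via igraph connected components over the
# same passable mask (the package uses its own BFS).
reachabilityOracle <- function(dims, passable, seeds) {
  n <- prod(dims)
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  ids <- which(passable)
  ids0 <- ids - 1L
  ix <- ids0 %% nx; iy <- (ids0 %/% nx) %% dims[2]; iz <- ids0 %/% nxy
  ef <- integer(0); et <- integer(0)
  addE <- function(sel, off) {
    ef <<- c(ef, ids[sel]); et <<- c(et, ids[sel] + off)
  }
  addE(ix < nx - 1L & passable[pmin(ids + 1L, n)], 1L)
  addE(iy < dims[2] - 1L & passable[pmin(ids + nx, n)], nx)
  addE(iz < dims[3] - 1L & passable[pmin(ids + nxy, n)], nxy)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  comp <- igraph::components(g)$membership
  seedComps <- unique(comp[seeds[passable[seeds]]])
  passable & comp %in% seedComps
}

# Direct enumeration of the Mann-Whitney U null (independent code path).
mwuEnumOracle <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  uOf <- function(xx, yy) {
    # count pairs xx > yy with half-credit ties (equals midrank U)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u <- uOf(x, y)
  us <- apply(combn(N, n1), 2, function(ii) uOf(pooled[ii], pooled[-ii]))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u + tol), mean(us >= u - tol)))
}

# Naive regex-based motif oracle.
motifOracle <- function(sequence, pattern) {
  rx <- paste0("(?=", gsub("x", ".", pattern, ignore.case = TRUE), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Random toy multimer parameters for fixture sweeps.
randomMultimer <- function(seed) {
  set.seed(seed)
  nSB <- sample(0:3, 1)
  nHB <- sample(0:4, 1)
  if (nSB + nHB == 0) nSB <- 1L
  # separation stays above the 3.5 A H-bond cutoff (plus jitter headroom)
  # so a designed bridge never doubles as an H-bond, and below the 4.0 A
  # salt-bridge cutoff
  makeToyMultimer(seed = seed, nSaltBridges = nSB, nHbonds = nHB,
                  separation = runif(1, 3.70, 3.82))
}

# Single-atom protein / single-atom ligand trajectory with a programmed
# min-distance series (for residence-time property tests).
distanceTrajectory <- function(dists, dt = 0.1) {
  newTrajectory(dt,
                lapply(dists, function(d) matrix(c(d, 0, 0), 1)),
                list(matrix(c(0, 0, 0), 1)),
                ligandLabels = "LIG", proteinLabels = "P")
}

# Path to optional user-supplied deposited structures/sequences (not
# shipped: they exceed the plain-text fixture budget and require network).
depositedPath <- function(...) {
  p1 <- system.file("extdata", "deposited", ..., package = "spiroscan")
  if (nzchar(p1) && file.exists(p1)) return(p1)
  file.path("../../inst/extdata/deposited", ...)
}
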