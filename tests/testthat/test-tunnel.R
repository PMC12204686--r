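# grid-probe tunnel finder, lining residues, widest point, enclosure

# one phantom set shared across this file (tunnel searches dominate runtime)
phantomFx <- makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3)
phantomTunnel <- findTunnel(phantomFx$structure, phantomFx$anchors$start,
                            phantomFx$anchors$end, gridSpacing = 0.6)

test_that("unobstructed space gives a straight path of the right length", {
  far <- newStructure(data.frame(serial = 1L, name = "C", resname = "ALA",
                                 chain = "A", resnum = 1L,
                                 x = 20, y = 20, z = 20, element = "C"))
  tun <- findTunnel(far, c(0, 0, 0), c(10, 0, 0), gridSpacing = 1.0)
  expect_true(tunnelFound(tun))
  expect_lt(abs(tunnelLength(tun) - 10), 1.0 + 1e-9)
  expect_lt(max(abs(tunnelCenterline(tun)[, 2:3])), 1.0)
})

test_that("a sealed enclosure with the exit outside yields 'no tunnel', not an error", {
  tun <- findTunnel(phantomFx$structure, phantomFx$anchors$start + c(2, 0, 0),
                    c(60, 40, 40), gridSpacing = 0.8)
  expect_false(tunnelFound(tun))
  expect_error(widestPoint(tun), "empty")
})

test_that("anchors inside an atom are an error", {
  a <- atomData(phantomFx$structure)
  wallPoint <- c(a$x[1], a$y[1], a$z[1])
  expect_error(findTunnel(phantomFx$structure, wallPoint,
                          phantomFx$anchors$end, gridSpacing = 0.8),
               "inside an atom")
})

test_that("phantom centerline is recovered within one grid spacing everywhere", {
  expect_true(tunnelFound(phantomTunnel))
  dev <- spiroscan:::distToPolyline(tunnelCenterline(phantomTunnel),
                                    phantomFx$truth$centerline)
  expect_lt(max(dev), 0.6)
  # and the path spans the tube
  expect_gt(tunnelLength(phantomTunnel), 16 - 2 * 0.6)
})

test_that("tunnel path cost matches an independent Dijkstra oracle", {
  # small empty-space grid so the naive oracle stays fast
  far <- newStructure(data.frame(serial = 1L, name = "C", resname = "ALA",
                                 chain = "A", resnum = 1L,
                                 x = 3, y = 4, z = 0, element = "C"))
  gridSpacing <- 1.0; probe <- 1.4
  grid <- spiroscan:::.probeGrid(far, gridSpacing, probe,
                                 extraPoints = rbind(c(0, 0, 0), c(6, 0, 0)))
  ed <- spiroscan:::.gridEdges(grid)
  inv <- 1 / (pmax(grid$clearance - probe, 0) + 0.1)
  w <- ed$len * 0.5 * (inv[ed$from] + inv[ed$to])
  s <- spiroscan:::.nearestNode(grid, c(0, 0, 0))
  e <- spiroscan:::.nearestNode(grid, c(6, 0, 0))
  oracle <- dijkstraOracle(prod(grid$dims), s, e,
                           list(from = ed$from, to = ed$to), w)
  tun <- findTunnel(far, c(0, 0, 0), c(6, 0, 0), gridSpacing = gridSpacing)
  # recompute the cost of the returned path on the same grid
  ids <- apply(tunnelCenterline(tun), 1, function(p) spiroscan:::.nearestNode(grid, p))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  wmap <- setNames(w, key(ed$from, ed$to))
  cost <- sum(wmap[key(ids[-length(ids)], ids[-1])])
  expect_equal(cost, oracle$dist, tolerance = 1e-9)
})

test_that("lining residues equal the designed set and a brute-force distance scan", {
  lin <- liningResidues(phantomFx$structure, phantomTunnel, margin = 3)
  expect_setequal(lin, phantomFx$truth$liningResidues)
  # brute force: per residue, min atom distance to any centerline point
  a <- atomData(phantomFx$structure)
  cl <- tunnelCenterline(phantomTunnel)
  rr <- tunnelRadii(phantomTunnel)
  keys <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(cl))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - cl[j, ])^2))
      if (d <= rr[j] + 3) {
        keys <- c(keys, spiroscan:::residueKey(a$chain[i], a$resnum[i], a$icode[i]))
        break
      }
    }
  }
  expect_setequal(lin, unique(keys))
  # a tunnel through empty space far from any protein lines nothing
  off <- new("Tunnel", centerline = cbind(0:5, 60, 60), radii = rep(2, 6),
             gridSpacing = 1, probeRadius = 1.4, found = TRUE)
  expect_length(liningResidues(phantomFx$structure, off), 0)
})

test_that("widest point: max radius, first on ties, programmed bulge located", {
  t1 <- new("Tunnel", centerline = cbind(0:2, 0, 0), radii = c(1, 3, 2),
            gridSpacing = 1.5, probeRadius = 0.5, found = TRUE)
  expect_equal(widestPoint(t1)$index, 2L)
  t2 <- new("Tunnel", centerline = cbind(0:2, 0, 0), radii = c(2, 2, 2),
            gridSpacing = 1.5, probeRadius = 0.5, found = TRUE)
  expect_equal(widestPoint(t2)$index, 1L)
  fb <- makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3, bulge = 1.5)
  tb <- findTunnel(fb$structure, fb$anchors$start, fb$anchors$end,
                   gridSpacing = 0.6)
  wp <- widestPoint(tb)
  expect_lt(sqrt(sum((wp$point - fb$truth$bulgePoint)^2)), 2 * 0.6)
  expect_gt(wp$radius, 3.5)
})

test_that("tunnel radii never exceed the true clearance (brute force)", {
  a <- atomData(phantomFx$structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cl <- tunnelCenterline(phantomTunnel)
  for (i in seq_len(nrow(cl))) {
    trueClear <- min(sqrt(rowSums(sweep(xyz, 2, cl[i, ])^2)) - a$vdw)
    expect_lte(tunnelRadii(phantomTunnel)[i], trueClear + 1e-9)
  }
})

test_that("grid refinement changes tunnel length by < 10%", {
  fx <- makeChannelPhantom(seed = 1, tubeLength = 10, radius = 3)
  l1 <- tunnelLength(findTunnel(fx$structure, fx$anchors$start, fx$anchors$end,
                                gridSpacing = 0.6))
  l2 <- tunnelLength(findTunnel(fx$structure, fx$anchors$start, fx$anchors$end,
                                gridSpacing = 0.3))
  expect_lt(abs(l1 - l2) / l2, 0.10)
})

test_that("sealed phantom is fully enclosed; windowed phantom is exposed at the window", {
  encl <- enclosureProfile(phantomFx$structure, phantomTunnel)
  expect_true(all(encl == "enclosed"))
  fw <- makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3,
                           window = list(axialFrom = 0.3, axialTo = 0.7,
                                         angleFrom = -55, angleTo = 55))
  tw <- findTunnel(fw$structure, fw$anchors$start, fw$anchors$end,
                   gridSpacing = 0.6)
  enclw <- enclosureProfile(fw$structure, tw)
  expect_true(any(enclw == "exposed"))
  # exposed flags concentrate at window-adjacent arc positions
  frac <- seq(0, 1, length.out = length(enclw))
  expect_true(all(frac[enclw == "exposed"] > 0.1 & frac[enclw == "exposed"] < 0.9))
  expect_true(all(enclw[frac < 0.1] == "enclosed"))
  expect_true(all(enclw[frac > 0.9] == "enclosed"))
})

test_that("no protein at all leaves every centerline point exposed", {
  far <- newStructure(data.frame(serial = 1L, name = "C", resname = "ALA",
                                 chain = "A", resnum = 1L,
                                 x = 22, y = 22, z = 22, element = "C"))
  tun <- findTunnel(far, c(0, 0, 0), c(8, 0, 0), gridSpacing = 0.8)
  encl <- enclosureProfile(far, tun)
  expect_true(all(encl == "exposed"))
})

test_that("enclosure flags match the graph-components reachability oracle exactly", {
  for (fx in list(phantomFx,
                  makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3,
                                     window = list(axialFrom = 0.3, axialTo = 0.7,
                                                   angleFrom = -55, angleTo = 55)))) {
    tun <- findTunnel(fx$structure, fx$anchors$start, fx$anchors$end,
                      gridSpacing = 0.6)
    mine <- enclosureProfile(fx$structure, tun)
    cl <- tunnelCenterline(tun)
    grid <- spiroscan:::.probeGrid(fx$structure, tun@gridSpacing, 1.4,
                                   extraPoints = cl,
                                   pad = 2 * 1.4 + 3 * tun@gridSpacing)
    channel <- spiroscan:::.channelMask(grid, tun)
    passable <- grid$open & !channel
    d <- grid$dims
    arr <- array(seq_len(prod(d)), dim = d)
    seeds <- unique(c(arr[1, , ], arr[d[1], , ], arr[, 1, ], arr[, d[2], ],
                      arr[, , 1], arr[, , d[3]]))
    reach <- reachabilityOracle(d, passable, seeds)
    lim <- tunnelRadii(tun) + sqrt(3) * grid$h
    coords <- spiroscan:::.nodeCoords(grid, which(reach))
    oracle <- vapply(seq_len(nrow(cl)), function(i) {
      if (!nrow(coords)) return("enclosed")
      dmin <- min(sqrt(rowSums(sweep(coords, 2, cl[i, ])^2)))
      if (dmin <= lim[i]) "exposed" else "enclosed"
    }, character(1))
    expect_identical(mine, oracle)
  }
})
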