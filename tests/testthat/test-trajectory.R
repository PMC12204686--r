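# trajectory readers, residence time, occupancy, path adherence

test_that("XYZ and multi-model PDB readers agree and reject ragged frames", {
  fx <- makeSyntheticTrajectories(seed = 4, n = 1, nFrames = 5, hazardPerFrame = 0)
  tr <- fx$trajectories[[1]]
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectoryXYZ(tr, xyz)
  t1 <- readTrajectory(xyz, dt = 0.1, ligandSelection = "element:O",
                       proteinSelection = "element:C")
  expect_equal(nFrames(t1), 5L)
  # same content as a multi-model PDB
  pdb <- withr::local_tempfile(fileext = ".pdb")
  con <- file(pdb, "w")
  for (f in 1:5) {
    lig <- ligandCoords(tr)[[f]]; prot <- proteinCoords(tr, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("HETATM%5d  O   ACD L   1    %8.3f%8.3f%8.3f  1.00  0.00           O",
                       1L, lig[1, 1], lig[1, 2], lig[1, 3]), con)
    writeLines(sprintf("ATOM  %5d  C   ALA T%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       seq_len(nrow(prot)) + 1L, seq_len(nrow(prot)) %% 9999L,
                       prot[, 1], prot[, 2], prot[, 3]), con)
    writeLines("ENDMDL", con)
  }
  close(con)
  t2 <- readTrajectory(pdb, dt = 0.1, ligandSelection = "resname:ACD",
                       proteinSelection = "not-resname:ACD")
  expect_equal(nFrames(t2), 5L)
  for (f in 1:5)
    expect_lt(max(abs(ligandCoords(t2)[[f]] - ligandCoords(t1)[[f]])), 1e-3)
  # ragged frame errors with the frame number
  bad <- readLines(xyz)
  bad[1] <- as.character(as.integer(bad[1]) + 1L)
  badf <- withr::local_tempfile(fileext = ".xyz")
  writeLines(bad, badf)
  expect_error(readTrajectory(badf, dt = 0.1, ligandSelection = "element:O",
                              proteinSelection = "element:C"))
})

test_that("residence time: programmed escape, censoring, and short excursions ignored", {
  # sustained escape starting frame 50 at dt 0.1 -> 5.0 ns
  d <- c(rep(2, 49), rep(20, 51))
  r <- residenceTime(distanceTrajectory(d), escapeDistance = 10, sustainFrames = 5)
  expect_false(isCensored(r))
  expect_equal(escapeFrame(r), 50L)
  expect_equal(residenceTimeNs(r), 5.0)
  # never beyond the threshold: censored at dt * n
  r2 <- residenceTime(distanceTrajectory(rep(3, 2000)), escapeDistance = 10)
  expect_true(isCensored(r2))
  expect_equal(residenceTimeNs(r2), 200.0)
  expect_true(is.na(escapeFrame(r2)))
  # a 3-frame excursion before a later true escape is ignored
  d3 <- c(rep(2, 30), rep(20, 3), rep(2, 30), rep(20, 10))
  r3 <- residenceTime(distanceTrajectory(d3), escapeDistance = 10, sustainFrames = 5)
  expect_equal(escapeFrame(r3), 64L)
  # brute-force sliding-window oracle over random distance series
  set.seed(12)
  for (k in 1:20) {
    dd <- runif(60, 0, 20)
    rr <- residenceTime(distanceTrajectory(dd), escapeDistance = 10, sustainFrames = 4)
    wins <- which(vapply(seq_len(57), function(f) all(dd[f:(f + 3)] > 10), TRUE))
    if (length(wins)) {
      expect_equal(escapeFrame(rr), wins[1])
    } else {
      expect_true(isCensored(rr))
    }
  }
})

test_that("residence time is monotone in escape distance and sustain frames (property)", {
  set.seed(31)
  for (k in 1:10) {
    dd <- cumsum(rnorm(80, 0.2, 1)) + 5
    tr <- distanceTrajectory(pmax(dd, 0.1))
    prev <- -Inf
    for (ed in c(5, 8, 12, 16)) {
      t <- residenceTimeNs(residenceTime(tr, escapeDistance = ed, sustainFrames = 3))
      expect_gte(t, prev)
      prev <- t
    }
    prev <- -Inf
    for (sf in c(1, 3, 6, 10)) {
      t <- residenceTimeNs(residenceTime(tr, escapeDistance = 10, sustainFrames = sf))
      expect_gte(t, prev)
      prev <- t
    }
  }
})

test_that("ensemble mean residence handles censoring as a lower bound", {
  mk <- function(t, cens) new("ResidenceResult", time = t, censored = cens,
                              escapeFrame = if (cens) NA_integer_ else 1L)
  m1 <- meanResidence(list(mk(4, FALSE), mk(4, FALSE), mk(4, FALSE)))
  expect_equal(m1$mean, 4); expect_equal(m1$sd, 0); expect_equal(m1$nCensored, 0)
  expect_false(m1$lowerBound)
  m2 <- meanResidence(list(mk(9, FALSE), mk(200, TRUE), mk(125, FALSE)))
  expect_equal(m2$mean, mean(c(9, 200, 125)), tolerance = 1e-9)
  expect_equal(m2$nCensored, 1L)
  expect_true(m2$lowerBound)
  expect_error(meanResidence(list()), "at least one")
})

test_that("hbond occupancy: always 1, never 0, Bernoulli truth recovered exactly", {
  close <- distanceTrajectory(rep(2.5, 40))
  expect_equal(hbondOccupancy(close, "ligand", "protein"), 1.0)
  farT <- distanceTrajectory(rep(9, 40))
  expect_equal(hbondOccupancy(farT, "ligand", "protein"), 0.0)
  fx <- makeSyntheticTrajectories(seed = 6, n = 2, nFrames = 1000,
                                  hazardPerFrame = 0, occupancyP = 0.30)
  for (k in 1:2) {
    occ <- hbondOccupancy(fx$trajectories[[k]], "ligand", "protein:ACC")
    expect_equal(occ, fx$truth$perTrajectory[[k]]$realizedOccupancy)
  }
})

test_that("path adherence: glued ligand 1.0, distant ligand 0.0, geometry oracle", {
  tun <- new("Tunnel", centerline = cbind(seq(0, 20, 0.5), 0, 0),
             radii = rep(3, 41), gridSpacing = 0.5, probeRadius = 1.4,
             found = TRUE)
  onAxis <- newTrajectory(0.1, lapply(seq(1, 19, length.out = 30),
                                      function(x) matrix(c(x, 0, 0), 1)),
                          list(matrix(c(10, 4.7, 0), 1)))
  expect_equal(pathAdherence(onAxis, tun), 1.0)
  away <- newTrajectory(0.1, lapply(1:30, function(x) matrix(c(x, 50, 0), 1)),
                        list(matrix(c(10, 49, 0), 1)))
  expect_equal(pathAdherence(away, tun, escapeDistance = 100), 0.0)
  # random positions vs a brute point-to-segment oracle
  set.seed(44)
  pts <- cbind(runif(50, -2, 22), runif(50, -8, 8), runif(50, -8, 8))
  tr <- newTrajectory(0.1, lapply(seq_len(50), function(i) matrix(pts[i, ], 1)),
                      list(matrix(c(10, 0, 0), 1)))
  mine <- pathAdherence(tr, tun, cutoff = 5, escapeDistance = 1e6)
  cl <- tunnelCenterline(tun)
  oracle <- mean(vapply(seq_len(50), function(i) {
    dmin <- Inf
    for (s in seq_len(nrow(cl) - 1)) {
      a <- cl[s, ]; b <- cl[s + 1, ]; ab <- b - a
      t <- max(0, min(1, sum((pts[i, ] - a) * ab) / sum(ab^2)))
      dmin <- min(dmin, sqrt(sum((pts[i, ] - (a + t * ab))^2)))
    }
    dmin <= 5
  }, TRUE))
  expect_equal(mine, oracle)
})

test_that("synthetic ensembles: residence recovers generator escape frames exactly", {
  fx <- makeSyntheticTrajectories(seed = 17, n = 4, dt = 0.1,
                                  hazardPerFrame = 0.02, nFrames = 400)
  for (k in 1:4) {
    r <- residenceTime(fx$trajectories[[k]])
    tr <- fx$truth$perTrajectory[[k]]
    expect_equal(isCensored(r), tr$censored)
    if (!tr$censored) expect_equal(escapeFrame(r), tr$escapeFrame)
    expect_equal(residenceTimeNs(r), tr$time)
  }
})
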