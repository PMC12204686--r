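# structure parsing, selection, writing, superposition

test_that("hand-written PDB parses with chains, residues, atoms and waters flagged", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END"), p)
  s <- readStructure(p)
  expect_s4_class(s, "SpiroStructure")
  expect_equal(chainIds(s), "A")
  expect_equal(nAtoms(s), 4L)
  rt <- residueTable(s)
  expect_equal(nrow(rt), 2L)
  expect_true(rt$hetero[rt$resname == "HOH"])
  expect_equal(atomData(s)$resnum[1], 1L)
})

test_that("identical content as PDB and mmCIF gives equal coordinates to 1e-3 A", {
  fx <- makeToyMultimer(seed = 11)
  a <- atomData(fx$structure)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(fx$structure, pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    sprintf("ATOM %d %s %s . %s %s %d ? %.3f %.3f %.3f 1.00",
            a$serial, a$element, a$name, a$resname, a$chain, a$resnum,
            a$x, a$y, a$z),
    "#"), cif)
  s1 <- readStructure(pdb)
  s2 <- readStructure(cif)
  expect_lt(max(abs(atomCoords(s1) - atomCoords(s2))), 1e-3)
  expect_identical(residueIds(s1), residueIds(s2))
})

test_that("unknown element is an error naming the atom", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  XX  ALA A   1       1.000   0.000   0.000  1.00  0.00          XX",
    "END"), p)
  expect_error(readStructure(p), "XX")
  expect_error(readStructure(p), "2")
})

test_that("write-then-reread reproduces coordinates to 1e-3 A and residue identities", {
  for (seed in c(1, 2)) {
    fx <- makeToyMultimer(seed = seed, nSaltBridges = 1, nHbonds = 2)
    p <- withr::local_tempfile(fileext = ".pdb")
    writeStructurePDB(fx$structure, p)
    s2 <- readStructure(p)
    expect_lt(max(abs(atomCoords(s2) - atomCoords(fx$structure))), 1e-3)
    expect_identical(residueIds(s2), residueIds(fx$structure))
    expect_identical(residueTable(s2)$resname, residueTable(fx$structure)$resname)
  }
})

test_that("selectChains returns exactly the requested chains and errors on absent ids", {
  fx <- makeToyMultimer(seed = 4)
  s <- fx$structure
  both <- selectChains(s, c("A", "B"))
  expect_equal(nAtoms(both), nAtoms(s))
  onlyA <- selectChains(s, "A")
  expect_equal(nAtoms(onlyA), sum(atomData(s)$chain == "A"))
  expect_identical(atomCoords(onlyA),
                   atomCoords(s)[atomData(s)$chain == "A", ])
  expect_error(selectChains(s, "Z"), "Z")
})

test_that("kabsch superposition: identity, rigid invariance, symmetry (property)", {
  set.seed(101)
  ref <- matrix(rnorm(45), ncol = 3)
  idk <- kabschSuperpose(ref, ref)
  expect_lte(idk$rmsd, 1e-9)
  for (rep in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    mob <- sweep(ref %*% R, 2, rnorm(3, 0, 10), `+`)
    k <- kabschSuperpose(ref, mob)
    expect_lte(k$rmsd, 1e-6)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    fitted <- applyTransform(mob, k$rotation, k$translation)
    expect_lt(max(abs(fitted - ref)), 1e-6)
  }
  # rmsd symmetric between noisy point sets
  noisy <- ref + matrix(rnorm(45, 0, 0.5), ncol = 3)
  expect_equal(kabschSuperpose(ref, noisy)$rmsd,
               kabschSuperpose(noisy, ref)$rmsd, tolerance = 1e-9)
})

test_that("kabsch rejects mismatched and degenerate input", {
  expect_error(kabschSuperpose(matrix(0, 3, 3), matrix(0, 4, 3)), "dimensions")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("sequence-paired Calpha superposition recovers a rigid transform", {
  set.seed(7)
  nres <- 25
  ca <- cbind(seq(0, 3.8 * (nres - 1), 3.8), rnorm(nres), rnorm(nres))
  resn <- sample(names(spiroscan:::AA3), nres, replace = TRUE)
  mk <- function(coords, ch) newStructure(data.frame(
    serial = seq_len(nres), name = "CA", resname = resn, chain = ch,
    resnum = seq_len(nres), x = coords[, 1], y = coords[, 2], z = coords[, 3],
    element = "C"))
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  out <- superposeChainsCA(mk(ca, "A"), "A",
                           mk(sweep(ca %*% R, 2, c(3, -4, 5), `+`), "B"), "B")
  expect_lt(out$rmsd, 1e-6)
  expect_equal(out$nPaired, nres)
})
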