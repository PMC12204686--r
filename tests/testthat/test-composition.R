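# composition, enrichment, MSA conservation, identity, motifs, homology

miniStructure <- function(resnames) {
  n <- length(resnames)
  newStructure(data.frame(serial = seq_len(n), name = "CA",
                          resname = resnames, chain = "A",
                          resnum = seq_len(n), x = 4 * seq_len(n), y = 0, z = 0,
                          element = "C"))
}

test_that("aa composition counts and frequencies; non-standard excluded with warning", {
  s <- miniStructure(c("ALA", "ALA", "GLY"))
  p <- aaComposition(residueIds(s), s)
  expect_equal(unname(aaCounts(p)[c("A", "G")]), c(2L, 1L))
  expect_equal(unname(aaFrequencies(p)[c("A", "G")]), c(2 / 3, 1 / 3))
  expect_equal(sum(aaFrequencies(p)), 1, tolerance = 1e-12)
  all20 <- miniStructure(names(spiroscan:::AA3))
  p20 <- aaComposition(residueIds(all20), all20)
  expect_true(all(abs(aaFrequencies(p20) - 0.05) < 1e-12))
  withNS <- miniStructure(c("ALA", "MSE", "GLY"))
  expect_warning(pns <- aaComposition(residueIds(withNS), withNS), "non-standard")
  expect_equal(sum(aaCounts(pns)), 2L)
  expect_equal(pns@nonStandard, 1L)
  expect_error(aaComposition(character(0), s), "empty")
})

test_that("composition of a phantom lining matches the generator design", {
  fx <- makeChannelPhantom(seed = 1, tubeLength = 16, radius = 3)
  p <- aaComposition(fx$truth$liningResidues, fx$structure)
  rt <- residueTable(fx$structure)
  expected <- table(factor(spiroscan:::AA3[rt$resname], levels = unname(spiroscan:::AA3)))
  expect_equal(unname(aaCounts(p)), as.integer(expected))
})

test_that("log2 enrichment: identity gives zeros; doubling gives ~ +1; zero counts stay finite", {
  s <- miniStructure(rep(names(spiroscan:::AA3), 10))
  p <- proteinComposition(s)
  e0 <- log2Enrichment(p, p)
  expect_true(all(log2FoldChange(e0) == 0))
  # channel with A at 10% vs protein at 5%, large counts
  chanNames <- c(rep("ALA", 40), rep(names(spiroscan:::AA3)[-1], each = 19))
  sc <- miniStructure(chanNames)
  ech <- log2Enrichment(proteinComposition(sc), p)
  expect_equal(unname(log2FoldChange(ech)["A"]), 1, tolerance = 0.05)
  # zero-count channel lysine: matches the smoothing formula and is strongly negative
  chan2 <- aaComposition(residueIds(miniStructure(rep("ALA", 50))),
                         miniStructure(rep("ALA", 50)))
  e2 <- log2Enrichment(chan2, p, alpha = 0.5)
  cc <- aaCounts(chan2); pc <- aaCounts(p)
  manual <- log2(((cc["K"] + 0.5) / (sum(cc) + 10)) / ((pc["K"] + 0.5) / (sum(pc) + 10)))
  expect_equal(unname(log2FoldChange(e2)["K"]), unname(manual), tolerance = 1e-12)
  expect_lt(log2FoldChange(e2)["K"], -2)
  expect_true(all(is.finite(log2FoldChange(e2))))
  expect_error(log2Enrichment(chan2, p, alpha = 0), "alpha")
})

test_that("MSA reading: FASTA and Clustal give the same matrix; ragged input errors", {
  fx <- makeToyMsa(seed = 2, nRows = 5, length = 12)
  fp <- withr::local_tempfile(fileext = ".fasta")
  writeMsaFasta(fx$msa, fp)
  m1 <- readMsa(fp)
  expect_identical(msaMatrix(m1), msaMatrix(fx$msa))
  expect_identical(msaNames(m1), msaNames(fx$msa))
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               sprintf("%-8s %s", msaNames(fx$msa),
                       apply(msaMatrix(fx$msa), 1, paste, collapse = ""))), cl)
  m2 <- readMsa(cl)
  expect_identical(msaMatrix(m2), msaMatrix(fx$msa))
  rag <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">row1", "ACDEF", ">row2", "ACD"), rag)
  expect_error(readMsa(rag), "row2")
  expect_error(setMsaReference(m1, "nonexistent"), "not found")
})

test_that("column conservation: invariant columns 100, fractions exact, truth recovered", {
  mm <- new("MsaAlignment", names = paste0("s", 1:10),
            seqs = matrix(rep("A", 10), ncol = 1), refIndex = 1L)
  expect_equal(columnConservation(mm)$conservation, 100)
  m4 <- new("MsaAlignment", names = paste0("s", 1:4),
            seqs = rbind(c("A", "C"), c("A", "C"), c("A", "-"), c("G", "C")),
            refIndex = 1L)
  expect_equal(columnConservation(m4)$conservation, c(75, 75))
  for (seed in c(3, 9)) {
    fx <- makeToyMsa(seed = seed, nRows = 8, length = 25)
    cc <- columnConservation(fx$msa)
    expect_equal(cc$conservation, fx$truth$realizedConservation)
    expect_true(all(cc$conservation > 0 & cc$conservation <= 100))
  }
})

test_that("pairwise identity: exact cases and symmetry", {
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKL")$identityPercent, 100)
  expect_equal(pairwiseIdentity("ACDE", "ACDF")$identityPercent, 75)
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYIARQRQISFVKSHFARQLEERLGLIEVQAPILSRVGDGTQDNLSGAEK"
  expect_equal(pairwiseIdentity(a, b)$identityPercent,
               pairwiseIdentity(b, a)$identityPercent, tolerance = 1e-9)
  expect_error(pairwiseIdentity("AC1DE", "ACDE"), "non-amino-acid")
  expect_error(pairwiseIdentity("", "ACDE"), "empty")
})

test_that("motif scan matches a regex oracle and handles overlaps", {
  expect_equal(motifScan("AAGAGTTGAA", "GxGxxG"), 3L)
  expect_length(motifScan("AAAAAAA", "GxGxxG"), 0)
  expect_equal(motifScan("GGGG", "GG"), c(1L, 2L, 3L))
  set.seed(5)
  for (k in 1:30) {
    s <- paste(sample(c("G", "A", "L", "S"), 40, replace = TRUE), collapse = "")
    expect_identical(motifScan(s, "GxGxxG"), motifOracle(s, "GxGxxG"))
    expect_identical(motifScan(s, "GAx"), motifOracle(s, "GAx"))
  }
  expect_error(motifScan("ACDE", ""), "non-empty")
})

test_that("set homology: identity mapping 100, divergent 0, designed 8/10 is 80", {
  mp <- alignmentMapping("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(setHomology(1:10, 1:10, mp)$identityPercent, 100)
  mpDiv <- alignmentMapping("AAAAKKKKWW", "GGGGRRRRFF")
  expect_equal(setHomology(1:10, 1:10, mpDiv)$identityPercent, 0)
  mp8 <- alignmentMapping("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVAA")
  h <- setHomology(11:20, 11:20, mp8)
  expect_equal(h$identityPercent, 80)
  expect_gte(h$similarityPercent, h$identityPercent)
  expect_error(setHomology(integer(0), 1:3, mp), "empty")
})
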