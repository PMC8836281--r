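test_that("modification-annotated sequences parse and round-trip", {
  p <- parsePeptide("LLLGAGCM(+15.99)")
  expect_equal(nResidues(p), 8)
  expect_equal(modifications(p), c("8" = 15.99))
  expect_equal(peptideString(p), "LLLGAGCM(+15.99)")
  expect_equal(peptideSequence(p), "LLLGAGCM")

  q <- parsePeptide("CPANGFY")
  expect_equal(nResidues(q), 7)
  expect_length(modifications(q), 0)

  # Unicode minus and internal modifications
  r <- parsePeptide("AM(−17.03)K")
  expect_equal(unname(modifications(r)), -17.03)
  expect_equal(names(modifications(r)), "2")

  expect_error(parsePeptide("M(+15.99)(+15.99)"), "dangling|preceding")
  expect_error(parsePeptide("(+15.99)M"), "dangling")
  expect_error(parsePeptide("ABZ"), "unknown residue letter 'B' at position 2")
  expect_error(parsePeptide("AM(+15.99"), "unterminated")
})

test_that("monoisotopic masses match reference values", {
  expect_equal(monoisotopicMass(parsePeptide("CPANGFY")), 770.3057,
               tolerance = 0.001 / 770)
  expect_equal(monoisotopicMass(parsePeptide("G")), 75.0320,
               tolerance = 0.001 / 75)
  # nominal +15.99 is promoted to the exact oxidised-Met delta by default
  p <- parsePeptide("LLLGAGCM(+15.99)")
  expect_equal(monoisotopicMass(p), 792.3874, tolerance = 0.001 / 792)
  expect_equal(monoisotopicMass(p, canonicalMods = FALSE),
               monoisotopicMass(p) - 15.994915 + 15.99, tolerance = 1e-12)
})

test_that("theoretical m/z and ppm error follow their definitions", {
  ccysvy <- parsePeptide("CCYSVY")
  expect_equal(theoreticalMz(ccysvy, 2), 369.1353, tolerance = 0.001 / 369)
  ld <- parsePeptide("LDTANEMNQLDLQFR")
  expect_equal(theoreticalMz(ld, 2), 904.4358, tolerance = 0.001 / 904)
  p <- parsePeptide("INTISGR")
  expect_equal(theoreticalMz(p, 1), monoisotopicMass(p) + 1.007276)
  expect_error(theoreticalMz(p, 0), "positive")

  expect_equal(ppmError(theoreticalMz(p, 2), p, 2), 0)
  expect_equal(ppmError(theoreticalMz(p, 2) * (1 + 1e-6), p, 2), 1,
               tolerance = 1e-6)
  expect_equal(ppmError(369.1365, ccysvy, 2), 3.3, tolerance = 0.1)
})

test_that("mass is additive over sequence splits", {
  set.seed(41)
  for (i in 1:25) {
    s <- randomPeptide(4, 30)
    cut <- sample(seq_len(nchar(s) - 1), 1)
    whole <- monoisotopicMass(parsePeptide(s))
    pre <- monoisotopicMass(parsePeptide(substr(s, 1, cut)))
    suf <- monoisotopicMass(parsePeptide(substr(s, cut + 1, nchar(s))))
    expect_equal(whole, pre + suf - 18.010565, tolerance = 1e-9)
  }
})

test_that("m/z decreases strictly in charge for fixed mass", {
  p <- parsePeptide("VHVFRFDQNQDLLPIGN")
  mz <- vapply(1:5, function(z) theoreticalMz(p, z), numeric(1))
  expect_true(all(diff(mz) < 0))
})

test_that("hydrophobic fraction and C-terminal rule behave positionally", {
  expect_equal(hydrophobicFraction(parsePeptide("AAAA")), 1)
  expect_equal(hydrophobicFraction(parsePeptide("KKKK")), 0)
  expect_equal(hydrophobicFraction(parsePeptide("CCYSVY")), 1 / 6)

  expect_true(ctermRule(parsePeptide("VCGEAFGKA")))
  expect_false(ctermRule(parsePeptide("GGGSSS")))
  expect_true(ctermRule(parsePeptide("R")))
  # hydrophobic fraction is permutation-invariant, the C-terminal rule is not
  expect_equal(hydrophobicFraction(parsePeptide("AGGGGG")),
               hydrophobicFraction(parsePeptide("GGGGGA")))
  expect_false(ctermRule(parsePeptide("AGGGGG")))
  expect_true(ctermRule(parsePeptide("GGGGGA")))
})

test_that("residue census counts every residue exactly once", {
  cen <- residueCensus(parsePeptide("CCYSVY"))
  expect_equal(cen[c("C", "Y", "S", "V")], c(C = 2L, Y = 2L, S = 1L, V = 1L))
  expect_equal(sum(cen), 6L)
  expect_equal(residueCensus(parsePeptide("G")), c(G = 1L))
  cen2 <- residueCensus(parsePeptide("DCHYFL"))
  expect_equal(unname(cen2[c("C", "H")]), c(1L, 1L))
})

test_that("residue class configuration rejects overlapping sets", {
  expect_error(residueClassConfig(hydrophobic = c("A", "K")),
               "disjoint")
  cfg <- residueClassConfig(hydrophobic = "G", basic = "K")
  expect_equal(hydrophobicFraction(parsePeptide("GGK"), cfg), 2 / 3)
})

test_that("FASTA round-trips bare sequences and keeps modifications in headers", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  peps <- list(parsePeptide("CCYSVY"), parsePeptide("LLLGAGCM(+15.99)"))
  writePeptideFasta(peps, tmp, names = c("a", "b"))
  back <- readPeptideFasta(tmp)
  expect_equal(names(back), c("a", "b"))
  expect_equal(peptideSequence(back$b), "LLLGAGCM")
  expect_match(readLines(tmp)[3], "LLLGAGCM\\(\\+15.99\\)")
})
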