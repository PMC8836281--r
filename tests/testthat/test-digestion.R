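golden_pepsin <- list(
  LDTANEMNQLDLQFR = "L-DTANEMNQL-DL-QF-R",
  VVLQDTSNNVNQLD = "VVL-QDTSNNVNQL-D",
  IFSGGESSGQPR = "IF-SGGESSGQPR",
  VHVFRFDQNQDLLPIGN = "VHVF-RF-DQNQDL-L-PIGN")

golden_chymo <- list(
  CPANGFY = "CPAN-GF-Y",
  CCYSVY = "CCY-SVY",
  LYPFAH = "L-YPF-AH",
  INTISGR = "IN-TISGR",
  NALLCSNS = "N-AL-L-CSN-S",
  QDTSNNVNQLDDIPRR = "QDTSN-N-VN-QL-DDIPRR",
  LDTANEMNQLDLQFR = "L-DTAN-EM-N-QL-DL-QF-R")

test_that("bundled enzyme profiles reproduce the reference fragmentations", {
  rules <- defaultEnzymes()
  for (seqstr in names(golden_pepsin)) {
    d <- cleave(parsePeptide(seqstr), rules$pepsin_ph1.3)
    expect_equal(fragmentString(d), golden_pepsin[[seqstr]], info = seqstr)
  }
  for (seqstr in names(golden_chymo)) {
    d <- cleave(parsePeptide(seqstr), rules$chymotrypsin_like)
    expect_equal(fragmentString(d), golden_chymo[[seqstr]], info = seqstr)
  }
  # trypsin: a terminal R is not an internal site
  expect_equal(fragmentString(cleave(parsePeptide("INTISGR"), rules$trypsin)),
               "INTISGR")
  # no P1 residues -> parent unchanged
  expect_equal(fragments(cleave(parsePeptide("GGSSAG"),
                                rules$pepsin_ph1.3)), "GGSSAG")
})

test_that("proline blocks cleavage at P1prime", {
  rules <- defaultEnzymes()
  d <- cleave(parsePeptide("LYPFAH"), rules$chymotrypsin_like)
  expect_equal(fragments(d), c("L", "YPF", "AH"))    # Y-P bond intact
  expect_equal(cutSites(d), c(1L, 4L))
  d2 <- cleave(parsePeptide("AKPR"), rules$trypsin)  # K-P intact
  expect_equal(fragments(d2), "AKPR")
})

test_that("digestion fragments always reassemble and re-digest to themselves", {
  rules <- defaultEnzymes()
  set.seed(13)
  for (i in 1:1000) {
    s <- randomPeptide(1, 30)
    r <- rules[[sample(length(rules), 1)]]
    d <- cleave(parsePeptide(s), r)
    expect_equal(paste(fragments(d), collapse = ""), s)
    expect_equal(length(fragments(d)), length(cutSites(d)) + 1L)
    for (f in fragments(d))
      expect_equal(fragments(cleave(parsePeptide(f), r)), f)
  }
})

test_that("cut sites equal the position-by-position rule oracle", {
  rules <- defaultEnzymes()
  set.seed(29)
  for (i in 1:100) {
    s <- randomPeptide(2, 25)
    for (r in rules) {
      expect_equal(cutSites(cleave(parsePeptide(s), r)),
                   bruteForceCutSites(s, r@p1, r@blockP1prime),
                   info = paste(s, r@name))
    }
  }
})

test_that("multi-enzyme digestion supports independent and sequential modes", {
  rules <- defaultEnzymes()
  p <- parsePeptide("LDTANEMNQLDLQFR")
  ind <- digestMulti(p, rules, mode = "independent")
  expect_named(ind, c("pepsin_ph1.3", "trypsin", "chymotrypsin_like"))
  expect_equal(fragmentString(ind$pepsin_ph1.3), golden_pepsin$LDTANEMNQLDLQFR)
  expect_equal(fragmentString(ind$chymotrypsin_like),
               golden_chymo$LDTANEMNQLDLQFR)

  seq_d <- digestMulti(p, rules, mode = "sequential")
  # cut sites accumulate along the chain
  expect_true(all(cutSites(seq_d[[1]]) %in% cutSites(seq_d[[2]])))
  expect_true(all(cutSites(seq_d[[2]]) %in% cutSites(seq_d[[3]])))
  expect_equal(cutSites(seq_d[[3]]),
               sort(Reduce(union, lapply(ind, cutSites))))
  expect_error(digestMulti(p, list()), "at least one")
})

test_that("whole fragments, not substrings, gain bioactivity annotations", {
  rules <- defaultEnzymes()
  lib <- defaultMotifLibrary()
  d1 <- annotateFragments(cleave(parsePeptide("CCYSVY"),
                                 rules$chymotrypsin_like), lib)
  ann1 <- annotations(d1)
  expect_equal(ann1$fragment[ann1$activity == "ACE_inhibitor"], "SVY")
  # VY occurs inside SVY but is not a released fragment: not annotated
  expect_false("VY" %in% ann1$fragment)

  d2 <- annotateFragments(cleave(parsePeptide("CPANGFY"),
                                 rules$chymotrypsin_like), lib)
  ann2 <- annotations(d2)
  expect_setequal(ann2$activity[ann2$fragment == "GF"],
                  c("ACE_inhibitor", "DPP_IV_inhibitor", "DPP_III_inhibitor"))

  d3 <- annotateFragments(cleave(parsePeptide("GGGG"),
                                 rules$pepsin_ph1.3), lib)
  expect_equal(nrow(annotations(d3)), 0)
})

test_that("digest reports are written in hyphen-joined notation", {
  rules <- defaultEnzymes()
  lib <- defaultMotifLibrary()
  p <- parsePeptide("CPANGFY")
  digs <- lapply(digestMulti(p, rules), annotateFragments, library = lib)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeDigestReport(list(CPANGFY = digs), tmp)
  tab <- read.delim(tmp)
  chym <- tab[tab$enzyme == "chymotrypsin_like", ]
  expect_equal(chym$fragments, "CPAN-GF-Y")
  expect_match(chym$bioactive_fragments, "GF: ACE_inhibitor")
})
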