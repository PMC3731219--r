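# Gate builders, constraints and specification validation.

test_that("the NOT builder emits the expected truth table and terms", {
  g <- makeNotGate(utrLen = 30, srnaLen = 20)
  expect_equal(gateType(g), "NOT_direct")
  expect_equal(length(g@entries), 2L)
  kinds <- vapply(g@terms, function(t) t@kind, character(1))
  expect_equal(sum(kinds == "kin"), 1L)
  expect_equal(sum(kinds == "str"), 2L)
  senses <- vapply(g@terms[kinds == "kin"], function(t) t@sense, character(1))
  expect_equal(senses, "occur")

  # SD sits 8 nt upstream of the start codon
  m <- g@species[[2]]
  sd <- m@motifs[[1]]
  aug <- m@motifs[[2]]
  expect_equal(sd$seq, "AGGAGA")
  expect_equal(aug$at - (sd$at + nchar(sd$seq)), 8L)

  expect_error(makeNotGate(srnaLen = 5), "cannot cover")
})

test_that("hairpin variants are accepted as sRNA targets", {
  for (tgt in c("((((....))))........",
                ".(((....))).((...)).",
                "((((((........))))))")) {
    g <- makeNotGate(utrLen = 30, srnaLen = 20, srnaTargetStructure = tgt)
    kinds <- vapply(g@terms, function(t) t@kind, character(1))
    # the structured sRNA adds an inverse-folding term
    expect_equal(sum(kinds == "str"), 3L)
  }
})

test_that("YES variants flip the structural masks appropriately", {
  g <- makeYesGate()
  tgt <- strsplit(g@species[[2]]@targetStructure, "")[[1]]
  sd <- g@species[[2]]@motifs[[1]]
  sdPos <- sd$at:(sd$at + 5L)
  expect_true(all(tgt[sdPos] == ")"))  # cis-repressed RBS

  offTerm <- g@terms[[1]]
  expect_identical(offTerm@maskState, "paired")
  onTerm <- g@terms[[3]]
  expect_identical(onTerm@maskState, "unpaired")

  gn <- makeYesGate(variant = "NOT_cis")
  expect_equal(gateType(gn), "NOT_cis")
  expect_identical(gn@terms[[1]]@maskState, "unpaired")
  expect_identical(gn@terms[[3]]@maskState, "paired")

  ga <- makeYesGate(variant = "YES_antiterm")
  expect_equal(gateType(ga), "YES_antiterm")
  motifs <- vapply(ga@species[[2]]@motifs, function(m) m$seq, character(1))
  expect_true("UUUUUU" %in% motifs)    # poly(U) tail
  tgt <- strsplit(ga@species[[2]]@targetStructure, "")[[1]]
  expect_equal(sum(tgt == "("), 6L)    # terminator stem
  expect_identical(ga@terms[[3]]@maskState, "unpaired")  # disrupted
})

test_that("the AND builder wires up avoid/occur reactions", {
  g <- makeAndGate()
  expect_equal(length(g@entries), 4L)  # 00, 01, 10, 11
  kin <- Filter(function(t) t@kind == "kin", g@terms)
  senses <- vapply(kin, function(t) t@sense, character(1))
  expect_equal(sum(senses == "avoid"), 2L)
  parts <- lapply(kin, function(t) t@participants)
  expect_true(any(vapply(parts, function(p)
    identical(p, c("sRNA1", "sRNA2")), logical(1))))  # dimer must form
  expect_true(any(lengths(parts) == 3L))               # triple complex
  # kin terms one per reaction
  expect_equal(length(kin), length(g@reactions))
})

test_that("every entry contributes at least one term", {
  for (g in list(makeNotGate(), makeYesGate(), makeAndGate())) {
    entryLabels <- unique(vapply(g@terms, function(t) t@entry, character(1)))
    expect_equal(length(setdiff(entryLabels, "species")), length(g@entries))
  }
})

test_that("constrainGate pins species and checks motifs", {
  g <- makeNotGate(utrLen = 17, srnaLen = 6)
  g2 <- constrainGate(g, c(sRNA = "UCUCCU"), gateType = "coupled_YES_NOT")
  expect_equal(gateType(g2), "coupled_YES_NOT")
  expect_identical(g2@species[[1]]@fixedSequence, "UCUCCU")

  # fixing a species with a motif mismatch is a spec error
  expect_error(constrainGate(g, c(mRNA = strrep("A", 17))), "motif")
  expect_error(constrainGate(g, c(sRNA = "ACGU")), "nt")
  expect_error(constrainGate(g, c(nope = "ACGUAC")), "unknown species")
})

test_that("validateGateSpec catches inconsistent specifications", {
  expect_true(validateGateSpec(makeYesGate()))

  # a target stem between two motif-fixed, non-complementary bases
  bad <- speciesSpec("x", "mRNA_5UTR", 8L, "(......)",
                     motifs = list(list(seq = "GG", at = 1L),
                                   list(seq = "GG", at = 7L)))
  g <- new("GateSpec", gateType = "YES",
           species = list(bad), entries = list(), reactions = list(),
           terms = list())
  expect_error(validateGateSpec(g), "not complementary")

  # missing truth-table entry
  g <- makeAndGate()
  g@entries <- g@entries[-2L]
  expect_error(validateGateSpec(g), "missing truth-table entry")

  # duplicate entry
  g <- makeNotGate()
  g@entries <- c(g@entries, g@entries[2L])
  expect_error(validateGateSpec(g), "duplicate truth-table entry")

  # contradictory mask within one entry
  g <- makeNotGate()
  g@terms <- c(g@terms, list(strTerm("mRNA", maskPositions = g@terms[[1]]@maskPos,
                                     maskState = "paired", entry = "0")))
  expect_error(validateGateSpec(g), "both paired and unpaired")

  # overlapping motifs
  bad <- speciesSpec("x", "mRNA_5UTR", 10L,
                     motifs = list(list(seq = "AGGAGA", at = 1L),
                                   list(seq = "AUG", at = 4L)))
  g <- new("GateSpec", gateType = "YES", species = list(bad),
           entries = list(), reactions = list(), terms = list())
  expect_error(validateGateSpec(g), "overlapping")
})

test_that("builders produce specs that their own validator accepts", {
  gates <- list(makeNotGate(), makeYesGate(), makeYesGate(variant = "NOT_cis"),
                makeYesGate(variant = "YES_antiterm"), makeAndGate())
  for (g in gates) expect_true(validateGateSpec(g))
})
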