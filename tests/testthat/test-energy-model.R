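# Folding engine: MFE prediction, structure evaluation, pairing
# probabilities.

test_that("single-strand MFE matches hand-checked cases", {
  f <- foldMFE("GGGAAAACCC")
  expect_equal(dbString(f), "(((....)))")
  expect_equal(freeEnergy(f), -9)

  f <- foldMFE("AAAAA")
  expect_equal(dbString(f), ".....")
  expect_equal(freeEnergy(f), 0)

  # the minimum hairpin loop of 3 forbids any pair of a 4-mer
  f <- foldMFE("ACGU")
  expect_equal(dbString(f), "....")
  expect_equal(freeEnergy(f), 0)
})

test_that("fold rejects invalid alphabets", {
  expect_error(foldMFE("ACGX"), "alphabet")
})

test_that("cofold handles complexes and non-interacting partners", {
  f <- cofoldMFE(c("GGGG", "CCCC"))
  expect_equal(freeEnergy(f), -12)
  expect_equal(nrow(pairMap(f)), 4L)   # 4 intermolecular GC pairs
  expect_equal(dbString(f), "((((&))))")

  expect_equal(freeEnergy(cofoldMFE(c("AAAA", "AAAA"))), 0)

  # a partner that cannot pair leaves the fold untouched
  expect_equal(freeEnergy(cofoldMFE(c("GGGAAAACCC", "AAAA"))),
               freeEnergy(foldMFE("GGGAAAACCC")))

  expect_error(cofoldMFE(c("GG", "CC", "GG", "CC")), "2 or 3")
})

test_that("evaluateStructure sums pair energies and rejects bad input", {
  expect_equal(evaluateStructure("GGGAAAACCC", "(((....)))"), -9)
  expect_equal(evaluateStructure("GGGAAAACCC", ".........."), 0)
  # loop minimum violated
  expect_error(evaluateStructure("GCGC", "()()"), "hairpin")
  # non-complementary pair under the model
  expect_error(evaluateStructure("GGAAAAGG", "(......)"), "not complementary")
  # strand mismatch
  expect_error(evaluateStructure("GGGG", "((((&))))"), "strand")
})

test_that("MFE equals exhaustive enumeration on random sequences", {
  set.seed(11)
  for (k in 1:60) {
    s <- randomRNA(sample(4:10, 1))
    expect_equal(freeEnergy(foldMFE(s)), oracleMFE(s), info = s)
  }
})

test_that("removing a pair from the MFE structure cannot go below MFE", {
  set.seed(12)
  for (k in 1:20) {
    s <- randomRNA(10)
    f <- foldMFE(s)
    pm <- pairMap(f)
    if (nrow(pm) == 0L) next
    sym <- strsplit(dbString(f), "")[[1]]
    sym[pm[1, ]] <- "."
    expect_gte(evaluateStructure(s, paste(sym, collapse = "")),
               freeEnergy(f))
  }
})

test_that("folding is deterministic", {
  set.seed(13)
  seqs <- replicate(10, randomRNA(12))
  a <- lapply(seqs, function(s) foldMFE(s))
  b <- lapply(seqs, function(s) foldMFE(s))
  expect_identical(lapply(a, dbString), lapply(b, dbString))
  expect_identical(lapply(a, freeEnergy), lapply(b, freeEnergy))
})

test_that("pairing probabilities are normalized and match enumeration", {
  # no intramolecular pair is possible in a G homopolymer
  expect_true(all(pairProbabilities("GGGG") == 0))

  # Boltzmann limit: the duplex pairs dominate at low RT
  P <- pairProbabilities(c("GGGG", "CCCC"), RT = 0.05)
  expect_true(all(diag(P[1:4, 8:5]) > 0.99))

  set.seed(14)
  for (k in 1:5) {
    a <- randomRNA(5)
    b <- randomRNA(5)
    P <- pairProbabilities(c(a, b), RT = 0.61)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(rowSums(P) <= 1 + 1e-9))
    expect_equal(P, oraclePairProb(a, b), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  expect_error(pairProbabilities(c(strrep("AC", 20), "GGG")),
               "limit")
})

test_that("the external engine adapter folds through RNAfold/RNAcofold", {
  m <- viennaEnergyModel()
  f <- foldMFE("GGGGAAAACCCC", m)
  expect_s4_class(foldedStructure(f), "DotBracket")
  expect_lte(freeEnergy(f), 0)
  f2 <- foldMFE("GGGGAAAACCCC", m)
  expect_identical(dbString(f), dbString(f2))

  cf <- cofoldMFE(c("GGGGGG", "CCCCCC"), m)
  expect_lte(freeEnergy(cf), 0)
  expect_equal(length(strsplit(dbString(cf), "&")[[1]]), 2L)
})
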