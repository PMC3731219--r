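# Simulated annealing: initialization, mutation operators, acceptance
# rule and full design runs.

test_that("initialization satisfies structural and subsequence constraints", {
  g <- makeYesGate()   # structured mRNA with SD/AUG motifs
  sdAt <- g@species[[2]]@motifs[[1]]$at
  db <- dotBracket(g@species[[2]]@targetStructure)
  pm <- pairMap(db)
  set.seed(41)
  for (k in 1:20) {
    cand <- initializeCandidate(g)
    seqs <- candidateSequences(cand)
    expect_equal(nchar(seqs[["mRNA"]]), 30L)
    expect_equal(substr(seqs[["mRNA"]], sdAt, sdAt + 5L), "AGGAGA")
    # every target stem pair is sampled complementary
    m <- riboforge:::.seqToInt(seqs[["mRNA"]])
    expect_true(all(m[pm[, 1]] + m[pm[, 2]] == 3L))
    # no illegal homopolymer run
    expect_false(riboforge:::.hasIllegalRun(
      m, cand$meta$mRNA$protected, 4L))
  }
  # seeded reproducibility
  set.seed(7)
  a <- candidateSequences(initializeCandidate(g))
  set.seed(7)
  b <- candidateSequences(initializeCandidate(g))
  expect_identical(a, b)
})

test_that("mutation proposals preserve every hard constraint", {
  g <- makeYesGate()
  sdAt <- g@species[[2]]@motifs[[1]]$at
  pm <- pairMap(dotBracket(g@species[[2]]@targetStructure))
  set.seed(42)
  cand <- initializeCandidate(g)
  lens <- vapply(cand$seqs, length, integer(1))
  protectedBases <- cand$seqs$mRNA[cand$meta$mRNA$protected]

  wordMoves <- 0L
  for (k in 1:2000) {
    wl <- sample(1:3, 1)
    prop <- mutateCandidate(cand, wl)
    expect_false(is.null(prop))
    s <- prop$candidate$seqs
    expect_identical(vapply(s, length, integer(1)), lens)
    expect_identical(s$mRNA[cand$meta$mRNA$protected], protectedBases)
    expect_true(all(s$mRNA[pm[, 1]] + s$mRNA[pm[, 2]] == 3L))
    for (nm in names(s)) {
      expect_false(riboforge:::.hasIllegalRun(
        s[[nm]], cand$meta[[nm]]$protected, 4L))
    }
    if (startsWith(prop$move, "word")) wordMoves <- wordMoves + 1L
    cand <- prop$candidate
  }
  expect_gt(wordMoves, 500L)
})

test_that("the directed move inserts the reverse complement of the word", {
  g <- makeNotGate(utrLen = 30, srnaLen = 20)
  set.seed(43)
  cand <- initializeCandidate(g)
  for (k in 1:50) {
    prop <- mutateCandidate(cand, 3L, moveMix = 1)
    m <- regmatches(prop$move,
                    regexec("word:(\\w+)\\[(\\d+)\\.\\.(\\d+)\\]->(\\w+)@(\\d+)",
                            prop$move))[[1]]
    if (length(m) == 0) next   # fell back to a point move
    src <- m[2]; i1 <- as.integer(m[3]); i2 <- as.integer(m[4])
    tgt <- m[5]; at <- as.integer(m[6])
    word <- cand$seqs[[src]][i1:i2]
    inserted <- prop$candidate$seqs[[tgt]][at:(at + (i2 - i1))]
    expect_identical(inserted, rev(3L - word))
  }
})

test_that("Metropolis acceptance matches its closed form", {
  expect_true(metropolisAccept(-1, 1))
  expect_true(metropolisAccept(0, 1))
  set.seed(44)
  temp <- 2
  acc <- vapply(1:20000, function(i) metropolisAccept(temp * log(2), temp),
                logical(1))
  # binomial 3-sigma band around 1/2
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("homodimer screening keeps inert sequences and drops palindromes", {
  expect_false(homodimerCheck("GGGGGG"))
  expect_true(homodimerCheck("GGGCCC"))
  expect_false(homodimerCheck("AAAA"))
})

test_that("annealing solves a toy inverse-folding problem exactly", {
  g <- toyFoldGate()
  res <- runDesign(g, optimizerConfig(iterations = 3000, rngSeed = 2))
  expect_equal(res@objective, 0)
  expect_equal(dbString(foldMFE(designSequences(res)[["hp"]])),
               "((((...))))")
})

test_that("design runs are deterministic and track the best candidate", {
  g <- makeNotGate(utrLen = 20, srnaLen = 10)
  a <- runDesign(g, optimizerConfig(iterations = 400, rngSeed = 99))
  b <- runDesign(g, optimizerConfig(iterations = 400, rngSeed = 99))
  expect_identical(designSequences(a), designSequences(b))
  expect_identical(trajectory(a), trajectory(b))
  expect_lte(a@objective, min(trajectory(a)$objective) + 1e-9)
  # every logged candidate keeps the motifs
  expect_equal(substr(designSequences(a)[["mRNA"]], 4, 9), "AGGAGA")
})

test_that("the word-length schedule steps 3 -> 2 -> 1", {
  expect_equal(riboforge:::.wordLenAt(1L, 9000L, 3L), 3L)
  expect_equal(riboforge:::.wordLenAt(3000L, 9000L, 3L), 3L)
  expect_equal(riboforge:::.wordLenAt(3001L, 9000L, 3L), 2L)
  expect_equal(riboforge:::.wordLenAt(6001L, 9000L, 3L), 1L)
  expect_equal(riboforge:::.wordLenAt(9000L, 9000L, 3L), 1L)
})

test_that("the harmonic relaxation penalizes structural deviation", {
  g <- toyFoldGate()
  seqs <- list(hp = riboforge:::.seqToInt("AAAAAAAAAAA"))
  plan <- riboforge:::.compileGate(g, objectiveConfig())
  plain <- riboforge:::.scoreCandidate(seqs, plan, objectiveConfig(),
                                       referenceEnergyModel(), -7.5)
  relaxed <- riboforge:::.scoreCandidate(seqs, plan, objectiveConfig(),
                                         referenceEnergyModel(), -7.5,
                                         harmonicStiffness = 0.5)
  d <- 8  # all 8 target brackets unpaired in the all-A fold
  expect_equal(relaxed$total - plain$total, 0.5 * d * d)
})
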