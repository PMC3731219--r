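# Dot-bracket parsing, file formats and the CLI surface.

test_that("dot-bracket parsing builds consistent pair maps", {
  db <- dotBracket("((....))")
  expect_equal(pairMap(db), cbind(i = c(1L, 2L), j = c(8L, 7L)))

  db <- dotBracket("(((&)))")
  pm <- pairMap(db)
  expect_equal(nrow(pm), 3L)           # 3 intermolecular pairs
  expect_equal(db@strandLengths, c(3L, 3L))

  expect_error(dotBracket("((..)"), "unbalanced")
  expect_error(dotBracket(")("), "unbalanced")
  expect_error(dotBracket("(x)"), "invalid")
  # intramolecular pairs must respect the minimum hairpin loop
  expect_error(dotBracket("(())"), "hairpin")
  expect_error(dotBracket("((..))"), "hairpin")
})

test_that("dot-bracket records round-trip through files", {
  f <- foldMFE("GGGAAAACCC")
  tf <- tempfile(fileext = ".db")
  writeDotBracket(f, tf, name = "hp")
  rec <- readDotBracket(tf)
  expect_equal(rec$name, "hp")
  expect_equal(rec$sequence, "GGGAAAACCC")
  expect_equal(dbString(rec$structure), "(((....)))")
  expect_equal(rec$energy, -9)

  tf2 <- tempfile(fileext = ".db")
  writeDotBracket(cofoldMFE(c("GGGG", "CCCC")), tf2)
  rec2 <- readDotBracket(tf2)
  expect_equal(dbString(rec2$structure), "((((&))))")

  writeLines("((..)", tf2)
  expect_error(readDotBracket(tf2))
})

test_that("FASTA IO round-trips and normalizes DNA input", {
  tf <- tempfile(fileext = ".fa")
  writeFastaRNA(c(a = "ACGUACGU", b = "GGGAAAACCC"), tf)
  recs <- readFastaRNA(tf)
  expect_equal(vapply(recs, residues, character(1)), c("ACGUACGU",
                                                       "GGGAAAACCC"))
  expect_equal(vapply(recs, function(s) s@name, character(1)), c("a", "b"))

  writeLines(c(">dna", "ACGTACGT"), tf)
  expect_warning(recs <- readFastaRNA(tf), "T -> U")
  expect_equal(residues(recs[[1]]), "ACGUACGU")

  file.create(tf2 <- tempfile(fileext = ".fa"))
  expect_identical(readFastaRNA(tf2), list())
})

test_that("gate specifications round-trip losslessly through YAML", {
  tf <- tempfile(fileext = ".yaml")
  for (gate in list(makeNotGate(), makeYesGate(variant = "YES_antiterm"),
                    makeAndGate())) {
    writeGateSpec(gate, tf)
    back <- readGateSpec(tf)
    tf2 <- tempfile(fileext = ".yaml")
    writeGateSpec(back, tf2)
    expect_identical(readLines(tf), readLines(tf2))
    expect_identical(gateType(back), gateType(gate))
    expect_identical(speciesNames(back), speciesNames(gate))
    expect_equal(length(back@terms), length(gate@terms))
  }
})

test_that("run configuration round-trips and rejects unknown keys", {
  cfg <- list(objective = objectiveConfig(Gp = -1.5, wStr = 2),
              optimizer = optimizerConfig(iterations = 123L, rngSeed = 9L),
              engine = "reference")
  tf <- tempfile(fileext = ".yaml")
  writeRunConfig(cfg, tf)
  back <- readRunConfig(tf)
  expect_equal(back$objective@Gp, -1.5)
  expect_equal(back$objective@wStr, 2)
  expect_equal(back$optimizer@iterations, 123L)
  expect_equal(back$optimizer@rngSeed, 9L)

  writeLines(c("objective:", "  Gp: -1.28", "banana: 1"), tf)
  expect_error(readRunConfig(tf), "unknown configuration key")
  writeLines(c("objective:", "  Gq: -1.28"), tf)
  expect_error(readRunConfig(tf), "unknown objective key")
})

test_that("the CLI scores, designs deterministically and flags bad input", {
  fa <- tempfile(fileext = ".fa")
  writeFastaRNA(c(s = "UCUCCU", m = "AGAAGAAGGAGAAGAAGAAGAUGA"), fa)
  out <- capture.output(code <- riboCLI(c("score", "--fasta", fa)))
  expect_equal(code, 0L)
  expect_match(out[1], "deltaG\talpha\tdGkin")
  expect_equal(length(out), 2L)

  faSmall <- tempfile(fileext = ".fa")
  writeFastaRNA(c(a = "GGGGG", b = "CCCCC"), faSmall)
  out <- capture.output(code <- riboCLI(c("landscape", "--fasta", faSmall)))
  expect_equal(code, 0L)
  expect_match(out[1], "^r\tG$")

  gateFile <- tempfile(fileext = ".yaml")
  writeGateSpec(makeNotGate(utrLen = 20, srnaLen = 10), gateFile)
  out <- capture.output(code <- riboCLI(c("validate", "--gate", gateFile)))
  expect_equal(code, 0L)

  # same seed twice -> byte-identical outputs
  p1 <- tempfile()
  p2 <- tempfile()
  capture.output({
    expect_equal(riboCLI(c("design", "--gate", gateFile, "--iterations",
                           "150", "--seed", "5", "--out", p1)), 0L)
    expect_equal(riboCLI(c("design", "--gate", gateFile, "--iterations",
                           "150", "--seed", "5", "--out", p2)), 0L)
  })
  expect_identical(readLines(paste0(p1, ".fa")), readLines(paste0(p2, ".fa")))
  expect_identical(readLines(paste0(p1, ".trajectory.tsv")),
                   readLines(paste0(p2, ".trajectory.tsv")))

  # malformed gate file -> exit code 2 naming the offending field
  bad <- tempfile(fileext = ".yaml")
  writeLines("gate_type: NOT_direct", bad)
  msgs <- capture.output(
    code <- riboCLI(c("validate", "--gate", bad)), type = "message")
  expect_equal(code, 2L)
  expect_match(paste(msgs, collapse = " "), "species")

  expect_equal(suppressMessages(riboCLI(character(0))), 2L)
})
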