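# Synthetic mutant libraries, log-linear fitting and the design QC
# report.

test_that("a noiseless library recovers the generative law exactly", {
  set.seed(51)
  lib <- generateLibrary(nMutants = 20, noiseSigma = 0)
  expect_true(all(lib$fold > 0))
  fit <- suppressWarnings(fitLogLinear(lib))
  expect_equal(fit@slope, -1 / 0.61, tolerance = 1e-9)
  expect_equal(fit@r2, 1, tolerance = 1e-9)
})

test_that("library generation is seeded and consistent with the scorer", {
  set.seed(52)
  a <- generateLibrary(nMutants = 11)
  set.seed(52)
  b <- generateLibrary(nMutants = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 11L)

  # recorded dGkin matches rescoring the stored sequences
  k <- 5L
  resc <- riboforge:::.scorePair(a$sRNA[k], a$mRNA[k],
                                 referenceEnergyModel(), objectiveConfig())
  expect_equal(a$dGkin[k], resc$dGkin)
})

test_that("degenerate inputs are rejected by the fitter", {
  expect_error(fitLogLinear(data.frame(dGkin = c(-5, -5), fold = c(2, 3))),
               "fit error")
  expect_error(fitLogLinear(data.frame(dGkin = c(-5, -5, -5),
                                       fold = c(2, 3, 4))), "fit error")
  expect_error(fitLogLinear(data.frame(x = 1)), "columns")
})

test_that("slope estimates tighten as the library grows", {
  spread <- vapply(c(11L, 50L, 200L), function(n) {
    set.seed(53)
    reps <- vapply(1:10, function(i) {
      suppressWarnings(fitLogLinear(
        generateLibrary(nMutants = n, noiseSigma = 0.5)))@slope
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  expect_lt(spread[3], spread[1])
})

test_that("evaluateDesigns reports interactions, structures and masks", {
  expect_identical(evaluateDesigns(list(), makeNotGate()), list())

  gate <- makeNotGate(utrLen = 30, srnaLen = 20)
  res <- runDesign(gate, optimizerConfig(iterations = 2000, rngSeed = 42))
  rep <- evaluateDesigns(list(res), gate)[[1]]
  expect_equal(nrow(rep$interactions), 1L)
  expect_true(all(rep$interactions$intended))
  # the converged NOT design blocks the whole RBS in the complex
  on <- rep$masks[rep$masks$entry == "1", ]
  expect_equal(on$satisfiedFraction, 1.0)

  # three species give a 3-pair cross-talk table with unintended pairs
  gateAnd <- makeAndGate()
  seqs <- list(c(sRNA1 = strrep("AC", 7), sRNA2 = strrep("CA", 7),
                 mRNA = paste0("AACAUCUCCUCAAAAGGAGAACAACAAAUG")))
  repAnd <- evaluateDesigns(seqs, gateAnd)[[1]]
  expect_equal(nrow(repAnd$interactions), 3L)
  expect_false(all(repAnd$interactions$intended))
  expect_equal(nrow(repAnd$structures), 3L)
})

test_that("libraries round-trip through tab-separated text", {
  set.seed(54)
  lib <- generateLibrary(nMutants = 8)
  tf <- tempfile(fileext = ".tsv")
  writeLibrary(lib, tf)
  back <- readLibrary(tf)
  expect_equal(back$sRNA, lib$sRNA)
  expect_equal(back$dGkin, lib$dGkin, tolerance = 1e-12)
})
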