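# Seed detection and the kinetic / structural objective terms.

test_that("seed detection finds the longest accessible complementary run", {
  s <- seedRegion(foldMFE("GGGG"), foldMFE("CCCC"))
  expect_equal(seedAlpha(s), 4L)
  expect_equal(s@startA, 1L)

  # A is fully paired except its AAA loop; only the loop is accessible
  fA <- foldMFE("GGGGGAAACCCCC")
  expect_equal(dbString(fA), "(((((...)))))")
  s <- seedRegion(fA, foldMFE("UUUUU"))
  expect_equal(seedAlpha(s), 3L)
  expect_equal(s@startA, 6L)

  # A-A is not complementary
  s <- seedRegion(foldMFE("AAAA"), foldMFE("AAAA"))
  expect_equal(seedAlpha(s), 0L)

  # GU counts only when asked
  expect_equal(seedAlpha(seedRegion(foldMFE("GGGG"), foldMFE("UUUU"))), 0L)
  expect_equal(seedAlpha(seedRegion(foldMFE("GGGG"), foldMFE("UUUU"),
                                    allowGU = TRUE)), 4L)
})

test_that("seed ties break to the smallest start in A", {
  # two equal 4-runs; the run starting at position 1 wins
  fA <- foldMFE("GGGGAGGGG")
  fB <- foldMFE("CCCCACCCC")
  s <- seedRegion(fA, fB)
  expect_equal(s@startA, 1L)
})

test_that("dGkin applies the printed saturation levels", {
  expect_equal(dGkin(-20, 8), -15 + 6 * (-1.28))
  expect_equal(dGkin(0, 0), 0)
  expect_equal(dGkin(-10, 4), -10 + 4 * (-1.28))

  # monotone and bounded below by the analytic floor
  set.seed(31)
  dg <- runif(2000, -60, 5)
  al <- sample(0:20, 2000, replace = TRUE)
  v <- dGkin(dg, al)
  expect_true(all(v >= -22.68 - 1e-12))
  expect_true(all(dGkin(dg - 1, al) <= v + 1e-12))
  expect_true(all(dGkin(dg, al + 1L) <= v + 1e-12))
})

test_that("dGstr is a rescaled Hamming distance and a metric", {
  expect_equal(dGstr("((....))", "((....))"), 0)
  expect_equal(dGstr("((....))", "(......)"), 1.28 * 2)
  expect_equal(dGstr("........", mask = list(positions = 1:6,
                                             state = "paired")), 7.68)
  # d = 3 at default Gp
  expect_equal(dGstr(".....", "(.)(."), 3.84)

  expect_error(dGstr("....", "....."), "length")
  expect_error(dGstr("....", mask = list(positions = 9, state = "paired")),
               "positions")

  # metric over compared positions
  set.seed(32)
  syms <- c(".", "(", ")")
  for (k in 1:20) {
    a <- paste(sample(syms, 10, replace = TRUE), collapse = "")
    b <- paste(sample(syms, 10, replace = TRUE), collapse = "")
    c <- paste(sample(syms, 10, replace = TRUE), collapse = "")
    expect_gte(dGstr(a, b), 0)
    expect_equal(dGstr(a, b), dGstr(b, a))
    expect_equal(dGstr(a, a), 0)
    expect_lte(dGstr(a, c), dGstr(a, b) + dGstr(b, c) + 1e-12)
  }

  # a "paired" mask position accepts either bracket
  expect_equal(dGstr("(...).", mask = list(positions = c(1, 5),
                                           state = "paired")), 0)
})

test_that("avoid contributions are sign-flipped and floored at zero", {
  expect_equal(avoidTerm(-5), 5)
  expect_equal(avoidTerm(2), 0)
  expect_equal(avoidTerm(0), 0)
  expect_true(all(avoidTerm(runif(100, -30, 30)) >= 0))
})

test_that("totalObjective assembles weighted terms", {
  gate <- toyYesGate()
  # the fixed mRNA satisfies the OFF entry by construction
  seqs <- c(sRNA = "UUUGGAGU", mRNA = "ACUCCAAAGGAG")
  res <- totalObjective(seqs, gate)
  expect_true(is.finite(res$total))
  expect_equal(nrow(res$breakdown), 3L)
  kin <- res$breakdown[res$breakdown$kind == "kin", ]
  expect_equal(kin$weighted,
               dGkin(kin$deltaG, kin$alpha))

  # missing species
  expect_error(totalObjective(c(sRNA = "UUUGGAGU"), gate), "missing species")
})

test_that("homodimer-forming sRNAs are excluded with an infinite objective", {
  gate <- makeNotGate(utrLen = 17, srnaLen = 6)
  seqs <- c(sRNA = "GGGCCC", mRNA = "AGGAGAACAACAACAUG")
  res <- totalObjective(seqs, gate)
  expect_identical(res$total, Inf)
  expect_match(res$breakdown$term[1], "homodimer")
})

test_that("an all-neutral candidate scores zero", {
  gate <- gateSpec("NOT_direct",
    species = list(speciesSpec("mRNA", "mRNA_5UTR", 10L)),
    entries = list(), reactions = list(),
    terms = list(strTerm("mRNA", target = "..........")))
  expect_equal(totalObjective(c(mRNA = "AACAACAACA"), gate)$total, 0)
})

test_that("improving one term with others fixed lowers the total", {
  gate <- toyYesGate()
  # identical except the ON-entry mask: more of the RBS released
  good <- totalObjective(c(sRNA = "CUCCUUUC", mRNA = "ACUCCAAAGGAG"), gate)
  base <- totalObjective(c(sRNA = "AAACACAA", mRNA = "ACUCCAAAGGAG"), gate)
  expect_lt(good$total, base$total)
})
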