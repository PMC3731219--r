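# Reaction-coordinate profiles, partition function, formation and
# activation energies.

test_that("profile enumeration matches the brute-force oracle", {
  p <- enumerateProfile("GGGG", "CCCC")
  expect_equal(p@G[p@r == 0], 0)
  expect_equal(p@G[p@r == 4], -12)
  expect_equal(p@rHyb, 4L)

  oracle <- oracleProfile("GGGG", "CCCC")
  expect_equal(unname(p@G), as.numeric(oracle[as.character(p@r)]))

  set.seed(21)
  for (k in 1:8) {
    a <- randomRNA(sample(3:5, 1))
    b <- randomRNA(sample(3:5, 1))
    p <- enumerateProfile(a, b)
    oracle <- oracleProfile(a, b)
    expect_equal(unname(p@G), as.numeric(oracle[as.character(p@r)]),
                 info = paste(a, b))
  }
})

test_that("non-interacting pairs give a single-state profile", {
  p <- enumerateProfile("AAAA", "AAAA")
  expect_equal(p@r, 0L)
  expect_equal(profileEnergies(p)@deltaG, 0)
  expect_equal(profileEnergies(p)@deltaGActivation, 0)
})

test_that("G(0) is the sum of the individual MFE energies", {
  set.seed(22)
  for (k in 1:10) {
    a <- randomRNA(sample(4:8, 1))
    b <- randomRNA(sample(4:8, 1))
    p <- enumerateProfile(a, b)
    expect_equal(p@G[p@r == 0],
                 freeEnergy(foldMFE(a)) + freeEnergy(foldMFE(b)),
                 info = paste(a, b))
  }
})

test_that("partition function sums Boltzmann terms", {
  single <- new("ReactionProfile", r = 0L, G = 0, rHyb = 0L, rTrans = 0L)
  expect_equal(partitionFunction(single, 0.61), 1)

  two <- new("ReactionProfile", r = 0:1, G = c(0, -0.61), rHyb = 1L,
             rTrans = 1L)
  expect_equal(partitionFunction(two, 0.61), 1 + exp(1))

  # adding any state strictly increases Z
  three <- new("ReactionProfile", r = 0:2, G = c(0, -0.61, 5), rHyb = 1L,
               rTrans = 1L)
  expect_gt(partitionFunction(three, 0.61), partitionFunction(two, 0.61))

  # invariant under state order
  twoRev <- new("ReactionProfile", r = c(1L, 0L), G = c(-0.61, 0),
                rHyb = 1L, rTrans = 1L)
  expect_equal(partitionFunction(twoRev, 0.61), partitionFunction(two, 0.61))

  expect_error(partitionFunction(two, 0), "RT")
})

test_that("-RT log Z approaches the profile minimum as RT -> 0", {
  p <- enumerateProfile("GGGG", "CCCC")
  RT <- 0.05
  # exact bound: the defect is at most RT * log(number of states)
  expect_lt(abs(-RT * log(partitionFunction(p, RT)) - min(p@G)),
            RT * log(length(p@G)) + 1e-9)
})

test_that("the MFE shortcut agrees with the enumerated profile", {
  expect_equal(deltaGMFE("GGGG", "CCCC"), -12)
  expect_equal(deltaGMFE("AAAA", "AAAA"), 0)
  set.seed(23)
  for (k in 1:10) {
    a <- randomRNA(sample(4:9, 1))
    b <- randomRNA(sample(4:9, 1))
    es <- profileEnergies(enumerateProfile(a, b))
    expect_equal(deltaGMFE(a, b), es@deltaG, info = paste(a, b))
    expect_gte(es@deltaGActivation, es@deltaG)
  }
})

test_that("a self-complementary sequence scores a strong homodimer", {
  dg <- deltaGMFE("GGGCCC", "GGGCCC")
  expect_lt(dg, -7.5)
  # against the enumeration oracle for the two-copy complex
  duo <- min(vapply(oracleStructures(
    strsplit("GGGCCCGGGCCC", "")[[1]], rep(1:2, each = 6)),
    function(s) s$energy, numeric(1)))
  expect_equal(dg, duo - 2 * oracleMFE("GGGCCC"))
})

test_that("profiles export as tab-separated text", {
  p <- enumerateProfile("GGGG", "CCCC")
  tf <- tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  df <- read.delim(tf)
  expect_equal(df$r, p@r)
  expect_equal(df$G, p@G)
})
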