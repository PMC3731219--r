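# Synthetic mutant libraries and the log-linear validation of the
# exponential free-energy model of regulatory fold change.

#' Example riboregulator pair used by the validation fixtures
#'
#' A small synthetic activator pair: a purine-rich 24-nt 5' UTR (which
#' is essentially unstructured, as A and G cannot pair each other) with
#' the SD sequence and start codon, and the pyrimidine anti-SD hexamer
#' as sRNA. The base interaction sits at the saturation boundary, so
#' seed mutations move both the formation free energy and the seed
#' length and spread the kinetic objective over several kcal/mol.
#' Synthetic stand-in constructed for the fixtures; not a published
#' sequence.
#'
#' @return `list(sRNA=, mRNA=)` of RNA strings.
#' @export
exampleValidationDesign <- function() {
  list(sRNA = "UCUCCU", mRNA = "AGAAGAAGGAGAAGAAGAAGAUGA")
}

# score one sRNA/mRNA pair: formation energy, seed, kinetic objective
.scorePair <- function(srna, mrna, model, cfg) {
  fA <- foldMFE(srna, model)
  fB <- foldMFE(mrna, model)
  dG <- cofoldMFE(list(srna, mrna), model)@energy - fA@energy - fB@energy
  alpha <- seedRegion(fA, fB, allowGU = cfg@seedGU)@alpha
  list(deltaG = dG, alpha = alpha, dGkin = dGkin(dG, alpha, cfg))
}

#' Generate a synthetic mutant library with a known fold-change law
#'
#' Emulates a randomized-trinucleotide mutant library: `nMutants`
#' variants of the base design are drawn by substituting a random
#' trinucleotide at seed positions of the sRNA, each variant is scored
#' (`deltaG`, `alpha`, `dGkin`), and a simulated "experimental" fold
#' change is drawn from the generative law
#' `log(fold) = intercept + trueSlope * dGkin + Normal(0, noiseSigma)`.
#'
#' @param baseDesign `list(sRNA=, mRNA=)` (default
#'   [exampleValidationDesign()]).
#' @param nMutants library size (default 11, the usual clone count of a
#'   screened trinucleotide library).
#' @param positions 1-based sRNA positions to randomize; default the
#'   three central positions of the base design's seed region.
#' @param noiseSigma standard deviation of the log-fold noise.
#' @param trueSlope generative slope per kcal/mol; the default `-1/RT`
#'   is the Boltzmann-consistent value.
#' @param intercept generative intercept.
#' @param model,cfg energy model and objective configuration used for
#'   scoring.
#' @return Data frame with columns
#'   `id, sRNA, mRNA, deltaG, alpha, dGkin, fold`. A warning is issued
#'   when all mutants are non-interacting (degenerate library).
#' @examples
#' set.seed(1)
#' lib <- generateLibrary(nMutants = 11, noiseSigma = 0)
#' fitLogLinear(lib)   # recovers the generative slope exactly
#' @export
generateLibrary <- function(baseDesign = exampleValidationDesign(),
                            nMutants = 11L, positions = NULL,
                            noiseSigma = 0.2, trueSlope = -1 / 0.61,
                            intercept = 0,
                            model = referenceEnergyModel(),
                            cfg = objectiveConfig()) {
  base <- .scorePair(baseDesign$sRNA, baseDesign$mRNA, model, cfg)
  if (!is.finite(base$dGkin)) {
    stop(.inputError("base design does not score finitely"))
  }
  if (is.null(positions)) {
    seed <- seedRegion(foldMFE(baseDesign$sRNA, model),
                       foldMFE(baseDesign$mRNA, model),
                       allowGU = cfg@seedGU)
    if (seed@alpha < 3L) {
      stop(.inputError(
        "base design seed shorter than 3 nt; give explicit positions"))
    }
    mid <- seed@startA + (seed@alpha - 3L) %/% 2L
    positions <- mid:(mid + 2L)
  }
  positions <- as.integer(positions)
  srnaInt <- .seqToInt(baseDesign$sRNA)
  if (any(positions < 1L | positions > length(srnaInt))) {
    stop(.inputError("mutated positions outside the sRNA"))
  }

  # distinct random trinucleotides (sampled without replacement while
  # the codon space allows it)
  k <- length(positions)
  space <- 4L^k
  idx <- if (nMutants <= space) {
    sample.int(space, nMutants) - 1L
  } else {
    sample.int(space, nMutants, replace = TRUE) - 1L
  }
  rows <- vector("list", nMutants)
  for (i in seq_len(nMutants)) {
    v <- srnaInt
    code <- idx[i]
    for (p in seq_len(k)) {
      v[positions[p]] <- code %% 4L
      code <- code %/% 4L
    }
    srnaMut <- .intToSeq(v)
    sc <- .scorePair(srnaMut, baseDesign$mRNA, model, cfg)
    rows[[i]] <- data.frame(
      id = sprintf("m%02d", i), sRNA = srnaMut, mRNA = baseDesign$mRNA,
      deltaG = sc$deltaG, alpha = sc$alpha, dGkin = sc$dGkin,
      stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, rows)
  if (all(lib$deltaG == 0)) {
    warning("degenerate library: all mutants are non-interacting")
  }
  lib$fold <- exp(intercept + trueSlope * lib$dGkin +
                    rnorm(nMutants, 0, noiseSigma))
  lib
}

#' Fit the log-linear fold-change model
#'
#' Ordinary least squares of `log(fold)` on the kinetic objective
#' `dGkin` across a mutant library.
#'
#' @param records data frame with columns `dGkin` and `fold` (as from
#'   [generateLibrary()]).
#' @return A [RegressionFit-class] (slope per kcal/mol, intercept, R2).
#' @examples
#' set.seed(1)
#' fitLogLinear(generateLibrary(nMutants = 20, noiseSigma = 0.1))
#' @export
fitLogLinear <- function(records) {
  if (!all(c("dGkin", "fold") %in% names(records))) {
    stop(.inputError("records need 'dGkin' and 'fold' columns"))
  }
  if (nrow(records) < 3L || length(unique(records$dGkin)) < 2L) {
    stop(.inputError(
      "fit error: need >= 3 records with variation in dGkin"))
  }
  if (any(records$fold <= 0)) {
    stop(.inputError("fold changes must be > 0"))
  }
  fit <- lm(log(fold) ~ dGkin, data = records)
  r2 <- summary(fit)$r.squared
  new("RegressionFit", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]), r2 = r2, n = nrow(records))
}

#' Post-design quality-control report
#'
#' For each design, reports every pairwise interaction between species
#' (formation free energy, seed length and kinetic objective; a
#' cross-talk matrix when some pairs are unintended), the per-species
#' MFE structures with their distance to target, and the pairedness of
#' every structural mask in the gate.
#'
#' @param designs list of named sequence vectors (or
#'   [DesignResult-class] objects).
#' @param gate the [GateSpec-class] the designs are for.
#' @param model,cfg energy model and objective configuration.
#' @return A list with one element per design:
#'   `list(interactions=, structures=, masks=)` data frames. The
#'   `satisfying` column flags species within 6 symbols (3 base pairs)
#'   of their target structure. Empty designs give an empty list.
#' @export
evaluateDesigns <- function(designs, gate, model = referenceEnergyModel(),
                            cfg = objectiveConfig()) {
  if (!length(designs)) return(list())
  spNames <- speciesNames(gate)
  # pairs whose association the gate requires; everything else is
  # cross-talk
  intended <- vapply(gate@reactions, function(rx) {
    if (length(rx$participants) == 2L && rx$sense == "occur") {
      paste(sort(rx$participants), collapse = ":")
    } else {
      NA_character_
    }
  }, character(1))

  lapply(designs, function(d) {
    seqs <- if (is(d, "DesignResult")) d@sequences else unlist(d)
    seqs <- seqs[spNames]

    combos <- utils::combn(spNames, 2L)
    inter <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
      a <- combos[1L, k]
      b <- combos[2L, k]
      sc <- .scorePair(seqs[[a]], seqs[[b]], model, cfg)
      data.frame(speciesA = a, speciesB = b, deltaG = sc$deltaG,
                 alpha = sc$alpha, dGkin = sc$dGkin,
                 intended = paste(sort(c(a, b)), collapse = ":") %in% intended,
                 stringsAsFactors = FALSE)
    }))

    structures <- do.call(rbind, lapply(gate@species, function(s) {
      f <- foldMFE(seqs[[s@name]], model)
      d <- sum(.structSymbols(f@structure) !=
                 .structSymbols(s@targetStructure))
      # final structures may vary up to three base pairs (6 symbols)
      data.frame(species = s@name, structure = dbString(f),
                 target = s@targetStructure, distance = d,
                 satisfying = d <= 6L,
                 stringsAsFactors = FALSE)
    }))

    maskRows <- list()
    for (tm in gate@terms) {
      if (tm@kind != "str" || !length(tm@maskPos)) next
      fold <- if (length(tm@subject) == 1L) {
        foldMFE(seqs[[tm@subject]], model)
      } else {
        cofoldMFE(as.list(seqs[tm@subject]), model)
      }
      sym <- .structSymbols(fold@structure)
      paired <- sym[tm@maskPos] != "."
      frac <- if (identical(tm@maskState, "paired")) mean(paired) else
        mean(!paired)
      maskRows[[length(maskRows) + 1L]] <- data.frame(
        entry = tm@entry, subject = paste(tm@subject, collapse = ":"),
        state = tm@maskState, satisfiedFraction = frac,
        stringsAsFactors = FALSE)
    }
    list(interactions = inter, structures = structures,
         masks = if (length(maskRows)) do.call(rbind, maskRows) else
           data.frame())
  })
}

#' Write / read a mutant library as tab-separated text
#'
#' @param lib library data frame from [generateLibrary()].
#' @param path file path.
#' @return `writeLibrary` the path invisibly; `readLibrary` the data
#'   frame.
#' @export
writeLibrary <- function(lib, path) {
  write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
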