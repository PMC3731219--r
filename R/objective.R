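# The scoring core: seed detection, the kinetic and structural
# objective terms, and the weighted-sum assembly of gate objectives.

#' Seed (nucleation) region between two folded species
#'
#' Returns the longest contiguous antiparallel Watson-Crick
#' complementary run between positions unpaired in A's individual MFE
#' structure and positions unpaired in B's (the individual folds form
#' before the intermolecular interaction; association nucleates at the
#' seed). Ties are broken by the smallest start position in A. Runs do
#' not cross strand boundaries when a partner is itself a complex.
#'
#' @param foldA,foldB [FoldResult-class] objects of the two partners.
#' @param allowGU count GU as complementary (default `FALSE`).
#' @return A [SeedRegion-class]; `alpha = 0` when no complementary
#'   accessible run exists.
#' @examples
#' seedRegion(foldMFE("GGGG"), foldMFE("CCCC"))   # alpha = 4
#' @export
seedRegion <- function(foldA, foldB, allowGU = FALSE) {
  sa <- .seedInput(foldA)
  sb <- .seedInput(foldB)
  res <- cpp_seed(sa$ints, sa$unpaired, sa$strand,
                  sb$ints, sb$unpaired, sb$strand, allowGU)
  if (res[3L] == 0L) {
    new("SeedRegion", startA = NA_integer_, startB = NA_integer_, alpha = 0L)
  } else {
    new("SeedRegion", startA = res[1L] + 1L, startB = res[2L] + 1L,
        alpha = res[3L])
  }
}

.seedInput <- function(fold) {
  if (!is(fold, "FoldResult")) {
    stop(.inputError("seedRegion expects FoldResult inputs"))
  }
  ints <- .seqToInt(fold@sequence)
  list(ints = ints,
       unpaired = as.integer(fold@structure@pairMap == 0L),
       strand = rep(seq_along(fold@strandLengths), fold@strandLengths))
}

#' Kinetic objective of a reaction
#'
#' `dGkin = max(deltaG, dGsat) + min(alpha, alphaSat) * Gp`: the
#' formation free energy saturated at `dGsat` plus the seed-length
#' contribution saturated at `alphaSat` nucleotides. With the default
#' constants the value is bounded below by
#' `-15 + 6 * (-1.28) = -22.68` kcal/mol.
#'
#' @param deltaG formation free energy, kcal/mol (vectorized).
#' @param alpha seed length in nt, or a [SeedRegion-class].
#' @param cfg an [ObjectiveConfig-class].
#' @return `dGkin` in kcal/mol.
#' @examples
#' dGkin(-20, 8)    # saturates at -22.68
#' dGkin(-10, 4)    # -15.12
#' @export
dGkin <- function(deltaG, alpha, cfg = objectiveConfig()) {
  if (is(alpha, "SeedRegion")) alpha <- alpha@alpha
  pmax(deltaG, cfg@dGsat) + pmin(alpha, cfg@alphaSat) * cfg@Gp
}

#' Structural objective: rescaled Hamming distance to a target
#'
#' `dGstr = -Gp * d >= 0`, with `d` the Hamming distance between the
#' observed and target structures over the compared positions. A full
#' target is compared literally over `. ( )`; a mask restricts the
#' comparison to constrained positions (e.g. the RBS) and demands a
#' pairedness state, where `"paired"` matches either bracket.
#'
#' @param observed a [FoldResult-class], [DotBracket-class] or
#'   dot-bracket string.
#' @param target full dot-bracket target of the same length (omit when
#'   using a mask).
#' @param mask `list(positions =, state =)` with 1-based residue
#'   positions and state `"paired"` or `"unpaired"`.
#' @param cfg an [ObjectiveConfig-class].
#' @return `dGstr` in kcal/mol; 0 iff all compared positions agree.
#' @examples
#' dGstr("((....))", "((....))")                      # 0
#' dGstr(".......", mask = list(positions = 1:3, state = "paired"))
#' @export
dGstr <- function(observed, target = NULL, mask = NULL,
                  cfg = objectiveConfig()) {
  obs <- .structSymbols(observed)
  if (!is.null(target)) {
    tgt <- .structSymbols(target)
    if (length(tgt) != length(obs)) {
      stop(.inputError("observed and target structures differ in length"))
    }
    d <- sum(obs != tgt)
  } else if (!is.null(mask)) {
    pos <- as.integer(mask$positions)
    if (any(pos < 1L | pos > length(obs))) {
      stop(.inputError("mask positions outside the structure"))
    }
    paired <- obs[pos] != "."
    d <- if (identical(mask$state, "paired")) sum(!paired) else sum(paired)
  } else {
    stop(.inputError("either a target structure or a mask is required"))
  }
  -cfg@Gp * d
}

# residue-level symbol vector ('&' removed)
.structSymbols <- function(x) {
  if (is(x, "FoldResult")) x <- x@structure
  if (is(x, "DotBracket")) x <- x@symbols
  v <- strsplit(x, "")[[1]]
  v[v != "&"]
}

#' Contribution of a must-not-occur reaction
#'
#' Minimizing the objective must *maximize* `dGkin` for reactions that
#' must not occur; the contribution is `max(-dGkin, 0)`, floored at
#' zero so that already non-interacting pairs earn no further reward
#' and avoid terms stay commensurate with the rest of the weighted sum.
#'
#' @param dGkinValue kinetic objective of the unwanted reaction
#'   (vectorized).
#' @return Nonnegative penalty in kcal/mol.
#' @examples
#' avoidTerm(-5)   # 5
#' avoidTerm(2)    # 0
#' @export
avoidTerm <- function(dGkinValue) {
  pmax(-dGkinValue, 0)
}

#' Total gate objective for a set of candidate sequences
#'
#' Evaluates every objective term of a gate for the given sequences:
#' occur-sense kinetic terms contribute `wKin * dGkin`, avoid-sense
#' terms `wKin * avoidTerm(dGkin)`, and structural terms
#' `wStr * dGstr`. Lower is better. Candidates whose sRNA species form
#' homodimers (self-association free energy below
#' `homodimerThreshold`) are excluded with an infinite objective.
#'
#' @param sequences named character vector or list covering every gate
#'   species.
#' @param gate a [GateSpec-class].
#' @param cfg an [ObjectiveConfig-class].
#' @param model an [EnergyModel-class].
#' @param homodimerThreshold kcal/mol; see [homodimerCheck()].
#' @return `list(total=, breakdown=)`, the breakdown a data frame with
#'   one row per term (deltaG, alpha, raw value and weighted value).
#' @examples
#' gate <- makeNotGate(utrLen = 30, srnaLen = 20)
#' # a candidate must name every species:
#' speciesNames(gate)
#' @export
totalObjective <- function(sequences, gate, cfg = objectiveConfig(),
                           model = referenceEnergyModel(),
                           homodimerThreshold = -7.5) {
  if (is.list(sequences)) {
    sequences <- vapply(sequences, function(s) {
      if (is(s, "NucleotideSequence")) s@residues else s
    }, character(1))
  }
  missing <- setdiff(speciesNames(gate), names(sequences))
  if (length(missing)) {
    stop(.specError(paste("missing species:", paste(missing, collapse = ", "))))
  }
  ints <- lapply(sequences[speciesNames(gate)], .seqToInt)
  plan <- .compileGate(gate, cfg)
  .scoreCandidate(ints, plan, cfg, model, homodimerThreshold)
}

# Precompute everything the hot scoring path needs: integer-coded
# targets and masks, species roles, term tables.
.compileGate <- function(gate, cfg) {
  spNames <- speciesNames(gate)
  roles <- vapply(gate@species, function(s) s@role, character(1))
  lens <- vapply(gate@species, function(s) s@length, integer(1))
  names(roles) <- names(lens) <- spNames

  kin <- list()
  str <- list()
  for (tm in gate@terms) {
    if (tm@kind == "kin") {
      kin[[length(kin) + 1L]] <- list(
        participants = match(tm@participants, spNames),
        label = paste(tm@participants, collapse = ":"),
        sense = tm@sense, weight = tm@weight)
    } else {
      tgtCode <- if (!is.na(tm@target)) .symbolsToCode(tm@target) else NULL
      str[[length(str) + 1L]] <- list(
        subject = match(tm@subject, spNames),
        label = paste(tm@subject, collapse = ":"),
        target = tgtCode, maskPos = tm@maskPos,
        maskPaired = identical(tm@maskState, "paired"),
        hasMask = length(tm@maskPos) > 0L, weight = tm@weight)
    }
  }
  # harmonic relaxation / per-species conformance uses the coded targets
  targets <- lapply(gate@species, function(s) .symbolsToCode(s@targetStructure))
  names(targets) <- spNames
  list(spNames = spNames, roles = roles, lens = lens, kin = kin, str = str,
       targets = targets)
}

# code: 0 = '.', 1 = '(', 2 = ')'
.symbolsToCode <- function(symbols) {
  v <- .structSymbols(symbols)
  code <- integer(length(v))
  code[v == "("] <- 1L
  code[v == ")"] <- 2L
  code
}

.codeFromPairs <- function(pairs0) {
  idx0 <- seq_along(pairs0) - 1L
  code <- integer(length(pairs0))
  code[pairs0 > idx0] <- 1L
  code[pairs0 >= 0L & pairs0 < idx0] <- 2L
  code
}

# Hot path: everything integer-coded, no S4 construction. With
# detail = FALSE only the total is computed (no breakdown rows), which
# is what the annealer and exhaustive searches use.
.scoreCandidate <- function(ints, plan, cfg, model, homodimerThreshold,
                            harmonicStiffness = 0, detail = TRUE) {
  par <- .modelPar(model)
  n <- length(ints)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    folds[[i]] <- cpp_fold(ints[[i]], rep(1L, length(ints[[i]])), par)
  }

  rows <- list()
  addRow <- function(term, kind, sense, deltaG, alpha, value, weighted) {
    if (!detail) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, kind = kind, sense = sense, deltaG = deltaG,
      alpha = alpha, value = value, weighted = weighted,
      stringsAsFactors = FALSE)
  }

  # homodimer exclusion on sRNA species
  for (i in seq_len(n)) {
    if (plan$roles[[i]] != "sRNA") next
    duo <- cpp_fold(c(ints[[i]], ints[[i]]),
                    rep(1:2, c(length(ints[[i]]), length(ints[[i]]))), par)
    dgSelf <- duo$energy - 2 * folds[[i]]$energy
    if (dgSelf < homodimerThreshold) {
      addRow(paste0("homodimer:", plan$spNames[[i]]), "exclusion", NA,
             dgSelf, NA, Inf, Inf)
      return(list(total = Inf,
                  breakdown = if (detail) do.call(rbind, rows) else NULL))
    }
  }

  complexCache <- list()
  getComplex <- function(idx) {
    key <- paste(idx, collapse = "+")
    hit <- complexCache[[key]]
    if (!is.null(hit)) return(hit)
    seqv <- unlist(ints[idx])
    strand <- rep(seq_along(idx), lengths(ints[idx]))
    res <- cpp_fold(seqv, strand, par)
    res$strand <- strand
    complexCache[[key]] <<- res
    res
  }

  total <- 0
  for (tm in plan$kin) {
    idx <- tm$participants
    cf <- getComplex(idx)
    if (length(idx) == 2L) {
      dG <- cf$energy - folds[[idx[1L]]]$energy - folds[[idx[2L]]]$energy
      a1 <- idx[1L]
      sA <- list(ints = ints[[a1]], unpaired = as.integer(folds[[a1]]$pairs < 0L),
                 strand = rep(1L, length(ints[[a1]])))
      b1 <- idx[2L]
      sB <- list(ints = ints[[b1]], unpaired = as.integer(folds[[b1]]$pairs < 0L),
                 strand = rep(1L, length(ints[[b1]])))
    } else {
      # dimer of the first two participants reacting with the third
      dimer <- getComplex(idx[1:2])
      dG <- cf$energy - dimer$energy - folds[[idx[3L]]]$energy
      sA <- list(ints = unlist(ints[idx[1:2]]),
                 unpaired = as.integer(dimer$pairs < 0L),
                 strand = dimer$strand)
      b1 <- idx[3L]
      sB <- list(ints = ints[[b1]], unpaired = as.integer(folds[[b1]]$pairs < 0L),
                 strand = rep(1L, length(ints[[b1]])))
    }
    seed <- cpp_seed(sA$ints, sA$unpaired, sA$strand,
                     sB$ints, sB$unpaired, sB$strand, cfg@seedGU)
    alpha <- seed[3L]
    kinVal <- max(dG, cfg@dGsat) + min(alpha, cfg@alphaSat) * cfg@Gp
    value <- if (tm$sense == "occur") kinVal else max(-kinVal, 0)
    weighted <- cfg@wKin * tm$weight * value
    total <- total + weighted
    addRow(tm$label, "kin", tm$sense, dG, alpha, value, weighted)
  }

  for (tm in plan$str) {
    obsCode <- if (length(tm$subject) == 1L) {
      .codeFromPairs(folds[[tm$subject]]$pairs)
    } else {
      .codeFromPairs(getComplex(tm$subject)$pairs)
    }
    if (tm$hasMask) {
      paired <- obsCode[tm$maskPos] != 0L
      d <- if (tm$maskPaired) sum(!paired) else sum(paired)
    } else {
      d <- sum(obsCode != tm$target)
    }
    value <- -cfg@Gp * d
    weighted <- cfg@wStr * tm$weight * value
    total <- total + weighted
    addRow(tm$label, "str", NA, NA, NA, value, weighted)
  }

  if (harmonicStiffness > 0) {
    for (i in seq_len(n)) {
      d <- sum(.codeFromPairs(folds[[i]]$pairs) != plan$targets[[i]])
      total <- total + harmonicStiffness * d * d
      if (d > 0) {
        addRow(paste0("harmonic:", plan$spNames[[i]]), "harmonic", NA, NA, NA,
               d, harmonicStiffness * d * d)
      }
    }
  }

  if (!detail) return(list(total = total, breakdown = NULL))
  list(total = total,
       breakdown = if (length(rows)) do.call(rbind, rows) else
         data.frame(term = character(), kind = character(),
                    sense = character(), deltaG = numeric(),
                    alpha = numeric(), value = numeric(),
                    weighted = numeric(), stringsAsFactors = FALSE))
}
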