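# Monte Carlo simulated annealing over sequence space with directed
# reverse-complement mutation operators.

# Per-species design metadata derived from a gate: target stem partner
# map, protected positions (motifs, fixed sequences and the stem
# partners of protected positions).
.designMeta <- function(gate) {
  meta <- list()
  for (s in gate@species) {
    n <- s@length
    db <- dotBracket(s@targetStructure)
    partner <- db@pairMap  # 0 = unpaired
    protected <- rep(FALSE, n)
    motifBase <- rep(NA_integer_, n)
    if (!is.na(s@fixedSequence)) {
      protected[] <- TRUE
      motifBase <- .seqToInt(s@fixedSequence)
    } else {
      for (m in s@motifs) {
        span <- m$at:(m$at + nchar(m$seq) - 1L)
        protected[span] <- TRUE
        motifBase[span] <- .seqToInt(m$seq)
      }
      # stem partners of protected positions are sequence-determined
      for (i in which(protected)) {
        j <- partner[i]
        if (j > 0L && !protected[j]) {
          protected[j] <- TRUE
          motifBase[j] <- .compInt(motifBase[i])
        }
      }
    }
    meta[[s@name]] <- list(n = n, partner = partner, protected = protected,
                           motifBase = motifBase,
                           fixed = !is.na(s@fixedSequence))
  }
  meta
}

#' Initialize a candidate from a gate specification
#'
#' Draws random sequences satisfying the structural and subsequence
#' constraints: motif positions take their fixed bases, target-structure
#' stem partners are sampled as complementary pairs, loop and
#' unconstrained positions are sampled freely, and homopolymer runs of
#' `maxRun` or more identical nucleotides (outside fixed motifs) are
#' resampled. Randomness comes from the current R RNG.
#'
#' @param gate a validated [GateSpec-class].
#' @param maxRun forbidden homopolymer run length (default 4).
#' @param attempts resampling budget before initialization fails.
#' @return A candidate: `list(seqs=, meta=)` with `seqs` a named list of
#'   integer-coded sequences.
#' @examples
#' set.seed(1)
#' cand <- initializeCandidate(makeNotGate())
#' candidateSequences(cand)
#' @export
initializeCandidate <- function(gate, maxRun = 4L, attempts = 200L) {
  meta <- .designMeta(gate)
  seqs <- list()
  for (nm in names(meta)) {
    m <- meta[[nm]]
    ok <- FALSE
    for (a in seq_len(attempts)) {
      v <- m$motifBase
      for (i in seq_len(m$n)) {
        if (!is.na(v[i])) next
        j <- m$partner[i]
        if (j > 0L && j < i && !is.na(v[j])) {
          v[i] <- .compInt(v[j])
        } else {
          v[i] <- sample.int(4L, 1L) - 1L
        }
      }
      if (!.hasIllegalRun(v, m$protected, maxRun)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(.specError(sprintf(
        "initialization failed for species '%s': constraints incompatible with the run rule",
        nm)))
    }
    seqs[[nm]] <- v
  }
  list(seqs = seqs, meta = meta)
}

#' Sequences of a candidate state
#'
#' @param candidate a candidate from [initializeCandidate()] or
#'   [mutateCandidate()].
#' @return Named character vector of RNA sequences.
#' @export
candidateSequences <- function(candidate) {
  vapply(candidate$seqs, .intToSeq, character(1))
}

# positions that may be touched by a move
.mutablePositions <- function(m) {
  which(!m$protected)
}

#' Propose a mutation of a candidate
#'
#' With probability `moveMix` applies the directed move: a word of
#' `wordLen` consecutive nucleotides is taken from one species, made
#' reverse-complementary, and written over `wordLen` designable
#' positions of another species (guaranteeing a complementary patch
#' between the two). Otherwise a single random point replacement is
#' made. If a mutated nucleotide belongs to a stem of its species'
#' target structure, its partner is co-mutated to the Watson-Crick
#' complement. Proposals touching fixed positions or creating
#' homopolymer runs of `maxRun` or more are resampled; lengths are
#' never changed.
#'
#' @param candidate a candidate state.
#' @param wordLen word length of the directed move (3 -> 2 -> 1 over a
#'   design run).
#' @param moveMix probability of the directed move.
#' @param maxRun forbidden homopolymer run length.
#' @param resampleBudget attempts before the move fails.
#' @return `list(candidate=, move=)` with the mutated candidate, or
#'   `NULL` if no legal move was found within the budget.
#' @examples
#' set.seed(1)
#' cand <- initializeCandidate(makeNotGate())
#' prop <- mutateCandidate(cand, wordLen = 3)
#' prop$move
#' @export
mutateCandidate <- function(candidate, wordLen = 3L, moveMix = 0.5,
                            maxRun = 4L, resampleBudget = 50L) {
  seqs <- candidate$seqs
  meta <- candidate$meta
  spNames <- names(seqs)
  mutableSp <- spNames[vapply(meta, function(m) any(!m$protected), logical(1))]
  if (!length(mutableSp)) {
    stop(.specError("no designable positions in any species"))
  }

  for (attempt in seq_len(resampleBudget)) {
    useWord <- length(spNames) >= 2L && wordLen >= 1L &&
      runif(1) < moveMix
    if (useWord) {
      tgt <- if (length(mutableSp) == 1L) mutableSp else sample(mutableSp, 1L)
      src <- if (length(spNames) == 2L) setdiff(spNames, tgt) else
        sample(setdiff(spNames, tgt), 1L)
      mT <- meta[[tgt]]
      w <- min(wordLen, meta[[src]]$n, mT$n)
      # window of w consecutive mutable target positions
      starts <- which(vapply(seq_len(mT$n - w + 1L), function(s) {
        all(!mT$protected[s:(s + w - 1L)])
      }, logical(1)))
      if (!length(starts)) {
        useWord <- FALSE
      } else {
        sFrom <- sample.int(meta[[src]]$n - w + 1L, 1L)
        word <- seqs[[src]][sFrom:(sFrom + w - 1L)]
        sTo <- starts[sample.int(length(starts), 1L)]
        span <- sTo:(sTo + w - 1L)
        v <- seqs[[tgt]]
        v[span] <- .revCompInt(word)
        fix <- .applyStemComutation(v, span, mT)
        if (is.null(fix)) next
        v <- fix
        if (.hasIllegalRun(v, mT$protected, maxRun)) next
        newSeqs <- seqs
        newSeqs[[tgt]] <- v
        return(list(
          candidate = list(seqs = newSeqs, meta = meta),
          move = sprintf("word:%s[%d..%d]->%s@%d", src, sFrom,
                         sFrom + w - 1L, tgt, sTo)))
      }
    }
    # point replacement
    tgt <- if (length(mutableSp) == 1L) mutableSp else sample(mutableSp, 1L)
    mT <- meta[[tgt]]
    pos <- .mutablePositions(mT)
    p <- if (length(pos) == 1L) pos else sample(pos, 1L)
    v <- seqs[[tgt]]
    old <- v[p]
    v[p] <- sample(setdiff(0:3, old), 1L)
    fix <- .applyStemComutation(v, p, mT)
    if (is.null(fix)) next
    v <- fix
    if (.hasIllegalRun(v, mT$protected, maxRun)) next
    newSeqs <- seqs
    newSeqs[[tgt]] <- v
    return(list(candidate = list(seqs = newSeqs, meta = meta),
                move = sprintf("point:%s@%d", tgt, p)))
  }
  NULL
}

# Co-mutate stem partners of the touched positions to the Watson-Crick
# complement; NULL when a protected partner would have to change.
.applyStemComutation <- function(v, touched, m) {
  for (p in touched) {
    q <- m$partner[p]
    if (q == 0L) next
    if (.isWCInt(v[p], v[q])) next
    if (m$protected[q]) return(NULL)
    v[q] <- .compInt(v[p])
  }
  v
}

#' Metropolis acceptance rule
#'
#' Accept when the objective does not worsen (`deltaF <= 0`), otherwise
#' with probability `exp(-deltaF / T)`.
#'
#' @param deltaF objective change of the proposal.
#' @param temperature Metropolis temperature (objective units, > 0).
#' @return `TRUE` to accept.
#' @examples
#' metropolisAccept(-1, 1)   # always TRUE
#' @export
metropolisAccept <- function(deltaF, temperature) {
  if (is.nan(deltaF)) return(FALSE)
  if (deltaF <= 0) return(TRUE)
  runif(1) < exp(-deltaF / temperature)
}

#' Homodimer exclusion check
#'
#' A sequence is rejected when its self-association free energy
#' (`deltaGMFE` of the sequence against itself) falls below the
#' threshold, i.e. when it would sequester itself as a homodimer
#' instead of engaging its intended partner.
#'
#' @param seq sequence to check.
#' @param model an [EnergyModel-class].
#' @param threshold kcal/mol (default -7.5).
#' @return `TRUE` when the sequence must be rejected.
#' @examples
#' homodimerCheck("GGGGGG")   # FALSE: G-G is not complementary
#' homodimerCheck("GGGCCC")   # TRUE: a perfect palindrome self-anneals
#' @export
homodimerCheck <- function(seq, model = referenceEnergyModel(),
                           threshold = -7.5) {
  deltaGMFE(seq, seq, model) < threshold
}

# iteration -> word length (start..1 over equal phases)
.wordLenAt <- function(iter, iterations, wordLenStart) {
  if (wordLenStart <= 1L) return(1L)
  phase <- ceiling(iter / iterations * wordLenStart)
  max(1L, wordLenStart - phase + 1L)
}

#' Design sequences for a gate by simulated annealing
#'
#' Iterative mutation and selection: starting from random sequences
#' satisfying the structural and subsequence constraints, proposals
#' from [mutateCandidate()] are accepted by the Metropolis rule under a
#' geometric temperature schedule, and the best candidate ever seen is
#' returned. The directed-move word length follows the
#' 3 -> 2 -> 1 schedule. Runs are deterministic given `rngSeed`.
#'
#' @param gate a validated [GateSpec-class].
#' @param cfg an [OptimizerConfig-class].
#' @param objCfg an [ObjectiveConfig-class].
#' @param model an [EnergyModel-class].
#' @return A [DesignResult-class].
#' @examples
#' gate <- makeNotGate(utrLen = 30, srnaLen = 20)
#' res <- runDesign(gate, optimizerConfig(iterations = 500, rngSeed = 7))
#' designSequences(res)
#' @export
runDesign <- function(gate, cfg = optimizerConfig(),
                      objCfg = objectiveConfig(),
                      model = referenceEnergyModel()) {
  validateGateSpec(gate)
  if (!is.na(cfg@rngSeed)) set.seed(cfg@rngSeed)

  plan <- .compileGate(gate, objCfg)
  score <- function(seqs, detail = FALSE) {
    .scoreCandidate(seqs, plan, objCfg, model, cfg@homodimerThreshold,
                    cfg@harmonicStiffness, detail = detail)
  }

  cand <- initializeCandidate(gate, cfg@maxIdenticalRun)
  cur <- score(cand$seqs)
  best <- list(seqs = cand$seqs, total = cur$total)

  iters <- cfg@iterations
  gamma <- (cfg@Tend / cfg@T0)^(1 / iters)
  temp <- cfg@T0

  moveLog <- character(iters)
  deltaLog <- numeric(iters)
  accLog <- logical(iters)
  objLog <- numeric(iters)

  for (it in seq_len(iters)) {
    temp <- temp * gamma
    wl <- .wordLenAt(it, iters, cfg@wordLenStart)
    prop <- mutateCandidate(cand, wl, cfg@moveMix, cfg@maxIdenticalRun,
                            cfg@resampleBudget)
    if (is.null(prop)) {
      moveLog[it] <- "none"
      deltaLog[it] <- NA_real_
      accLog[it] <- FALSE
      objLog[it] <- cur$total
      next
    }
    propScore <- score(prop$candidate$seqs)
    deltaF <- propScore$total - cur$total
    acc <- if (!is.finite(deltaF)) propScore$total < cur$total else
      metropolisAccept(deltaF, temp)
    if (acc) {
      cand <- prop$candidate
      cur <- propScore
      if (cur$total < best$total) {
        best <- list(seqs = cand$seqs, total = cur$total)
      }
    }
    moveLog[it] <- prop$move
    deltaLog[it] <- deltaF
    accLog[it] <- acc
    objLog[it] <- cur$total
  }

  bestScore <- score(best$seqs, detail = TRUE)
  seqsChr <- vapply(best$seqs, .intToSeq, character(1))

  structures <- vapply(names(best$seqs), function(nm) {
    dbString(foldMFE(seqsChr[[nm]], model))
  }, character(1))
  for (rx in gate@reactions) {
    key <- paste(rx$participants, collapse = ":")
    structures[[key]] <- dbString(cofoldMFE(as.list(seqsChr[rx$participants]),
                                            model))
  }

  new("DesignResult", sequences = seqsChr, objective = bestScore$total,
      breakdown = bestScore$breakdown, structures = structures,
      trajectory = data.frame(iteration = seq_len(iters), move = moveLog,
                              deltaF = deltaLog, accepted = accLog,
                              objective = objLog, stringsAsFactors = FALSE),
      gateType = gate@gateType)
}
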