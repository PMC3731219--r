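# Secondary-structure prediction and energy evaluation.

# normalize sequence inputs to integer vectors
.asIntSeq <- function(seq) {
  if (is(seq, "NucleotideSequence")) seq <- seq@residues
  if (!is.character(seq) || length(seq) != 1L) {
    stop(.inputError("a sequence must be a single string or NucleotideSequence"))
  }
  .seqToInt(seq)
}

.asIntSeqs <- function(seqs) {
  if (is(seqs, "NucleotideSequence") || is.character(seqs) && length(seqs) == 1L) {
    seqs <- list(seqs)
  }
  if (is.character(seqs)) seqs <- as.list(seqs)
  lapply(seqs, .asIntSeq)
}

.foldResult <- function(ints, strandLengths, pairs0, energy, modelId) {
  symbols <- .pairsToSymbols(pairs0, strandLengths)
  new("FoldResult", sequence = .intToSeq(ints),
      strandLengths = as.integer(strandLengths),
      structure = dotBracket(symbols), energy = energy, modelId = modelId)
}

#' Minimum free energy fold of a single RNA strand
#'
#' Predicts the pseudoknot-free minimum-free-energy structure under the
#' given energy model. Under the reference model the prediction is a
#' deterministic dynamic programme whose tie-breaking prefers the
#' structure with the leftmost differing position unpaired; under the
#' `"vienna"` backend the call delegates to `RNAfold`.
#'
#' @param seq a [NucleotideSequence-class] or RNA string.
#' @param model an [EnergyModel-class] (default [referenceEnergyModel()]).
#' @return A [FoldResult-class]; energy is 0 for a structure without
#'   pairs.
#' @examples
#' foldMFE("GGGAAAACCC")   # (((....))), -9 kcal/mol
#' foldMFE("ACGU")         # no pair fits the minimum hairpin loop
#' @export
foldMFE <- function(seq, model = referenceEnergyModel()) {
  ints <- .asIntSeq(seq)
  if (model@backend == "vienna") {
    return(.viennaFold(list(ints), model))
  }
  res <- cpp_fold(ints, rep(1L, length(ints)), .modelPar(model))
  .foldResult(ints, length(ints), res$pairs, res$energy, model@modelId)
}

#' Minimum free energy structure of an RNA complex
#'
#' Folds the concatenation of 2-3 strands with nested-only pairing
#' across the whole complex. Intermolecular pairs are exempt from the
#' minimum hairpin-loop separation.
#'
#' @param seqs list (or character vector) of 2-3 sequences.
#' @param model an [EnergyModel-class].
#' @return A [FoldResult-class] for the complex; the structure string
#'   uses `&` between strands.
#' @examples
#' cofoldMFE(c("GGGG", "CCCC"))   # 4 intermolecular GC pairs, -12
#' @export
cofoldMFE <- function(seqs, model = referenceEnergyModel()) {
  intSeqs <- .asIntSeqs(seqs)
  if (length(intSeqs) < 2L || length(intSeqs) > 3L) {
    stop(.capabilityError("cofoldMFE supports complexes of 2 or 3 strands"))
  }
  if (model@backend == "vienna") {
    if (length(intSeqs) > 2L) {
      stop(.capabilityError("the external engine adapter cofolds 2 strands only"))
    }
    return(.viennaFold(intSeqs, model))
  }
  ints <- unlist(intSeqs)
  lens <- lengths(intSeqs)
  strand <- rep(seq_along(intSeqs), lens)
  res <- cpp_fold(ints, strand, .modelPar(model))
  .foldResult(ints, lens, res$pairs, res$energy, model@modelId)
}

#' Evaluate the free energy of a given structure
#'
#' Additive sum of the pair energies of all pairs in the structure's
#' pair map (reference model only). Errors when a pair is
#' non-complementary under the model's flags.
#'
#' @param seqs one sequence or a list matching the structure's strands.
#' @param structure a [DotBracket-class] or dot-bracket string (with
#'   `&` between strands).
#' @param model an [EnergyModel-class] with backend `"reference"`.
#' @return Free energy in kcal/mol (0 for an all-dot structure).
#' @examples
#' evaluateStructure("GGGAAAACCC", "(((....)))")   # -9
#' @export
evaluateStructure <- function(seqs, structure,
                              model = referenceEnergyModel()) {
  if (model@backend != "reference") {
    stop(.capabilityError("evaluateStructure requires the reference model"))
  }
  db <- dotBracket(structure)
  intSeqs <- .asIntSeqs(seqs)
  ints <- unlist(intSeqs)
  lens <- lengths(intSeqs)
  if (length(lens) != length(db@strandLengths) ||
      !all(lens == db@strandLengths)) {
    stop(.inputError("structure strand lengths do not match the sequence(s)"))
  }
  strand <- rep(seq_along(lens), lens)
  pm <- pairMap(db)
  if (nrow(pm) == 0L) return(0)
  energy <- 0
  pe <- .modelPar(model)
  for (row in seq_len(nrow(pm))) {
    i <- pm[row, 1L]
    j <- pm[row, 2L]
    a <- ints[i]
    b <- ints[j]
    same <- strand[i] == strand[j]
    e <- if ((a == 1L && b == 2L) || (a == 2L && b == 1L)) {
      pe$eGC
    } else if ((a == 0L && b == 3L) || (a == 3L && b == 0L)) {
      pe$eAU
    } else if (((a == 2L && b == 3L) || (a == 3L && b == 2L)) &&
               (if (same) pe$allowGU else pe$allowGUInter)) {
      pe$eGU
    } else {
      stop(.inputError(sprintf(
        "structure error: pair (%d, %d) = %s-%s is not complementary under the model",
        i, j, RIBO_BASES[a + 1L], RIBO_BASES[b + 1L])))
    }
    energy <- energy + e
  }
  energy
}

#' Base-pairing probability matrix
#'
#' Boltzmann-weighted pairing probabilities over the full nested
#' ensemble of one or more strands under the reference model, computed
#' exactly (total length capped at `maxTotal` positions).
#'
#' @param seqs one sequence or a list of up to 3.
#' @param model reference [EnergyModel-class].
#' @param RT thermal energy, kcal/mol (default 0.61, 37 degrees C).
#' @param maxTotal size cap for the exact computation.
#' @return Symmetric matrix with entries in `[0, 1]`;
#'   `1 - rowSums(P)` gives per-position unpaired probabilities.
#' @examples
#' pairProbabilities("GGGG")                     # all zero
#' pairProbabilities(c("GGGG", "CCCC"), RT = 0.01) # ~1 on the duplex pairs
#' @export
pairProbabilities <- function(seqs, model = referenceEnergyModel(),
                              RT = 0.61, maxTotal = 30L) {
  if (model@backend != "reference") {
    stop(.capabilityError(
      "pairProbabilities is computed for the reference model only"))
  }
  if (RT <= 0) stop(.paramError("RT must be > 0"))
  intSeqs <- .asIntSeqs(seqs)
  if (length(intSeqs) > 3L) {
    stop(.capabilityError("at most 3 strands supported"))
  }
  ints <- unlist(intSeqs)
  if (length(ints) > maxTotal) {
    stop(.capabilityError(sprintf(
      "total length %d exceeds the exact-enumeration limit of %d",
      length(ints), maxTotal)))
  }
  strand <- rep(seq_along(intSeqs), lengths(intSeqs))
  P <- cpp_pairprob(ints, strand, .modelPar(model), RT)
  dimnames(P) <- list(seq_len(nrow(P)), seq_len(ncol(P)))
  P
}

# ---- ViennaRNA command-line adapter ----------------------------------

.viennaAvailable <- function() {
  nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAcofold"))
}

# Parse "structure ( -1.20)" style output lines.
.viennaParse <- function(lines, nres) {
  structLine <- grep("[().]", lines, value = TRUE)
  structLine <- structLine[grepl("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", structLine)]
  if (!length(structLine)) {
    stop(.capabilityError("could not parse external engine output"))
  }
  line <- structLine[[1L]]
  m <- regmatches(line, regexec("^([.()&]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", line))[[1L]]
  if (length(m) != 3L) {
    stop(.capabilityError("could not parse external engine output"))
  }
  list(symbols = m[[2L]], energy = as.numeric(m[[3L]]))
}

.viennaFold <- function(intSeqs, model) {
  if (!.viennaAvailable()) {
    stop(.capabilityError(
      "external engine not found: RNAfold/RNAcofold must be on the PATH"))
  }
  seqs <- vapply(intSeqs, .intToSeq, character(1))
  if (length(seqs) == 1L) {
    out <- system2("RNAfold", c("--noPS"), stdout = TRUE, input = seqs)
  } else {
    out <- system2("RNAcofold", c("--noPS"), stdout = TRUE,
                   input = paste(seqs, collapse = "&"))
  }
  parsed <- .viennaParse(out, sum(lengths(intSeqs)))
  ints <- unlist(intSeqs)
  new("FoldResult", sequence = .intToSeq(ints),
      strandLengths = lengths(intSeqs),
      structure = dotBracket(parsed$symbols), energy = parsed$energy,
      modelId = model@modelId)
}
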