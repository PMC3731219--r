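# S4 class definitions and user-facing constructors.

# ---- EnergyModel -----------------------------------------------------

#' Energy model contract
#'
#' An `EnergyModel` fixes the thermodynamic rules used by the folding
#' engine: per-pair energies (kcal/mol) for GC, AU and GU pairs, the
#' minimum hairpin-loop separation, and wobble-pair flags. Two backends
#' exist: the self-contained additive `"reference"` model, exhaustively
#' verifiable at toy scale, and a `"vienna"` adapter delegating
#' fold/cofold to an external nearest-neighbor engine.
#'
#' @slot modelId identifier reported in [FoldResult-class] objects.
#' @slot pairEnergies named numeric, energies for `GC`, `AU`, `GU` pairs
#'   (all `<= 0`, kcal/mol).
#' @slot minHairpin intramolecular pairs (i, j) require `j - i > minHairpin`;
#'   intermolecular pairs are exempt.
#' @slot allowGU,allowGUInter allow GU wobble pairs within / between strands.
#' @slot backend `"reference"` or `"vienna"`.
#' @seealso [referenceEnergyModel()], [viennaEnergyModel()]
#' @exportClass EnergyModel
setClass("EnergyModel",
  representation(
    modelId = "character", pairEnergies = "numeric", minHairpin = "integer",
    allowGU = "logical", allowGUInter = "logical", backend = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (!all(c("GC", "AU", "GU") %in% names(object@pairEnergies))) {
      msg <- c(msg, "pairEnergies must name GC, AU and GU")
    } else if (any(object@pairEnergies > 0)) {
      msg <- c(msg, "all pair energies must be <= 0")
    }
    if (object@minHairpin < 0L) msg <- c(msg, "minHairpin must be >= 0")
    if (!object@backend %in% c("reference", "vienna")) {
      msg <- c(msg, "backend must be 'reference' or 'vienna'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Reference additive energy model
#'
#' Purely additive per-pair energies with no stacking or loop terms:
#' GC = -3, AU = -2, GU = -1 kcal/mol by default. Deterministic and
#' small enough that every prediction can be checked against exhaustive
#' enumeration of pseudoknot-free structures.
#'
#' @param eGC,eAU,eGU pair energies in kcal/mol (must be `<= 0`).
#' @param allowGU allow GU wobble pairs within a strand (default `TRUE`).
#' @param allowGUInter allow GU pairs between strands (default `FALSE`;
#'   intermolecular interactions are modelled as Watson-Crick).
#' @param minHairpin minimum hairpin separation: intramolecular pairs
#'   (i, j) need `j - i > minHairpin` (default 3, i.e. a loop of at
#'   least 3 unpaired positions).
#' @return An [EnergyModel-class] object.
#' @examples
#' foldMFE("GGGAAAACCC", referenceEnergyModel())
#' @export
referenceEnergyModel <- function(eGC = -3, eAU = -2, eGU = -1,
                                 allowGU = TRUE, allowGUInter = FALSE,
                                 minHairpin = 3L) {
  new("EnergyModel",
    modelId = "reference-additive",
    pairEnergies = c(GC = eGC, AU = eAU, GU = eGU),
    minHairpin = as.integer(minHairpin),
    allowGU = allowGU, allowGUInter = allowGUInter, backend = "reference"
  )
}

#' External thermodynamic engine adapter
#'
#' Delegates [foldMFE()] and [cofoldMFE()] to the ViennaRNA command-line
#' programs (`RNAfold`, `RNAcofold`), which use full nearest-neighbor
#' parameters at 37 degrees C. Landscape enumeration and pairing
#' probabilities remain reference-model capabilities.
#'
#' @return An [EnergyModel-class] with backend `"vienna"`.
#' @export
viennaEnergyModel <- function() {
  new("EnergyModel",
    modelId = "vienna-rna",
    pairEnergies = c(GC = -3, AU = -2, GU = -1),
    minHairpin = 3L, allowGU = TRUE, allowGUInter = TRUE,
    backend = "vienna"
  )
}

# parameter list handed to the C++ core
.modelPar <- function(model) {
  list(
    eGC = unname(model@pairEnergies[["GC"]]),
    eAU = unname(model@pairEnergies[["AU"]]),
    eGU = unname(model@pairEnergies[["GU"]]),
    allowGU = model@allowGU, allowGUInter = model@allowGUInter,
    minHairpin = model@minHairpin
  )
}

# ---- NucleotideSequence ----------------------------------------------

#' RNA sequence with a designable-position mask
#'
#' @slot name identifier.
#' @slot residues string over `{A, C, G, U}`.
#' @slot designable logical, one flag per position (`TRUE` = mutable
#'   during optimization).
#' @seealso [nucleotideSequence()]
#' @exportClass NucleotideSequence
setClass("NucleotideSequence",
  representation(name = "character", residues = "character",
                 designable = "logical"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@residues) == 0L) msg <- c(msg, "sequence must be nonempty")
    if (grepl("[^ACGU]", object@residues)) {
      msg <- c(msg, "alphabet restricted to A, C, G, U")
    }
    if (length(object@designable) != nchar(object@residues)) {
      msg <- c(msg, "designable mask length must equal sequence length")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a NucleotideSequence
#'
#' @param residues RNA string (T is normalized to U).
#' @param name identifier.
#' @param designable logical mask, recycled from a scalar; default all
#'   `TRUE`.
#' @return A [NucleotideSequence-class].
#' @examples
#' nucleotideSequence("AGGAGAAACAAUG", name = "utr")
#' @export
nucleotideSequence <- function(residues, name = "seq", designable = TRUE) {
  residues <- gsub("T", "U", toupper(residues))
  n <- nchar(residues)
  if (length(designable) == 1L) designable <- rep(designable, n)
  new("NucleotideSequence", name = name, residues = residues,
      designable = designable)
}

# ---- DotBracket ------------------------------------------------------

#' Dot-bracket secondary structure
#'
#' Pseudoknot-free pairing of one or more strands. `&` separates
#' strands; `pairMap[i]` holds the partner of residue i (positions count
#' residues only, `&` excluded) or 0 when unpaired. Intramolecular pairs
#' must satisfy `j - i > 3`; intermolecular pairs are exempt.
#'
#' @slot symbols structure string over `. ( ) &`.
#' @slot pairMap integer partner vector (0 = unpaired), 1-based residue
#'   coordinates.
#' @slot strandLengths integer lengths of the strands.
#' @seealso [dotBracket()], [pairMap()]
#' @exportClass DotBracket
setClass("DotBracket",
  representation(symbols = "character", pairMap = "integer",
                 strandLengths = "integer"),
  validity = function(object) {
    reparsed <- tryCatch(.parseDotBracket(object@symbols),
                         error = function(e) conditionMessage(e))
    if (is.character(reparsed)) return(reparsed)
    if (!identical(reparsed$pairMap, object@pairMap)) {
      return("pairMap inconsistent with symbols")
    }
    if (!identical(reparsed$strandLengths, object@strandLengths)) {
      return("strandLengths inconsistent with symbols")
    }
    TRUE
  }
)

# Stack parse of a dot-bracket string; enforces balance, nesting (the
# stack grammar admits only nested pairings) and the minimum hairpin
# separation for intramolecular pairs.
.parseDotBracket <- function(symbols, minHairpin = 3L) {
  chars <- strsplit(symbols, "")[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")", "&"))
  if (length(bad)) {
    stop(.inputError(sprintf("invalid structure symbol(s): %s",
                             paste(bad, collapse = " "))))
  }
  res <- chars[chars != "&"]
  n <- length(res)
  if (n == 0L) stop(.inputError("empty structure"))
  # strand id per residue position
  strand <- integer(n)
  s <- 1L
  p <- 0L
  for (ch in chars) {
    if (ch == "&") {
      s <- s + 1L
    } else {
      p <- p + 1L
      strand[p] <- s
    }
  }
  strandLengths <- as.integer(tabulate(strand))
  if (any(strandLengths == 0L)) stop(.inputError("empty strand in structure"))
  pairMap <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (res[i] == "(") {
      stack <- c(stack, i)
    } else if (res[i] == ")") {
      if (!length(stack)) {
        stop(.inputError(sprintf("unbalanced ')' at residue %d", i)))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairMap[j] <- i
      pairMap[i] <- j
    }
  }
  if (length(stack)) {
    stop(.inputError(sprintf("unbalanced '(' at residue %d", stack[1])))
  }
  for (j in which(pairMap > seq_len(n))) {
    i <- pairMap[j]
    if (strand[i] == strand[j] && i - j <= minHairpin) {
      stop(.inputError(sprintf(
        "pair (%d, %d) violates the minimum hairpin loop of %d unpaired positions",
        j, i, minHairpin
      )))
    }
  }
  list(pairMap = pairMap, strandLengths = strandLengths, strand = strand)
}

#' Construct a DotBracket structure
#'
#' @param symbols structure string over `. ( ) &` (`&` separates strands).
#' @return A [DotBracket-class] object.
#' @examples
#' db <- dotBracket("((..))&..")
#' pairMap(db)
#' @export
dotBracket <- function(symbols) {
  if (is(symbols, "DotBracket")) return(symbols)
  parsed <- .parseDotBracket(symbols)
  new("DotBracket", symbols = symbols, pairMap = parsed$pairMap,
      strandLengths = parsed$strandLengths)
}

# structure string from a 0-based partner vector and strand lengths
.pairsToSymbols <- function(pairs0, strandLengths) {
  n <- length(pairs0)
  sym <- rep(".", n)
  sym[pairs0 > seq_len(n) - 1L] <- "("
  sym[pairs0 >= 0L & pairs0 < seq_len(n) - 1L] <- ")"
  pieces <- character(length(strandLengths))
  off <- 0L
  for (k in seq_along(strandLengths)) {
    pieces[k] <- paste(sym[(off + 1L):(off + strandLengths[k])], collapse = "")
    off <- off + strandLengths[k]
  }
  paste(pieces, collapse = "&")
}

# ---- FoldResult ------------------------------------------------------

#' Result of a secondary-structure prediction
#'
#' @slot sequence concatenated residues of the folded strand(s).
#' @slot strandLengths lengths of the strands.
#' @slot structure the predicted [DotBracket-class].
#' @slot energy free energy in kcal/mol (0 for a pair-free structure
#'   under the reference model).
#' @slot modelId identifier of the energy model used.
#' @seealso [foldMFE()], [cofoldMFE()]
#' @exportClass FoldResult
setClass("FoldResult",
  representation(sequence = "character", strandLengths = "integer",
                 structure = "DotBracket", energy = "numeric",
                 modelId = "character")
)

# ---- Landscape types -------------------------------------------------

#' Reaction-coordinate energy profile
#'
#' Effective free energy G(r) along the reaction coordinate r, the
#' number of intermolecular pairs (r = 0 is the pre-association state of
#' individually folded species). `rHyb` is the coordinate of the complex
#' minimum; `rTrans` the barrier coordinate on the path 1..rHyb.
#'
#' @slot r integer reaction coordinates with feasible structures.
#' @slot G effective free energies G(r), kcal/mol (G = 0 for the fully
#'   unfolded state).
#' @slot rHyb,rTrans hybridization and transition coordinates.
#' @seealso [enumerateProfile()], [profileEnergies()]
#' @exportClass ReactionProfile
setClass("ReactionProfile",
  representation(r = "integer", G = "numeric", rHyb = "integer",
                 rTrans = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@r) != length(object@G)) msg <- c(msg, "r/G length mismatch")
    if (!0L %in% object@r) msg <- c(msg, "profile must contain r = 0")
    if (object@rHyb < 0L) msg <- c(msg, "rHyb must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Free-energy summary of an association reaction
#'
#' @slot deltaG formation free energy `G(rHyb) - G(0)`, kcal/mol.
#' @slot deltaGActivation activation free energy `G(rTrans) - G(0)`,
#'   kcal/mol; always `>= deltaG` since the barrier is a maximum over a
#'   path that includes the endpoint.
#' @slot Z partition function over the profile states.
#' @slot RT thermal energy used, kcal/mol.
#' @exportClass EnergySummary
setClass("EnergySummary",
  representation(deltaG = "numeric", deltaGActivation = "numeric",
                 Z = "numeric", RT = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@Z <= 0) msg <- c(msg, "Z must be > 0")
    if (object@deltaGActivation < object@deltaG - 1e-9) {
      msg <- c(msg, "activation energy cannot be below formation energy")
    }
    if (length(msg)) msg else TRUE
  }
)

# ---- Objective types -------------------------------------------------

#' Seed (nucleation) region between two folded RNAs
#'
#' The longest contiguous antiparallel Watson-Crick complementary run
#' between positions unpaired in both partners' individual MFE
#' structures; the first nucleotides paired during association.
#'
#' @slot startA,startB 1-based start positions of the run in each
#'   partner (`NA` when `alpha = 0`).
#' @slot alpha seed length in nucleotides.
#' @seealso [seedRegion()]
#' @exportClass SeedRegion
setClass("SeedRegion",
  representation(startA = "integer", startB = "integer", alpha = "integer"),
  validity = function(object) {
    if (object@alpha < 0L) "alpha must be >= 0" else TRUE
  }
)

#' Objective configuration
#'
#' Constants of the energy-based objective. Defaults are the published
#' calibration: `Gp = -1.28` kcal/mol (average energetic contribution of
#' one paired nucleotide), saturation levels `dGsat = -15` kcal/mol and
#' `alphaSat = 6` nt beyond which further minimization earns no credit,
#' and `RT = 0.61` kcal/mol (37 degrees C).
#'
#' @slot Gp per-nucleotide pairing energy, kcal/mol (`< 0`).
#' @slot dGsat formation-energy saturation level, kcal/mol (`< 0`).
#' @slot alphaSat seed-length saturation, nt (`>= 1`).
#' @slot RT thermal energy, kcal/mol.
#' @slot wKin,wStr nonnegative weights of the kinetic and structural
#'   terms in the weighted sum.
#' @slot seedGU whether GU pairs count as complementary in seed
#'   detection (default `FALSE`: seeds are Watson-Crick).
#' @seealso [objectiveConfig()]
#' @exportClass ObjectiveConfig
setClass("ObjectiveConfig",
  representation(Gp = "numeric", dGsat = "numeric", alphaSat = "integer",
                 RT = "numeric", wKin = "numeric", wStr = "numeric",
                 seedGU = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@Gp >= 0) msg <- c(msg, "Gp must be < 0")
    if (object@dGsat >= 0) msg <- c(msg, "dGsat must be < 0")
    if (object@alphaSat < 1L) msg <- c(msg, "alphaSat must be >= 1")
    if (object@RT <= 0) msg <- c(msg, "RT must be > 0")
    if (object@wKin < 0 || object@wStr < 0) msg <- c(msg, "weights must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ObjectiveConfig-class
#' @param Gp,dGsat,alphaSat,RT,wKin,wStr,seedGU see slot documentation.
#' @return An [ObjectiveConfig-class].
#' @examples
#' objectiveConfig()
#' @export
objectiveConfig <- function(Gp = -1.28, dGsat = -15, alphaSat = 6L,
                            RT = 0.61, wKin = 1, wStr = 1, seedGU = FALSE) {
  new("ObjectiveConfig", Gp = Gp, dGsat = dGsat,
      alphaSat = as.integer(alphaSat), RT = RT, wKin = wKin, wStr = wStr,
      seedGU = seedGU)
}

#' One term of a gate objective
#'
#' `kin` terms score a reaction between species (minimized when the
#' reaction must occur, sign-flipped and floored at zero when it must
#' not); `str` terms score the structural distance of a species or
#' complex to a target structure or pairedness mask, and are always
#' minimized.
#'
#' @slot kind `"kin"` or `"str"`.
#' @slot participants species names of the reaction (`kin` only).
#' @slot sense `"occur"` or `"avoid"` (`kin` only).
#' @slot subject species name(s) whose folded structure is compared
#'   (`str` only; length > 1 means the cofolded complex).
#' @slot target full dot-bracket target compared literally (`NA` when a
#'   mask is used).
#' @slot maskPos residue positions of the mask in the subject's
#'   concatenated coordinates.
#' @slot maskState `"paired"` or `"unpaired"`; a `"paired"` mask
#'   position matches either bracket.
#' @slot weight term weight.
#' @slot entry truth-table entry label the term belongs to.
#' @exportClass ObjectiveTerm
setClass("ObjectiveTerm",
  representation(kind = "character", participants = "character",
                 sense = "character", subject = "character",
                 target = "character", maskPos = "integer",
                 maskState = "character", weight = "numeric",
                 entry = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("kin", "str")) msg <- c(msg, "kind must be kin/str")
    if (object@kind == "kin" && !object@sense %in% c("occur", "avoid")) {
      msg <- c(msg, "kin terms need sense occur/avoid")
    }
    if (object@kind == "str" && !is.na(object@sense)) {
      msg <- c(msg, "occur/avoid sense applies to kin terms only")
    }
    if (object@weight < 0) msg <- c(msg, "weight must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

.kinTerm <- function(participants, sense, weight = 1, entry = "") {
  new("ObjectiveTerm", kind = "kin", participants = participants,
      sense = sense, subject = character(0), target = NA_character_,
      maskPos = integer(0), maskState = NA_character_, weight = weight,
      entry = entry)
}

.strTerm <- function(subject, target = NA_character_, maskPos = integer(0),
                     maskState = NA_character_, weight = 1, entry = "") {
  new("ObjectiveTerm", kind = "str", participants = character(0),
      sense = NA_character_, subject = subject, target = target,
      maskPos = as.integer(maskPos), maskState = maskState, weight = weight,
      entry = entry)
}

# ---- Gate types ------------------------------------------------------

#' Species of a gate specification
#'
#' @slot name species identifier.
#' @slot role `"sRNA"` or `"mRNA_5UTR"`.
#' @slot length sequence length, nt.
#' @slot targetStructure dot-bracket target imposed on the species'
#'   individual fold.
#' @slot motifs list of fixed subsequences, each `list(seq=, at=)` with
#'   1-based start `at` (e.g. Shine-Dalgarno `AGGAGA`, start codon
#'   `AUG`, poly(U) tail).
#' @slot fixedSequence full fixed sequence (`NA` unless the species is
#'   constrained); when present the species has no designable positions.
#' @seealso [speciesSpec()]
#' @exportClass SpeciesSpec
setClass("SpeciesSpec",
  representation(name = "character", role = "character", length = "integer",
                 targetStructure = "character", motifs = "list",
                 fixedSequence = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@role %in% c("sRNA", "mRNA_5UTR")) {
      msg <- c(msg, "role must be sRNA or mRNA_5UTR")
    }
    if (object@length < 1L) msg <- c(msg, "length must be >= 1")
    nres <- nchar(gsub("&", "", object@targetStructure))
    if (nres != object@length) {
      msg <- c(msg, "target structure length must equal species length")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname SpeciesSpec-class
#' @param name,role,length,targetStructure,motifs,fixedSequence see slot
#'   documentation; `targetStructure` defaults to all-unpaired.
#' @return A [SpeciesSpec-class].
#' @export
speciesSpec <- function(name, role, length,
                        targetStructure = strrep(".", length),
                        motifs = list(), fixedSequence = NA_character_) {
  length <- as.integer(length)
  if (!is.na(fixedSequence)) {
    fixedSequence <- gsub("T", "U", toupper(fixedSequence))
  }
  new("SpeciesSpec", name = name, role = role, length = length,
      targetStructure = targetStructure, motifs = motifs,
      fixedSequence = fixedSequence)
}

#' Gate specification
#'
#' Declarative description of a logic device: its RNA species, the
#' truth table (one entry per input combination, each mapping to a
#' structural requirement), the reactions that must or must not occur,
#' and the compiled objective terms.
#'
#' @slot gateType one of `NOT_direct`, `YES`, `NOT_cis`, `YES_antiterm`,
#'   `AND`, `coupled_YES_NOT`, `OR_extend`.
#' @slot species list of [SpeciesSpec-class].
#' @slot entries list of truth-table entries, each
#'   `list(inputs=, requiredOutput=)`.
#' @slot reactions list of `list(participants=, sense=)`.
#' @slot terms list of [ObjectiveTerm-class].
#' @seealso [makeNotGate()], [makeYesGate()], [makeAndGate()],
#'   [validateGateSpec()]
#' @exportClass GateSpec
setClass("GateSpec",
  representation(gateType = "character", species = "list",
                 entries = "list", reactions = "list", terms = "list")
)

# ---- Optimizer types -------------------------------------------------

#' Optimizer configuration
#'
#' Monte Carlo simulated annealing settings. The temperature schedule is
#' geometric from `T0` down to `Tend` (objective units); the directed
#' mutation word length follows a 3 -> 2 -> 1 schedule over thirds of
#' the run.
#'
#' @slot iterations number of annealing steps (`>= 1`).
#' @slot T0,Tend initial and final Metropolis temperatures (objective
#'   units, both `> 0`).
#' @slot wordLenStart initial word length of the reverse-complement
#'   transplant move (reduced to 1 during the run).
#' @slot moveMix probability of a word-transplant move versus a point
#'   replacement.
#' @slot rngSeed integer seed driving every stochastic choice (`NA` =
#'   use the current RNG state).
#' @slot harmonicStiffness optional harmonic relaxation: adds
#'   `harmonicStiffness * d^2` per species, `d` the Hamming distance of
#'   its fold to its target structure (0 disables).
#' @slot homodimerThreshold sRNA self-association free energies below
#'   this (kcal/mol) are excluded.
#' @slot maxIdenticalRun runs of this many identical nucleotides (or
#'   longer) are forbidden outside fixed motifs.
#' @slot resampleBudget proposal resampling attempts before a move is
#'   counted as failed.
#' @seealso [optimizerConfig()], [runDesign()]
#' @exportClass OptimizerConfig
setClass("OptimizerConfig",
  representation(iterations = "integer", T0 = "numeric", Tend = "numeric",
                 wordLenStart = "integer", moveMix = "numeric",
                 rngSeed = "integer", harmonicStiffness = "numeric",
                 homodimerThreshold = "numeric", maxIdenticalRun = "integer",
                 resampleBudget = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
    if (object@T0 <= 0 || object@Tend <= 0) msg <- c(msg, "temperatures must be > 0")
    if (object@moveMix < 0 || object@moveMix > 1) msg <- c(msg, "moveMix in [0,1]")
    if (object@maxIdenticalRun < 2L) msg <- c(msg, "maxIdenticalRun must be >= 2")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname OptimizerConfig-class
#' @param iterations,T0,Tend,wordLenStart,moveMix,rngSeed see slot
#'   documentation.
#' @param harmonicStiffness,homodimerThreshold,maxIdenticalRun,resampleBudget
#'   see slot documentation.
#' @return An [OptimizerConfig-class].
#' @examples
#' optimizerConfig(iterations = 1000, rngSeed = 1)
#' @export
optimizerConfig <- function(iterations = 10000L, T0 = 5, Tend = 0.05,
                            wordLenStart = 3L, moveMix = 0.5,
                            rngSeed = NA_integer_, harmonicStiffness = 0,
                            homodimerThreshold = -7.5,
                            maxIdenticalRun = 4L, resampleBudget = 50L) {
  new("OptimizerConfig", iterations = as.integer(iterations), T0 = T0,
      Tend = Tend, wordLenStart = as.integer(wordLenStart), moveMix = moveMix,
      rngSeed = as.integer(rngSeed), harmonicStiffness = harmonicStiffness,
      homodimerThreshold = homodimerThreshold,
      maxIdenticalRun = as.integer(maxIdenticalRun),
      resampleBudget = as.integer(resampleBudget))
}

#' Result of a design run
#'
#' @slot sequences named character vector, the best-seen sequences.
#' @slot objective best-seen objective value.
#' @slot breakdown per-term data frame for the returned candidate.
#' @slot structures named character vector of dot-bracket strings:
#'   individual MFE folds and the complexes of each reaction.
#' @slot trajectory data frame with one row per iteration (proposed
#'   move, delta F, acceptance, objective after the step).
#' @slot gateType gate type the run designed.
#' @seealso [runDesign()]
#' @exportClass DesignResult
setClass("DesignResult",
  representation(sequences = "character", objective = "numeric",
                 breakdown = "data.frame", structures = "character",
                 trajectory = "data.frame", gateType = "character")
)

# ---- Kinetics / validation types -------------------------------------

#' Rate constants of the riboregulation mass-action model
#'
#' Association of species A and B to the transition-state intermediate
#' (kOn, kOff), hybridization of the intermediate to the final complex
#' (kHyb), and first-order degradation of the free species (delta1) and
#' of the final complex (delta2). `KM = (kOff + kHyb)/kOn`.
#'
#' @slot kOn,kOff,kHyb,delta1,delta2 nonnegative rate constants
#'   (arbitrary consistent units).
#' @slot KM Michaelis constant.
#' @seealso [kineticParameters()], [simulateKinetics()]
#' @exportClass KineticParameters
setClass("KineticParameters",
  representation(kOn = "numeric", kOff = "numeric", kHyb = "numeric",
                 delta1 = "numeric", delta2 = "numeric", KM = "numeric"),
  validity = function(object) {
    vals <- c(object@kOn, object@kOff, object@kHyb, object@delta1,
              object@delta2)
    if (any(vals < 0)) return("negative rate constant")
    if (object@kOn > 0 && object@KM <= 0) return("KM must be > 0 when kOn > 0")
    TRUE
  }
)

#' @rdname KineticParameters-class
#' @param kOn,kOff,kHyb,delta1,delta2 nonnegative rate constants.
#' @return A [KineticParameters-class] with `KM` filled in.
#' @examples
#' kineticParameters(kOn = 1, kOff = 9, kHyb = 1, delta1 = 0.01)
#' @export
kineticParameters <- function(kOn, kOff, kHyb, delta1 = 0, delta2 = 0) {
  if (any(c(kOn, kOff, kHyb, delta1, delta2) < 0)) {
    stop(.paramError("rate constants must be nonnegative"))
  }
  KM <- if (kOn > 0) (kOff + kHyb) / kOn else Inf
  new("KineticParameters", kOn = kOn, kOff = kOff, kHyb = kHyb,
      delta1 = delta1, delta2 = delta2, KM = KM)
}

#' Predicted expression fold change from the kinetic objective
#'
#' @slot dGkin kinetic objective value, kcal/mol.
#' @slot RT thermal energy, kcal/mol.
#' @slot scale free multiplicative constant (only fold ratios are
#'   meaningful).
#' @slot fold predicted fold change, `scale * exp(-dGkin/RT) > 0`.
#' @seealso [predictedFold()]
#' @exportClass FoldPrediction
setClass("FoldPrediction",
  representation(dGkin = "numeric", RT = "numeric", scale = "numeric",
                 fold = "numeric"),
  validity = function(object) {
    if (object@fold <= 0) "predicted fold must be > 0" else TRUE
  }
)

#' Log-linear regression fit of fold change on the kinetic objective
#'
#' @slot slope slope per kcal/mol.
#' @slot intercept intercept of the log-fold regression.
#' @slot r2 coefficient of determination, in `[0, 1]`.
#' @slot n number of records fitted.
#' @seealso [fitLogLinear()]
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 n = "integer"),
  validity = function(object) {
    if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9) "R2 must lie in [0, 1]" else TRUE
  }
)
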