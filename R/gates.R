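# Declarative gate specifications: species, truth tables, reactions and
# the compiled objective terms for the supported logic devices.

SD_SEQUENCE <- "AGGAGA"
START_CODON <- "AUG"
SD_SPACING <- 8L  # nt between the SD sequence and the start codon

# Shine-Dalgarno / start-codon layout at the 3' end of a 5' UTR:
# [ ... ][SD 6][spacer 8][AUG 3]
.sdLayout <- function(utrLen) {
  utrLen <- as.integer(utrLen)
  sdStart <- utrLen - nchar(START_CODON) - SD_SPACING - nchar(SD_SEQUENCE) + 1L
  if (sdStart < 1L) {
    stop(.specError(sprintf(
      "5' UTR of %d nt cannot hold SD + %d-nt spacer + start codon", utrLen,
      SD_SPACING)))
  }
  list(sdStart = sdStart, sdPos = sdStart:(sdStart + nchar(SD_SEQUENCE) - 1L),
       augStart = utrLen - nchar(START_CODON) + 1L)
}

.utrMotifs <- function(layout) {
  list(list(seq = SD_SEQUENCE, at = layout$sdStart),
       list(seq = START_CODON, at = layout$augStart))
}

# default cis-repressing 5' UTR target: an anti-SD stem sequestering the
# SD sequence ( [..][anti-SD 6][loop 4][SD 6][..] )
.cisRepressedTarget <- function(utrLen, layout) {
  antiStart <- layout$sdStart - 10L
  if (antiStart < 1L) {
    stop(.specError(sprintf(
      "5' UTR of %d nt too short for the default cis-repressing stem", utrLen)))
  }
  sym <- rep(".", utrLen)
  sym[antiStart:(antiStart + 5L)] <- "("
  sym[layout$sdPos] <- ")"
  paste(sym, collapse = "")
}

#' Construct a gate specification from its parts
#'
#' Low-level constructor for custom devices; the [makeNotGate()] family
#' covers the standard mechanisms. The spec is validated before being
#' returned.
#'
#' @param gateType gate type label.
#' @param species list of [SpeciesSpec-class].
#' @param entries list of truth-table entries
#'   `list(inputs =, requiredOutput =)`.
#' @param reactions list of `list(participants =, sense =)`.
#' @param terms list of [ObjectiveTerm-class] from [kinTerm()] /
#'   [strTerm()].
#' @return A validated [GateSpec-class].
#' @export
gateSpec <- function(gateType, species, entries, reactions, terms) {
  gate <- new("GateSpec", gateType = gateType, species = species,
              entries = entries, reactions = reactions, terms = terms)
  validateGateSpec(gate)
  gate
}

#' Construct objective terms
#'
#' `kinTerm` scores the reaction between `participants` (2 species, or
#' 3 where the first two form the reacting dimer) with sense `"occur"`
#' or `"avoid"`. `strTerm` scores the structure of `subject` (one
#' species, or several for their cofolded complex) against a full
#' dot-bracket `target` or a pairedness mask.
#'
#' @param participants species names of the reaction.
#' @param sense `"occur"` or `"avoid"`.
#' @param subject species name(s) whose fold is compared.
#' @param target full dot-bracket target (alternative to the mask).
#' @param maskPositions 1-based residue positions in the subject's
#'   concatenated coordinates.
#' @param maskState `"paired"` or `"unpaired"`.
#' @param weight term weight.
#' @param entry truth-table entry label.
#' @return An [ObjectiveTerm-class].
#' @export
kinTerm <- function(participants, sense, weight = 1, entry = "") {
  .kinTerm(participants, sense, weight, entry)
}

#' @rdname kinTerm
#' @export
strTerm <- function(subject, target = NULL, maskPositions = NULL,
                    maskState = NULL, weight = 1, entry = "") {
  .strTerm(subject,
           target = if (is.null(target)) NA_character_ else target,
           maskPos = if (is.null(maskPositions)) integer(0) else maskPositions,
           maskState = if (is.null(maskState)) NA_character_ else maskState,
           weight = weight, entry = entry)
}

# per-species inverse-folding terms for species with structured targets
.speciesStructureTerms <- function(species, entry = "species") {
  terms <- list()
  for (s in species) {
    if (grepl("[()]", s@targetStructure)) {
      terms[[length(terms) + 1L]] <-
        .strTerm(s@name, target = s@targetStructure, entry = entry)
    }
  }
  terms
}

#' NOT gate: an sRNA blocks the RBS of an unstructured 5' UTR
#'
#' The trans-repressing sRNA binds the mRNA 5' UTR so that the
#' Shine-Dalgarno sequence (placed 8 nt upstream of the start codon) is
#' paired in the complex, preventing ribosome docking. Truth table:
#' without sRNA the RBS is accessible on the mRNA alone; with sRNA the
#' sRNA:mRNA reaction must occur and the RBS is blocked in the complex.
#'
#' @param utrLen 5' UTR length in nt (>= 17 to hold SD + spacer + AUG).
#' @param srnaLen sRNA length in nt (>= 6, so the SD can be covered).
#' @param srnaTargetStructure dot-bracket target for the sRNA's
#'   individual fold (default unstructured; hairpin variants are
#'   accepted).
#' @param utrTargetStructure dot-bracket target for the mRNA 5' UTR
#'   (default unstructured, leaving the RBS accessible).
#' @return A validated [GateSpec-class].
#' @examples
#' makeNotGate(utrLen = 30, srnaLen = 20)
#' @export
makeNotGate <- function(utrLen = 30L, srnaLen = 20L,
                        srnaTargetStructure = NULL,
                        utrTargetStructure = NULL) {
  utrLen <- as.integer(utrLen)
  srnaLen <- as.integer(srnaLen)
  if (srnaLen < nchar(SD_SEQUENCE)) {
    stop(.specError(sprintf(
      "sRNA of %d nt cannot cover the %d-nt SD sequence", srnaLen,
      nchar(SD_SEQUENCE))))
  }
  layout <- .sdLayout(utrLen)
  if (is.null(srnaTargetStructure)) srnaTargetStructure <- strrep(".", srnaLen)
  if (is.null(utrTargetStructure)) utrTargetStructure <- strrep(".", utrLen)

  species <- list(
    speciesSpec("sRNA", "sRNA", srnaLen, srnaTargetStructure),
    speciesSpec("mRNA", "mRNA_5UTR", utrLen, utrTargetStructure,
                motifs = .utrMotifs(layout))
  )
  entries <- list(
    list(inputs = character(0), requiredOutput = "RBS_accessible"),
    list(inputs = "sRNA", requiredOutput = "RBS_blocked")
  )
  reactions <- list(list(participants = c("sRNA", "mRNA"), sense = "occur"))
  terms <- c(
    list(
      .strTerm("mRNA", maskPos = layout$sdPos, maskState = "unpaired",
               entry = "0"),
      .kinTerm(c("sRNA", "mRNA"), "occur", entry = "1"),
      .strTerm(c("sRNA", "mRNA"), maskPos = srnaLen + layout$sdPos,
               maskState = "paired", entry = "1")
    ),
    .speciesStructureTerms(species)
  )
  gate <- new("GateSpec", gateType = "NOT_direct", species = species,
              entries = entries, reactions = reactions, terms = terms)
  validateGateSpec(gate)
  gate
}

#' YES gate and variants: sRNA-triggered conformational switching
#'
#' In the plain `YES` gate the 5' UTR is cis-repressed (the SD sequence
#' sequestered by an intramolecular anti-SD stem) and the sRNA releases
#' it: the sRNA:mRNA reaction must occur and the RBS must be unpaired
#' in the complex. The `NOT_cis` variant flips the masks (the sRNA
#' induces cis-repression of an otherwise accessible RBS). The
#' `YES_antiterm` variant places an intrinsic transcription terminator
#' (a >= 6-bp stem followed by a poly(U) tail) upstream of the RBS in
#' the 5' UTR; the sRNA must disrupt the terminator stem in the
#' complex.
#'
#' @param utrLen 5' UTR length in nt (default 30; the `YES_antiterm`
#'   default is 42).
#' @param srnaLen sRNA length in nt.
#' @param utrTargetStructure dot-bracket target of the 5' UTR alone;
#'   defaults to the variant's canonical structure.
#' @param srnaTargetStructure dot-bracket target of the sRNA (default
#'   unstructured).
#' @param variant `"YES"`, `"NOT_cis"` or `"YES_antiterm"`.
#' @return A validated [GateSpec-class].
#' @examples
#' makeYesGate()
#' makeYesGate(variant = "NOT_cis")
#' @export
makeYesGate <- function(utrLen = NULL, srnaLen = 20L,
                        utrTargetStructure = NULL,
                        srnaTargetStructure = NULL,
                        variant = c("YES", "NOT_cis", "YES_antiterm")) {
  variant <- match.arg(variant)
  if (is.null(utrLen)) utrLen <- if (variant == "YES_antiterm") 42L else 30L
  utrLen <- as.integer(utrLen)
  srnaLen <- as.integer(srnaLen)
  if (srnaLen < nchar(SD_SEQUENCE)) {
    stop(.specError(sprintf(
      "sRNA of %d nt cannot cover the %d-nt SD sequence", srnaLen,
      nchar(SD_SEQUENCE))))
  }
  layout <- .sdLayout(utrLen)
  if (is.null(srnaTargetStructure)) srnaTargetStructure <- strrep(".", srnaLen)

  motifs <- .utrMotifs(layout)
  termStem <- NULL
  if (variant == "YES") {
    if (is.null(utrTargetStructure)) {
      utrTargetStructure <- .cisRepressedTarget(utrLen, layout)
    }
  } else if (variant == "NOT_cis") {
    if (is.null(utrTargetStructure)) utrTargetStructure <- strrep(".", utrLen)
  } else {  # YES_antiterm
    # terminator: [stem 6][loop 4][stem' 6][UUUUUU] ahead of the SD
    need <- 6L + 4L + 6L + 6L
    if (layout$sdStart <= need) {
      stop(.specError(sprintf(
        "5' UTR of %d nt too short for a terminator upstream of the RBS",
        utrLen)))
    }
    stem1 <- 1:6
    stem2 <- 11:16
    polyU <- 17:22
    termStem <- c(stem1, stem2)
    if (is.null(utrTargetStructure)) {
      sym <- rep(".", utrLen)
      sym[stem1] <- "("
      sym[stem2] <- ")"
      utrTargetStructure <- paste(sym, collapse = "")
    }
    motifs <- c(motifs, list(list(seq = "UUUUUU", at = polyU[1L])))
  }

  species <- list(
    speciesSpec("sRNA", "sRNA", srnaLen, srnaTargetStructure),
    speciesSpec("mRNA", "mRNA_5UTR", utrLen, utrTargetStructure,
                motifs = motifs)
  )
  outputs <- switch(variant,
    YES = c("RBS_blocked", "RBS_accessible"),
    NOT_cis = c("RBS_accessible", "RBS_blocked"),
    YES_antiterm = c("terminator_formed", "terminator_disrupted"))
  entries <- list(
    list(inputs = character(0), requiredOutput = outputs[1L]),
    list(inputs = "sRNA", requiredOutput = outputs[2L])
  )
  reactions <- list(list(participants = c("sRNA", "mRNA"), sense = "occur"))

  offPos <- if (variant == "YES_antiterm") termStem else layout$sdPos
  offState <- switch(variant, YES = "paired", NOT_cis = "unpaired",
                     YES_antiterm = "paired")
  onState <- switch(variant, YES = "unpaired", NOT_cis = "paired",
                    YES_antiterm = "unpaired")
  terms <- c(
    list(
      .strTerm("mRNA", maskPos = offPos, maskState = offState, entry = "0"),
      .kinTerm(c("sRNA", "mRNA"), "occur", entry = "1"),
      .strTerm(c("sRNA", "mRNA"), maskPos = srnaLen + offPos,
               maskState = onState, entry = "1")
    ),
    .speciesStructureTerms(species)
  )
  gateType <- switch(variant, YES = "YES", NOT_cis = "NOT_cis",
                     YES_antiterm = "YES_antiterm")
  gate <- new("GateSpec", gateType = gateType, species = species,
              entries = entries, reactions = reactions, terms = terms)
  validateGateSpec(gate)
  gate
}

#' AND gate: two sRNAs dimerize to release a cis-repressed RBS
#'
#' Neither sRNA alone may activate the mRNA (avoid-sense reactions);
#' the two sRNAs must form a dimer (occur), and the three-species
#' complex must expose the RBS of the cis-repressed 5' UTR.
#'
#' @param utrLen 5' UTR length (default 30).
#' @param srnaLens lengths of the two sRNAs.
#' @param utrTargetStructure target of the 5' UTR alone (default: the
#'   canonical cis-repressing anti-SD stem).
#' @param srnaTargetStructures list of two dot-bracket targets (default
#'   unstructured).
#' @return A validated [GateSpec-class] with the four truth-table
#'   entries of a 2-input gate.
#' @examples
#' makeAndGate()
#' @export
makeAndGate <- function(utrLen = 30L, srnaLens = c(14L, 14L),
                        utrTargetStructure = NULL,
                        srnaTargetStructures = NULL) {
  utrLen <- as.integer(utrLen)
  srnaLens <- as.integer(srnaLens)
  layout <- .sdLayout(utrLen)
  if (is.null(utrTargetStructure)) {
    utrTargetStructure <- .cisRepressedTarget(utrLen, layout)
  }
  if (is.null(srnaTargetStructures)) {
    srnaTargetStructures <- lapply(srnaLens, function(n) strrep(".", n))
  }
  species <- list(
    speciesSpec("sRNA1", "sRNA", srnaLens[1L], srnaTargetStructures[[1L]]),
    speciesSpec("sRNA2", "sRNA", srnaLens[2L], srnaTargetStructures[[2L]]),
    speciesSpec("mRNA", "mRNA_5UTR", utrLen, utrTargetStructure,
                motifs = .utrMotifs(layout))
  )
  entries <- list(
    list(inputs = character(0), requiredOutput = "RBS_blocked"),
    list(inputs = "sRNA1", requiredOutput = "RBS_blocked"),
    list(inputs = "sRNA2", requiredOutput = "RBS_blocked"),
    list(inputs = c("sRNA1", "sRNA2"), requiredOutput = "RBS_accessible")
  )
  reactions <- list(
    list(participants = c("sRNA1", "mRNA"), sense = "avoid"),
    list(participants = c("sRNA2", "mRNA"), sense = "avoid"),
    list(participants = c("sRNA1", "sRNA2"), sense = "occur"),
    list(participants = c("sRNA1", "sRNA2", "mRNA"), sense = "occur")
  )
  maskComplex <- sum(srnaLens) + layout$sdPos
  terms <- c(
    list(
      .strTerm("mRNA", maskPos = layout$sdPos, maskState = "paired",
               entry = "00"),
      .kinTerm(c("sRNA1", "mRNA"), "avoid", entry = "10"),
      .kinTerm(c("sRNA2", "mRNA"), "avoid", entry = "01"),
      .kinTerm(c("sRNA1", "sRNA2"), "occur", entry = "11"),
      .kinTerm(c("sRNA1", "sRNA2", "mRNA"), "occur", entry = "11"),
      .strTerm(c("sRNA1", "sRNA2", "mRNA"), maskPos = maskComplex,
               maskState = "unpaired", entry = "11")
    ),
    .speciesStructureTerms(species)
  )
  gate <- new("GateSpec", gateType = "AND", species = species,
              entries = entries, reactions = reactions, terms = terms)
  validateGateSpec(gate)
  gate
}

#' Constrain a gate by fixing species sequences
#'
#' Returns the same gate with the named species pinned to the given
#' sequences (their designable positions cleared), enabling serial
#' constrained design: fixing the sRNA of a designed gate and
#' redesigning a new 5' UTR yields a coupled YES/NOT device; fixing a
#' designed 5' UTR and designing a second sRNA extends it into an OR
#' gate.
#'
#' @param gate a [GateSpec-class].
#' @param fixed named character vector, species name -> full sequence.
#' @param gateType optional new gate-type label (e.g.
#'   `"coupled_YES_NOT"` or `"OR_extend"`).
#' @return The constrained [GateSpec-class].
#' @examples
#' g <- makeNotGate(utrLen = 30, srnaLen = 20)
#' d <- runDesign(g, optimizerConfig(iterations = 200, rngSeed = 1))
#' constrainGate(g, designSequences(d)["sRNA"], gateType = "coupled_YES_NOT")
#' @export
constrainGate <- function(gate, fixed, gateType = NULL) {
  spNames <- speciesNames(gate)
  for (nm in names(fixed)) {
    if (!nm %in% spNames) {
      stop(.specError(sprintf("unknown species '%s'", nm)))
    }
    i <- match(nm, spNames)
    s <- gate@species[[i]]
    seqStr <- gsub("T", "U", toupper(fixed[[nm]]))
    if (nchar(seqStr) != s@length) {
      stop(.specError(sprintf(
        "fixed sequence for '%s' has %d nt, species requires %d", nm,
        nchar(seqStr), s@length)))
    }
    for (m in s@motifs) {
      at <- m$at
      if (substr(seqStr, at, at + nchar(m$seq) - 1L) != m$seq) {
        stop(.specError(sprintf(
          "fixed sequence for '%s' violates motif %s at position %d", nm,
          m$seq, at)))
      }
    }
    s@fixedSequence <- seqStr
    gate@species[[i]] <- s
  }
  if (!is.null(gateType)) gate@gateType <- gateType
  validateGateSpec(gate)
  gate
}

#' Validate a gate specification
#'
#' Checks that species names are unique; motifs fit inside their
#' species, do not overlap, and use the RNA alphabet; target-structure
#' stems whose two sides are both sequence-determined (by motifs or a
#' fixed sequence) are Watson-Crick compatible; reactions and terms
#' reference existing species; masks lie within their subjects; a mask
#' never demands a position paired and unpaired within the same
#' truth-table entry; and the truth table covers every input
#' combination of the gate's sRNA inputs exactly once.
#'
#' @param gate a [GateSpec-class].
#' @return `TRUE` invisibly; otherwise a spec error is signalled.
#' @export
validateGateSpec <- function(gate) {
  spNames <- speciesNames(gate)
  if (anyDuplicated(spNames)) stop(.specError("duplicate species names"))

  for (s in gate@species) {
    db <- dotBracket(s@targetStructure)
    if (length(db@strandLengths) != 1L) {
      stop(.specError(sprintf("species '%s' target must be single-strand",
                              s@name)))
    }
    # motif placement
    occupied <- rep(FALSE, s@length)
    for (m in s@motifs) {
      if (grepl("[^ACGU]", m$seq)) {
        stop(.specError(sprintf("motif '%s' is not an RNA sequence", m$seq)))
      }
      span <- m$at:(m$at + nchar(m$seq) - 1L)
      if (m$at < 1L || max(span) > s@length) {
        stop(.specError(sprintf(
          "motif '%s' at %d does not fit species '%s' (%d nt)", m$seq, m$at,
          s@name, s@length)))
      }
      if (any(occupied[span])) {
        stop(.specError(sprintf("overlapping motifs in species '%s'", s@name)))
      }
      occupied[span] <- TRUE
    }
    # sequence-determined positions vs target stems
    det <- rep(NA_integer_, s@length)
    if (!is.na(s@fixedSequence)) {
      if (nchar(s@fixedSequence) != s@length) {
        stop(.specError(sprintf("fixed sequence length mismatch for '%s'",
                                s@name)))
      }
      det <- .seqToInt(s@fixedSequence)
    } else {
      for (m in s@motifs) {
        det[m$at:(m$at + nchar(m$seq) - 1L)] <- .seqToInt(m$seq)
      }
    }
    pm <- pairMap(db)
    if (nrow(pm)) {
      for (row in seq_len(nrow(pm))) {
        a <- det[pm[row, 1L]]
        b <- det[pm[row, 2L]]
        if (!is.na(a) && !is.na(b) && !.isWCInt(a, b)) {
          stop(.specError(sprintf(
            "species '%s': target pairs position %d to %d but the fixed bases %s-%s are not complementary",
            s@name, pm[row, 1L], pm[row, 2L], RIBO_BASES[a + 1L],
            RIBO_BASES[b + 1L])))
        }
      }
    }
  }

  for (rx in gate@reactions) {
    if (!all(rx$participants %in% spNames)) {
      stop(.specError("reaction references an unknown species"))
    }
  }

  lens <- vapply(gate@species, function(s) s@length, integer(1))
  names(lens) <- spNames
  maskSeen <- list()  # entry -> position -> state, to catch contradictions
  for (tm in gate@terms) {
    if (tm@kind == "kin") {
      if (!all(tm@participants %in% spNames)) {
        stop(.specError("kin term references an unknown species"))
      }
    } else {
      if (!all(tm@subject %in% spNames)) {
        stop(.specError("str term references an unknown species"))
      }
      total <- sum(lens[tm@subject])
      if (!is.na(tm@target)) {
        if (length(.structSymbols(tm@target)) != total) {
          stop(.specError("str term target length does not match its subject"))
        }
      }
      if (length(tm@maskPos)) {
        if (any(tm@maskPos < 1L | tm@maskPos > total)) {
          stop(.specError("mask positions outside the subject"))
        }
        key <- paste0(tm@entry, "|", paste(tm@subject, collapse = ":"))
        prev <- maskSeen[[key]]
        for (p in tm@maskPos) {
          pk <- as.character(p)
          if (!is.null(prev[[pk]]) && prev[[pk]] != tm@maskState) {
            stop(.specError(sprintf(
              "entry '%s' demands position %d both paired and unpaired",
              tm@entry, p)))
          }
          prev[[pk]] <- tm@maskState
        }
        maskSeen[[key]] <- prev
      }
    }
  }

  # truth table: every combination of sRNA inputs exactly once
  inputs <- spNames[vapply(gate@species, function(s) s@role, character(1)) == "sRNA"]
  if (length(inputs) && length(gate@entries)) {
    keys <- vapply(gate@entries, function(e) {
      paste(sort(intersect(e$inputs, inputs)), collapse = "+")
    }, character(1))
    want <- unlist(lapply(0:length(inputs), function(k) {
      if (k == 0L) return("")
      apply(utils::combn(sort(inputs), k), 2L, paste, collapse = "+")
    }))
    if (anyDuplicated(keys)) {
      stop(.specError("duplicate truth-table entry"))
    }
    missing <- setdiff(want, keys)
    if (length(missing)) {
      stop(.specError(sprintf("missing truth-table entry for input set {%s}",
                              missing[1L])))
    }
  }
  invisible(TRUE)
}
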