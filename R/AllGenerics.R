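# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for riboforge classes
#' @description Slot access goes through these accessors rather than
#'   `@`.
#' @param x the object.
#' @return `residues()` the sequence string; `designable()` the logical
#'   mask; `dbString()` the dot-bracket string; `pairMap()` a two-column
#'   matrix of 1-based pairs (i < j); `freeEnergy()` the energy in
#'   kcal/mol; `foldedStructure()` the [DotBracket-class] of a fold;
#'   `seedAlpha()` the seed length; `gateType()` the gate type string;
#'   `speciesNames()` the species identifiers; `designSequences()` the
#'   designed sequences; `trajectory()` the per-iteration log.
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setMethod("residues", "NucleotideSequence", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("residues", "FoldResult", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("designable", function(x) standardGeneric("designable"))
#' @rdname accessors
#' @export
setMethod("designable", "NucleotideSequence", function(x) x@designable)

#' @rdname accessors
#' @export
setGeneric("dbString", function(x) standardGeneric("dbString"))
#' @rdname accessors
#' @export
setMethod("dbString", "DotBracket", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("dbString", "FoldResult", function(x) x@structure@symbols)

#' @rdname accessors
#' @export
setGeneric("pairMap", function(x) standardGeneric("pairMap"))
#' @rdname accessors
#' @export
setMethod("pairMap", "DotBracket", function(x) {
  i <- which(x@pairMap > seq_along(x@pairMap))
  cbind(i = i, j = x@pairMap[i])
})
#' @rdname accessors
#' @export
setMethod("pairMap", "FoldResult", function(x) pairMap(x@structure))

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "FoldResult", function(x) x@energy)

#' @rdname accessors
#' @export
setGeneric("foldedStructure", function(x) standardGeneric("foldedStructure"))
#' @rdname accessors
#' @export
setMethod("foldedStructure", "FoldResult", function(x) x@structure)

#' @rdname accessors
#' @export
setGeneric("seedAlpha", function(x) standardGeneric("seedAlpha"))
#' @rdname accessors
#' @export
setMethod("seedAlpha", "SeedRegion", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("gateType", function(x) standardGeneric("gateType"))
#' @rdname accessors
#' @export
setMethod("gateType", "GateSpec", function(x) x@gateType)
#' @rdname accessors
#' @export
setMethod("gateType", "DesignResult", function(x) x@gateType)

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setMethod("speciesNames", "GateSpec", function(x) {
  vapply(x@species, function(s) s@name, character(1))
})

#' @rdname accessors
#' @export
setGeneric("designSequences", function(x) standardGeneric("designSequences"))
#' @rdname accessors
#' @export
setMethod("designSequences", "DesignResult", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setMethod("trajectory", "DesignResult", function(x) x@trajectory)

# ---- show methods ----------------------------------------------------

setMethod("show", "NucleotideSequence", function(object) {
  cat(sprintf("NucleotideSequence '%s' (%d nt, %d designable)\n",
              object@name, nchar(object@residues), sum(object@designable)))
  cat(" ", object@residues, "\n")
})

setMethod("show", "DotBracket", function(object) {
  np <- sum(object@pairMap > 0L) / 2L
  cat(sprintf("DotBracket (%d strand%s, %d pair%s)\n",
              length(object@strandLengths),
              if (length(object@strandLengths) > 1L) "s" else "",
              np, if (np != 1) "s" else ""))
  cat(" ", object@symbols, "\n")
})

setMethod("show", "FoldResult", function(object) {
  seqs <- character(length(object@strandLengths))
  off <- 0L
  for (k in seq_along(object@strandLengths)) {
    seqs[k] <- substr(object@sequence, off + 1L, off + object@strandLengths[k])
    off <- off + object@strandLengths[k]
  }
  cat(sprintf("FoldResult [%s]\n", object@modelId))
  cat(" ", paste(seqs, collapse = "&"), "\n")
  cat(sprintf("  %s (%.2f kcal/mol)\n", object@structure@symbols,
              object@energy))
})

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf("EnergyModel '%s' (backend: %s)\n", object@modelId,
              object@backend))
  cat(sprintf("  pair energies: GC %.2f, AU %.2f, GU %.2f kcal/mol\n",
              object@pairEnergies[["GC"]], object@pairEnergies[["AU"]],
              object@pairEnergies[["GU"]]))
  cat(sprintf("  min hairpin %d; GU intra %s, inter %s\n", object@minHairpin,
              object@allowGU, object@allowGUInter))
})

setMethod("show", "ReactionProfile", function(object) {
  cat(sprintf("ReactionProfile (%d states, rHyb = %d, rTrans = %d)\n",
              length(object@r), object@rHyb, object@rTrans))
  print(stats::setNames(round(object@G, 3), paste0("r=", object@r)))
})

setMethod("show", "EnergySummary", function(object) {
  cat(sprintf(
    "EnergySummary: dG = %.2f, dG-activation = %.2f kcal/mol, Z = %.4g (RT = %.2f)\n",
    object@deltaG, object@deltaGActivation, object@Z, object@RT))
})

setMethod("show", "SeedRegion", function(object) {
  if (object@alpha == 0L) {
    cat("SeedRegion: none (alpha = 0)\n")
  } else {
    cat(sprintf("SeedRegion: alpha = %d nt (A: %d, B: %d)\n", object@alpha,
                object@startA, object@startB))
  }
})

setMethod("show", "GateSpec", function(object) {
  cat(sprintf("GateSpec '%s': %d species, %d truth-table entries, %d reactions, %d terms\n",
              object@gateType, length(object@species), length(object@entries),
              length(object@reactions), length(object@terms)))
  for (s in object@species) {
    cat(sprintf("  %s (%s, %d nt%s)\n", s@name, s@role, s@length,
                if (!is.na(s@fixedSequence)) ", fixed" else ""))
  }
})

setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult (%s gate): objective %.2f\n", object@gateType,
              object@objective))
  for (nm in names(object@sequences)) {
    cat(sprintf("  %s: %s\n", nm, object@sequences[[nm]]))
  }
})

setMethod("show", "KineticParameters", function(object) {
  cat(sprintf(
    "KineticParameters: kOn %.3g, kOff %.3g, kHyb %.3g, delta1 %.3g, delta2 %.3g (KM %.3g)\n",
    object@kOn, object@kOff, object@kHyb, object@delta1, object@delta2,
    object@KM))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: slope %.4f, intercept %.4f, R2 %.4f (n = %d)\n",
              object@slope, object@intercept, object@r2, object@n))
})

setMethod("show", "FoldPrediction", function(object) {
  cat(sprintf("FoldPrediction: dGkin %.2f kcal/mol -> fold %.4g (scale %.3g, RT %.2f)\n",
              object@dGkin, object@fold, object@scale, object@RT))
})
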