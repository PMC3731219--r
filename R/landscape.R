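# Reaction-coordinate energy profiles, partition function and the
# formation / activation free energies derived from them.

#' Enumerate the reaction-coordinate energy profile of a pair
#'
#' For two strands, computes the effective free energy `G(r)` at every
#' reaction coordinate `r` (number of intermolecular pairs; `r` = 0 is
#' the pre-association state of individually folded species, `G = 0`
#' being the fully unfolded reference). `G(r)` is the minimum energy
#' over all valid joint structures with exactly `r` intermolecular
#' pairs, obtained exactly by an r-resolved dynamic programme.
#' `rHyb` is the coordinate of the global minimum (the complex MFE) and
#' `rTrans` the barrier, the maximum of `G(r)` on the path
#' `1..rHyb`.
#'
#' @param seqA,seqB sequences ([NucleotideSequence-class] or strings).
#' @param model reference [EnergyModel-class].
#' @param maxTotal combined-length cap for the exact computation
#'   (default 24 nt).
#' @return A [ReactionProfile-class].
#' @examples
#' enumerateProfile("GGGG", "CCCC")
#' @export
enumerateProfile <- function(seqA, seqB, model = referenceEnergyModel(),
                             maxTotal = 24L) {
  if (model@backend != "reference") {
    stop(.capabilityError("enumerateProfile requires the reference model"))
  }
  a <- .asIntSeq(seqA)
  b <- .asIntSeq(seqB)
  if (length(a) + length(b) > maxTotal) {
    stop(.capabilityError(sprintf(
      "combined length %d exceeds the enumeration limit of %d",
      length(a) + length(b), maxTotal)))
  }
  rmax <- min(length(a), length(b))
  G <- cpp_profile(c(a, b), rep(1:2, c(length(a), length(b))),
                   .modelPar(model), rmax)
  r <- 0:rmax
  keep <- is.finite(G)
  r <- r[keep]
  G <- G[keep]
  rHyb <- r[which.min(G)]  # ties resolve to the smallest r
  rTrans <- if (rHyb == 0L) {
    0L
  } else {
    path <- which(r >= 1L & r <= rHyb)
    r[path][which.max(G[path])]
  }
  new("ReactionProfile", r = as.integer(r), G = as.numeric(G),
      rHyb = as.integer(rHyb), rTrans = as.integer(rTrans))
}

#' Partition function over a reaction profile
#'
#' `Z = sum_r exp(-G(r)/RT)`, with `G = 0` for the unfolded reference
#' state so that every Boltzmann term is positive and Z is invariant to
#' the order of states.
#'
#' @param profile a [ReactionProfile-class].
#' @param RT thermal energy, kcal/mol (`> 0`).
#' @return The dimensionless partition function `Z > 0`.
#' @examples
#' p <- enumerateProfile("GGGG", "CCCC")
#' partitionFunction(p, RT = 0.61)
#' @export
partitionFunction <- function(profile, RT = 0.61) {
  if (RT <= 0) stop(.paramError("RT must be > 0"))
  if (!length(profile@G)) stop(.inputError("empty profile"))
  sum(exp(-profile@G / RT))
}

#' Formation and activation free energies from a profile
#'
#' `deltaG = G(rHyb) - G(0)` (free energy of formation) and
#' `deltaGActivation = G(rTrans) - G(0)` (free energy of activation,
#' the barrier on the path to hybridization). The partition function is
#' attached.
#'
#' @param profile a [ReactionProfile-class].
#' @param RT thermal energy, kcal/mol.
#' @return An [EnergySummary-class]; `deltaGActivation >= deltaG`
#'   always.
#' @examples
#' profileEnergies(enumerateProfile("GGGG", "CCCC"))
#' @export
profileEnergies <- function(profile, RT = 0.61) {
  G0 <- profile@G[profile@r == 0L]
  Gh <- profile@G[profile@r == profile@rHyb]
  Gt <- if (profile@rHyb == 0L) G0 else profile@G[profile@r == profile@rTrans]
  new("EnergySummary", deltaG = Gh - G0, deltaGActivation = Gt - G0,
      Z = partitionFunction(profile, RT), RT = RT)
}

#' Formation free energy via the MFE shortcut
#'
#' `deltaG = E(cofold(A, B)) - E(fold(A)) - E(fold(B))`. The production
#' route for scoring reactions; agrees with [profileEnergies()] on
#' every instance where the exhaustive profile is feasible. Applied to
#' a sequence against itself it scores homodimer formation.
#'
#' @param seqA,seqB sequences.
#' @param model an [EnergyModel-class].
#' @return Formation free energy in kcal/mol (`<= 0` for the reference
#'   model, 0 for a non-interacting pair).
#' @examples
#' deltaGMFE("GGGG", "CCCC")   # -12
#' @export
deltaGMFE <- function(seqA, seqB, model = referenceEnergyModel()) {
  cofoldMFE(list(seqA, seqB), model)@energy -
    foldMFE(seqA, model)@energy - foldMFE(seqB, model)@energy
}

#' Export a reaction profile as tab-separated text
#'
#' @param profile a [ReactionProfile-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  df <- data.frame(r = profile@r, G = profile@G)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
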