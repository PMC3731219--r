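# Toy gates used across tests: small enough for exhaustive search.

# One-species inverse-folding problem: an 11-nt hairpin target.
toyFoldGate <- function() {
  gateSpec("YES",
    species = list(speciesSpec("hp", "mRNA_5UTR", 11L, "((((...))))")),
    entries = list(),
    reactions = list(),
    terms = list(strTerm("hp", target = "((((...))))")))
}

# YES gate with a fixed cis-repressed 12-nt mRNA (stem 2-5 : 9-12
# sequesters the 4-nt RBS at 9-12) and a fully designable 8-nt sRNA:
# exactly 8 designable nucleotides, 4^8 assignments.
toyYesGate <- function() {
  gateSpec("YES",
    species = list(
      speciesSpec("sRNA", "sRNA", 8L),
      speciesSpec("mRNA", "mRNA_5UTR", 12L, ".((((...))))",
                  fixedSequence = "ACUCCAAAGGAG")),
    entries = list(
      list(inputs = character(0), requiredOutput = "RBS_blocked"),
      list(inputs = "sRNA", requiredOutput = "RBS_accessible")),
    reactions = list(list(participants = c("sRNA", "mRNA"), sense = "occur")),
    terms = list(
      strTerm("mRNA", maskPositions = 9:12, maskState = "paired",
              entry = "0"),
      kinTerm(c("sRNA", "mRNA"), "occur", entry = "1"),
      strTerm(c("sRNA", "mRNA"), maskPositions = 8L + 9:12,
              maskState = "unpaired", entry = "1")))
}

# exhaustive minimum of the toy YES gate over all legal 8-nt sRNAs
toyYesExhaustiveMin <- function(gate = toyYesGate(),
                                cfg = objectiveConfig(),
                                model = referenceEnergyModel()) {
  plan <- riboforge:::.compileGate(gate, cfg)
  mRNA <- riboforge:::.seqToInt("ACUCCAAAGGAG")
  best <- Inf
  for (code in 0:(4^8 - 1)) {
    v <- integer(8)
    c0 <- code
    for (p in 1:8) {
      v[p] <- c0 %% 4L
      c0 <- c0 %/% 4L
    }
    if (riboforge:::.hasIllegalRun(v, NULL, 4L)) next
    sc <- riboforge:::.scoreCandidate(list(sRNA = v, mRNA = mRNA), plan, cfg,
                                      model, -7.5, detail = FALSE)
    if (sc$total < best) best <- sc$total
  }
  best
}
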