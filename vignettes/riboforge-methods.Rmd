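---
title: "Designing multi-state sRNA logic devices with riboforge"
author: "riboforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-state sRNA logic devices with riboforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboforge)
```

## The design problem

Small regulatory RNAs (sRNAs) control bacterial gene expression by
base-pairing with the 5' untranslated region (UTR) of a target mRNA.
Whether the ribosome binding site (RBS, here the Shine-Dalgarno
sequence `AGGAGA` placed 8 nt upstream of the start codon) is paired or
accessible decides whether translation proceeds, so conformational
switching of the 5' UTR implements logic: an sRNA that blocks the RBS
is a NOT gate, one that releases a cis-repressed RBS is a YES gate,
sRNA-triggered cis-repression and terminator disruption
(anti-termination) give further NOT/YES mechanisms, and two sRNAs that
must dimerize before they can open the RBS give an AND gate.

riboforge solves the *inverse* problem: given a gate's truth table,
the target secondary structures of all species and the fixed sequence
motifs, find sequences that realize the device. Each truth-table entry
is translated into objective terms, and simulated annealing searches
sequence space for a minimum.

## The objective

Every candidate is scored as a weighted sum of two kinds of terms,
both in kcal/mol (lower is better).

**Kinetic terms.** Association of two RNAs nucleates at the *seed*
(the first contiguous stretch of intermolecular Watson-Crick pairs,
length $\alpha$); the stability of the final complex is the formation
free energy $\Delta G$ (complex MFE minus the individual MFEs, the
individual folds being formed long before the much slower
hybridization). The kinetic objective of a reaction is

$$\Delta G_{kin} = \max(\Delta G, \Delta G_{sat}) +
  \min(\alpha, \alpha_{sat})\, G_p ,$$

with $G_p = -1.28$ kcal/mol (the average energetic contribution of one
paired nucleotide), and saturation levels $\Delta G_{sat} = -15$
kcal/mol and $\alpha_{sat} = 6$ nt beyond which further minimization
earns no credit. The floor implied by these constants is
$-15 + 6 \times (-1.28) = -22.68$ kcal/mol. Reactions that must occur
contribute $\Delta G_{kin}$; reactions that must *not* occur contribute
$\max(-\Delta G_{kin}, 0)$. The clip at zero is a design choice: an
unbounded reward for non-interaction would dominate the weighted sum,
and a pair that already fails to interact deserves no further credit.
All thermal quantities use $RT = 0.61$ kcal/mol (37 °C).

**Structural terms.** The structural objective is a Hamming distance
$d$ between the observed and target dot-bracket structures, rescaled
to energy units: $\Delta G_{str} = -G_p\, d \ge 0$. A full target is
compared literally; a *mask* restricts the comparison to constrained
positions (e.g. "the six RBS positions must be paired in the
complex"), where a position demanding "paired" accepts either bracket
— blocking requires pairedness, not a particular partner.

Candidates whose sRNAs self-anneal strongly (self-cofold formation
energy below −7.5 kcal/mol, half the saturation level) are excluded
outright with an infinite objective: a homodimer-forming sRNA would
titrate itself away from its target. The exclusion is applied to
sRNA-role species; structured 5' UTRs are exempt because any
cis-repressing stem trivially self-anneals in a two-copy cofold, which
would rule out every YES-type device by construction rather than by
merit.

## The folding engine

All scoring rests on secondary-structure prediction. The built-in
*reference model* is deliberately minimal: purely additive per-pair
energies (GC = −3, AU = −2, GU = −1 kcal/mol; no stacking or loop
terms), pseudoknot-free nested pairing, a minimum hairpin loop of 3
unpaired positions for intramolecular pairs (intermolecular pairs are
exempt), GU wobble allowed within strands but not between them (the
reaction coordinate counts Watson-Crick intermolecular pairs).
Complexes of up to three strands are folded as concatenations with
nested-only pairing across strands — some three-strand topologies are
therefore out of reach, a known simplification.

The point of this model is verifiability: every MFE prediction, every
reaction-coordinate profile and every pairing probability can be
checked against exhaustive enumeration of all structures at toy sizes,
and the test suite does exactly that. Tie-breaking in the traceback
prefers the structure whose leftmost differing position is unpaired,
making predictions bit-reproducible. An adapter
(`viennaEnergyModel()`) delegates fold/cofold to an external
nearest-neighbor engine (`RNAfold`/`RNAcofold`) for realistic
energies; landscapes and pairing probabilities remain reference-model
capabilities.

The *landscape* module exposes the thermodynamic backbone: the
effective free energy $G(r)$ along the reaction coordinate $r$ (number
of intermolecular pairs, $r = 0$ the pre-association state, $G = 0$
the unfolded reference), computed exactly by an $r$-resolved dynamic
programme (default cap 24 nt combined, which keeps exhaustive
cross-checks under a minute); the partition function
$Z = \sum_r e^{-G(r)/RT}$; the formation energy
$\Delta G = G(r_{hyb}) - G(0)$ at the profile minimum; and the
activation energy $\Delta G^\ddagger = G(r_{trans}) - G(0)$, where the
transition coordinate is taken as the maximum of $G(r)$ on the path
$1..r_{hyb}$ — a barrier convention consistent with transition-state
theory. The production scorer uses the MFE shortcut
$\Delta G = E(\mathrm{cofold}) - E(\mathrm{fold}_A) -
E(\mathrm{fold}_B)$, which provably agrees with the profile; the
$\alpha G_p$ term of $\Delta G_{kin}$ stands in for the barrier, so the
transition-state convention only affects reported landscapes, not
optimization. $Z$ is reported for inspection but is not an objective
term.

## The optimizer

Design runs are Monte Carlo simulated annealing over sequence space:

* **Initialization** draws random sequences satisfying all hard
  constraints: motif positions (SD, start codon, poly(U) tails) take
  their fixed bases, stem partners in each species' target structure
  are sampled as complementary pairs, and loops are free. If the
  subsequence constraints contradict the structures (e.g. a target
  stem between two non-complementary motif bases), validation stops
  the run before it starts.
* **Moves** are either point replacements or the *directed* move: a
  word of consecutive nucleotides is copied from one species,
  reverse-complemented, and written over designable positions of
  another, planting a guaranteed complementary patch between the two.
  The word length follows a 3 → 2 → 1 schedule over thirds of the run.
  When a mutated nucleotide belongs to a target-structure stem, its
  partner is co-mutated to the Watson-Crick complement. Insertions and
  deletions are never made — lengths are constant. Proposals touching
  fixed positions or creating runs of ≥ 4 identical nucleotides
  (outside fixed motifs — a fixed poly(U) tail is legal) are resampled.
* **Acceptance** is the Metropolis rule, accept if
  $\Delta F \le 0$, else with probability $e^{-\Delta F/T}$, under a
  geometric temperature schedule. The defaults $T_0 = 5$ to
  $T_{end} = 0.05$ (objective units) bracket the typical size of
  single-move objective changes (one base pair is 1–3 kcal/mol):
  early moves that lose a few pairs are routinely accepted, late ones
  essentially never. No cooling schedule is prescribed by the
  mechanism itself; the geometric form was chosen once for simplicity.
* An optional **harmonic relaxation** adds
  $k\, d^2$ per species ($d$ the distance of its fold to its target),
  letting runs tolerate dissimilar intermediate structures when the
  hard per-species terms would otherwise dominate.

All randomness flows from a single seed; trajectories are replayable
and the best-seen candidate is returned with a per-term breakdown.
Full-length devices in the literature of this method use $10^6$–$10^7$
iterations with nearest-neighbor energies; the reduced problems in
this package converge orders of magnitude faster (the end-to-end NOT
gate here uses $5 \times 10^4$ iterations, the 8-nt toy gate $10^4$ —
sizes chosen so the whole suite verifies in minutes while still
exercising every mechanism).

A design is reported as satisfying its structural targets when its
Hamming distance is at most 6 symbols (3 base pairs) from them —
final structures are allowed to vary up to three base pairs.

## Gate builders

`makeNotGate()`, `makeYesGate()` (with `NOT_cis` and `YES_antiterm`
variants) and `makeAndGate()` compile the canonical mechanisms into
`GateSpec` objects; `gateSpec()`/`kinTerm()`/`strTerm()` build custom
devices. Conventions baked into the builders:

* SD-to-AUG spacing is 8 nt (the typical placement of the SD about
  eight base pairs upstream of the start codon).
* The default cis-repressing 5' UTR target pairs the SD against an
  upstream anti-SD hexamer across a 4-nt loop.
* The anti-termination UTR encodes a 6-bp terminator stem with a fixed
  `UUUUUU` tail; "disrupted" in reports means ≥ 80 % of stem positions
  unpaired in the complex (the mechanism itself carries no printed
  numeric criterion; the objective simply minimizes stem pairedness in
  the complex).
* Per-species inverse-folding terms are emitted only for species whose
  target actually contains pairs; an unstructured target is already
  covered by the entry masks.
* `constrainGate()` pins named species to fixed sequences (after
  checking motifs and stem complementarity), enabling serial design:
  fix a designed sRNA and redesign the UTR for a coupled YES/NOT
  device, or fix a designed UTR and add a second sRNA for an OR gate.
  Cross-talk between the two sRNAs of an OR device is *reported* by
  `evaluateDesigns()` but not added as an objective term by default,
  matching the serial-design workflow.

## Kinetics and the exponential fold-change model

The mass-action scheme behind the kinetic objective is
$A + B \rightleftharpoons [A{:}B]^\ddagger \rightarrow A{:}B$ with
rates $k_{on}, k_{off}, k_{hyb}$, degradation $\delta_1$ of the free
species and $\delta_2$ of the final complex ($\delta_2$ is applied to
the final complex by default; the intermediate is transient on the
binding timescale). When $k_{off} + k_{hyb} \gg \delta_1$ the
intermediate settles at $[A{:}B]^\ddagger = AB/K_M$ with
$K_M = (k_{off}+k_{hyb})/k_{on}$, and the complex accumulates at rate
$k_{hyb} AB / K_M$ — `simulateKinetics()` (adaptive stiff-capable
integration, relative tolerance $10^{-8}$) and `qssaIntermediate()`
verify this numerically, with a validity flag when the ratio drops
below 10. Writing $k_{on} \propto e^{-\alpha G_p/RT}$ and
$k_{hyb} \propto e^{-\Delta G/RT}$ makes steady-state output
proportional to $e^{-\Delta G_{kin}/RT}$; only the ratio between two
devices is meaningful, so the prefactor is a free scale parameter in
`predictedFold()`.

## Synthetic validation fixtures

The validation module emulates a mutant-library experiment: a
randomized trinucleotide in the seed of a base design
(`generateLibrary()`, default 11 mutants, the usual clone count of such
a screen), each variant scored for $\Delta G$, $\alpha$ and
$\Delta G_{kin}$, and a synthetic "measured" fold change drawn from
$\log f = a + b\,\Delta G_{kin} + \mathcal N(0, \sigma)$. The default
generative slope is the Boltzmann-consistent $b = -1/RT$; the default
noise $\sigma = 0.2$ on the natural-log scale (≈ 20 % multiplicative
error) is typical of fluorometric fold-change measurements. The base
pair was built so the library is informative: a purine-rich UTR that
cannot fold on itself, with the pyrimidine anti-SD hexamer as sRNA,
puts the base interaction at the saturation boundary so seed mutations
spread $\Delta G_{kin}$ over several kcal/mol. `fitLogLinear()`
recovers the slope by OLS of $\log f$ on $\Delta G_{kin}$.

What this does and does not show: the fixtures validate the
*methodology* — that the scoring pipeline plus log-linear regression
recovers a known exponential free-energy law from sequence-level
perturbations. They are generated under the package's own energy
model, so passing tests say nothing about nearest-neighbor accuracy on
real mutant libraries, whose sequences are not bundled here.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based inclusive in
  every report and file format; energies print with 2 decimals.
* Folding ties resolve to "leftmost position unpaired"; seed ties to
  the smallest start in the first partner; profile ties to the
  smallest reaction coordinate.
* `pairProbabilities()` rescales its partition sums by a per-position
  energy shift (exact algebra) so small-RT Boltzmann limits stay in
  double range; extremely small RT can still underflow, in which case
  a larger RT is the remedy.
* Empty FASTA files read as empty lists; a structure with no pairs has
  energy 0; a single-state landscape has
  $\Delta G = \Delta G^\ddagger = 0$; libraries whose mutants all fail
  to interact warn as degenerate; fitting requires ≥ 3 records with
  variation in $\Delta G_{kin}$.

## Known limitations

Pseudoknots, non-canonical pairs, suboptimal-ensemble effects,
temperature dependence beyond fixed $RT$, RNA chaperones (Hfq) and
divalent-ion effects are out of scope. The reference energy model is a
teaching-grade additive model — realistic design work should use the
external-engine adapter. Three-strand complexes are folded as nested
concatenations, which misses some genuine topologies of sRNA-dimer
devices.

## A worked session

```{r example, eval = FALSE}
gate <- makeNotGate(utrLen = 30, srnaLen = 20)
res <- runDesign(gate, optimizerConfig(iterations = 50000, rngSeed = 1))
res
evaluateDesigns(list(res), gate)[[1]]$masks
```
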