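---
title: "Models and methods behind goldenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind goldenr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldenr)
```

goldenr models a six-module Golden Gate expression-vector system for
budding yeast: the overhang grammar that orders the modules, the
thermodynamics and quality battery behind tailed-primer design, silent
removal of internal BsaI sites, one-pot digestion/ligation assembly, and a
combinatorial model of single-copy chromosomal integration with inverted
homology arms. This vignette explains each model, its assumptions and
parameters, and the design decisions taken where more than one reasonable
convention exists.

## The type IIS overhang model

BsaI recognises `GGTCTC`, skips one spacer nucleotide and cuts the top
strand there, and cuts the bottom strand four nucleotides further along.
That geometry yields 4-nt **5' extensions**. (Descriptions of such systems
occasionally call these "3' overhangs"; the modelled cut geometry forces 5'
extensions, and we follow that consistently. Nothing downstream depends on
the label: assembly logic only needs each end's 4-mer.)

Every fragment end is represented by its overhang 4-mer written on the top
strand **in product orientation**, and two ends ligate iff their
representations are equal. This collapses the double-stranded annealing
rule (single strands pair antiparallel) into string equality, which is what
makes the ligation graph analysis simple: for the seven junctions of a
standard assembly (`ATCC, TATG, GAAC, CGCA, CAGG, AGCA, CCAT`) the 4-mers
are pairwise distinct and none equals its own reverse complement, so the
graph admits exactly one circular path and `assemble()` can assert
uniqueness rather than assume it.

Fragments record each terminal 4-mer exactly once; ligation therefore joins
`A$bases` to `B$bases` minus B's first four bases, and a circular product of
k fragments has length `sum(fragment lengths) - 4k`. Digestion keeps every
recognition site on the fragment that carries it (outside-cutting), which is
why correct products are refractory to re-digestion and why `assemble()`
discards any fragment still carrying a site before enumerating products —
in the pot, such fragments are re-cut whenever they religate.

The destination vector's own junction overhangs (`ATCC` on the module-1
side, `CCAT` on the module-6 side) are forced by compatibility with the
position-1 forward overhang and the reverse complement of the position-6
reverse overhang; no other choice closes the circle.

Degenerate inputs are first-class: a circular molecule with no site returns
itself with a `no_cut` flag; missing positions raise an incomplete-path
error naming the gap; duplicated positions produce several distinct circular
products and an ambiguity error; a corrupted overhang yields a no-closure
error. Product rotation is normalised to start at the destination-vector
backbone's first base so output is reproducible.

## Nearest-neighbor thermodynamics

Duplex stability is the sum of unified nearest-neighbor dinucleotide terms
plus initiation terms per terminal base pair (and a symmetry term for
self-complementary oligos); the parameter tables ship as plain-text TSVs
under `inst/extdata/` with their literature citations in the header.
Single internal mismatches use the published mismatch series; stacks are
looked up with the strand-symmetry rule `XY/ZW = WZ/YX`.

The melting temperature is the two-state formula

$$T_m = \frac{1000\,\Delta H}{\Delta S_{salt} + R \ln(C_T/x)} - 273.15$$

with `x = 4` for non-self-complementary primers (each strand at half the
total concentration) and `x = 1` for self-complementary ones. Salt enters
through the entropy correction
`dS_salt = dS + 0.368 (N-1) ln[Na_eq]`, where the effective monovalent
concentration `Na_eq = mono + 120 * sqrt(max(div - dNTP, 0))` (mM) accounts
for divalent cations after dNTP chelation. Default reaction conditions are
ordinary PCR: 50 mM monovalent, 1.5 mM Mg²⁺, 0.2 mM dNTPs, 500 nM primer —
all settable via `reaction_conditions()`.

Restrictions, stated rather than hidden: duplexes must be ≥ 8 nt, carry at
most 3 mismatches, and mismatches must be internal and isolated (terminal
or adjacent mismatches are rejected — the published single-mismatch
parameters do not cover them). `N` is allowed in stored sequences but
rejected by `translate_dna()` and all thermodynamic operations.

Annealing recommendations: the Q5-style profile is
`min(pair Tm) + 1 °C capped at 72 °C` — a documented heuristic, since no
closed formula exists for it — and the Taq profile is exactly 7 °C lower.
The 7 °C offset is a fixed property of the output, tested as such.

The test suite checks the whole Tm path against an independent
parameter-sum oracle (its own copy of the published constants, its own
formula) on 100 random 18–25-mers at 0.5 °C tolerance, plus salt
monotonicity and mismatch destabilisation properties.

## Tailed primers and the quality battery

A tailed primer is `MCS tail (25 nt) + GGTCTC + spacer + overhang + core`,
with the spacer `G` on forward and `T` on reverse sites, reproducing the
published cassette layout literally. The shipped 25-nt MCS tails are
pUC57-polylinker-style defaults; the real tails of any given project are
configuration (`position_tail_spec()`), because their exact identity is a
property of the cloning vector, not of the method. Reverse cores are given
5'→3' on the bottom strand, the universal primer convention.

Core design enumerates all forward/reverse core lengths in the design range
(18–25 nt by default, within the hard 15–25 bound) anchored at the target
span's ends — 64 candidate pairs — and minimises a weighted penalty:
distance of Tm/length/GC% from their optima (60 °C, 20 nt, 50%), excesses
of the dimer scores over their thresholds, and the pair ΔTm. Exhaustive
enumeration is deliberate: desk-scale templates make it cheap, and it turns
"the returned pair is optimal" into a testable brute-force property rather
than a hope. Ties break toward shorter cores, making the search
deterministic. Template (mispriming) metrics are computed in the QC report
but not inside the design loop, where they would dominate the runtime
without changing the anchored-candidate ranking materially.

All complementarity metrics use one convention: the best ungapped
antiparallel alignment scored +1 per complementary pair and −1 per
mismatch, floored at 0 (`complementarity_score()`); 3' variants restrict
the query to the terminal 5 nt; template variants mask the primer's
intended footprint. The QC report always contains exactly the thirteen
published metrics in their published order.

Which metrics are *hard* (fail) versus *soft* (warn) is a design decision:
hard are core length, the two 3'-anchored dimer metrics, and cores that
cannot be located on the template; everything else warns. The reasoning is
chemical: a complementary 3' terminus primes extension artefacts, whereas
central dimers mainly lower effective concentration — and the 25-bp MCS
tails are palindrome-rich by construction (they are restriction-site
clusters), so whole-molecule dimer scores are structurally inflated for
*every* tailed primer and cannot sensibly be fatal.

## Domestication

Internal BsaI sites in a coding module are removed codon by codon: for each
site, all synonymous replacements of every codon the 6-mer overlaps are
enumerated; candidates must destroy the site without creating a new one;
the winner has the fewest nucleotide changes, ties broken by the highest
S. cerevisiae codon preference (the CAI relative-adaptiveness table from
seqinr), then alphabetically. Several escapes usually exist and all are
correct; the tie-break only fixes which one the tool picks
deterministically. The invariant that matters — and is tested — is that
translation is unchanged and residual sites are zero whenever an exhaustive
enumeration oracle confirms an escape exists. Noncoding modules cannot be
edited silently, so the plan lists the sites with strategy
`fusion_pcr_suggested`; a coding site with no synonymous escape yields
`impossible` with a positive residual count. A CDS whose translation
contains internal stops triggers a warning, not a failure.

## Single-copy integration

The integration module is `arm3 + AscI + FseI + arm5`: the locus's halves
in reverse order, *reordered but not reverse-complemented*. Both readings
of "placed in reverse order" occur in the wild; reordering without
reverse-complementing is the one under which the linearized plasmid's
terminal homology segments are genome-collinear, which is what the
recombination geometry requires, so that is what is implemented (and tested
via substring orientation checks). Linearization uses AscI unless AscI
occurs in the arms (then FseI); both rare sites in the arms is a design
failure.

Recombination is modelled as an exact double crossover at the arm
sequences: no mismatch tolerance, no gene-conversion tracts, no efficiency
model. That is sufficient because the single-copy argument is purely
combinatorial: with inverted arms the integrated state still contains
exactly one copy of each arm (mode `replacement`), so a further integration
can only swap the payload; with a conventional marker-cut design the
homology region is duplicated (mode `duplication`), licensing further
tandem integrations. `simulate_integration()` classifies the mode from
pre/post substring counts rather than asserting it, so the model checks
itself on every call. Real integration frequencies are empirical
measurements and are out of scope.

Arm defaults: split at the locus midpoint, minimum arm length 50 nt (the
151-bp example loci imply ~75-bp arms); both configurable. Locus selection
criteria default to the published thresholds — ≥ 1000 bp ORF-free,
≥ 200 bp free of binding sites and ncRNA — plus a ≥ 20 kb
telomere/centromere distance, which is *not* a published value and is
flagged as this package's default.

## The synthetic library generator

`build_library(seed)` emulates the published 28-plasmid collection
structurally: 26 modules with the published ids, positions, type labels and
resistances (plus the stop-codon footnote for the position-3 fusion
modules), a destination vector with exactly two BsaI sites flanking a LacZ
stuffer and an SV40 polyA on the backbone, and a module cloning vector with
none. Insert sequences are seeded random placeholders with
domain-plausible shapes: promoters 400–800 nt, reporter ORFs ~720 nt
in-frame with start (and stop only where the role requires), a ~540 nt
degron ORF, a 30 nt stop linker, a 250 nt terminator, marker ORFs
750–1200 nt, and integration modules built from synthetic 151-bp loci
embedded in 3-kb toy chromosome segments. Backbones are ~2.5 kb. All
generated sequence excludes BsaI on both strands and the two rare 8-cutters
(AscI/FseI are rare in real DNA by design — that is why the system uses
them — so excluding them keeps the linearization site of an assembled
integration vector unique for every seed); plasmids are additionally
validated to carry exactly the intended site count, resampling the variable
parts otherwise, so the invariants hold for any seed, not just lucky ones.

What the generator does **not** emulate: real promoter/ORF composition
biases, repeats, secondary structure, or the actual published module
sequences (the loader accepts user-supplied real sequences keyed by id, so
a real collection drops in without code changes). Passing tests therefore
demonstrate the correctness of the grammar, the algorithms and the
bookkeeping — not sequence-level properties of any real plasmid.

## Problem sizes and runtime choices

The suite exercises: 100 sampled module combinations assembled end-to-end
(of 2800 possible), 100 random oligos against the thermodynamic oracle, 50
random CDS fixtures with 1–3 seeded BsaI sites for domestication, and toy
genomes of a few hundred bp to a few kb for integration. These sizes are
the package's own choice of a thorough-but-quick default; every generator
is seeded and parameterised, so heavier runs are one argument away.

## Known limitations

- Ligation is exact-match on 4-nt overhangs; Golden Gate fidelity
  (mismatched-overhang ligation rates) is not modelled.
- Thermodynamics covers single isolated internal mismatches only — no
  dangling ends, loops, or secondary-structure partition functions.
- Domestication edits one codon per site; sites resistant to all
  single-codon synonymous changes are reported, not solved.
- The GenBank writer/reader handles simple `start..end` /
  `complement(start..end)` locations, which is all the package emits;
  compound joins are rejected with a parse error.
- Methylation-dependent behaviour (e.g. template destruction by DpnI) is a
  wet-lab step and is not simulated.
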