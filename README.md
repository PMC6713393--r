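# goldenr

Design and in-silico validation tools for a one-pot Golden Gate cloning
system that builds yeast expression vectors from six position-committed
functional modules: (1) plasmid type / replication mode, (2) promoter,
(3) coding sequence, (4) fusion partner or stop, (5) terminator,
(6) selection marker.

It is written for yeast molecular biologists who use a modular BsaI-based
toolbox and want to design new modules, check primers, and verify an
assembly on the computer before touching a pipette — and for anyone who
wants to simulate type IIS overhang grammars.

## What it implements

**Overhang grammar.** BsaI (recognition `GGTCTC`, 1-nt spacer) cuts outside
its site and leaves programmable 4-nt 5' overhangs. Each cloning position
uses a fixed forward/reverse overhang pair, chained so that
`revcomp(fwd(i+1)) = rev(i)`:

| position | forward | reverse |
|---|---|---|
| 1 | ATCC | CATA |
| 2 | TATG | GTTC |
| 3 | GAAC | TGCG |
| 4 | CGCA | CCTG |
| 5 | CAGG | TGCT |
| 6 | AGCA | ATGG |

Together with the destination-vector junctions (ATCC, CCAT) the seven
fusion sites are pairwise distinct and none is self-complementary, so the
ligation graph has exactly one circular path — one product, in one pot.

**Primer design.** Tailed primers are
`25-bp MCS tail + GGTCTC + spacer (G/T) + overhang + 15–25-nt core`.
Core selection is exhaustive over the allowed lengths and minimises a
weighted penalty over a thirteen-metric battery (Tm, length, self/3'/
template/cross complementarity, GC%, GC clamp, 3' stability, 3' GC%, pair
ΔTm). Melting temperatures use unified nearest-neighbor thermodynamics
(`Tm = 1000·ΔH / (ΔS_salt + R·ln(C_T/4)) − 273.15`) with a divalent-aware
salt correction and published single-mismatch parameters; the Taq annealing
recommendation is exactly 7 °C below the Q5 one.

**Domestication.** Internal BsaI sites in coding modules are removed by
synonymous single-codon substitutions (fewest changes, then highest yeast
codon preference); noncoding modules get a fusion-PCR suggestion instead.

**Assembly simulation.** `digest()` + `assemble()` model simultaneous
digestion/ligation with exact 4-nt overhang matching, enumerate every
formable circular product, and report junctions, module order, stuffer
loss and residual sites. `dilution_fmol()`/`dilution_ng()` implement the
protocol's `fmol/µl = ng/µl × 1520 / size_bp` conversion.

**Single-copy integration.** `design_integration_module()` places a locus's
two halves in reverse order (3' arm before 5' arm) around AscI + FseI sites;
after linearization between the arms, homologous recombination *replaces*
the target rather than duplicating it, so the arm copy number is conserved
and re-integration can only swap the payload. `simulate_integration()`
demonstrates both this and the copy-duplicating behaviour of conventional
marker-cut integration.

## Worked example

```r
library(goldenr)

lib <- build_library(seed = 42)    # synthetic 28-plasmid collection
lib
#> <module library> 28 records (26 modules + pDV + pUC57), seed 42
#> modules per position: 5 7 4 4 1 5
count_combinations(lib)
#> [1] 2800

res <- assemble_combination(lib, c("pMV13", "pMV1", "pMV3", "pMV5", "pMV6", "pMV10"))
res
#> <assembly> pDV_assembly: 6123 bp circular, 6 modules, 0 BsaI site(s)
#> junctions: ATCC TATG GAAC CGCA CAGG AGCA CCAT
```

The junction list reads around the product: destination-vector backbone →
module 1 (ATCC), module 1 → module 2 (TATG), …, module 6 → backbone (CCAT).
Zero BsaI sites means the product is refractory to re-digestion — the mark
of a correct Golden Gate assembly.

```r
set.seed(42)
target <- nuc_seq(paste(sample(c("A","C","G","T"), 450, TRUE), collapse = ""),
                  name = "myPromoter")
design_module_primers(target, position = 2)
#> Module primer design, position 2: warn
#> <tailed primer> position 2 forward (57 nt)
#>   GAATTCGAGCTCGGTACCTCGCGAA | GGTCTC | G | TATG | AAAACTCCATGTGTAACTCCG
#> <tailed primer> position 2 reverse (54 nt)
#>   AAGCTTGCATGCAGGCCTCTGCAGT | GGTCTC | T | GTTC | ACCGGTCATCTCAGGGGT
#> core Tm: fwd 60.0 C, rev 64.0 C; annealing Q5 61.0 / Taq 54.0 C
#> domestication: silent_substitution (0 edit(s), 0 residual site(s)); QC: warn
```

Primer segments are kept separately (`tidy()` the QC report for the full
thirteen-metric table); `warn` flags soft-threshold excursions such as a
pair ΔTm above 3 °C while hard failures (dimerising 3' ends, out-of-range
cores) are reported as `fail`.

```r
dilution_ng(40, 3800)   # ng/µl needed to reach the 40 fmol/µl working stock
#> [1] 100
```

A command-line wrapper over the same functions ships at
`inst/cli/goldenr` (subcommands `design-primers`, `domesticate`,
`assemble`, `design-integration`, `simulate-integration`, `library`).

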