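# crisparray

Design and in-silico validation of multi-spacer CRISPR arrays assembled in
one pot through junctions placed in the trimmed ends of spacers.

## The problem

CRISPR arrays — alternating ~36-nt repeats and target-derived spacers,
transcribed as one precursor RNA — are the natural multiplexing format for
Cas9, Cas12a and Cas13a, but their recurring repeats make them hard to
build: identical repeat ends cannot direct an ordered ligation. The scheme
this package implements exploits crRNA biogenesis itself: Cas12a/Cas13a trim
the spacer 3' end (a 30-nt transcribed spacer region matures to a ~23-nt
guide, of which only the first 20 nt hybridize with the target), and Cas9
trims ~10 nt from the spacer 5' end. A 4-nt assembly junction placed in that
trimmed, non-hybridizing region gives every repeat-spacer unit a unique
programmable overhang without touching either the repeat or the targeting
guide. Each unit is just two annealed 66-nt oligos (4-nt junction + 36-nt
repeat + 26-nt spacer); a one-pot Type IIS digestion–ligation cycle then
assembles any number of units into a backbone whose GFP dropout leaves with
the recognition sites, so only the intended, re-digestion-proof array
survives.

`crisparray` turns that scheme into software for molecular biologists
building multiplexed CRISPR constructs:

* **junctions** — validation and proposal of orthogonal overhang sets
  (no palindromes, pairwise Hamming distance ≥ 2 directly and against
  reverse complements);
* **array design** — repeat-spacer units, annealing-oligo sheets, composite
  (multi-nuclease) arrays, combinatorial libraries (3 positions × 5 variants
  = 125 arrays from 30 oligos), and the one-pot protocol sheet (400 fmol per
  insert, 20 fmol backbone, 25 or 35 digestion/ligation cycles);
* **assembly simulation** — Type IIS digestion with exact cut geometry,
  enumeration of every circular ligation product, and fixed-point
  digestion/ligation semantics that identify misassemblies;
* **crRNA biogenesis** — repeat finding, cleavage and trimming to mature
  guides, classification of terminal repeats, and prediction of the
  extraneous crRNA that a consensus-like terminal repeat liberates from
  downstream sequence;
* **structure screening** — a self-contained maximum-pairing folding engine
  (Nussinov-style dynamic program with G·U wobble plus an exact
  inside–outside Boltzmann ensemble) that flags crRNAs whose repeat hairpin
  is disrupted by global array structure, and proposes destabilizing
  mutations;
* **library quantification** — amplicon read simulation, exact-match read
  assignment, and abundance-uniformity statistics (relative abundance
  normalized to mean 1, fold range, per-position variant marginals).

Built-in nuclease profiles ship with clearly labelled synthetic placeholder
repeats; real applications should substitute the genuine repeat of their
nuclease via `nuclease_profile()` or a JSON run configuration.

## Worked example

```r
library(crisparray)

profile  <- builtin_profile("FnCas12a")
backbone <- make_backbone(profile)             # circular, GFP-dropout, BsmBI
design   <- plan_array(clean_trio(), profile, backbone,
                       junctions = fixture_junctions())
design
#> <array_design: 3 unit(s), 3 spacer(s), 4 junctions, construct 421 bp>
#> <unit 1 FnCas12a: J CCCT | spacer AAAACAAAAAAACAAAAAAAACAAAA | J CCAA>
#> <unit 2 FnCas12a: J CCAA | spacer AAAAAAACAAAAAAAACAAAAAAACA | J GGTA>
#> <unit 3 FnCas12a: J GGTA | spacer AACAAAAAACAAAAAAAACAAAAAAA | J GCTG>
#>   junctions: CCCT CCAA GGTA GCTG

make_oligos(design$units[[1]])
#> <oligo_pair: top 66 nt, bottom 66 nt, duplex 62 bp>

simulate_golden_gate(design)
#> Golden-Gate simulation (BsmBI): 2 circular product(s), 1 survivor(s)
#>   intended design unique survivor: TRUE
#>   dropout absent from survivors: TRUE

crs <- process_transcript(design_transcript(design), profile, n_spacers = 3)
crs
#> <crrna_set: 4 crRNA(s)>
#> <crRNA internal: 42 nt (handle 19 + guide 23) [21, 63)>
#> <crRNA internal: 42 nt (handle 19 + guide 23) [87, 129)>
#> <crRNA internal: 42 nt (handle 19 + guide 23) [153, 195)>
#> <crRNA terminal_extraneous: 42 nt (handle 19 + guide 23) [219, 261)>
```

Three spacers give three internal crRNAs with 23-nt guides (30-nt
transcribed spacer regions trimmed at the 3' end) plus one extraneous crRNA
from the consensus terminal repeat — rebuilding the backbone with
`terminal_variant = "native_mutated"` or `"absent"` suppresses it. The
structure screen (`screen_array(design)`) reports per-repeat hairpin
integrity and flags bridged or disrupted repeats;
`suggest_destabilizing_mutations()` proposes single-base fixes and verifies
them by re-screening.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from a fresh run of the package, the deterministic design
arithmetic of the assembly scheme: the annealing-oligo length under the
default geometry, and the mature guide lengths produced by the processing
simulator for the Cas12a-style (3'-trim) and Cas9-style (5'-trim) profiles.
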