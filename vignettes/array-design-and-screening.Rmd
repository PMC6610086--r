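---
title: "Designing, assembling and screening modular CRISPR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, assembling and screening modular CRISPR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisparray)
```

## The model

A CRISPR array is transcribed as one precursor RNA of alternating repeats
(R) and spacers (S): `R S1 R S2 ... R`. Single-effector nucleases mature
this precursor themselves (Cas12a, Cas13a) or with tracrRNA and host RNase
III (Cas9), and in doing so trim one end of each spacer: Cas12a/Cas13a trim
the 3' end (a 30-nt transcribed spacer region yields a ~23-nt guide, of
which only the first 20 nt hybridize with the target), Cas9 trims ~10 nt
from the 5' end leaving a 20-nt guide. The assembly scheme implemented here
places a short junction — 4 nt by default — inside that trimmed,
non-hybridizing region. Each repeat-spacer unit then carries a unique
overhang pair, so a single-pot Type IIS digestion/ligation reaction
assembles units in a programmed order even though every repeat is
identical. One unit is two annealed oligos: with the default geometry
(36-nt repeat, 26-nt target-derived spacer, 4-nt junction) each oligo is
66 nt and the double-stranded core is 62 bp.

The package models this pipeline end to end: junction set validation and
proposal, unit/oligo/backbone design (including composite multi-nuclease
arrays and combinatorial libraries), digestion–ligation simulation with
misassembly enumeration, crRNA biogenesis, secondary-structure risk
screening, and amplicon-based library quantification.

## Coordinates and sequence conventions

All coordinates are 0-based, half-open `[start, end)`; strand `+` is the
array-sense (transcribed) strand. Circular topology is supported for DNA
constructs, with intervals read modulo the length. Ambiguity codes are
rejected everywhere: a design must be fully specified (in read assignment an
N simply never matches).

## Junction orthogonality

`validate_overhang_set()` rejects palindromic overhangs (self-ligation),
duplicates, and any pair closer than `min_mismatch` substitutions either
directly or against the partner's reverse complement (cross-ligation after a
single synthesis or ligation error). The default `min_mismatch = 2` is this
package's choice: the source protocol only requires "highly dissimilar"
overhangs, and a floor of two mismatches is the weakest rule that excludes
single-error cross-ligation. GC-content bounds are available
(`gc_bounds = c(0.25, 0.75)`) but off by default, since no published rule
exists. `propose_overhang_set()` draws candidates in a seeded random order
and grows the set greedily; infeasible requests error rather than silently
relaxing a rule.

## Assembly simulation

`digest()` uses explicit cut-offset geometry (BsmBI `CGTCTC(1/5)`, BsaI
`GGTCTC(1/5)`, both leaving 4-nt 5' overhangs) taken from standard enzyme
definitions — the protocol assumes them, and they are editable through
`enzyme_def()`. `enumerate_assemblies()` walks the end-compatibility graph
and reports every circular product up to a fragment cap, canonicalized by
rotation; `simulate_golden_gate()` applies the fixed point of the cyclic
reaction: any product still containing a recognition site is re-digested,
so only site-free products survive. Three modeling decisions are worth
knowing:

* blunt ends never ligate (T4 blunt ligation is inefficient, and allowing
  it would explode the product space);
* ligation requires perfect overhang complementarity — mismatch ligation is
  a junction-design problem and is handled by the orthogonality rules, not
  by the simulator;
* fragments keep their orientation; products are capped (default 10,000)
  with an explicit truncation notice, never silently.

## crRNA biogenesis

`find_repeats()` scans for the profile's repeat with up to 3 substitutions
and no indels (a terminal repeat diverged enough to need gaps is the
business of `classify_terminal_repeat()`, which runs a global alignment at
match +1 / mismatch −1 / gap −2). `process_transcript()` cuts each
processable repeat at the profile's cleavage offset and emits mature
crRNAs; with the default FnCas12a profile a crRNA is a 19-nt repeat-derived
handle plus a 23-nt guide (~42 nt, matching the ~44-nt species seen in
sequencing data; the handle length is not printed anywhere authoritative,
so it is a configurable profile parameter and reports always show the
handle/guide breakdown). Cas9 maturation is modeled as deterministic
trimming; the tracrRNA/RNase III requirement is recorded, not simulated.

Terminal repeats matter: a consensus-like terminal repeat is itself
processed and liberates an *extraneous* crRNA whose guide is whatever
sequence lies downstream of the array — a real off-target liability.
`classify_terminal_repeat()` calls a terminal repeat `disrupted` when any
deviation from consensus overlaps the critical region (the processing
hairpin ± 4-nt flanks by default — the figure-derived region is not
machine-readable, so the flank width is configurable) or when the hairpin
no longer folds in the standalone repeat (at least half of the canonical
stem pairs present in the maximum-pairing structure). Only a `processable`
terminal repeat emits the extraneous crRNA; backbones built with
`terminal_variant = "native_mutated"` (three substitutions in the 3' stem,
mimicking the disruptions that natural terminal repeats accumulate) or
`"absent"` suppress it. The ~26-nt standalone trimmed-repeat product seen
in some hosts is reported as a note, not emitted as a species.

## The folding engine and its limits

The screen needs secondary structure, and it needs it to be exhaustively
testable. The engine is therefore a maximum-pairing (Nussinov-style)
dynamic program — Watson–Crick plus G·U wobble, hairpin loops of at least
3 nt, nested structures only, no pseudoknots — with an exact inside–outside
Boltzmann ensemble in which a structure's weight is `exp(beta * pairs)`.
Both algorithms are verified against brute-force enumeration of all nested
structures for short sequences in the test suite. Ties in the maximum are
broken deterministically toward the lexicographically smallest pair list. A
different engine (e.g. a thermodynamic folder) can be plugged in through
the `fold_engine` argument of `screen_array()`.

This is **not** nearest-neighbor thermodynamics: there are no stacking
energies and no loop penalties, so the ensemble is far more diffuse than a
thermodynamic one. That has one important consequence, measured during
development: at `beta = 1` essentially no specific base pair in a ~200-nt
array reaches a probability of 0.8 — even a perfect repeat hairpin sits
near 0.1 — which would make the published-style screening thresholds (pair
probabilities above 80%) meaningless. The pair-probability operation
`pair_probabilities()` keeps `beta = 1` as its neutral default, but
`screen_array()` defaults to `beta = 5`, the smallest sharpness at which an
undisturbed repeat hairpin scores above the 0.8 threshold in array context.
`beta` is a single dimensionless knob; there is no temperature model.

## The structure screen

`screen_array()` folds, by default, the window from the array's 5' repeat
through its 3' spacer (the whole-transcript window is available via
`window = "transcript"`; with identical repeats neither window is uniformly
better, so both are provided). For each crRNA it reports:

* **hairpin integrity** — the fraction of the repeat's canonical stem pairs
  with pairing probability at least `p_star` (default 0.8, from the
  published use of an 80% probability cutoff); a crRNA is flagged when
  integrity falls below `p_star`;
* **spacer 3' stems** — a crRNA is also flagged when its spacer's
  non-hybridizing 3' region participates in a stem of at least
  `stem_len_flag` (default 10, from the published 10-bp hairpin remark)
  consecutive pairs at `p_star`.

Stems are *detected* at a permissive threshold (`p_explore = 0.3`) so that
diffuse competition — several moderately probable decoy pairings sharing
one target — is still visible in the report and can seed the mutation
search; the flag itself only counts strong sub-runs. A disrupted repeat's
offenders include both stems touching the repeat and stems *enclosing* it:
an enclosing (bridging) helix between two spacers competes with and
crossing-excludes the intervening repeat's hairpin — the bridging-hairpin
signature associated with context-dependent loss of crRNA activity.

`suggest_destabilizing_mutations()` proposes single-base substitutions at
spacer positions participating in offending stems, re-screens every
candidate, and ranks them by the recovered hairpin integrity. Positions
inside the hybridizing guide (first 20 nt) are excluded unless
`allow_guide_edits = TRUE`; guide edits change the target and are labelled,
mirroring the experimental practice of co-mutating spacer and target.

## What the synthetic fixtures do and do not establish

The generator (`generate_fixtures()`) emulates the stated experimental
world: a circular backbone with promoter, GFP-dropout stuffer flanked by
two BsmBI sites, terminal repeat and terminator; 26-nt spacers; 4-nt
junctions with the two protocol-printed backbone overhangs (CCCT/GCTG); a
3-position × 5-variant library (125 members, 30 oligos); and paired-end-like
150-nt amplicon reads with a 0.001 per-base substitution error rate over
Dirichlet(α = 5) member proportions — a spread comparable to a real one-pot
library. Reads carry no adapters or indexes (the real prep's indexing is
out of scope). Built-in repeats are synthetic placeholders with a designed
3'-proximal hairpin; they exercise the machinery faithfully but are *not*
the real nuclease repeats, which must be supplied by the user for real
designs.

The structural trios are constructed cases. The clean trio is adenine-rich
with sparse cytosines: it pairs almost nothing, so all six spacer orders
screen clean — establishing the screen's specificity, not its behavior on
arbitrary natural sequence. The pathological trio encodes G/C decoy
segments complementary to (spacer-tail + junction-start) targets whose
contiguity depends on which spacer occupies which position; in exactly one
of the six orders a single bridging helix forms between spacer A's trimmed
3' end and spacer C, enclosing the intervening repeat and collapsing its
hairpin integrity, so exactly one crRNA is flagged — and the suggested
single-base mutations clear that flag while reverting them restores it. In
the remaining orders several decoys fire or cancel at once. This reproduces
the qualitative one-in-six discrimination pattern and the
mutate/revert logic; because the energy model is a pair-count surrogate,
the fixture's sequences were chosen (by search against this package's own
partition function) to sit robustly on the right side of the thresholds,
and a green test establishes internal consistency of screen + mutation
search, not quantitative agreement with thermodynamic folding.

## Numerical and design choices

* Junction proposal, read simulation and library variant generation are the
  only stochastic components; each takes a single integer seed and is
  byte-reproducible.
* `hairpin_folds` in terminal-repeat classification requires at least half
  of the canonical stem pairs in the standalone MFE structure — a
  deliberately coarse criterion, since a 3-substitution stem disruption
  removes half the stem outright.
* The last repeat in a transcript is treated as terminal when fewer than
  one transcribed-spacer-length of sequence remains before the terminator,
  or exactly when the design's spacer count is supplied (`n_spacers`).
* Degenerate inputs: empty arrays are designable only as explicit
  no-spacer controls (two consecutive repeats); zero-total count tables,
  infeasible junction requests and re-digestible intended products are
  errors, never warnings.
* LsCas13a's mature spacer length is not published as a single number; the
  profile defaults to the Cas12a value (23 nt) and is configurable.

## Known limitations

* The energy model ignores stacking and loop entropies; quantitative
  abundance prediction is explicitly out of scope — the screen produces
  qualitative risk flags.
* Fragments do not flip during assembly enumeration, and mismatch/blunt
  ligation is not modeled.
* Read assignment is exact-substring matching: reads with any error in the
  diagnostic region fall to the unassigned bucket rather than being
  best-hit assigned. This is deterministic and oracle-checkable, and with
  short references it loses only the expected fraction of reads.
* Co-transcriptional folding and processing-intermediate refolding are not
  modeled.
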