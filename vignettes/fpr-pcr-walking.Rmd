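---
title: "In-silico fusion primer-driven racket PCR: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico fusion primer-driven racket PCR: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racketpcr)
```

## The method being modeled

Fusion primer-driven racket PCR (FPR-PCR) is a genome-walking scheme:
starting from a sequenced ("known") region it retrieves the unknown DNA
immediately 3′ of it. Four sequence-specific fragments are picked 5′→3′
from the known region — two alternative SSP1s, SSP2, SSP3 (the *fragment
mediating intra-strand annealing*, FISA) and SSP4 — and the FISA is fused
to the 5′ end of an SSP1 to make a tri-functional *fusion primer*. A
single-primer primary reaction then runs three annealing stages:

1. **Moderate stringency (55 °C, 5 cycles).** Only the primer's 3′ part
   (SSP1) finds its exact complement, synthesizing target *first strands*
   that run from the SSP1 site through the unknown flank.
2. **Low stringency (25 °C, 1 cycle).** The fusion primer partially
   anneals at imperfect sites inside the unknown part of a first strand
   and is extended back to its 5′ end, producing a *second strand* that
   ends in the fusion primer's inverted repeat.
3. **High stringency (65 °C, 30 cycles).** Only the full fusion primer
   primes; the second strand and its complement re-prime each other
   (exponential amplification). New first-strand copies whose 3′ terminus
   is the FISA inverted repeat fold back onto the internal FISA site and
   extend along their own known region — the *racket-like DNA*, a stem of
   copied known sequence enclosing a single-stranded loop that carries
   the SSP4 site and the walked unknown sequence.

The secondary reaction is ordinary end-to-end PCR with SSP2 + SSP4 on the
primary product; only racket-derived molecules offer perfect convergent
sites for both primers, which is where the method's specificity comes
from.

The simulator in this package is *symbolic*: a pool of unique strand
species with provenance annotations and a multiplicity class
(`SEED`/`LINEAR`/`EXPONENTIAL`), iterated to a fixed point of species
discovery. Product identity — which molecules exist, their sequence,
their recovered flank — is the testable output; copy numbers and yields
are not modeled.

## Stringency as discrete annealing modes

Annealing temperature enters the model only through three discrete modes
(configurable per stage through `cycle_stage()`):

| stage temp | mode | rule |
|---|---|---|
| 55 °C | `PERFECT_3PART` | the primer's 3′ `k`-mer (the SSP1 part) must match exactly |
| 25 °C | `PARTIAL` | mismatch-tolerant model below |
| 65 °C / 60 °C | `PERFECT_FULL` | the whole primer must match exactly |

The mapping is a modeling decision: the underlying report describes these
stringencies narratively, not thermodynamically, and a ΔG-based annealing
probability is out of scope.

The `PARTIAL` model accepts a gapless window iff all three hold
(`annealing_model()`):

* matched run at the primer 3′ terminus ≥ `min_three_prime_run`
  (default 2 bp) — two paired 3′ bases appear mandatory for extension;
* total matches ≥ `min_total_matches` (default 14 bp) — the smallest
  match count observed in sequenced walking products;
* mismatches ≤ `max_mismatch_fraction` × primer length (default 0.6) —
  the mismatch tolerance reported for walking primers.

The floors are enforced conjunctively and are independently configurable
because it is not established which is operative. A consequence worth
knowing: on a 39-nt fusion primer the 60 % ceiling (≤23 mismatches)
implies ≥16 matches, so a 14-match site can only be *accepted* on fusion
primers of ≤35 nt. The run threshold is a configurable default, not a
constant, since it may be an empirical observation rather than a rule of
the method. `N` never matches anything. Alignments are gapless —
sequenced annealing loci show no indels — and the scanner searches only
the strand it is given; the simulator orchestrates strand sense.

During the low-stringency cycle only strands carrying unknown-flank
provenance are scanned (walking happens on the unknown region); a
permissive `scan_all` mode exists for background studies and for the
event-enumeration oracle in the test suite.

## Primer design

`design_walk_set()` picks the five fragments under the published windows
(FISA 17–18 nt / 45–55 °C, SSP1 17–21 nt / 50–55 °C, fusion 34–39 nt /
65–70 °C, SSP2/SSP4 25–30 nt / 60–66 °C), a minimum 3 nt separation of
the two SSP1 3′ ends, and structure screens. Interpretation choices:

* **"Sequential 5′→3′" is read as non-overlapping placement** (each
  fragment ends before the next begins; the two SSP1s may overlap each
  other). Start-ordering alone would admit arbitrarily short regions,
  which contradicts the intent; published loci that violate this (one
  locus pair in the validation panel) are *surfaced* by
  `check_primer_table()` as ordering notes — printed sequences are
  trusted over printed coordinates, never silently repaired.
* **Tm windows are warnings by default** (`strict_tm = TRUE` makes them
  hard): window satisfaction depends on the Tm calculator, which the
  method's description does not fix.
* **Selection objective.** Feasible sets are totally ordered by the sum
  of per-fragment scores, `(1 − |Tm − window center| / half width)` minus
  `0.15·stem/stem_threshold + 0.15·dimer_run/dimer_threshold`; ties break
  on the leftmost SSP1-α start and then fixed lexicographic order, so a
  rerun is byte-identical. The search keeps each role's `beam`
  best-scoring candidates (60 by default; all of them when fewer) and
  falls back to an exhaustive feasibility-pruned search if the beam holds
  no feasible combination — on a 500-nt region the beam optimum is the
  practical optimum, and on the minimal regions where it is not, the
  fallback is exact.
* **Cross-dimer checks** apply to the primer pair that shares a tube
  (SSP2 + SSP4); severity thresholds are a hairpin stem ≥ 4 bp closing
  over a loop ≥ 3 nt, or a 3′-anchored (self- or cross-) dimer run
  ≥ 5 bp. "Severe" is all the method's description states; the values are
  common primer-QC practice and are configurable
  (`structure_thresholds()`).

### Melting temperatures

`melting_temperature()` implements the unified nearest-neighbor
parameter set with terminal initiation terms, the entropy salt correction
`0.368·(N−1)·ln[mon]`, and divalent cations folded in as
`120·√(Mg − dNTP)` mM monovalent equivalents. Defaults follow the
published mix: 0.2 µM primer, 50 mM monovalent, 2.5 mM Mg²⁺, 1.6 mM total
dNTP. The test suite pins two probe sequences to values frozen from an
independent nearest-neighbor implementation of the same parameter set
(agreement ≪ 0.5 °C). Since acceptance quantities are length-based, the
Tm-model choice cannot move them.

## Coordinates and strand conventions

Externally everything is 1-based inclusive, matching both the published
primer table ("the first nucleotide of the known sequence is numbered 1")
and R/Bioconductor convention; internally the same representation is kept
(an R-idiomatic deviation from a 0-based internal scheme — with a single
convention there is no boundary to get wrong), and only the BED export
converts to 0-based half-open. The known region is given on the plus
strand and the walk proceeds into the flank 3′ of it; walking upstream is
done by reverse-complementing the input, not by a special case. A primer
lies antiparallel to the template it anneals to, so its 3′ base pairs the
*5′-most* position of the template window; match masks are reported along
the primer 5′→3′.

## Numerical and degenerate-case choices

* `max_extension` defaults to 10 000 nt (a 3-min extension with a
  long-range polymerase; observed walks are ≤ 1.6 kb), applied to every
  synthesis including loop-back. Polymerase run-off length is otherwise
  unspecified, so the cap is an explicit stand-in.
* Pool caps: 200 species / 50 000 nt per strand by default; overflow
  warns and never silently drops an already-ranked lineage.
* **Loop-back fires once per lineage.** `detect_loopback()` uses the
  3′-most internal FISA site (warning when several exist). Inside the
  simulator a `looped` flag, inherited by copies, prevents re-folding:
  re-applying the 3′-most rule to a racket would append the same tail
  every cycle (`R`, `R·tail`, `R·tail·tail`, …), an unbounded concatemer
  family that the single-event description of racket formation does not
  license; after one loop-back the 3′ terminus mirrors the full stem and
  the flush panhandle leaves nothing to extend. A strand whose only
  internal FISA site is its own 5′ tag "loops back" with an empty
  extension — a no-op by deduplication.
* **Secondary products are trimmed to innermost sites.** A candidate
  amplicon still containing an internal perfect SSP2/SSP4 site is a
  transient molecule (cycling re-primes every internal site), so only
  site-free end-to-end products are reported. `exponential` is `TRUE`
  only when the two ends are sites of the two *distinct* primers;
  same-primer products between inverted sites additionally carry a
  terminal inverted repeat and are flagged `hairpin_suppressed` (default
  threshold 15 bp) and ranked last — such molecules fold into hairpins
  instead of amplifying, which is why multi-band background is rare in
  this method. Amplicons are deduplicated as duplexes (a product equals
  its reverse complement).
* Ranking is deterministic: non-suppressed first, then the match score of
  the founding partial site, then length, then sequence.

## The synthetic-fixture generator

`make_fixture()` embeds a designed known region in a random genome
(defaults 5 kb, GC 0.42 — resembling a low-GC lactic-acid bacterium host;
both configurable) and writes, at a chosen distance downstream of the
known region's 3′ end, a *degenerate reverse complement of the fusion
primer* with exactly the requested total matches and 3′-terminal run:
matched positions carry the pairing base, non-matched positions carry a
guaranteed-mismatch base (never a random one), so the mask is exact by
construction. The flanks — and the known-region background outside the
designed primer loci — are then scrubbed of accidental perfect or partial
primer windows, so the planted sites are the only walk signal and
`GroundTruth` (site coordinates, mask, expected walk distance and
amplicon length) is recovered by construction. Two window classes are
deliberately left: minus-strand windows wholly inside the known region
(they are the walk's own SSP1 machinery) and minus-strand windows
overlapping a planted site (the plant's unavoidable shadow — the reverse
complement of a degenerate primer complement may itself weakly pair the
primer; both only spawn inert plus-sense copies).

What the generator emulates: the statistical shape of functional partial
annealing (14–19 matches, ≥2-bp 3′ anchor, 3′-skewed pairing is left to
the mask draw), walk distances up to a few kb, and parallel α/β designs.
What it does not: real genomic repeat structure and homopolymers,
thermodynamic annealing competition, polymerase errors, or yields — so
green tests demonstrate mechanism correctness, not wet-lab band patterns,
and published band sizes are deliberately not desk-reproduced (they
depend on specific genomic loci and stochastic annealing). Mechanism
correctness is instead accepted through properties: exact recovery of
planted flanks at distances 50–1500 nt, equivalence with a brute-force
event-enumeration oracle on ≤2-kb genomes (three cycles per stage,
unbounded pool), the specificity invariant, a closed-form 227-bp toy
amplicon, and byte-reproducibility at fixed seeds.

Test and acceptance problem sizes — 500-nt known regions, 1.5–4-kb
genomes, 20-design batteries — were chosen as the smallest sizes at which
every constraint of the design problem is active; all randomness flows
from a single documented seed.

## Known limitations

* Gapless annealing only; no indel-tolerant sites, no degenerate/IUPAC
  primers.
* Discrete stringency modes; no ΔG folding of long strands (primer-length
  hairpin/dimer screens only).
* Copy numbers are classes, not quantities; gel intensities are out of
  scope.
* The designer optimizes a fixed documented score; it does not explore
  Pareto trade-offs between Tm centrality and structure penalties.
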