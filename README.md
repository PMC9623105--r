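# racketpcr

Design and in-silico rehearsal of **fusion primer-driven racket PCR
(FPR-PCR)** genome walking — for molecular biologists who need to
retrieve the unknown DNA flanking a sequenced region (promoters and
regulators upstream of a gene, transgene/transposon insertion sites,
gap-filling in assemblies) and want to check a primer design and predict
the walk products before touching a thermocycler.

## The method

FPR-PCR walks from a known region into its 3′ flank with a single
tri-functional *fusion primer* and a nested primer pair. Four
sequence-specific fragments are chosen 5′→3′ from the known sequence —
SSP1 (two alternatives α/β), SSP2, SSP3 = FISA (the fragment mediating
intra-strand annealing) and SSP4 — and the fusion primer is FISA appended
to the 5′ end of an SSP1 (34–39 nt total).

The primary reaction is driven by the fusion primer alone through three
annealing stages (94 °C 2 min; [94 °C 30 s, T<sub>a</sub> 30 s, 72 °C
3 min] with T<sub>a</sub> = 55 °C ×5, 25 °C ×1, 65 °C ×30; 72 °C
10 min):

* at 55 °C only the SSP1 part primes (on its exact complement), making
  target **first strands** that run through the unknown flank;
* the single 25 °C cycle lets the primer **partially anneal** inside the
  unknown region — functional sites pair ≥14 bases in total, at least 2
  of them at the primer's 3′ terminus, tolerating up to 60 % mismatch —
  creating a **second strand** that ends in the primer's inverted repeat;
* at 65 °C the full primer amplifies that species exponentially, and new
  first-strand copies fold back (FISA ↔ its inverted repeat) and extend
  into **racket-like DNA**: a double-stranded known-region stem enclosing
  the single-stranded unknown loop.

The secondary reaction (25 cycles, 60 °C) is classical end-to-end PCR
with SSP2 + SSP4; only racket-derived DNA offers perfect convergent
sites for both, so the target is the major product and the recovered
flank is read straight off the amplicon.

`racketpcr` implements the designer (windows, Tm, hairpin/dimer screens,
SSP1α/β 3′-end separation ≥ 3 nt), the mismatch-tolerant annealing
scanner, a symbolic strand-pool simulator of both reactions (species +
provenance, not copy numbers), amplicon validation against the known
region, thermal-program emission, and a seeded fixture generator that
plants partial-annealing sites with exact statistics into synthetic
genomes. See the methods vignette
(`vignettes/fpr-pcr-walking.Rmd`) for the model's assumptions and knobs.

## Worked example

Design a walk on a synthetic 500-nt known region, plant a partial
annealing site 120 nt into the unknown flank of a 5-kb genome, and
simulate both reactions:

```r
library(racketpcr)

known <- synth_known_region(500, seed = 1)
ws <- design_walk_set(known, seed = 1)
ws
#> FPR-PCR walking-primer set (known region 500 nt, score 4.275)
#>   ssp1_alpha TGCCTAATTCTAATCTATGT   (216-235) 20 nt  Tm 52.4 C
#>   ssp1_beta  GTTTTTCATATATCGCTGTA   (237-256) 20 nt  Tm 52.5 C
#>   ssp2       CACACTATCAGCAGGTTTCAATTCA (355-379) 25 nt  Tm 63.0 C
#>   fisa       CAACCACAACTATGTTA      (384-400) 17 nt  Tm 50.0 C
#>   ssp4       TTACCCCATTACGATCATTGATTCAAC (425-451) 27 nt  Tm 63.0 C
#>   fp_alpha   CAACCACAACTATGTTATGCCTAATTCTAATCTATGT    37 nt  Tm 65.9 C
#>   fp_beta    CAACCACAACTATGTTAGTTTTTCATATATCGCTGTA    37 nt  Tm 66.3 C

spec <- fixture_spec(genome_length = 5000, known_start = 1001,
                     planted_sites = data.frame(distance = 120,
                                                total_matches = 16,
                                                three_prime_run = 3),
                     seed = 7)
fx <- make_fixture(spec, ws)
report <- simulate_walk(fx$genome, fx$walk)
report
#> FPR-PCR walk report
#>   rackets formed: 1
#>   predicted amplicons: 1
#>   top amplicon: amp01, 262 bp, SSP4/SSP2, walk distance 120 nt
#>   overlap with known region: 76 bp (exact), abuts the known 3' end
```

The one exponential amplicon is 262 bp: SSP4-to-known-end (76 bp,
the exact overlap confirming the product abuts the known region's 3′
end) + the 120 walked bases + the copied fusion-primer site and
SSP2–FISA stretch. `report$amplicons$recovered_unknown` equals the
genome's flank bases 1–120 exactly — the walk distance is the distance
from the known-region boundary to the founding partial site, which the
alignment report renders in the style of a sequencing read-out:

```r
cat(format_site_alignment(fx$walk$fp_alpha$seq,
      substr(fx$genome$seq, fx$truth$site_start, fx$truth$site_end),
      name = "planted site"))
#> planted site (16 matches, 3' run 3)
#>   5'-CAACCACAACTATGTTATGCCTAATTCTAATCTATGT-3'  primer
#>      |....|||.|.|...|.|.||..||.......|.|||
#>   3'-GAACCTGTAGTTTGTAAAGGGTATATCTAATCAAACA-5'  template
```

A command-line interface wraps the same pipeline
(`exec/racketpcr design | simulate | protocol | fixtures | validate`),
and `emit_protocol()` prints the two thermal programs ready for the
cycler.

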