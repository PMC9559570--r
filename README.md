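# plastidSV

Quadripartite plastome structure, SSC switching, and structural-variant
analysis from long reads.

## The problem

Plant chloroplast genomes (plastomes) are circular molecules organized as
LSC–IR1–SSC–IR2: a large and a small single-copy region separated by two
inverted repeats that are near-identical reverse complements. Recombination
between the IRs flips the whole SSC, so a single plant carries a mixture of
SSC-forward (LSC-IR1-SSC-IR2) and SSC-reverse (LSC-IR1-ssc-IR2) molecules —
*SSC switching*. An assembly collapses that mixture into one arbitrary
orientation; only long *junction reads*, spanning an entire IR with
anchored sequence on both sides, phase the orientation of individual
molecules. A rarer, irreversible *asymmetric* recombination exchanges
unequal segments, creating molecules that gained an IR copy (with a
truncated-IR junction, organization IR1d–prefix–i1–IR1) or lost one.

plastidSV is a Bioconductor-style S4 package for scientists studying these
dynamics. It provides:

* `findInvertedRepeats()` / `canonicalizeGenome()` — detect the IR pair on
  a circular genome (k-mer seeding on anti-diagonals, mismatch budget
  `ceil(rate · length)`) and partition it into LSC/IR1/SSC/IR2;
* `flipSsc()`, `buildHaplotypePair()` — construct the two orientation
  haplotypes; `applyIRDuplication()`, `applyIRLoss()` — apply the IR gain
  and loss rearrangements; `findHsp()` — high-score segment pairs
  (match +2, mismatch −3, gap of length *g* costs 5 + 2(*g*−1));
* `mapRead()` / `classifyReads()` / `summarizeOrientation()` — map long
  reads to both haplotypes and classify junction reads (aligned fraction
  > 90%, IR1 covered 100%, two 200-bp aligned overhangs into LSC and
  SSC/ssc), then report orientation counts, proportions, the SSC/ssc
  ratio and a Wilson 95% interval;
* `screenJunctionSignature()` / `callChimera()` — classify assemblies by
  the conserved 24-nt rice IR1-SSC junction signatures
  (`TGGAAAAAATCG|GCAAATAGGAAA` for SSC-F, `TGGAAAAAATCG|CGGAAAACCGAA` for
  SSC-R) and flag assemblies whose junction type and SSC body orientation
  disagree;
* `findSTRLoci()` / `strCopyNumbers()` — short-tandem-repeat detection and
  anchor-based copy-number calling from spanning reads, with the
  `position[unit]min-max` notation (`formatStrNotation()` /
  `parseStrNotation()`);
* `simConfig()` / `simulateGenome()` / `simulateMolecules()` /
  `simulateReads()` — a provenance-tracked generator of quadripartite
  genomes, mixed-orientation molecule pools and error-bearing long reads;
* `runPipeline()` plus a thin CLI (`inst/scripts/plastidsv.R`) with
  subcommands `partition`, `flip`, `haplotypes`, `simulate`, `classify`,
  `screen`, `chimera`, `strscan`, `report`.

## Worked example

Simulate a scaled plastome mixture (regions 8,000/2,000/1,200 bp, 55%
SSC-reverse molecules), classify the reads, and summarize:

```r
library(plastidSV)

cfg  <- simConfig(nReads = 200, nMolecules = 50)  # pReverse = 0.55
sim  <- simulateGenome(cfg, seed = 11)
st   <- findInvertedRepeats(sim$genome, minLen = 500)
st
#> QuadripartiteStructure: 13200 bp | LSC 8000, IR1 2000, SSC 1200, IR2 2000
#>   IR mismatches: 0; rotation offset to canonical: 0
#>   LSC         1..    8000 (8000 bp)
#>   IR1      8001..   10000 (2000 bp)
#>   SSC     10001..   11200 (1200 bp)
#>   IR2     11201..   13200 (2000 bp)

pair  <- buildHaplotypePair(sim$genome, sim$structure)
mols  <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 11)
reads <- simulateReads(mols, cfg, seed = 11)
calls <- classifyReads(reads$reads, pair)
summarizeOrientation(calls)
#> OrientationReport (SSC orientation among junction reads)
#>   forward (SSC-F): 9   reverse (SSC-R): 16
#>   ambiguous: 0   non-junction: 175
#>   prop F/R: 0.3600 / 0.6400; SSC/ssc ratio 0.5625 (printed-style 0.56)
#>   wilson 95% CI for prop F: [0.2025, 0.5548]
```

The detector recovered the planted partition exactly. Of 200 reads, 25
spanned the LSC-IR1-SSC(ssc) junction with the required anchoring and were
phased — every one to its true source orientation (the provenance table in
`reads$provenance` records the truth) — while the rest are honest
`non_junction` calls: too short, wrongly placed, or orientation-blind
(an IR+SSC fragment without an LSC anchor maps perfectly to both
haplotypes). At this read count the Wilson interval is wide; it tightens
toward the planted 0.45/0.55 mixture as reads accumulate.

The published junction-read counts reproduce the printed arithmetic
directly:

```r
summarizeOrientation(nForward = 82, nReverse = 99)
#> OrientationReport (SSC orientation among junction reads)
#>   forward (SSC-F): 82   reverse (SSC-R): 99
#>   ambiguous: 0   non-junction: 0
#>   prop F/R: 0.4530 / 0.5470; SSC/ssc ratio 0.8283 (printed-style 0.82)
#>   wilson 95% CI for prop F: [0.3822, 0.5258]
```

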