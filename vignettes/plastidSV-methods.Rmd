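---
title: "Quantifying SSC switching and plastome structural variants with plastidSV"
author: "plastidSV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SSC switching and plastome structural variants with plastidSV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidSV)
```

## The biological problem

Land-plant chloroplast genomes (plastomes) are circular molecules with a
conserved quadripartite organization: a large single-copy region (LSC), a
small single-copy region (SSC), and two inverted repeats (IR1, IR2) that are
near-identical reverse complements of each other and separate the two
single-copy regions. Homologous recombination between the IRs inverts the
whole SSC, so a single plant — even a single seedling — carries a mixture of
two orientation haplotypes, conventionally called SSC-forward
(LSC-IR1-SSC-IR2) and SSC-reverse (LSC-IR1-ssc-IR2). This frequent,
reversible inversion is called SSC switching. Because short-read assemblies
collapse the two haplotypes into one arbitrary orientation, the mixture is
only observable with long reads that span an entire IR plus flanking
sequence on both sides: such junction reads phase the SSC orientation of the
molecule they came from.

A rarer, irreversible class of recombination (asymmetric recombination)
exchanges unequal segments, producing molecules that gained an IR copy (with
a characteristic truncated-IR junction) or lost one. plastidSV implements
the computations needed to study both phenomena: quadripartite partitioning,
orientation-haplotype construction, junction-read classification and
orientation statistics, junction-signature screening and chimera detection,
short-tandem-repeat (STR) copy-number calling, and a synthetic-data
generator that makes every stage testable without external data.

## Quadripartite partitioning

`findInvertedRepeats()` searches a circular genome for the highest-scoring
pair of disjoint segments such that one is the reverse complement of the
other, up to a mismatch-rate budget. The search seeds exact k-mer matches
(default k = 15) between the sequence and its reverse complement, clusters
them on circular *anti-diagonals* (for an inverted pair, the sum of paired
positions is constant modulo the genome length), and greedily extends the
seeded runs. A mismatch gap is absorbed only when the exact-match run beyond
it more than offsets it (match +1, mismatch −3), so reported IR boundaries
always land on exact-match ends rather than creeping over chance matches;
the total mismatch count is additionally capped at
`ceiling(maxMismatchRate * length)`. Among candidates the longest wins, with
ties broken by fewest mismatches and then smallest start position.

Defaults: `minLen = 1000` (plastome IRs are tens of kilobases; anything
shorter is noise at this scale) and `maxMismatchRate = 0.001` (the IRs of
one molecule are essentially identical; the budget tolerates occasional
curation differences). On a 135-kb plastome the search takes a couple of
seconds in pure R; correctness on small genomes is guarded in the test
suite by an exhaustive brute-force oracle over all rotations and all
complementary runs.

The two gaps between the IR copies become LSC (the longer) and SSC (the
shorter); equal gaps are unresolvable and raise a structured error, as does
the absence of any adequate pair (`noIRError`, the situation of IR-lacking
plastomes such as those described in *Onobrychis*). `canonicalizeGenome()`
rotates the genome so the LSC starts at position 1, immediately followed by
IR1. All coordinates use 1-based closed `IRanges`, the Bioconductor
convention, and all reports are 1-based.

## Orientation haplotypes and rearrangements

`flipSsc()` reverse-complements the SSC interval in place (an involution);
`buildHaplotypePair()` packages the genome and its flipped image as the
SSC-F/SSC-R pair. `applyIRDuplication()` constructs the IR-gain molecule of
the asymmetric-recombination model: deletion of `d1Len` bases from the 3'
end of IR1 and insertion, at that point, of a de-novo prefix, the first
`i1Len` bases of LSC, and a full IR1 copy — the junction organization
IR1d–prefix–i1–IR1. The default `svSpec()` carries the rice values (d1 =
319 bp, prefix `"ATTTT"`, i1 = 2,000 bp), whose insert length with a
20,805-bp IR is 22,810 bp. `applyIRLoss()` removes one full IR copy; the
product (LSC-IR-SSC) does not record which copy was lost, so the package
fixes the choice to IR2 and documents it. `findHsp()` returns the
high-score segment pair between two sequences — the best local alignment
under match +2, mismatch −3, gap of length g costing 5 + 2(g − 1) — used to
look for short homologies at rearrangement breakpoints and to orient SSC
bodies. The alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; the test suite checks it against an
independent plain dynamic-programming implementation on all inputs up to
30 nt. Among equal-scoring segment pairs the aligner's deterministic
traceback decides which is reported.

## Junction-read classification

`mapRead()` is a deterministic seed–chain–extend mapper against the doubled
reference (so reads crossing the circle origin stay contiguous): exact
k-mer anchors, modal diagonal band, greedy co-linear chaining, block
assembly with direct mismatch counting on a shared diagonal, small global
alignments across diagonal shifts, and X-drop end extension. Two rules
matter for classification correctness and are worth stating precisely:

* anchors on one diagonal are merged across an unanchored stretch only when
  that stretch's direct-comparison identity is at least 0.5 (or it is
  ≤ 10 bp); this prevents the mapper from "bridging" the entire reversed
  ssc when a read from one haplotype is aligned to the other, which would
  otherwise make every long junction read look ambiguous;
* diagonal-shift gaps that align with ≥ 0.5 identity are kept as explicit
  blocks, so small indels do not punch holes into reference coverage.

`classifyJunctionRead()` applies the junction criteria against both
haplotypes: aligned read fraction strictly greater than 0.90, IR1 covered
completely (`minIrCover = 1`), and at least 200 aligned bases immediately
flanking IR1 on both sides — into the LSC at its 5' end and into the
SSC/ssc at its 3' end. Overhangs are measured in aligned reference bases
from the block structure, never from raw read length, so clipped bases are
not spanning evidence. A read satisfying only the F haplotype is `forward`,
only R `reverse`, both `ambiguous` (excluded from proportions — the
conservative choice for a case the criteria do not define), neither
`non_junction`. The full-scale convention of screening reads shorter than
20 kb is exposed as `minReadLen` (off by default at scaled sizes, set by
the `"paper"` preset). An option extends the same rule to the SSC-IR2-LSC
junctions (`useIr2`), disabled by default. Reads are counted per input
read; whether multiple subreads of one molecule should collapse is a
library-preparation question the package does not decide.

`summarizeOrientation()` reports counts, proportions over classified reads,
and the SSC/ssc ratio twice: at full precision and in the printed style —
each proportion rounded to two decimals before dividing, then the ratio
rounded to two decimals — the convention under which 82 forward and 99
reverse reads yield 0.45/0.55 = 0.82. The uncertainty on the forward
proportion is a Wilson score interval (default 95%); with no classified
reads the proportions are undefined (`NA`), not an error.

## Junction signatures and chimeras

Rice plastomes carry highly conserved 24-nt sequences straddling the
IR1-SSC junction: `TGGAAAAAATCG|GCAAATAGGAAA` in SSC-F molecules and
`TGGAAAAAATCG|CGGAAAACCGAA` in SSC-R molecules. `screenJunctionSignature()`
classifies an assembly by which signature it carries. One geometric fact
shapes the implementation: in any coherent quadripartite genome whose
SSC ends are built so that flipping produces the other signature, the
*other* motif is always present on the minus strand at the SSC-IR2 junction
(it is the reverse complement of the flipped molecule's IR1-ssc junction).
A position-blind scan of both strands therefore finds both motifs in every
complete genome and can never be conclusive. The screen consequently
canonicalizes the assembly (detecting the structure if not supplied) and
scans the canonical plus strand only; the verdict is thus relative to the
presented strand, exactly as database plastomes are conventionally
linearized. For fragments with no detectable quadripartite structure the
screen falls back to a both-strand scan with the conservative rule: one
motif type → that verdict; both or neither → `unknown`. Strand symmetry
holds on that fragment path; for complete molecules it is mathematically
unachievable without a species-specific marker of LSC orientation, because
the F/R distinction is *defined* relative to the LSC.

`callChimera()` detects assemblies whose junction signature and SSC body
disagree — the signature of hybrid assemblies built from mixed-orientation
data. Body orientation is the strand of the better `findHsp()` alignment of
the assembly's SSC against a reference SSC of known orientation, required
to win by a relative margin (default 10% of the winning score; below that
the body is `unknown` and no chimera is called). The motifs are parameters
with rice defaults, since the signatures are rice-specific.

## STR detection and copy-number calling

`findSTRLoci()` reports maximal tandem runs with unit lengths 1–6,
requiring at least 6 copies for homopolymers and 3 for longer units;
runs equivalent to a smaller unit are suppressed (a 12-A run is `[A]12`,
never `[AA]6`), and units are canonicalized to their least rotation.
`strCopyNumbers()` counts unit copies per spanning read between two
anchored flanks (default 10 bp each side), located in the read near the
positions implied by the alignment blocks — anchor-based counting rather
than alignment-gap counting, because aligners place gaps arbitrarily inside
homopolymers. A copy number needs at least 3 supporting reads (the
package's choice; no published threshold exists for this design), and a
locus whose supported minimum and maximum differ is a copy-number-variation
call. The notation `position[unit]min-max` (e.g. `11291[T]7-8`) is
serialized and parsed by `formatStrNotation()` / `parseStrNotation()`, with
print-style subscript markup flattened.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised:

* region lengths 8,000 / 2,000 / 1,200 bp — a ~1/10 scaling of the
  published 80,553 / 20,805 / 12,346 bp, keeping tests in seconds; a
  `"paper"` preset restores the full-scale lengths, the unscaled SV
  parameters and the 20-kb read screen;
* `pReverse = 0.55` — the observed SSC-R proportion;
* lognormal read lengths, median 4,000 bp and sigma 0.35 at scaled size
  (so a read must be well into the upper half of the distribution to span
  IR + 2×200 bp, mirroring how >20-kb reads relate to a 20.8-kb IR), with
  2,000 reads by default;
* per-base substitution/insertion/deletion rates, 0 by default and
  exercised at 1–2% in tests;
* optional embedding of the rice junction signatures at the IR1-SSC and
  SSC-IR2 boundaries so that flipping the SSC produces the R signature by
  construction;
* planted STR loci with per-molecule copy-number choices.

Single-copy regions are i.i.d. uniform A/C/G/T and IR2 is the exact
reverse complement of IR1. One base at each region boundary is adjusted
when needed so the planted IR pair is maximal and planted STR runs cannot
extend — otherwise chance complementarity at a junction would legitimately
lengthen the true maximal pair and the planted partition would not be the
ground truth (the same subtlety that makes naive hand-built examples
non-maximal). Molecules draw orientation and IR-duplication status
independently; reads record full provenance (molecule, orientation, SV
status, start, strand), which is what makes exact accuracy measurement
possible.

What the generator deliberately does not emulate: homopolymer-biased and
chemistry-specific error profiles (errors are positionally uniform),
ZMW/subread structure, adapters, and quality-value information (qualities
are constant and never read). Passing tests therefore demonstrate
correctness of the computations under clean mixture conditions, not
robustness to every artefact of real instrument data.

## Numerical and design choices

* Coordinates: 1-based closed intervals everywhere a human sees them;
  `IRanges` internally.
* "More than 90% of their lengths" is read literally as a strict
  inequality on the aligned read fraction.
* IR detection ties (equal length, mismatches and start) cannot occur
  twice for one genome; equal LSC/SSC gap lengths are refused rather than
  guessed.
* `applyIRLoss()` removes IR2; the choice is arbitrary but fixed.
* N matches nothing: it scores as a mismatch in IR detection, HSPs and
  motif scans.
* The no-anchor case in mapping yields an empty alignment, not an error;
  empty alignments classify as `non_junction`.
* Problem sizes in the tests (1,000 oracle genomes up to ~300 nt; 2,000
  error-free reads for the accuracy check; 50 replicates at a reduced
  genome scale for the interval-coverage check; 150–250 reads for STR
  recovery) are chosen to exercise each property at the smallest scale
  where it is meaningful.

## Known limitations

* The junction-signature defaults are rice-specific; other taxa need their
  own motifs (they are plain parameters).
* Full-molecule strand symmetry of the signature screen is impossible in
  principle (see above); verdicts are relative to the presented strand.
* The mapper is a purpose-built long-read aligner for references the size
  of plastomes; it is not a general-purpose aligner and makes no attempt at
  split-strand (chimeric) alignments.
* STR copy counting requires clean flank matches; at high error rates
  loci become uncallable rather than wrong (the support threshold filters
  sporadic miscounts).
* SAM import takes identity from the NM tag when present; without it,
  identity is undefined while block structure and fractions remain exact.
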