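---
title: "Cataloguing lineage-specific ERV insertions: models, parameters, and design"
author: "ervscribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing lineage-specific ERV insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscribe)
```

## The problem

Endogenous retroviruses (ERVs) are remnants of ancient germ-line
infections: a full-length provirus is a ~7.5 kb internal region carrying
the *gag*, *pro*, *pol* and *env* genes between two ~1 kb long terminal
repeats (LTRs). The youngest human family, HERV-K, kept inserting after
the human–chimpanzee split, so some copies exist only in humans and some
still segregate in human populations as three allele states: locus empty,
full provirus, or a solitary LTR left behind when a provirus's own LTRs
recombine.

Identifying such insertions from a reference genome involves a chain of
inferences, each with its own failure modes:

1. repeat annotations report *fragments*, not elements — nested
   insertions split one locus across many rows;
2. presence or absence at the orthologous position in an outgroup genome
   must be read off flank alignments;
3. the insertion *mechanism* is written in the junctions: classical
   integration duplicates 4–6 bp of target (a TSD), while non-classical,
   DNA-repair-associated integration leaves blunt, truncated ends,
   deletes target sequence, and often shows short microhomology between
   element termini and the breakpoint — the NHEJ signature;
4. subtype and coding status are read off an alignment to a consensus
   gene map;
5. population state is read off PCR band patterns.

This package implements that chain as testable functions, and — because
the real inputs are multi-gigabase primate genomes — ships a generator
that plants insertions of every observed class into a synthetic
background with full knowledge of the truth. Every stage of the pipeline
is validated by recovering planted truth exactly.

## The synthetic genome generator

`sim_config()` fixes the study conditions. The defaults are the
conditions under which all properties in the test suite are asserted:

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 2 Mb | large enough for 40 well-separated loci with 2 kb flanks and multi-kb target deletions; small enough to keep a full run in tens of seconds |
| `gc_fraction` | 0.41 | the human genome-wide average |
| `n_insertions` | 40 | covers all six structural classes several times over |
| `class_mix` | 0.35/0.20/0.15/0.15/0.075/0.075 | full-length, truncated, solo-LTR, non-classical, tandem, inverted — roughly the published census with every class represented |
| `tsd_len_range` | 4–6 bp | the TSD lengths observed at classical loci |
| `target_del_range` | 6–10,207 bp | the published envelope of target deletion sizes at non-classical loci |
| `microhomology_range` | 0–10 bp | short exact junction overlaps, as observed |
| `ltr_divergence` | 0.01/site | within-element LTR divergence, young-family scale |
| `founder_ltr_divergence` | 0.05/site | between-element divergence; one founder per locus |
| `flank_divergence` | 0 | outgroup flanks identical to the carrier by default; a knob stresses the mapper |
| `fragmentation_rate` | 0.2 | chance an internal annotation is split by a nested repeat |

Two generator behaviours deserve emphasis because they are what make
exact truth recovery a meaningful test rather than a tautology:

* **Junction sanitation.** A random background occasionally produces an
  accidental ≥4 bp duplication at a junction where the truth says
  "blunt", or extends a planted TSD by chance. The generator runs the
  same longest-duplication scan the detector uses and perturbs single
  background bases until the realized junction equals the recorded
  truth. The truth table is therefore exact by construction, not
  approximately true.
* **Microhomology is exact-match only.** Non-classical element termini
  are overwritten with the first/last bases of the deleted target
  region, and the base just beyond each planted overlap is forced to
  mismatch, so the planted length is the unique longest overlap.
  Mismatched ("imperfect") microhomology is out of scope.

Fragmentation is an *annotation-level* artifact: `emit_repeat_annotations()`
splits an internal part's hit in two and labels the gap with a
nested-repeat family, with consensus coordinates continuing across the
gap exactly as a real nested insertion would produce — but the carrier
sequence itself is untouched. Everything downstream of fragmentation
(merge rules, nested-insertion detection) consumes hit geometry only, so
nothing is lost, and the sequence-level invariant "re-extracting a
planted element reproduces its constructed sequence" stays intact.

The bundled consensus is a *synthetic* ~9.5 kb provirus built
deterministically in code (`toy_provirus()`): 968 bp LTRs (the modal LTR
length in the catalogue), stop-free gag/pro/pol/env frames, and a marked
292 bp pol–env boundary segment. The pol span is a codon multiple, so
excising the boundary segment (the type I configuration) shifts *env*
into the *pol* frame — reproducing the diagnostic in-frame pol–env
fusion. It is not a transcription of any database sequence; users can
supply their own consensus FASTA and gene-map TSV.

### What the generator does not emulate

No indel mutations (flank divergence is substitution-only, which keeps
anchor coordinates in register — the mapper verifies candidates at a
fixed offset and would need banded alignment for indel divergence); no
substitution model along a phylogeny (one outgroup equals the background);
no segmental duplications or satellite arrays (loci that would be
unamplifiable in practice are modelled simply as loci flagged
ungenotypable); no CpG or
mutation-rate heterogeneity. Passing the recovery suites therefore shows
the *logic* of the pipeline is correct under clean and mildly diverged
(≤2%) conditions; it does not certify performance on real primate
genomes, where alignment ambiguity dominates.

## Defragmentation and assembly

Merging follows three rules. Same-family, same-strand hits merge iff
their consensus spans are collinear in strand order (overlap ≤ 50 bp)
and the genomic gap is either ≤ 5,000 bp or ≥ 80% covered by hits of
other repeat families (the nested-repeat bridge). A gap occupied ≥ 50%
by the *partnered* LTR/internal family blocks merging: an intervening
LTR annotation marks an element-internal boundary (a tandem junction),
not a nested repeat — without this rule the two internal regions of a
K124-like locus, whose consensus spans happen to be collinear, would
fuse across the inverted LTR between them. The 5,000/50/100 bp
thresholds have no published counterpart (the original reassembly was
manual); they are exposed in the API and calibrated only against
synthetic truth.

Assembly chains adjacent LTR/internal groups within 100 bp into one
element and, deliberately, chains across strands: the inverted-LTR
layout requires it, and orientation is recorded per part. Structure
classes follow the field's definitions — ≥2 internals with ≥3 LTRs is a
multi-LTR tandem, a lone LTR is a solo LTR, otherwise full-length versus
truncated by whether the largest contiguous internal exceeds 7 kb
(strict inequality).

## Lineage calls and mechanism

Flanks are anchored in each outgroup by seed-and-verify mapping: exact
32-mers every 64 bp locate candidate offsets, full-length mismatch
counting scores them (floor 0.9 identity), and a second candidate within
5% of the best returns UNRESOLVED — the segmental-duplication guard. The
signed gap between the two flank images carries the signal:

* gap ≈ element length (±20%) → element PRESENT;
* gap < 0.1 × element length → ABSENT (at a classical locus the two
  images overlap by exactly the TSD length, so the gap is *negative*);
* otherwise the gap is suspicious and is resolved the way a curator
  would: by examining the outgroup sequence between the flanks — if the inter-anchor outgroup sequence shares
  essentially no 20-mers with the element, the locus is ABSENT with the
  gap as the target-deletion size, else UNRESOLVED. This matters
  because published target deletions (6–10,207 bp) routinely exceed 10%
  of, and can exceed, the element length; a pure gap-threshold rule
  would misclassify them.

A locus is human-specific iff no outgroup is PRESENT and at least one is
ABSENT; UNRESOLVED outgroups are non-informative. Mechanism:
CLASSICAL iff TSD ≥ 4 bp and no positive absent-gap; NON_CLASSICAL iff
the junction is blunt and the median absent-gap ≥ 1 bp (ties across an
even number of informative outgroups resolve toward the closest, i.e.
first-listed, outgroup). The 4 bp TSD floor is this package's choice —
no published floor exists — set so the chance of a random ≥4 bp
duplication at a blunt junction stays below ~0.5% per locus (the test
suite checks ≥99% of random junctions scan as blunt). The TSD scan
allows one mismatch from 8 bp up, reflecting post-insertion mutation of
one TSD copy. Microhomology search uses a 15 bp terminal window and
1 bp minimum; the source figures show short exact boxes only, so both
values are defaults, not published quantities.

Solitary LTRs were excluded from the published candidate set;
`lineage_screen(include_solo = FALSE)` reproduces that convention, but
the default screens them, because the synthetic truth includes them and
their TSDs are informative.

## Structure typing

Subtype: type II iff ≥ 50% of the 292 bp boundary segment's consensus
columns align to element bases; type I iff the segment is absent while
≥ 200 aligned bp flank the boundary on each side; NA otherwise. ORF
annotation projects each gene span through one global pairwise alignment
(no spliced or HMM gene models): under 50% projection is MISSING, a net
indel not ≡ 0 (mod 3) is BROKEN_FRAME, otherwise the projected frame is
translated and the first TAG/TGA/TAA reported. TAA is included even
though the source tables happen to list only TAG/TGA — it is a stop
codon. The pol–env fusion is only reportable for type I elements.
Tandem loci are typed and ORF-annotated per internal copy but counted
as one insertion event in summaries.

LTR divergence uses the Kimura two-parameter distance
$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$ over gap-free
columns of a global pairwise alignment with deliberately stiff gap
penalties (open 25, extend 2): with permissive penalties the aligner
converts substitution runs into paired gaps and deflates the distance.
Pairs with fewer than 100 aligned columns, or saturated pairs (a log
argument ≤ 0), return NA with a flag.

## The LTR tree

The published tree came from a likelihood search; this package uses
neighbor joining on the K2P matrix instead — a documented method
substitution. The tree answers one question here: do an element's two
LTRs pair as sisters? NJ answers it deterministically, in milliseconds,
and recovers additive trees exactly, which the test suite exploits as an
oracle. Negative NJ branch lengths are clamped to zero with the deficit
moved to the sister branch, preserving path lengths through the parent.
Bootstrap support is column resampling with replacement; supports below
50% are suppressed in rendered labels but retained in the data. LTRs
under 300 bp are excluded from the alignment with a reason, mirroring
the published exclusion of 23–257 bp LTRs. The bundled aligner is
reference-anchored (center-star to the longest sequence) and adequate
for the substitution-dominated synthetic fixtures; real LTR sets should
be aligned externally and passed in aligned.

## Genomic context

GC content is computed over the 20 kb windows flanking the element —
the element itself excluded, ambiguity codes excluded from both
numerator and denominator. Whether the published calculation excluded
the element is unstated; exclusion of the element only is this
package's contract. Gene density counts distinct gene identifiers
overlapping a 2 Mb window centered on the element midpoint by ≥ 1 bp,
divided by the realized window length in Mb (clipped windows rescale
the denominator). The two windows differ (flanking versus centered)
because the source describes them differently, and both wordings are
followed literally. Recombination context takes the rate of the tile
containing the element midpoint and averages per chromosome arm, to
one decimal.

## Genotyping

In-silico PCR places one primer in each conserved flank and one inside
the internal region. Primer matching allows ≤ 2 mismatches but requires
an exact 3′-terminal base; melting temperature and dimer checks are out
of scope. Products above 12 kb (the long-range PCR ceiling; configurable)
are reported without a band. The three allele states are separable by
flank–flank product size — absent (pre-insertion size), solo LTR
(+ LTR + one TSD), provirus (+ element + one TSD) — with the
flank–internal band marking the internal region; genotypes are the
unique state pair whose pooled signature matches the observed bands
within 5% relative size tolerance, else UNRESOLVED. A locus is
polymorphic iff ≥ 2 distinct haplotype states are observed among
genotyped individuals; no minor-allele-count threshold is applied,
matching the source's qualitative usage. Ungenotypable loci (the
segmental-duplication/centromere analogs) leave the denominator.

The panel frequency scheme (`panel_study_frequencies()`) reproduces the
published pattern at matched scale — 29 loci: 4 ungenotypable, 13 fixed,
9 segregating absent/provirus at 0.5/0.5, 3 segregating all three states
at 0.4/0.4/0.2. With 160 haplotypes per locus, the probability that a
0.5/0.5 locus drifts to monomorphism or a tri-state locus fails to show
all three states is below 10⁻¹⁵, so the realized counts are effectively
deterministic for any seed.

## Problem sizes and runtime

The acceptance-scale runs are: truth recovery on the 2 Mb / 40-locus
default (about half a minute), the LTR tree on a 12-element full-length
genome with 1,000 bootstrap replicates on an 8-taxon fixture (seconds),
and the 29-locus / 80-individual panel (seconds). These sizes were
chosen so the whole suite re-runs comfortably on a laptop while still
exercising every class of planted event several times.

## Known limitations

* The flank mapper assumes substitution-style divergence; indel-diverged
  or rearranged outgroups need an external aligner.
* Gene projection uses one global alignment; elements with internal
  rearrangements beyond simple truncation/nesting would need anchored
  piecewise alignment.
* The inverted-LTR (K124-like) generator plants the depicted end state;
  the two-step inversion/template-switch history is not simulated, so
  nothing here tests mechanism hypotheses for that architecture — nor
  does cherry recovery test gene conversion, which the K115-like swap
  fixture merely *detects* as a broken sister pair.
* `summarize_fixture()`'s genotyped-locus denominator derives the four
  unamplifiable loci from the feature annotations (segmental-duplication
  or centromeric, never observed polymorphic); the source does not name
  them explicitly.
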