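---
title: "Detecting reciprocal translocations from linkage, mate pairs and junction signatures"
author: "TransloMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reciprocal translocations from linkage, mate pairs and junction signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TransloMap)
```

## The problem

A reciprocal translocation exchanges the distal parts of two
non-homologous chromosomes.  Relative to a reference assembly, a carrier
genome has two derived chromosomes (we write 2T8 and 8T2 for an
exchange between chromosomes 2 and 8), and in banana and other crops
such events segregate within wild gene pools, distort meiosis in
structural hybrids, and matter directly to breeding.  Three independent
lines of short-read evidence can reveal them:

1. **Genetic linkage in a selfed progeny.** Markers that are physically
   adjacent on the reference but lie on different chromosomes of the
   parent show a *complete linkage break*, while markers from two
   reference chromosomes that travel together in the parent form
   *trans-chromosome linkage blocks*.
2. **Discordant large-insert mate pairs.** Pairs whose mates map to two
   chromosomes, in the wrong orientation, or with an inflated insert,
   cluster at novel adjacencies; segments absent from the accession
   show zero read coverage.
3. **Signature segment junctions (SSJs).** Once segment architectures
   are known, a junction that exists in exactly one chromosome
   structure is a positive signature of that structure, countable in
   any accession's paired-end data.

TransloMap implements all three, plus a dissimilarity-based factorial
analysis to place carriers within a germplasm panel, and a seeded
synthetic-data generator so the whole pipeline is testable end to end
at desk scale.

## The segment model

Chromosome structures are ordered lists of named segments
(`KaryotypeModel`).  The bundled two-translocation fixture mirrors the
architecture characterized in *Musa acuminata*:

```{r fixture}
fx <- buildFixtureKaryotype(scale = 20000, seed = 1)
genomeKaryotype(fx$translocated)
```

Chromosome 2 (`a-b-c`) and chromosome 8 (`d-e-f`) are rearranged into
`2T8 = a-x-f` and `8T2 = d-y-c`: the micro-segments b (1.2 kb) and e
(3 kb) are lost, and novel breakpoint segments x (600 bp) and y
(1.2 kb) appear.  Chromosomes 1 and 9 rearrange with duplications:
`1T9 = g-h-k1-k2-k3-l` and `9T1 = j-k1-k3-h-i` share h, k1 and k3, and
k2 survives on only one derived chromosome (a heterozygous loss in the
derived set).

`identifySSJs()` computes junction ownership directly from the
structures:

```{r ssjs}
identifySSJs(fx$karyotype)
```

The 2/8 event has eight signatures, two per structure.  For 1/9 no
junction is specific to the reference chromosomes — every reference
adjacency survives somewhere in the derived pair — and three junctions
are specific to the derived structures.  Computed from the printed
structures, `h-k1` belongs to the `g-h-k1-...` structure and `k1-k3` /
`k3-h` to `j-k1-k3-h-i`; published tables sometimes attach these labels
the other way around, so the package always reports ownership derived
from the structures rather than hard-coding labels.

## Reconstruction from adjacency constraints

`reconstructStructures()` enumerates all assignments of segments into a
given number of ordered structures that satisfy the evidence:
required adjacencies (from discordant clusters and from concordant
pairs spanning retained reference junctions), absent segments (zero
coverage), heterozygous deletions (half coverage), and chromosome-end
anchors.  Three semantic choices deserve justification:

* **Closed-world joins.** Structures may only join segments across
  adjacencies present in the constraint set.  Any junction truly
  present in a sequenced genome is spanned by read pairs and therefore
  appears as evidence; allowing unobserved joins admits spurious
  solutions that duplicate segments across chromosomes even for the
  trivial "reference adjacencies only" instance.
* **Runs for fragment contiguity.** Pairwise adjacencies alone do not
  always determine the answer.  For the 1/9 architecture the
  constraint set `{k1-k3, k3-h, h-k1, ...}` admits *two* solutions:
  the true pair and an alternative that swaps which derived chromosome
  carries k2 — and the two are genuinely indistinguishable at the
  mate-pair level (identical adjacency sets and segment copy numbers).
  What resolves it is fragment-level contiguity — local assembly
  showing the k1-k3 deletion fragment joined to h on one molecule —
  expressed here as a `required_run` constraint (`k1-k3-h`), after
  which the solution is unique.  `interpretClusters()` accordingly
  reports the full solution set and accepts such run constraints as
  `extraConstraints`; it never fabricates contiguity the reads cannot
  support.
* **Anchors are positional.** A chromosome-end segment may only begin
  (or end) a structure; when the number of anchors equals the number
  of structures being built, every structure must start (end) with
  one.  These are logical deductions, so the exhaustive search with
  them prunes nothing valid.  Instances are capped at 12 active
  segments (the search is exponential; real breakpoint regions
  decompose into far fewer derived segments).

## Mate-pair characterization

`classifyPairs()` labels each pair concordant, insert-size discordant,
orientation discordant, interchromosomal, or unmapped, using the
declared library model (5 kb ± 300 bp inserts, forward-reverse
orientation, acceptance window mean ± 4 SD).  `clusterDiscordant()`
single-links discordant pairs that share a class and sit within one
insert length on both sides (support floor 5 pairs, mapping quality
floor 10).  `detectUncoveredSegments()` reports zero-coverage runs of
at least 500 bp.

`interpretClusters()` cuts the reference at cluster footprint edges
(the junction faces the strand of the supporting mates) and at
zero-coverage boundaries — the latter are sharper (± one read length)
and win when both fall within `mergeTol` (500 bp) — then emits
constraints and reconstructs.  Structural heterozygotes superimpose
the reference and rearranged chromosome sets, so when no solution
exists with one structure per template the solver is re-run with twice
as many; success there is itself the heterozygosity call.  Breakpoint
zygosity from concordant spanning pairs is *only informative where the
reconstructed structures do not retain the reference junction*: for
duplication-rich events like 1/9, every reference junction survives,
spanning pairs are expected regardless of zygosity, and the call is
honestly `undetermined` — segregation data must arbitrate, which is
exactly what the linkage module provides.

## Linkage scanning

`pairwiseLinkage()` estimates recombination fractions for all marker
pairs of a selfed F2 by maximum likelihood with unknown phase: an EM
algorithm treats the double heterozygote as a mixture of parental and
recombinant gamete pairs, runs under both phases (the repulsion table
is the coupling table with one marker's dosage flipped), and keeps the
phase with the higher likelihood; `LOD = log10 L(r̂)/L(0.5)`.  The
update is elementwise over the nine pair-count matrices, so a few
hundred markers take about a second.  Two caveats are documented
rather than hidden: the estimator is truncated at 0.5 and maximized
over phase, so over truly unlinked pairs at n ≈ 67 its mean sits near
0.45 (it is consistent — the mean approaches 0.5 as n grows), and LOD,
not r̂, should decide linkage (95th percentile LOD of unlinked pairs
is < 2).

`detectLinkageBreaks()` reports a break between consecutive markers
when the median LOD of the 10 × 10 cross-boundary pairs falls below 3
while both flank medians stay at or above it; within a run of
qualifying boundaries the physical break is placed at the gap whose
two flanking markers are themselves unlinked.
`detectTranslocationSignal()` single-links markers at LOD ≥ 3 ignoring
chromosome assignment and decomposes clusters spanning two or more
reference chromosomes into reciprocal blocks.

## SSJ genotyping

`countJunctionSupport()` counts concordant pairs with one mate
entirely inside `(J − 1000, J]` and the other entirely inside
`[J, J + 1000)`; a mate overlapping the junction point is not "on
either side" and is excluded by default (a spanning-read mode exists
behind a flag).  Detection needs 3 supporting pairs — at 20× coverage
this guards against stray mismapping while leaving detection
essentially certain when the junction is present.

Because polymorphism near a junction can abolish mapping on one
template, `multiTemplateTyping()` counts support against each template
independently and ORs detections (support is reported per template,
never summed).  The decision table is positive-evidence-only: all
alternative signatures with no reference signal is `hom_alt`; both
reference chromosomes plus any alternative signal is `het`; both
reference chromosomes alone is `hom_ref`; evidence missing for one
chromosome of the group is `partial`; nothing is `undetermined`.  When
one member of a reciprocal pair is detected without its partner, the
partner is recorded as an *inference* (`inferredComplement`) — a
diploid lacking it would miss a chromosome segment, which is assumed
gametically lethal — and never as a detection.  Consequences worth
stating: a 1/9 `hom_ref` accession is `undetermined` (nothing to
detect), and a 1/9 heterozygote is indistinguishable from `hom_alt` by
SSJs alone.

## Diversity analysis

`dissimilarityMatrix()` scores complete diallelic sites 0 / 0.5 / 1
(identical / het-vs-hom / opposite homozygotes) and averages —
literally the proportion of unmatching alleles.
`factorialAnalysis()` is classical metric principal coordinates
(double-center −D²/2, eigendecompose, scale by √λ); negative
eigenvalues are reported with a warning and excluded only from the
percent-variance denominator.  `projectSupplementary()` uses the Gower
add-a-point formula *including* the double-centering diagonal term:
that term is what makes an active point supplied as supplementary
recover its own coordinates exactly.  A consequence: a supplementary
point equidistant from all actives projects to the origin only when
the actives are themselves equidistant from their centroid (e.g. a
regular simplex); in general it does not, and the package makes no
such claim.

## The synthetic-data generator

`buildFixtureKaryotype()` draws macro-segments at `scale` bp (± 20 %
seeded jitter; default 50 kb) with the micro-segments fixed at their
characterized sizes, and i.i.d. uniform base composition.
`simulateReadPairs()` draws fragments from an accession's two
haplotype structure sets in proportion to length, inserts Normal and
truncated at twice the read length, and computes truth alignments by
coordinate arithmetic; mates in segments the template lacks are
unmapped, and multi-copy placements are resolved pair-aware, like a
real aligner scoring pair concordance.  Substitution errors are
optional; indels, PCR duplicates and empirical error profiles are
deliberately out of scope.

`simulateSelfProgeny()` places marker sites on *segments* and calls an
offspring's genotype from the summed allele dosage over **all** copies
of that segment it inherits, emulating a mapping pipeline that piles
reads from every copy onto one projected position.  Single-copy sites
segregate 1:2:1; sites on segments duplicated across the derived 1/9
chromosomes segregate ≈ 1:14:1 and are removed by the χ² filter
(Pearson, df 2, asymptotic p, α = 4 × 10⁻⁶) — reproducing the
real-data mechanism that empties duplicated breakpoint regions of
usable markers and makes the linkage breaks clean.  Meiosis is
Haldane (Poisson crossovers, default one crossover-Morgan per
structure, a free parameter recorded in the provenance log);
structural-heterozygote meiosis (quadrivalents, semi-sterility) is not
modelled and is refused.

`simulateAccessionPanel()` uses a two-level allele-frequency model
(ancestral frequency Uniform(0.05, 0.95); Balding–Nichols Beta
perturbation with group divergence F, default 0.15; admixed accessions
draw one allele per site from each parent group) and simulates
breakpoint-region read sets for the same individuals, so SSJ calls and
factorial placement can be cross-validated.

What passing tests on these simulations do **not** show: robustness to
repeat-induced mismapping, indel alignment artefacts, GC or coverage
bias, restriction-site marker clustering, or reference bias beyond the
simple divergent-patch emulation used for the multi-template tests.
The generator is a correctness harness, not an error-model study.

## Problem sizes and numerical choices

The packaged analyses run at fixture scale 50 kb (genome ≈ 0.6 Mb),
30× mate-pair and 20× paired-end coverage, progenies of 100
individuals × 400 markers, and panels of tens of accessions; the full
pipeline (`runPipeline()`) completes in well under a minute per seed
on one CPU, and the bundled end-to-end acceptance checks repeat it
across 20 seeds.  EM iterates to |Δr| < 10⁻⁸ (cap 100 iterations) with
r clamped to [10⁻⁷, 0.5]; ties at r = 0.5 give LOD 0.  All
coordinates are 0-based half-open internally, converted to 1-based at
VCF/SAM boundaries.  Every stochastic step takes an explicit seed and
identical seeds give byte-identical outputs, including the pipeline
report (timings go to a log file, not the report).

## Known limitations

* Reconstruction is exhaustive and capped at 12 active segments.
* Inversions are carried in the data model (orientation flags) but
  not exercised; the two modelled events involve none.
* Mate-pair zygosity is undetermined for events that retain every
  reference junction (1/9-type); linkage or long-range data decide.
* The linkage matrix is dense; thousands of markers are fine, tens of
  thousands are not — the intended use is per-chromosome scans of
  filtered marker sets.
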