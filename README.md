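# TransloMap

Detection and characterization of large reciprocal chromosomal
translocations from short-read evidence, for plant genomicists working
with a reference assembly and collections of resequenced accessions.

A reciprocal translocation exchanges the distal regions of two
non-homologous chromosomes: a carrier of an exchange between
chromosomes 2 and 8 has derived chromosomes 2T8 and 8T2 instead of (or
alongside) the reference pair. TransloMap implements the three
complementary detection strategies such events admit, plus the
population-level placement of carriers:

* **Linkage scanning** of a selfed F2 progeny: pairwise recombination
  fractions are estimated for phase-unknown codominant markers by EM
  (the double heterozygote is a mixture of parental and recombinant
  gamete pairs; both phases are evaluated and the better likelihood
  wins), with `LOD = log10 L(r̂)/L(0.5)`. Complete linkage breaks and
  trans-chromosome linkage blocks localize the rearrangement on the
  reference.
* **Discordant mate-pair analysis**: classification of 5 kb-insert
  pairs against a declared library model, single-linkage clustering of
  discordant pairs, zero-coverage detection of lost segments, and a
  combinatorial reconstruction of chromosome structures from the
  resulting adjacency constraints (required adjacencies, runs, absent
  segments, heterozygous deletions, chromosome-end anchors), with
  per-breakpoint zygosity from concordant spanning pairs.
* **Signature segment junction (SSJ) genotyping**: a junction present
  in exactly one chromosome structure is positive evidence for that
  structure; properly mapped pairs flanking it within 1000 bp windows
  are counted per accession, across multiple reference templates with
  OR-merged detection. Only positive results are interpreted; missing
  reciprocal partners are reported as inference, never detection.
* **Factorial analysis**: allele-mismatch dissimilarities (0 / 0.5 / 1
  per site), classical principal coordinates, and supplementary
  projection of additional accessions onto axes computed from a core
  (e.g. wild) set.

A deterministic synthetic-data generator builds desk-scale rearranged
genomes (the bundled fixture reproduces the segment architectures
`chr2 = a-b-c`, `chr8 = d-e-f`, `2T8 = a-x-f`, `8T2 = d-y-c` and
`chr1 = g-h-i`, `chr9 = j-k1-k2-k3-l`, `1T9 = g-h-k1-k2-k3-l`,
`9T1 = j-k1-k3-h-i`), read pairs with truth alignments, selfed
progenies and structured accession panels, so every stage is testable
without external data.

## Worked example

```r
library(TransloMap)

fx  <- buildFixtureKaryotype(scale = 50000, seed = 1)
lib <- libraryModel(5000, 300, 150, coverage = 30)
c4  <- accessionSpec("C4like", "burmannica_like",
                     c(`2/8` = "hom_alt", `1/9` = "hom_alt"))

pr  <- simulateReadPairs(fx, c4, lib, seed = 5)
clu <- clusterDiscordant(pr, lib)
unc <- detectUncoveredSegments(pr, fx$reference)
ic  <- interpretClusters(clu, unc, fx$reference, pr, lib)

ic$calls[["chr2+chr8"]]$type
#> [1] "reciprocal_translocation"
ic$calls[["chr2+chr8"]]$zygosity
#> [1] "homozygous_rearranged"
sapply(ic$calls[["chr2+chr8"]]$structures[[1]], paste, collapse = "-")
#> [1] "chr2.s1-chr8.s3" "chr8.s1-chr2.s3"
nrow(unc)   # the two lost micro-segments b (1.2 kb) and e (3 kb)
#> [1] 2
```

The 2/8 call is a homozygous reciprocal translocation: the derived
structures join the proximal part of chromosome 2 (`chr2.s1`, segment
a) to the distal part of chromosome 8 (`chr8.s3`, segment f) and vice
versa, exactly the simulated 2T8/8T2 architecture; the two
zero-coverage intervals are the lost b and e segments. For the 1/9
event the same call reports the full solution set (two structure pairs
are genuinely indistinguishable from mate pairs alone) and zygosity
`undetermined`, with `extraConstraints` accepting fragment-contiguity
evidence that collapses it to the unique answer.

SSJ identification on the fixture karyotype:

```r
identifySSJs(fx$karyotype)
#>    structure left right
#> 1        1T9    h    k1
#> 2        2T8    a     x
#> 3        2T8    x     f
#> 4        8T2    d     y
#> 5        8T2    y     c
#> 6        9T1   k1    k3
#> 7        9T1   k3     h
#> 8       chr2    a     b
#> 9       chr2    b     c
#> 10      chr8    d     e
#> 11      chr8    e     f
```

Eight signatures for the 2/8 event (two per structure), three for the
derived 1/9 chromosomes, none for reference chromosomes 1 and 9 —
which is why 1/9 reference homozygotes are `undetermined` and only
positive junction evidence is ever interpreted.

`runPipeline(runConfig(seed = 42))` chains all stages (simulate →
filter → linkage → mate-pair SV → SSJ typing → diversity) into a run
directory with per-stage outputs and a consolidated `report.json`
cross-checked against the simulator truth manifest.

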