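test_that("fixture karyotype matches the two-translocation architecture", {
    fx <- testFixture()
    kar <- fx$karyotype
    expect_identical(structureSegments(kar, "2T8")$segment,
                     c("a", "x", "f"))
    expect_identical(structureSegments(kar, "8T2")$segment,
                     c("d", "y", "c"))
    expect_identical(structureSegments(kar, "1T9")$segment,
                     c("g", "h", "k1", "k2", "k3", "l"))
    expect_identical(structureSegments(kar, "9T1")$segment,
                     c("j", "k1", "k3", "h", "i"))
    seg <- segmentCatalog(kar)
    lens <- setNames(seg$length, seg$name)
    expect_identical(lens[c("b", "e", "x", "y")],
                     c(b = 1200, e = 3000, x = 600, y = 1200))
    macro <- setdiff(seg$name, c("b", "e", "x", "y"))
    expect_true(all(lens[macro] >= 0.8 * 50000 &
                    lens[macro] <= 1.2 * 50000))
    # micro-segments shorter than any macro-segment even at minimum scale
    fx10 <- buildFixtureKaryotype(scale = 10000, seed = 3)
    l10 <- setNames(segmentCatalog(fx10$karyotype)$length,
                    segmentCatalog(fx10$karyotype)$name)
    expect_true(all(l10[c("b", "e", "x", "y")] <
                    min(l10[setdiff(names(l10), c("b", "e", "x", "y"))])))
    expect_error(buildFixtureKaryotype(scale = 9999), "scale")
})

test_that("genome sequences are deterministic and segment-consistent", {
    fx1 <- buildFixtureKaryotype(scale = 20000, seed = 7)
    fx2 <- buildFixtureKaryotype(scale = 20000, seed = 7)
    expect_identical(as.character(genomeSequences(fx1$reference)),
                     as.character(genomeSequences(fx2$reference)))
    f1 <- withr::local_tempfile(fileext = ".fa")
    f2 <- withr::local_tempfile(fileext = ".fa")
    writeGenomeFASTA(fx1$translocated, f1)
    writeGenomeFASTA(fx2$translocated, f2)
    expect_identical(readLines(f1), readLines(f2))

    # shared segments carry identical sequence wherever they appear
    getSeg <- function(genome, structure, segment) {
        sc <- segmentCoords(genome)
        r <- sc[sc$structure == structure & sc$segment == segment, ][1, ]
        as.character(Biostrings::subseq(genomeSequences(genome)[[structure]],
                                        r$start + 1, r$end))
    }
    expect_identical(getSeg(fx1$reference, "chr2", "a"),
                     getSeg(fx1$translocated, "2T8", "a"))
    expect_identical(getSeg(fx1$translocated, "1T9", "k1"),
                     getSeg(fx1$translocated, "9T1", "k1"))

    # sequence length bookkeeping (class validity enforces it; spot-check)
    seg <- segmentCatalog(fx1$karyotype)
    lens <- setNames(seg$length, seg$name)
    for (nm in names(genomeSequences(fx1$reference)))
        expect_identical(
            length(genomeSequences(fx1$reference)[[nm]]),
            as.integer(sum(lens[structureSegments(fx1$karyotype,
                                                  nm)$segment])))
})

test_that("truth alignments are consistent with the template sequence", {
    fx <- testFixture(scale = 20000, seed = 2)
    lib <- libraryModel(2000, 150, 100, coverage = 2)
    pr <- simulateReadPairs(fx, accHomAlt(), lib, seed = 11,
                            emitSequences = TRUE)
    seqs <- as.character(genomeSequences(fx$reference))
    s1 <- attr(pr, "seq1"); s2 <- attr(pr, "seq2")
    m1 <- !is.na(pr$tmpl1)
    expect_identical(
        unname(substring(seqs[pr$tmpl1[m1]], pr$start1[m1] + 1,
                         pr$end1[m1])),
        unname(s1[m1]))
    m2 <- !is.na(pr$tmpl2)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s2[m2])))
    expect_identical(
        unname(substring(seqs[pr$tmpl2[m2]], pr$start2[m2] + 1,
                         pr$end2[m2])),
        unname(rc))
})

test_that("read simulation honours structural genotype and coverage", {
    fx <- testFixture()
    lib <- matePairLib()
    prRef <- testPairs("hom_ref")
    clsRef <- classifyPairs(prRef, lib)
    # concordant up to the insert-size tail
    expect_lt(mean(clsRef != "concordant"), 2e-3)
    expect_identical(sum(is.na(prRef$tmpl1)), 0L)

    prAlt <- testPairs("hom_alt")
    clsAlt <- classifyPairs(prAlt, lib)
    expect_gt(sum(clsAlt == "discordant_interchromosomal"), 100)
    # the lost micro-segments b and e have no mapped reads at all
    sc <- segmentCoords(fx$reference)
    for (sg in c("b", "e")) {
        r <- sc[sc$segment == sg, ]
        hit1 <- !is.na(prAlt$tmpl1) & prAlt$tmpl1 == r$structure &
            prAlt$end1 > r$start & prAlt$start1 < r$end
        hit2 <- !is.na(prAlt$tmpl2) & prAlt$tmpl2 == r$structure &
            prAlt$end2 > r$start & prAlt$start2 < r$end
        expect_identical(sum(hit1) + sum(hit2), 0L)
    }

    # zero coverage -> empty output; determinism
    expect_identical(
        nrow(simulateReadPairs(fx, accHomRef(),
                               libraryModel(5000, 300, 150, coverage = 0),
                               seed = 1)), 0L)
    expect_identical(simulateReadPairs(fx, accHomAlt(), lib, seed = 5),
                     prAlt)
})

test_that("expected pair count scales as coverage * genome / (2 read length)", {
    fx <- testFixture()
    lib <- matePairLib(coverage = 10)
    pr <- simulateReadPairs(fx, accHomRef(), lib, seed = 21)
    gsize <- sum(Biostrings::width(genomeSequences(fx$reference)))
    expected <- 10 * gsize / (2 * 150)
    expect_lt(abs(nrow(pr) - expected) / expected, 0.05)
})

test_that("SAM and FASTQ writers round-trip the simulated pairs", {
    fx <- testFixture(scale = 20000, seed = 2)
    lib <- libraryModel(2000, 150, 100, coverage = 1)
    pr <- simulateReadPairs(fx, accHomAlt(), lib, seed = 13,
                            emitSequences = TRUE)
    sam <- withr::local_tempfile(fileext = ".sam")
    writeAlignmentSAM(pr, fx$reference, sam)
    back <- readAlignmentSAM(sam)
    expect_identical(back$qname, pr$qname)
    expect_equal(back$start1, pr$start1)
    expect_equal(back$end2, pr$end2)
    expect_identical(back$strand2[!is.na(back$tmpl2)],
                     pr$strand2[!is.na(pr$tmpl2)])
    expect_equal(back$mapq1, pr$mapq1)

    pre <- withr::local_tempfile()
    paths <- writeReadPairsFASTQ(pr, pre)
    r1 <- readLines(paths[1])
    expect_identical(length(r1), 4L * nrow(pr))
    expect_identical(sub("/1$", "", sub("^@", "", r1[1])), pr$qname[1])
    expect_identical(r1[2], unname(attr(pr, "seq1")[1]))
})

test_that("self-progeny single-copy markers segregate 1:2:1", {
    fx <- testFixture()
    gm <- simulateSelfProgeny(fx, accHomRef(), nIndividuals = 5000,
                              nMarkers = 60, seed = 17)
    calls <- genotypeCalls(gm)
    truth <- provenanceLog(gm)$truth
    single <- truth$copies == 1
    # one marker, binomial check at 3 SD as for the generating design
    v <- calls[which(single)[1], ]
    n <- length(v)
    for (g in 0:2) {
        p <- c(0.25, 0.5, 0.25)[g + 1]
        expect_lt(abs(mean(v == g) - p), 3 * sqrt(p * (1 - p) / n))
    }
    expect_true(all(calls %in% c(0L, 1L, 2L)))
})

test_that("self-progeny projection and guards behave", {
    fx <- testFixture()
    gm <- simulateSelfProgeny(fx, accHomAlt(), 20, 100, seed = 19)
    mk <- markerInfo(gm)
    # all projected positions lie on reference chromosomes within bounds
    refLen <- tapply(segmentCoords(fx$reference)$end,
                     segmentCoords(fx$reference)$structure, max)
    expect_true(all(mk$chrom %in% names(refLen)))
    expect_true(all(mk$pos >= 1 & mk$pos <= refLen[mk$chrom]))
    # no markers survive in novel segments
    expect_false(any(provenanceLog(gm)$truth$segment %in% c("x", "y")))
    # duplicated segments produce multi-copy sites
    expect_setequal(
        unique(provenanceLog(gm)$truth$segment[
            provenanceLog(gm)$truth$copies == 2]),
        c("h", "k1", "k3"))
    expect_error(simulateSelfProgeny(fx, accHet28(), 20, 100, seed = 1),
                 "heterozygotes")
    expect_error(simulateSelfProgeny(fx, accHomRef(), 20, 1e5, seed = 1),
                 "spacing")
})

test_that("panel genotypes follow the group allele-frequency model", {
    fx <- testFixture()
    specs <- c(lapply(1:10, function(i)
                   accessionSpec(sprintf("A%02d", i), "g1",
                                 c(`2/8` = "hom_ref", `1/9` = "hom_ref"),
                                 snpDivergence = 0.15)),
               lapply(1:10, function(i)
                   accessionSpec(sprintf("B%02d", i), "g2",
                                 c(`2/8` = "hom_ref", `1/9` = "hom_ref"),
                                 snpDivergence = 0.15)))
    pan <- simulateAccessionPanel(fx, specs, nSnps = 400, seed = 23,
                                  library = NULL)
    G <- genotypeCalls(pan$genotypes)
    expect_false(anyNA(G))
    D <- dissimilarityMatrix(pan$genotypes)
    within <- c(D[1:10, 1:10][upper.tri(diag(10))],
                D[11:20, 11:20][upper.tri(diag(10))])
    between <- as.vector(D[1:10, 11:20])
    expect_gt(mean(between), mean(within))

    # divergence 0: within- and between-group pairs exchangeable
    specs0 <- lapply(specs, function(s) { s$snpDivergence <- 0; s })
    pan0 <- simulateAccessionPanel(fx, specs0, nSnps = 400, seed = 23,
                                   library = NULL)
    D0 <- dissimilarityMatrix(pan0$genotypes)
    w0 <- c(D0[1:10, 1:10][upper.tri(diag(10))],
            D0[11:20, 11:20][upper.tri(diag(10))])
    b0 <- as.vector(D0[1:10, 11:20])
    expect_gt(t.test(w0, b0)$p.value, 0.01)

    expect_error(simulateAccessionPanel(fx, specs[1:10], 400, 1,
                                        library = NULL), "two groups")
})
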