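mkPair <- function(t1, s1, st1, t2, s2, st2, len = 150, mapq = 60,
                   qname = "q") {
    data.frame(qname = qname, srcStructure = NA, srcStart = NA,
               insert = NA, hap = NA,
               tmpl1 = t1, start1 = s1, end1 = s1 + len, strand1 = st1,
               mapq1 = ifelse(is.na(t1), 0, mapq),
               tmpl2 = t2, start2 = s2, end2 = s2 + len, strand2 = st2,
               mapq2 = ifelse(is.na(t2), 0, mapq))
}

test_that("pair classification covers the five outcomes", {
    lib <- matePairLib()
    p <- rbind(
        mkPair("chrA", 1000, "+", "chrA", 5900, "-"),   # span 5050
        mkPair("chr2", 1000, "+", "chr8", 2000, "-"),   # interchrom
        mkPair("chrA", 1000, "+", "chrA", 80850, "-"),  # span 80000
        mkPair("chrA", 1000, "+", "chrA", 5900, "+"),   # orientation
        mkPair("chrA", 1000, "+", NA, NA, NA))          # unmapped mate
    expect_identical(classifyPairs(p, lib),
                     c("concordant", "discordant_interchromosomal",
                       "discordant_large_insert",
                       "discordant_orientation", "unmapped"))
    bad <- mkPair("chrA", -5, "+", "chrA", 5900, "-")
    expect_error(classifyPairs(bad, lib), "negative")
})

test_that("discordant clustering groups co-located pairs and applies the support floor", {
    lib <- matePairLib()
    set.seed(59)
    # 20 interchromosomal pairs within 2 kb on each side: one cluster
    grp <- do.call(rbind, lapply(1:20, function(i)
        mkPair("chr2", 40000 + i * 100, "+", "chr8", 60000 + i * 100,
               "-", qname = paste0("g", i))))
    # 2 isolated pairs far away
    iso <- rbind(mkPair("chr2", 500, "+", "chr8", 500, "-", qname = "x1"),
                 mkPair("chr2", 900, "+", "chr8", 900, "-", qname = "x2"))
    cl <- clusterDiscordant(rbind(grp, iso), lib)
    expect_identical(nrow(cl), 1L)
    expect_identical(cl$support, 20L)
    expect_identical(cl$tmplA, "chr2")
    expect_identical(cl$startA, 40100)
    expect_identical(cl$endA, 42150)

    # order independence
    perm <- rbind(grp, iso)[sample(22), ]
    expect_identical(clusterDiscordant(perm, lib), cl)

    # support floor: nothing below 5
    expect_identical(nrow(clusterDiscordant(iso, lib)), 0L)
    # every pair in at most one cluster: total support <= pair count
    expect_lte(sum(cl$support), 22L)
    # low-quality pairs are ignored
    grpLow <- grp
    grpLow$mapq1 <- 5
    expect_identical(nrow(clusterDiscordant(grpLow, lib)), 0L)
})

test_that("zero-coverage detection finds the lost micro-segments only", {
    fx <- testFixture()
    prAlt <- testPairs("hom_alt")
    unc <- detectUncoveredSegments(prAlt, fx$reference)
    expect_identical(nrow(unc), 2L)
    sc <- segmentCoords(fx$reference)
    for (sg in c("b", "e")) {
        r <- sc[sc$segment == sg, ]
        hit <- unc[unc$tmpl == r$structure, ]
        expect_lte(abs(hit$start - r$start), 150)
        expect_lte(abs(hit$end - r$end), 150)
    }
    # heterozygously deleted k2 is covered (half depth), never reported
    k2 <- sc[sc$segment == "k2", ]
    expect_false(any(unc$tmpl == k2$structure &
                     unc$start < k2$end & unc$end > k2$start))

    prRef <- testPairs("hom_ref")
    expect_identical(nrow(detectUncoveredSegments(prRef, fx$reference)),
                     0L)
})

test_that("cluster interpretation reconstructs both reciprocal translocations", {
    fx <- testFixture()
    lib <- matePairLib()
    pr <- testPairs("hom_alt")
    clu <- clusterDiscordant(pr, lib)
    unc <- detectUncoveredSegments(pr, fx$reference)
    ic <- interpretClusters(clu, unc, fx$reference, pr, lib)
    expect_setequal(names(ic$calls), c("chr1+chr9", "chr2+chr8"))

    c28 <- ic$calls[["chr2+chr8"]]
    expect_identical(c28$type, "reciprocal_translocation")
    expect_identical(c28$zygosity, "homozygous_rearranged")
    expect_length(c28$structures, 1L)
    # map derived segments back to fixture names via coordinates
    segName <- function(dseg) {
        s <- ic$segments[ic$segments$name == dseg, ]
        sc <- segmentCoords(fx$reference)
        sc$segment[sc$structure == s$tmpl &
                   abs(sc$start - s$start) <= 500 &
                   abs(sc$end - s$end) <= 500]
    }
    sol28 <- lapply(c28$structures[[1]], function(p)
        vapply(p, function(x) segName(x)[1], ""))
    expect_identical(unname(sol28[[1]]), c("a", "f"))
    expect_identical(unname(sol28[[2]]), c("d", "c"))

    c19 <- ic$calls[["chr1+chr9"]]
    expect_identical(c19$type, "reciprocal_translocation")
    expect_identical(c19$zygosity, "undetermined")
    # mate-pair evidence leaves the documented two-way ambiguity; the
    # true pair is always among the solutions
    keys <- vapply(c19$structures, function(s)
        paste(vapply(s, function(p)
            paste(vapply(p, function(x) segName(x)[1], ""),
                  collapse = "-"), ""), collapse = " / "), "")
    expect_true("g-h-k1-k2-k3-l / j-k1-k3-h-i" %in% keys)
    expect_lte(length(keys), 2L)

    # scaffold-level fragment contiguity collapses it to the truth
    segs19 <- ic$segments[ic$segments$tmpl %in% c("chr1", "chr9"), ]
    segOf <- function(seg) {
        sc <- segmentCoords(fx$reference)
        hit <- sc[sc$segment == seg, ]
        segs19$name[segs19$tmpl == hit$structure &
                    abs(segs19$start - hit$start) <= 500]
    }
    run <- adjacencyConstraint("required_run",
                               c(segOf("k1"), segOf("k3"), segOf("h")))
    ic2 <- interpretClusters(clu, unc, fx$reference, pr, lib,
                             extraConstraints = list(run))
    expect_length(ic2$calls[["chr1+chr9"]]$structures, 1L)
})

test_that("breakpoints are localized within one insert SD of the truth", {
    fx <- testFixture()
    lib <- matePairLib()
    pr <- testPairs("hom_alt")
    clu <- clusterDiscordant(pr, lib)
    # every true novel junction (alt-structure cut on the reference)
    # must fall inside a cluster footprint extended by one insert SD
    truthCuts <- data.frame(
        tmpl = c("chr2", "chr8", "chr8", "chr2", "chr1", "chr9", "chr9",
                 "chr1", "chr9", "chr9"),
        pos = c(fx$junctions$coord[fx$junctions$structure == "chr2"][1],
                fx$junctions$coord[fx$junctions$structure == "chr8"][2],
                fx$junctions$coord[fx$junctions$structure == "chr8"][1],
                fx$junctions$coord[fx$junctions$structure == "chr2"][2],
                fx$junctions$coord[fx$junctions$structure == "chr1"][1],
                fx$junctions$coord[fx$junctions$structure == "chr9"][1],
                fx$junctions$coord[fx$junctions$structure == "chr9"][2],
                fx$junctions$coord[fx$junctions$structure == "chr1"][2],
                fx$junctions$coord[fx$junctions$structure == "chr9"][3],
                fx$junctions$coord[fx$junctions$structure == "chr9"][4]))
    sd1 <- lib$insertSd
    for (i in seq_len(nrow(truthCuts))) {
        tc <- truthCuts[i, ]
        inA <- clu$tmplA == tc$tmpl & clu$startA - sd1 <= tc$pos &
            clu$endA + sd1 >= tc$pos
        inB <- clu$tmplB == tc$tmpl & clu$startB - sd1 <= tc$pos &
            clu$endB + sd1 >= tc$pos
        expect_true(any(inA | inB), label = sprintf(
            "junction %s:%d inside an extended footprint", tc$tmpl,
            tc$pos))
    }
})

test_that("zygosity calls separate hom_alt, het and hom_ref accessions", {
    fx <- testFixture()
    lib <- matePairLib()
    run <- function(which) {
        pr <- testPairs(which)
        clu <- clusterDiscordant(pr, lib)
        unc <- detectUncoveredSegments(pr, fx$reference)
        interpretClusters(clu, unc, fx$reference, pr, lib)
    }
    het <- run("het")
    expect_identical(names(het$calls), "chr2+chr8")
    expect_identical(het$calls[[1]]$type, "reciprocal_translocation")
    expect_identical(het$calls[[1]]$zygosity, "heterozygous")
    # the 4-structure solution carries both the reference and the
    # translocated chromosome sets
    expect_length(het$calls[[1]]$structures[[1]], 4L)

    ref <- run("hom_ref")
    expect_length(ref$calls, 0L)
})

test_that("clusters with unmodelled strand patterns surface as uninterpreted, never silently", {
    lib <- matePairLib()
    # same-strand pairs on both sides fit no translocation junction model
    grp <- do.call(rbind, lapply(1:8, function(i)
        mkPair("chr2", 40000 + i * 100, "+", "chr8", 60000 + i * 100,
               "+", qname = paste0("w", i))))
    clu <- clusterDiscordant(grp, lib)
    expect_identical(nrow(clu), 1L)
    fx <- testFixture()
    ic <- interpretClusters(clu, grp[0, ], fx$reference, grp, lib)
    expect_length(ic$calls, 1L)
    expect_identical(ic$calls[[1]]$type, "uninterpreted_cluster_pattern")
})
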