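mkProper <- function(tmpl, s1, s2, len = 150, mapq = 60, qname = "q") {
    data.frame(qname = qname, srcStructure = NA, srcStart = NA,
               insert = NA, hap = NA,
               tmpl1 = tmpl, start1 = s1, end1 = s1 + len, strand1 = "+",
               mapq1 = mapq,
               tmpl2 = tmpl, start2 = s2, end2 = s2 + len, strand2 = "-",
               mapq2 = mapq)
}

test_that("junction support counts pairs flanking the junction strictly", {
    lib <- pairedEndLib()
    J <- 10000
    # 7 proper pairs (insert within 500 +/- 4*50) straddling within the
    # 1 kb windows
    inWin <- do.call(rbind, lapply(1:7, function(i)
        mkProper("T", J - 200 - i * 10, J + 20 + i * 10,
                 qname = paste0("in", i))))
    # 2 proper pairs beyond the window
    outWin <- rbind(mkProper("T", J - 5000, J - 4650, qname = "o1"),
                    mkProper("T", J + 3000, J + 3400, qname = "o2"))
    # one mate overlapping the junction point: excluded
    cross <- mkProper("T", J - 75, J + 300, qname = "c1")
    pr <- rbind(inWin, outWin, cross)
    expect_identical(countJunctionSupport(pr, lib, "T", J), 7L)
    # spanning-read mode counts the crossing pair too
    expect_identical(countJunctionSupport(pr, lib, "T", J,
                                          countSpanningReads = TRUE), 8L)
    # no alignments
    expect_identical(countJunctionSupport(pr[0, ], lib, "T", J), 0L)
    expect_error(countJunctionSupport(pr, lib, "T", J, window = 100),
                 "read length")
    # MAPQ floor
    low <- inWin; low$mapq2 <- 5
    expect_identical(countJunctionSupport(low, lib, "T", J), 0L)
    # input order and repeated duplicate removal do not matter
    shuf <- pr[rev(seq_len(nrow(pr))), ]
    expect_identical(countJunctionSupport(shuf, lib, "T", J), 7L)
    dedup <- unique(unique(rbind(pr, pr)))
    expect_identical(countJunctionSupport(dedup, lib, "T", J), 7L)
})

supportDF <- function(structure, left, right, support)
    data.frame(structure = structure, left = left, right = right,
               support = support)

grp28 <- list(ref = c("chr2", "chr8"), alt = c("2T8", "8T2"))

full28 <- function(ref = c(0, 0, 0, 0), alt = c(0, 0, 0, 0))
    supportDF(c("chr2", "chr2", "chr8", "chr8",
                "2T8", "2T8", "8T2", "8T2"),
              c("a", "b", "d", "e", "a", "x", "d", "y"),
              c("b", "c", "e", "f", "x", "f", "y", "c"),
              c(ref, alt))

test_that("the positive-evidence decision table reproduces the panel archetypes", {
    # all four alt signatures, no reference signal: hom_alt
    gt <- genotypeStructure(full28(alt = c(9, 7, 12, 5)), grp28)
    expect_identical(gt$call, "hom_alt")
    expect_length(gt$inferredComplement, 0L)

    # four ref + three alt: structurally heterozygous
    gt <- genotypeStructure(full28(ref = c(4, 6, 3, 8),
                                   alt = c(5, 4, 6, 0)), grp28)
    expect_identical(gt$call, "het")

    # ref chromosome 2 only: partial, chromosome 8 presence inferred
    gt <- genotypeStructure(full28(ref = c(7, 5, 0, 0)), grp28)
    expect_identical(gt$call, "partial")
    expect_identical(gt$inferredComplement, "chr8")

    # one translocated chromosome without its reciprocal
    gt <- genotypeStructure(full28(ref = c(4, 6, 3, 8),
                                   alt = c(5, 4, 0, 0)), grp28)
    expect_identical(gt$call, "het")
    expect_identical(gt$inferredComplement, "8T2")

    # four ref, nothing else: hom_ref; nothing at all: undetermined
    expect_identical(genotypeStructure(full28(ref = c(5, 5, 5, 5)),
                                       grp28)$call, "hom_ref")
    expect_identical(genotypeStructure(full28(), grp28)$call,
                     "undetermined")
    expect_error(genotypeStructure(supportDF(character(), character(),
                                             character(), numeric()),
                                   grp28), "no SSJs")
})

test_that("raising the support floor only moves calls toward less-detected states", {
    rank <- c(undetermined = 0, partial = 1, hom_alt = 2, hom_ref = 2,
              het = 3)
    sup <- full28(ref = c(4, 6, 3, 8), alt = c(5, 4, 6, 2))
    calls <- vapply(c(1, 3, 5, 7, 10), function(ms)
        genotypeStructure(sup, grp28, minSupport = ms)$call, "")
    expect_true(all(diff(rank[calls]) <= 0))
})

test_that("multi-template typing rescues junctions hidden by local divergence", {
    fx <- testFixture()
    lib <- pairedEndLib()
    acc <- accHomRef("RESC")
    loci <- ssjLoci(fx)
    regions <- data.frame(structure = fx$junctions$structure,
                          start = pmax(0, fx$junctions$coord - 3000),
                          end = fx$junctions$coord + 3000)
    pr <- simulateReadPairs(fx, acc, lib, seed = 61,
                            template = fx$reference, regions = regions)
    # emulate a divergent patch across the chr8 d-e-f breakpoint region
    # on template 1: reads near its junctions fail to map
    j8 <- fx$junctions[fx$junctions$structure == "chr8", ]
    patch <- pr$tmpl1 == "chr8" &
        (abs((pr$start1 + pr$end2) / 2 - j8$coord[1]) < 2800 |
         abs((pr$start1 + pr$end2) / 2 - j8$coord[2]) < 2800)
    patched <- pr
    patched$mapq1[patch] <- 0
    patched$mapq2[patch] <- 0

    gt1 <- multiTemplateTyping(list(t1 = patched), loci, grp28, lib)
    expect_identical(gt1$call, "partial")
    gt2 <- multiTemplateTyping(list(t1 = patched, t2 = pr), loci,
                               grp28, lib)
    expect_identical(gt2$call, "hom_ref")
    # support reported per template, never summed
    expect_identical(ncol(gt2$perTemplate), 2L)
    expect_identical(gt2$perTemplate["chr8 d e", "t1"], 0L)
    expect_gt(gt2$perTemplate["chr8 d e", "t2"], 0L)

    # identical templates: OR is idempotent
    gt3 <- multiTemplateTyping(list(t1 = pr, t2 = pr), loci, grp28, lib)
    gt4 <- multiTemplateTyping(list(t1 = pr), loci, grp28, lib)
    expect_identical(gt3$call, gt4$call)
    # nothing detected anywhere
    gt5 <- multiTemplateTyping(list(t1 = pr[0, ]), loci, grp28, lib)
    expect_identical(gt5$call, "undetermined")
})

test_that("panel SSJ typing matches simulated truth with inference flags only for absences", {
    fx <- testFixture()
    lib <- pairedEndLib()
    specs <- list(accHomAlt("P1"), accHomRef("P2"), accHet28("P3"),
                  accessionSpec("P4", "burmannica_like",
                                c(`2/8` = "hom_alt", `1/9` = "hom_ref")))
    pan <- simulateAccessionPanel(fx, specs, nSnps = 100, seed = 67,
                                  library = lib)
    ty <- typePanelSSJs(pan, fx, lib)
    for (spec in specs) for (g in c("2/8", "1/9")) {
        want <- expectedSSJCall(spec$structuralGenotype[[g]], g)
        expect_identical(ty[[spec$name]][[g]]$call, want,
                         label = sprintf("%s %s call", spec$name, g))
    }
    # positive-only semantics: absences appear only as inference flags;
    # detections never include a structure with zero support
    for (a in names(ty)) for (g in names(ty[[a]])) {
        gt <- ty[[a]][[g]]
        det <- gt$detections
        expect_true(all(det$support[det$detected] >= gt$minSupport))
        expect_false(any(gt$inferredComplement %in%
                         det$structure[det$detected]))
    }
})
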