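test_that("junction enumeration lists every ordered adjacency once with its owners", {
    kar <- karyotype28()
    j <- enumerateJunctions(kar)
    key <- paste(j$left, j$right)
    expect_setequal(key, c("a b", "b c", "d e", "e f",
                           "a x", "x f", "d y", "y c"))
    # incidence conservation: sum over structures of (k - 1)
    expect_identical(sum(lengths(j$structures)),
                     sum(vapply(structureNames(kar), function(nm)
                         nrow(structureSegments(kar, nm)) - 1L, 0L)))

    # duplicated segments create shared junctions
    j19 <- enumerateJunctions(karyotype19())
    gh <- j19[j19$left == "g" & j19$right == "h", "structures"][[1]]
    expect_setequal(gh, c("chr1", "1T9"))

    single <- karyotypeModel(
        segments = data.frame(name = "a", length = 100, origin = "chr1"),
        structures = list(chr1 = "a"))
    expect_identical(nrow(enumerateJunctions(single)), 0L)

    empty <- karyotypeModel(
        segments = data.frame(name = character(), length = numeric(),
                              origin = character()),
        structures = list())
    expect_identical(nrow(enumerateJunctions(empty)), 0L)
})

test_that("the 2/8 architecture yields eight signature junctions, two per structure", {
    s <- identifySSJs(karyotype28())
    expect_identical(nrow(s), 8L)
    expect_true(all(table(s$structure) == 2L))
    expect_setequal(paste(s$left, s$right),
                    c("a b", "b c", "d e", "e f", "a x", "x f",
                      "d y", "y c"))
    # every SSJ is a junction owned by exactly one structure
    j <- enumerateJunctions(karyotype28())
    expect_true(all(paste(s$left, s$right) %in% paste(j$left, j$right)))
})

test_that("the 1/9 architecture has no reference-specific junctions and three translocation-specific ones", {
    s <- identifySSJs(karyotype19())
    expect_identical(sum(s$structure %in% c("chr1", "chr9")), 0L)
    expect_identical(nrow(s), 3L)
    # ownership computed from the structures: h-k1 belongs to the
    # g-h-k1-k2-k3-l structure, k1-k3 and k3-h to j-k1-k3-h-i
    expect_setequal(paste(s$structure, s$left, s$right),
                    c("1T9 h k1", "9T1 k1 k3", "9T1 k3 h"))
})

test_that("identical structures under different names yield no SSJs", {
    kar <- karyotypeModel(
        segments = data.frame(name = c("a", "b"), length = 100,
                              origin = "chr1"),
        structures = list(s1 = c("a", "b"), s2 = c("a", "b")))
    expect_identical(nrow(identifySSJs(kar)), 0L)
})

test_that("reconstruction recovers the printed 1/9 structure pair uniquely", {
    sol <- reconstructStructures(c("g", "h", "i", "j", "k1", "k2", "k3", "l"),
                                 constraints19(), 2)
    expect_length(sol, 1L)
    expect_identical(sol[[1]][[1]], c("g", "h", "k1", "k2", "k3", "l"))
    expect_identical(sol[[1]][[2]], c("j", "k1", "k3", "h", "i"))
})

test_that("dropping the fragment-contiguity run leaves the documented two-solution ambiguity", {
    sol <- reconstructStructures(c("g", "h", "i", "j", "k1", "k2", "k3", "l"),
                                 constraints19(pairwiseOnly = TRUE), 2)
    expect_length(sol, 2L)
    keys <- canonicalSolutions(sol)
    expect_true("g|h|k1|k2|k3|l / j|k1|k3|h|i" %in% keys)
})

test_that("reconstruction of the 2/8 instance gives the unique a-f / d-c pair", {
    sol <- reconstructStructures(c("a", "b", "c", "d", "e", "f"),
                                 constraints28(), 2)
    expect_length(sol, 1L)
    expect_identical(sol[[1]], list(c("a", "f"), c("d", "c")))
})

test_that("reference adjacencies alone reconstruct the reference structures", {
    cons <- constraintsFromStructures(list(c("a", "b", "c"),
                                           c("d", "e", "f")))
    sol <- reconstructStructures(c("a", "b", "c", "d", "e", "f"), cons, 2)
    expect_length(sol, 1L)
    expect_identical(sol[[1]], list(c("a", "b", "c"), c("d", "e", "f")))
})

test_that("unsatisfiable constraints give an empty solution list, oversized instances an error", {
    bad <- list(adjacencyConstraint("required_adjacency", c("a", "b")),
                adjacencyConstraint("absent_segment", "b"))
    expect_length(reconstructStructures(c("a", "b", "c"), bad, 1), 0L)
    expect_error(
        reconstructStructures(paste0("s", 1:13),
                              list(adjacencyConstraint("anchor_start", "s1")),
                              2),
        "too large")
    expect_error(adjacencyConstraint("required_adjacency", "a"),
                 "segment names")
})

test_that("solver agrees with the brute-force permutation oracle", {
    instances <- list(
        list(segs = c("a", "b", "c", "d", "e", "f"),
             cons = constraints28(), n = 2),
        list(segs = c("a", "b", "c", "d", "e", "f"),
             cons = constraintsFromStructures(list(c("a", "b", "c"),
                                                   c("d", "e", "f"))),
             n = 2),
        list(segs = c("g", "h", "i", "j", "k1", "k2", "k3", "l"),
             cons = constraints19(), n = 2),
        list(segs = c("g", "h", "i", "j", "k1", "k2", "k3", "l"),
             cons = constraints19(pairwiseOnly = TRUE), n = 2),
        list(segs = c("p", "q", "r"),
             cons = constraintsFromStructures(list(c("p", "q", "r"))),
             n = 1))
    for (inst in instances) {
        got <- reconstructStructures(inst$segs, inst$cons, inst$n)
        want <- bruteForceReconstruct(inst$segs, inst$cons, inst$n)
        expect_identical(canonicalSolutions(got), canonicalSolutions(want))
    }
})

test_that("translocation builder round-trips through reconstruction", {
    set.seed(20260925)
    for (rep in seq_len(25)) {
        nA <- sample(2:4, 1)
        nB <- sample(2:4, 1)
        segA <- paste0("A", seq_len(nA))
        segB <- paste0("B", seq_len(nB))
        kar <- karyotypeModel(
            segments = data.frame(name = c(segA, segB), length = 1000,
                                  origin = rep(c("c1", "c2"), c(nA, nB))),
            structures = list(c1 = segA, c2 = segB))
        kar2 <- applyReciprocalTranslocation(
            kar, "c1", "c2",
            breakAfterA = sample(nA - 1, 1),
            breakAfterB = sample(nB - 1, 1))
        truth <- lapply(structureGroups(kar2)[["c1/c2"]]$alt, function(nm)
            structureSegments(kar2, nm)$segment)
        cons <- constraintsFromStructures(truth)
        sol <- reconstructStructures(c(segA, segB), cons, 2)
        expect_length(sol, 1L)
        expect_identical(canonicalSolutions(sol),
                         canonicalSolutions(list(truth)))
    }
})

test_that("karyotype JSON and BED round-trips preserve the model", {
    kar <- karyotype28()
    path <- withr::local_tempfile(fileext = ".json")
    writeKaryotypeJSON(kar, path)
    back <- readKaryotypeJSON(path)
    expect_identical(segmentCatalog(back), segmentCatalog(kar))
    expect_identical(structureNames(back), structureNames(kar))
    expect_identical(structureSegments(back, "2T8"),
                     structureSegments(kar, "2T8"))
    expect_identical(structureGroups(back)[["2/8"]]$absent, c("b", "e"))

    bed <- karyotypeSegmentBED(kar)
    expect_identical(bed$start[bed$chrom == "chr2"],
                     c(0, 5e4, 5e4 + 1200))
    expect_true(all(bed$end - bed$start ==
        segmentCatalog(kar)$length[match(bed$name,
                                         segmentCatalog(kar)$name)]))
})

test_that("karyotype validity enforces the segment-completeness rule", {
    expect_error(karyotypeModel(
        segments = data.frame(name = c("a", "b", "c"), length = 100,
                              origin = "chr2"),
        structures = list(chr2 = c("a", "b", "c"), alt = c("a", "c")),
        groups = list(g = list(ref = "chr2", alt = "alt"))),
        "miss chromosome segment")
    # declaring the loss makes it valid
    expect_s4_class(karyotypeModel(
        segments = data.frame(name = c("a", "b", "c"), length = 100,
                              origin = "chr2"),
        structures = list(chr2 = c("a", "b", "c"), alt = c("a", "c")),
        groups = list(g = list(ref = "chr2", alt = "alt", absent = "b"))),
        "KaryotypeModel")
})
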