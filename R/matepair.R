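#' Classify an aligned read pair against a library model
#'
#' Each pair receives exactly one label: \code{unmapped} (either mate
#' unmapped), \code{discordant_interchromosomal} (mates on different
#' templates), \code{discordant_orientation} (same template but not the
#' library's expected relative orientation), \code{discordant_large_insert}
#' (expected orientation but outer span outside
#' \code{insertMean +/- 4 insertSd}; deletions on the sequenced genome
#' inflate the span), or \code{concordant}.
#'
#' @param pairs pair \code{data.frame} as produced by
#'   [simulateReadPairs()] or [readAlignmentSAM()].
#' @param library a [libraryModel()].
#' @param nSd half-width of the insert acceptance window in SDs.
#' @return character vector of labels, one per pair.
#' @export
classifyPairs <- function(pairs, library, nSd = 4) {
    if (any(c(pairs$start1, pairs$start2) < 0, na.rm = TRUE))
        stop("negative coordinates")
    lo <- library$insertMean - nSd * library$insertSd
    hi <- library$insertMean + nSd * library$insertSd
    un <- is.na(pairs$tmpl1) | is.na(pairs$tmpl2)
    same <- !un & pairs$tmpl1 == pairs$tmpl2
    left1 <- same & pairs$start1 <= pairs$start2
    okOrient <- same & ((left1 & pairs$strand1 == "+" &
                             pairs$strand2 == "-") |
                        (!left1 & pairs$strand1 == "-" &
                             pairs$strand2 == "+"))
    span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
    out <- rep("concordant", nrow(pairs))
    out[same & !okOrient] <- "discordant_orientation"
    out[okOrient & (span < lo | span > hi)] <- "discordant_large_insert"
    out[!un & !same] <- "discordant_interchromosomal"
    out[un] <- "unmapped"
    out
}

# normalized two-sided representation of discordant pairs: side A is the
# lexicographically smaller (template, start)
.discordantSides <- function(pairs, classes) {
    keep <- classes %in% c("discordant_large_insert",
                           "discordant_orientation",
                           "discordant_interchromosomal")
    d <- pairs[keep, , drop = FALSE]
    d$class <- classes[keep]
    swap <- d$tmpl2 < d$tmpl1 | (d$tmpl1 == d$tmpl2 & d$start2 < d$start1)
    sideA <- data.frame(tmpl = ifelse(swap, d$tmpl2, d$tmpl1),
                        start = ifelse(swap, d$start2, d$start1),
                        end = ifelse(swap, d$end2, d$end1),
                        strand = ifelse(swap, d$strand2, d$strand1))
    sideB <- data.frame(tmpl = ifelse(swap, d$tmpl1, d$tmpl2),
                        start = ifelse(swap, d$start1, d$start2),
                        end = ifelse(swap, d$end1, d$end2),
                        strand = ifelse(swap, d$strand1, d$strand2))
    list(d = d, A = sideA, B = sideB)
}

#' Cluster discordant pairs into putative novel adjacencies
#'
#' Single-linkage grouping of discordant pairs that share an orientation
#' class and whose mate footprints lie within \code{maxGap} of each
#' other on both sides.  Clusters with fewer than \code{minSupport}
#' members are discarded.  Clustering is order-independent: permuting
#' the input yields identical clusters.
#'
#' @param pairs pair \code{data.frame}.
#' @param library a [libraryModel()].
#' @param classes optional precomputed [classifyPairs()] labels.
#' @param maxGap linkage distance in bp (default the library insert
#'   mean).
#' @param minSupport minimum member count.
#' @param minMapq both mates must reach this mapping quality.
#' @return \code{data.frame}, one row per cluster: \code{class},
#'   per-side template, footprint \code{start}/\code{end} (union of
#'   member mates), majority \code{strand}, and \code{support}.
#' @export
clusterDiscordant <- function(pairs, library, classes = NULL,
                              maxGap = library$insertMean,
                              minSupport = 5L, minMapq = 10) {
    stopifnot(maxGap > 0)
    if (is.null(classes)) classes <- classifyPairs(pairs, library)
    ok <- pairs$mapq1 >= minMapq & pairs$mapq2 >= minMapq
    ok[is.na(ok)] <- FALSE
    sides <- .discordantSides(pairs[ok, , drop = FALSE], classes[ok])
    d <- sides$d; A <- sides$A; B <- sides$B
    n <- nrow(d)
    if (!n)
        return(data.frame(cluster = integer(), class = character(),
                          tmplA = character(), startA = numeric(),
                          endA = numeric(), strandA = character(),
                          tmplB = character(), startB = numeric(),
                          endB = numeric(), strandB = character(),
                          support = integer()))
    key <- paste(d$class, A$tmpl, B$tmpl)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (k in unique(key)) {
        idx <- which(key == k)
        idx <- idx[order(A$start[idx])]
        for (u in seq_along(idx)) {
            i <- idx[u]
            for (v in seq_len(length(idx) - u)) {
                j <- idx[u + v]
                if (A$start[j] - A$end[i] > maxGap) break
                if (abs(B$start[j] - B$start[i]) <= maxGap ||
                    abs(B$end[j] - B$end[i]) <= maxGap ||
                    (B$start[j] < B$end[i] && B$end[j] > B$start[i])) {
                    a <- find(i); b <- find(j)
                    if (a != b) parent[a] <- b
                }
            }
        }
    }
    comp <- vapply(seq_len(n), find, 0L)
    out <- lapply(unique(comp), function(cp) {
        mem <- comp == cp
        if (sum(mem) < minSupport) return(NULL)
        maj <- function(s) names(sort(table(s), decreasing = TRUE))[1L]
        data.frame(class = d$class[mem][1L],
                   tmplA = A$tmpl[mem][1L],
                   startA = min(A$start[mem]), endA = max(A$end[mem]),
                   strandA = maj(A$strand[mem]),
                   tmplB = B$tmpl[mem][1L],
                   startB = min(B$start[mem]), endB = max(B$end[mem]),
                   strandB = maj(B$strand[mem]),
                   support = sum(mem))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(data.frame(cluster = integer(), class = character(),
                          tmplA = character(), startA = numeric(),
                          endA = numeric(), strandA = character(),
                          tmplB = character(), startB = numeric(),
                          endB = numeric(), strandB = character(),
                          support = integer()))
    out <- out[order(out$tmplA, out$startA, out$tmplB, out$startB), ,
               drop = FALSE]
    cbind(cluster = seq_len(nrow(out)), out, row.names = NULL)
}

#' Detect intervals with zero read coverage
#'
#' Maximal runs of zero mapped-base coverage of at least \code{minLen},
#' computed from all mapped mates (concordant and discordant) at mapping
#' quality >= \code{minMapq}.  A segment absent from the sequenced
#' accession leaves such a gap on the template; a heterozygous deletion
#' merely halves coverage and is not reported here.
#'
#' @param pairs pair \code{data.frame}.
#' @param template a [SimulatedGenome-class] (for template lengths).
#' @param minLen shortest reported interval in bp.
#' @param minMapq mapping-quality floor.
#' @return \code{data.frame} with \code{tmpl}, \code{start}, \code{end}
#'   (0-based half-open).
#' @export
detectUncoveredSegments <- function(pairs, template, minLen = 500,
                                    minMapq = 10) {
    lens <- stats::setNames(Biostrings::width(genomeSequences(template)),
                            names(genomeSequences(template)))
    mates <- rbind(
        data.frame(tmpl = pairs$tmpl1, start = pairs$start1,
                   end = pairs$end1, mapq = pairs$mapq1),
        data.frame(tmpl = pairs$tmpl2, start = pairs$start2,
                   end = pairs$end2, mapq = pairs$mapq2))
    mates <- mates[!is.na(mates$tmpl) & mates$mapq >= minMapq, ]
    out <- list()
    for (tn in names(lens)) {
        mm <- mates[mates$tmpl == tn, ]
        ir <- IRanges::IRanges(start = mm$start + 1L, end = mm$end)
        cov <- IRanges::coverage(ir, width = lens[[tn]])
        zero <- IRanges::IRanges(cov == 0L)
        zero <- zero[IRanges::width(zero) >= minLen]
        if (length(zero))
            out[[tn]] <- data.frame(tmpl = tn,
                                    start = IRanges::start(zero) - 1L,
                                    end = IRanges::end(zero))
    }
    if (!length(out))
        return(data.frame(tmpl = character(), start = numeric(),
                          end = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Count concordant pairs spanning a template position
#'
#' @param pairs pair \code{data.frame}.
#' @param library a [libraryModel()].
#' @param tmpl,pos template name and 0-based position.
#' @param classes optional precomputed [classifyPairs()] labels.
#' @param minMapq mapping-quality floor.
#' @return number of concordant pairs whose fragment covers \code{pos}.
#' @export
countSpanningPairs <- function(pairs, library, tmpl, pos, classes = NULL,
                               minMapq = 10) {
    if (is.null(classes)) classes <- classifyPairs(pairs, library)
    ok <- classes == "concordant" & pairs$tmpl1 == tmpl &
        pairs$mapq1 >= minMapq & pairs$mapq2 >= minMapq
    ok[is.na(ok)] <- FALSE
    lo <- pmin(pairs$start1[ok], pairs$start2[ok])
    hi <- pmax(pairs$end1[ok], pairs$end2[ok])
    sum(lo < pos & hi > pos)
}

# mean coverage of [start, end) on tmpl from mapped mates
.meanCoverage <- function(pairs, tmpl, start, end, minMapq = 10) {
    sel <- function(t, s, e, q) !is.na(t) & t == tmpl & q >= minMapq &
        s < end & e > start
    b1 <- sel(pairs$tmpl1, pairs$start1, pairs$end1, pairs$mapq1)
    b2 <- sel(pairs$tmpl2, pairs$start2, pairs$end2, pairs$mapq2)
    bases <- sum(pmin(pairs$end1[b1], end) - pmax(pairs$start1[b1], start)) +
        sum(pmin(pairs$end2[b2], end) - pmax(pairs$start2[b2], start))
    bases / (end - start)
}

#' Interpret discordant clusters into chromosome-structure calls
#'
#' Implements the evidence-to-structure logic for reciprocal
#' translocations: the template is cut into breakpoint-derived segments
#' at cluster footprint edges (the junction lies at the strand-facing
#' edge of each footprint) and at zero-coverage interval boundaries
#' (sharper, preferred when both agree within \code{mergeTol}).
#' Constraints are then emitted -- novel adjacencies from discordant
#' clusters (when two clusters join the same pair of segment ends
#' through a shared middle fragment, the fragment contiguity becomes a
#' run constraint), absent segments from zero-coverage intervals,
#' heterozygous deletions from intra-template deletion-type clusters
#' whose skipped segment keeps roughly half coverage, reference
#' adjacencies retained wherever concordant pairs span a cut, and
#' chromosome-end anchors -- and [reconstructStructures()] is called per
#' connected group of templates.
#'
#' Zygosity is assessed per breakpoint from concordant pairs spanning
#' the reference junction, and is only informative where the
#' reconstructed structures do not themselves retain that reference
#' adjacency (duplication-rich events like the 1/9 translocation retain
#' every reference junction, leaving mate-pair zygosity undetermined --
#' segregation data must arbitrate, as in the original analysis).
#'
#' @param clusters result of [clusterDiscordant()].
#' @param uncovered result of [detectUncoveredSegments()].
#' @param template the [SimulatedGenome-class] the alignments were
#'   computed against.
#' @param pairs the classified pair \code{data.frame} (for spanning and
#'   coverage evidence).
#' @param library a [libraryModel()].
#' @param minSpan concordant spanning pairs needed to call a breakpoint
#'   heterozygous (or a reference adjacency retained).
#' @param mergeTol cut positions closer than this are merged, bp.
#' @return list with \code{calls} (one element per template group:
#'   \code{type} (\code{"reciprocal_translocation"},
#'   \code{"rearrangement"} or \code{"uninterpreted_cluster_pattern"}),
#'   \code{templates}, \code{structures} (solution list),
#'   \code{breakpoints} with per-breakpoint zygosity), plus
#'   \code{segments} (the derived-segment catalogue), and
#'   \code{constraints}.
#' @export
interpretClusters <- function(clusters, uncovered, template, pairs,
                              library, minSpan = 3L, mergeTol = 500,
                              extraConstraints = list()) {
    classes <- classifyPairs(pairs, library)
    lens <- stats::setNames(Biostrings::width(genomeSequences(template)),
                            names(genomeSequences(template)))
    empty <- list(calls = list(),
                  segments = data.frame(), constraints = list())
    if (!nrow(clusters)) return(empty)

    # --- cut positions per template -------------------------------------
    cutRows <- list()
    addCut <- function(tmpl, pos, kind, clusterId = NA)
        cutRows[[length(cutRows) + 1L]] <<- data.frame(
            tmpl = tmpl, pos = pos, kind = kind, cluster = clusterId)
    for (i in seq_len(nrow(clusters))) {
        cl <- clusters[i, ]
        posA <- if (cl$strandA == "+") cl$endA else cl$startA
        posB <- if (cl$strandB == "+") cl$endB else cl$startB
        addCut(cl$tmplA, posA, "cluster", cl$cluster)
        addCut(cl$tmplB, posB, "cluster", cl$cluster)
    }
    if (nrow(uncovered))
        for (i in seq_len(nrow(uncovered))) {
            addCut(uncovered$tmpl[i], uncovered$start[i], "uncovered")
            addCut(uncovered$tmpl[i], uncovered$end[i], "uncovered")
        }
    cuts <- do.call(rbind, cutRows)

    # merge nearby cuts; zero-coverage edges are sharper than cluster
    # footprint edges and win inside a merge group
    mergedCuts <- do.call(rbind, lapply(split(cuts, cuts$tmpl),
        function(ct) {
            ct <- ct[order(ct$pos), ]
            grp <- cumsum(c(1, diff(ct$pos) > mergeTol))
            do.call(rbind, lapply(split(ct, grp), function(g) {
                best <- if (any(g$kind == "uncovered"))
                    g[g$kind == "uncovered", ][1L, ] else g[nrow(g), ]
                best$members <- I(list(g))
                best
            }))
        }))

    # --- derived segments ----------------------------------------------
    segRows <- list()
    for (tn in unique(mergedCuts$tmpl)) {
        cp <- sort(unique(mergedCuts$pos[mergedCuts$tmpl == tn]))
        cp <- cp[cp > 0 & cp < lens[[tn]]]
        bounds <- c(0, cp, lens[[tn]])
        segRows[[tn]] <- data.frame(
            name = sprintf("%s.s%d", tn, seq_len(length(bounds) - 1L)),
            tmpl = tn, start = bounds[-length(bounds)], end = bounds[-1L])
    }
    segments <- do.call(rbind, segRows)
    rownames(segments) <- NULL
    segAt <- function(tn, pos, side) {
        s <- segments[segments$tmpl == tn, ]
        if (side == "end") s$name[which.min(abs(s$end - pos))]
        else s$name[which.min(abs(s$start - pos))]
    }
    cutFor <- function(tn, pos) {
        m <- mergedCuts[mergedCuts$tmpl == tn, ]
        m$pos[which.min(abs(m$pos - pos))]
    }

    # --- constraints ----------------------------------------------------
    cons <- list()
    usedTmpl <- unique(segments$tmpl)
    for (tn in usedTmpl) {
        s <- segments[segments$tmpl == tn, ]
        cons <- c(cons,
                  list(adjacencyConstraint("anchor_start", s$name[1L]),
                       adjacencyConstraint("anchor_end",
                                           s$name[nrow(s)])))
    }
    absentSegs <- character()
    if (nrow(uncovered))
        for (i in seq_len(nrow(uncovered))) {
            s <- segments[segments$tmpl == uncovered$tmpl[i], ]
            hit <- s$name[abs(s$start - uncovered$start[i]) <= mergeTol &
                          abs(s$end - uncovered$end[i]) <= mergeTol]
            absentSegs <- c(absentSegs, hit)
        }
    for (sg in unique(absentSegs))
        cons <- c(cons, list(adjacencyConstraint("absent_segment", sg)))

    # novel adjacencies from clusters; deletion-type intra-template
    # clusters may instead flag a heterozygous deletion
    novel <- list()
    hetdel <- character()
    for (i in seq_len(nrow(clusters))) {
        cl <- clusters[i, ]
        ends <- list(
            A = list(tmpl = cl$tmplA,
                     pos = cutFor(cl$tmplA,
                                  if (cl$strandA == "+") cl$endA
                                  else cl$startA),
                     strand = cl$strandA),
            B = list(tmpl = cl$tmplB,
                     pos = cutFor(cl$tmplB,
                                  if (cl$strandB == "+") cl$endB
                                  else cl$startB),
                     strand = cl$strandB))
        plus <- vapply(ends, function(e) e$strand == "+", NA)
        if (sum(plus) != 1L) {
            novel[[i]] <- list(ok = FALSE, cluster = cl$cluster)
            next
        }
        left <- ends[[which(plus)]]
        right <- ends[[which(!plus)]]
        leftSeg <- segAt(left$tmpl, left$pos, "end")
        rightSeg <- segAt(right$tmpl, right$pos, "start")
        hetFlag <- FALSE
        if (cl$class == "discordant_large_insert" &&
            cl$tmplA == cl$tmplB) {
            # skipped fragment between the two footprints
            sk <- segments[segments$tmpl == cl$tmplA &
                           segments$start >= left$pos - mergeTol &
                           segments$end <= right$pos + mergeTol, ]
            sk <- sk[!sk$name %in% absentSegs, , drop = FALSE]
            if (nrow(sk)) {
                covIn <- .meanCoverage(pairs, cl$tmplA,
                                       min(sk$start), max(sk$end))
                # local baseline: the cluster's own footprints flank the
                # skipped fragment
                covFlank <- (.meanCoverage(pairs, cl$tmplA, cl$startA,
                                           cl$endA) +
                             .meanCoverage(pairs, cl$tmplB, cl$startB,
                                           cl$endB)) / 2
                if (covIn > 0.1 * covFlank && covIn < 0.8 * covFlank) {
                    hetdel <- c(hetdel, sk$name)
                    hetFlag <- TRUE
                }
            }
        }
        novel[[i]] <- list(ok = TRUE, cluster = cl$cluster,
                           left = leftSeg, right = rightSeg,
                           leftPos = left$pos, leftTmpl = left$tmpl,
                           rightPos = right$pos, rightTmpl = right$tmpl,
                           hetdel = hetFlag)
        cons <- c(cons, list(adjacencyConstraint(
            "required_adjacency", c(leftSeg, rightSeg))))
    }
    for (sg in unique(hetdel))
        cons <- c(cons, list(adjacencyConstraint("heterozygous_deletion",
                                                 sg)))

    # retained reference adjacencies: cuts spanned by concordant pairs
    spanned <- list()
    retained <- character()
    for (r in seq_len(nrow(mergedCuts))) {
        tn <- mergedCuts$tmpl[r]; pos <- mergedCuts$pos[r]
        nsp <- countSpanningPairs(pairs, library, tn, pos, classes)
        spanned[[r]] <- data.frame(tmpl = tn, pos = pos, spanning = nsp)
        if (nsp >= minSpan) {
            lseg <- segAt(tn, pos, "end")
            rseg <- segAt(tn, pos, "start")
            retained <- c(retained, paste(lseg, rseg, sep = "\r"))
            cons <- c(cons, list(adjacencyConstraint(
                "required_adjacency", c(lseg, rseg))))
        }
    }
    spanned <- do.call(rbind, spanned)
    cons <- c(cons, extraConstraints)
    okNovel <- Filter(function(x) x$ok, novel)

    # --- group templates and reconstruct --------------------------------
    adjTmpl <- unique(do.call(rbind, lapply(okNovel, function(x)
        data.frame(a = x$leftTmpl, b = x$rightTmpl))))
    tmplGroups <- list()
    if (!is.null(adjTmpl)) {
        gparent <- stats::setNames(usedTmpl, usedTmpl)
        gfind <- function(t) {
            while (gparent[[t]] != t) t <- gparent[[t]]
            t
        }
        for (r in seq_len(nrow(adjTmpl))) {
            a <- gfind(adjTmpl$a[r]); b <- gfind(adjTmpl$b[r])
            if (a != b) gparent[[a]] <- b
        }
        roots <- vapply(usedTmpl, gfind, "")
        tmplGroups <- split(usedTmpl, roots)
    } else tmplGroups <- as.list(usedTmpl)

    calls <- list()
    for (tg in tmplGroups) {
        segs <- segments[segments$tmpl %in% tg, ]
        inGroup <- vapply(cons, function(ct)
            all(ct$segments %in% segs$name), NA)
        gcons <- cons[inGroup]
        hasNovel <- any(vapply(okNovel, function(x)
            x$leftTmpl %in% tg, NA))
        if (!hasNovel) next
        # a structurally homozygous accession has one structure per
        # template; a heterozygote superimposes the reference and the
        # rearranged set, needing twice as many structures
        sol <- reconstructStructures(segs$name, gcons, length(tg))
        hetSet <- FALSE
        if (!length(sol)) {
            sol <- reconstructStructures(segs$name, gcons, 2L * length(tg))
            hetSet <- length(sol) > 0
        }
        interTmpl <- sum(vapply(okNovel, function(x)
            x$leftTmpl %in% tg && x$leftTmpl != x$rightTmpl, NA))
        type <- if (!length(sol)) "uninterpreted_cluster_pattern"
            else if (length(tg) == 2 && interTmpl >= 2)
                "reciprocal_translocation"
            else "rearrangement"
        # per-breakpoint zygosity at the novel junction cuts
        solAdj <- unique(unlist(lapply(sol, function(s)
            lapply(s, function(p) if (length(p) > 1)
                paste(p[-length(p)], p[-1L], sep = "\r")))))
        bps <- do.call(rbind, lapply(okNovel, function(x) {
            if (!x$leftTmpl %in% tg) return(NULL)
            rbind(
                data.frame(tmpl = x$leftTmpl, pos = x$leftPos,
                           junction = paste(x$left, x$right, sep = "|")),
                data.frame(tmpl = x$rightTmpl, pos = x$rightPos,
                           junction = paste(x$left, x$right, sep = "|")))
        }))
        zygosity <- "undetermined"
        if (!is.null(bps)) {
            bps <- unique(bps)
            bps$spanning <- vapply(seq_len(nrow(bps)), function(r)
                spanned$spanning[spanned$tmpl == bps$tmpl[r] &
                                 spanned$pos == bps$pos[r]][1L], 0)
            refAdjKey <- vapply(seq_len(nrow(bps)), function(r)
                paste(segAt(bps$tmpl[r], bps$pos[r], "end"),
                      segAt(bps$tmpl[r], bps$pos[r], "start"),
                      sep = "\r"), "")
            # informative only where the reconstructed structures do not
            # themselves retain the reference junction
            informative <- !refAdjKey %in% solAdj
            bps$zygosity <- ifelse(!informative, "uninformative",
                                   ifelse(bps$spanning >= minSpan,
                                          "heterozygous",
                                          "homozygous_rearranged"))
            if (hetSet) zygosity <- "heterozygous"
            else if (any(informative))
                zygosity <- if (any(bps$zygosity == "heterozygous"))
                    "heterozygous" else "homozygous_rearranged"
        }
        calls[[paste(sort(tg), collapse = "+")]] <-
            list(type = type, templates = sort(tg), structures = sol,
                 zygosity = zygosity, breakpoints = bps)
    }
    # clusters whose strand pattern fits no junction model must still be
    # surfaced, never dropped silently
    badNovel <- Filter(function(x) !x$ok, novel)
    if (length(badNovel)) {
        ids <- vapply(badNovel, function(x) x$cluster, 0)
        bad <- clusters[clusters$cluster %in% ids, , drop = FALSE]
        tgs <- sort(unique(c(bad$tmplA, bad$tmplB)))
        key <- paste(tgs, collapse = "+")
        if (is.null(calls[[key]]))
            calls[[key]] <- list(type = "uninterpreted_cluster_pattern",
                                 templates = tgs, structures = list(),
                                 zygosity = "undetermined",
                                 breakpoints = NULL,
                                 clusters = bad$cluster)
    }
    list(calls = calls, segments = segments, constraints = cons,
         spanned = spanned)
}
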