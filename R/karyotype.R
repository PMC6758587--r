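#' Enumerate segment junctions of every chromosome structure
#'
#' A junction is an ordered adjacency of two segments read left-to-right
#' along a structure.  Each distinct (left, right) pair is reported once,
#' annotated with the set of structures that contain it; a structure with
#' \eqn{k} segments contributes \eqn{k - 1} junction incidences.
#'
#' @param karyotype a [KaryotypeModel-class].
#' @return \code{data.frame} with columns \code{left}, \code{right} and a
#'   list-column \code{structures} (character vector of owning structure
#'   names), ordered by \code{left} then \code{right}.  Reverse-oriented
#'   segments are written with a trailing apostrophe.
#' @examples
#' kar <- karyotypeModel(
#'   segments = data.frame(name = letters[1:3], length = 1000, origin = "chr2"),
#'   structures = list(chr2 = c("a", "b", "c")))
#' enumerateJunctions(kar)
#' @export
enumerateJunctions <- function(karyotype) {
    stopifnot(is(karyotype, "KaryotypeModel"))
    acc <- list()
    for (nm in names(karyotype@structures)) {
        st <- karyotype@structures[[nm]]
        if (nrow(st) < 2) next
        lab <- ifelse(st$orient == "-", paste0(st$segment, "'"), st$segment)
        for (i in seq_len(nrow(st) - 1L)) {
            key <- paste(lab[i], lab[i + 1L], sep = "\r")
            acc[[key]] <- c(acc[[key]], nm)
        }
    }
    if (!length(acc))
        return(data.frame(left = character(), right = character(),
                          structures = I(list())))
    parts <- strsplit(names(acc), "\r", fixed = TRUE)
    out <- data.frame(left  = vapply(parts, `[`, "", 1L),
                      right = vapply(parts, `[`, "", 2L))
    out$structures <- I(unname(acc))
    out <- out[order(out$left, out$right), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Identify signature segment junctions (SSJs)
#'
#' A signature segment junction is a junction present in exactly one
#' chromosome structure of the karyotype; observing read pairs across it
#' is positive evidence for that structure.  Junctions shared by several
#' structures (as happens around duplicated segments) are not signatures.
#'
#' @param karyotype a [KaryotypeModel-class] with at least one structure.
#' @return \code{data.frame} with columns \code{structure}, \code{left},
#'   \code{right}, ordered by structure name, then left, then right
#'   segment.
#' @examples
#' kar <- karyotypeModel(
#'   segments = data.frame(
#'     name   = c("a", "b", "c", "d", "e", "f", "x", "y"),
#'     length = c(5e4, 1200, 5e4, 5e4, 3000, 5e4, 600, 1200),
#'     origin = c("chr2", "chr2", "chr2", "chr8", "chr8", "chr8",
#'                "novel", "novel")),
#'   structures = list(chr2 = c("a", "b", "c"), chr8 = c("d", "e", "f"),
#'                     `2T8` = c("a", "x", "f"), `8T2` = c("d", "y", "c")))
#' identifySSJs(kar)   # 8 junctions, 2 per structure
#' @export
identifySSJs <- function(karyotype) {
    stopifnot(is(karyotype, "KaryotypeModel"))
    if (!length(karyotype@structures))
        stop("karyotype contains no structures")
    j <- enumerateJunctions(karyotype)
    own <- vapply(j$structures, length, 0L)
    j <- j[own == 1L, , drop = FALSE]
    out <- data.frame(structure = vapply(j$structures, `[`, "", 1L),
                      left = j$left, right = j$right)
    out <- out[order(out$structure, out$left, out$right), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build an adjacency constraint
#'
#' Constraints drive [reconstructStructures()].  Kinds:
#' \describe{
#'   \item{required_adjacency}{the two named segments must be adjacent, in
#'     order, in at least one reconstructed structure (from a discordant
#'     read cluster or a retained reference junction).}
#'   \item{absent_segment}{the segment appears in no structure (a region
#'     with zero read coverage).}
#'   \item{heterozygous_deletion}{the segment appears in exactly one
#'     structure of the reconstructed set (half coverage plus an
#'     intra-chromosomal discordant cluster).}
#'   \item{anchor_start / anchor_end}{the segment is a chromosome
#'     extremity and may only begin / end a structure.}
#' }
#'
#' In addition, \code{required_run} names an ordered run of two or more
#' segments that must appear consecutively within a single structure.  A
#' run of length 2 is equivalent to \code{required_adjacency}; longer runs
#' express fragment contiguity, e.g. when a discordant cluster links an
#' already-joined deletion fragment to a third segment, tying two
#' adjacencies to the same chromosome.
#'
#' @param kind one of the six kinds above.
#' @param segments character; >= 2 names for \code{required_run}, exactly
#'   2 for \code{required_adjacency}, exactly 1 otherwise.
#' @return a list of class \code{"AdjacencyConstraint"}.
#' @export
adjacencyConstraint <- function(kind = c("required_adjacency",
                                         "required_run",
                                         "absent_segment",
                                         "heterozygous_deletion",
                                         "anchor_start", "anchor_end"),
                                segments) {
    kind <- match.arg(kind)
    ok <- switch(kind,
                 required_adjacency = length(segments) == 2L,
                 required_run = length(segments) >= 2L,
                 length(segments) == 1L)
    if (!ok)
        stop("wrong number of segment names for kind '", kind, "'")
    structure(list(kind = kind, segments = as.character(segments)),
              class = "AdjacencyConstraint")
}

#' Reconstruct chromosome structures from adjacency constraints
#'
#' Exhaustively enumerates assignments of segments into
#' \code{nChromosomes} ordered structures satisfying all constraints:
#' every non-absent segment is used at least once, absent segments never,
#' heterozygous-deletion segments exactly once overall, each required
#' adjacency is realized in at least one structure, anchor segments only
#' begin/end structures, and a segment appears at most once per structure.
#' Adjacencies are closed-world: structures may only join segments across
#' adjacencies present in the constraint set (directly required or
#' implied by a run), since a junction truly present in the genome would
#' itself be spanned by read pairs and appear as evidence.
#' Solutions are canonicalized (structures sorted by first segment) and
#' deduplicated as unordered sets, so a reciprocal pair counts once.
#'
#' @param segments character vector of catalogued segment names (or the
#'   \code{data.frame} from [segmentCatalog()]).
#' @param constraints list of [adjacencyConstraint()] objects.
#' @param nChromosomes number of structures to reconstruct.
#' @param maxSegments refuse instances with more active segments than
#'   this (default 12); the search is exponential.
#' @return list of solutions; each solution is a list of
#'   \code{nChromosomes} character vectors of segment names.  Empty list
#'   when the constraints are unsatisfiable.
#' @examples
#' cons <- list(adjacencyConstraint("required_adjacency", c("a", "f")),
#'              adjacencyConstraint("required_adjacency", c("d", "c")),
#'              adjacencyConstraint("anchor_start", "a"),
#'              adjacencyConstraint("anchor_start", "d"),
#'              adjacencyConstraint("anchor_end", "f"),
#'              adjacencyConstraint("anchor_end", "c"),
#'              adjacencyConstraint("absent_segment", "b"),
#'              adjacencyConstraint("absent_segment", "e"))
#' reconstructStructures(c("a","b","c","d","e","f"), cons, 2)
#' @export
reconstructStructures <- function(segments, constraints, nChromosomes,
                                  maxSegments = 12L) {
    if (is.data.frame(segments)) segments <- segments$name
    segments <- as.character(segments)
    stopifnot(nChromosomes >= 1L)
    kinds <- vapply(constraints, function(ct) ct$kind, "")
    segs <- lapply(constraints, function(ct) ct$segments)
    bad <- setdiff(unlist(segs), segments)
    if (length(bad))
        stop("constraints reference uncatalogued segments: ",
             paste(bad, collapse = ", "))
    absent  <- unique(unlist(segs[kinds == "absent_segment"]))
    hetdel  <- unique(unlist(segs[kinds == "heterozygous_deletion"]))
    aStart  <- unique(unlist(segs[kinds == "anchor_start"]))
    aEnd    <- unique(unlist(segs[kinds == "anchor_end"]))
    runs    <- segs[kinds == "required_run"]
    required <- unique(vapply(segs[kinds == "required_adjacency"],
                              paste, "", collapse = "\r"))
    active <- setdiff(segments, absent)
    if (length(active) > maxSegments)
        stop("instance too large: ", length(active), " active segments (cap ",
             maxSegments, ")")
    if (length(intersect(c(aStart, aEnd, hetdel, unlist(runs),
                           unlist(strsplit(required, "\r"))), absent)))
        return(list())
    if (length(aStart) > nChromosomes || length(aEnd) > nChromosomes)
        return(list())

    runKeys <- vapply(runs, paste, "", collapse = "\r")
    needKeys <- unique(c(required, runKeys))
    if (length(needKeys) > 30L || length(active) > 30L)
        stop("instance too large: too many constraints")

    # Phase 1: enumerate every admissible complete structure (path).
    # Anchor-start segments may only occupy position 1; anchor-end
    # segments terminate a structure.  When the number of anchor starts
    # (ends) equals the structure count, every structure must start (end)
    # with one -- a forced deduction, not a heuristic.
    mustStartAnchor <- length(aStart) == nChromosomes && length(aStart) > 0L
    mustEndAnchor <- length(aEnd) == nChromosomes && length(aEnd) > 0L
    # closed-world joins: a junction in the true genome would be spanned
    # by read pairs and hence appear among the constraints, so structures
    # may only realize observed adjacencies (required ones and those
    # implied by runs)
    runPairs <- unlist(lapply(runs, function(r)
        paste(r[-length(r)], r[-1L], sep = "\r")))
    allowed <- unique(c(required, runPairs))
    successor <- lapply(stats::setNames(nm = active), function(s) {
        hit <- strsplit(allowed[startsWith(allowed, paste0(s, "\r"))], "\r")
        setdiff(vapply(hit, `[`, "", 2L), absent)
    })
    nodeBudget <- 2e6L
    nodes <- 0L
    pathsOut <- new.env(parent = emptyenv())
    np <- 0L
    grow <- function(path) {
        nodes <<- nodes + 1L
        if (nodes > nodeBudget)
            stop("instance too large: search budget exceeded")
        last <- path[length(path)]
        if (!mustEndAnchor || last %in% aEnd) {
            np <<- np + 1L
            assign(sprintf("p%07d", np), path, envir = pathsOut)
        }
        if (last %in% aEnd) return()
        for (s in setdiff(successor[[last]], path)) {
            if (s %in% aStart) next
            grow(c(path, s))
        }
    }
    for (s in (if (mustStartAnchor) aStart else active)) grow(s)
    paths <- mget(sort(ls(pathsOut)), envir = pathsOut)
    names(paths) <- NULL
    if (!length(paths)) return(list())

    # Phase 2: per-path bitmasks, then a pruned combination search with
    # repetition over canonically ordered path indices.
    segBit <- stats::setNames(as.integer(2^(seq_along(active) - 1L)), active)
    coverMask <- vapply(paths, function(p) as.integer(sum(segBit[p])), 0L)
    needBit <- stats::setNames(as.integer(2^(seq_along(needKeys) - 1L)),
                               needKeys)
    pathMet <- function(p) {
        adds <- if (length(p) > 1L)
            paste(p[-length(p)], p[-1L], sep = "\r") else character()
        hit <- intersect(required, adds)
        for (i in seq_along(runs)) {
            r <- runs[[i]]; m <- length(r)
            if (length(p) < m) next
            for (j in seq_len(length(p) - m + 1L))
                if (identical(p[j:(j + m - 1L)], r)) {
                    hit <- c(hit, runKeys[i]); break
                }
        }
        as.integer(sum(needBit[unique(hit)]))
    }
    metMask <- vapply(paths, pathMet, 0L)
    starts <- vapply(paths, `[`, "", 1L)
    ends <- vapply(paths, function(p) p[length(p)], "")
    ord <- order(starts, vapply(paths, paste, "", collapse = "\r"))
    paths <- paths[ord]
    coverMask <- coverMask[ord]; metMask <- metMask[ord]
    starts <- starts[ord]; ends <- ends[ord]
    P <- length(paths)
    # suffix-reachable masks: what coverage/requirements any choice from
    # index i onward could still contribute
    sufCover <- rev(Reduce(bitwOr, rev(coverMask), accumulate = TRUE))
    sufMet <- rev(Reduce(bitwOr, rev(metMask), accumulate = TRUE))
    fullCover <- as.integer(sum(segBit))
    fullNeed <- as.integer(sum(needBit))
    hetBits <- if (length(hetdel)) segBit[hetdel] else integer()

    solutions <- list()
    choose <- function(idx, from, cover, met) {
        if (length(idx) == nChromosomes) {
            if (cover != fullCover || bitwAnd(met, fullNeed) != fullNeed)
                return()
            for (hb in hetBits)
                if (sum(bitwAnd(coverMask[idx], hb) > 0L) != 1L) return()
            if (!all(aStart %in% starts[idx]) || !all(aEnd %in% ends[idx]))
                return()
            solutions[[length(solutions) + 1L]] <<- paths[idx]
            return()
        }
        if (from > P) return()
        if (bitwOr(cover, sufCover[from]) != fullCover) return()
        if (bitwAnd(bitwOr(met, sufMet[from]), fullNeed) != fullNeed)
            return()
        for (i in from:P) {
            nodes <<- nodes + 1L
            if (nodes > nodeBudget)
                stop("instance too large: search budget exceeded")
            choose(c(idx, i), i, bitwOr(cover, coverMask[i]),
                   bitwOr(met, metMask[i]))
        }
    }
    choose(integer(), 1L, 0L, 0L)
    # indices are non-decreasing, so each unordered set arises once:
    # solutions are already canonical and deduplicated
    solutions
}

#' Apply a reciprocal translocation to two chromosome structures
#'
#' Exchanges the distal parts of two structures after the given segment
#' positions, producing the two derived chromosomes (e.g. 2T8 and 8T2).
#' Optionally replaces the segments straddling each breakpoint with novel
#' breakpoint segments.
#'
#' @param karyotype a [KaryotypeModel-class].
#' @param chromA,chromB names of the two structures to rearrange.
#' @param breakAfterA,breakAfterB number of proximal segments of each
#'   structure retained on its own derivative (the break falls after that
#'   many segments).
#' @param derivedNames names for the two derived structures
#'   (default \code{"<A>T<B>"}, \code{"<B>T<A>"} with any "chr" prefix
#'   stripped).
#' @return a new \code{KaryotypeModel} containing the original segments
#'   and structures plus the two derived structures, grouped against the
#'   two parents.
#' @export
applyReciprocalTranslocation <- function(karyotype, chromA, chromB,
                                         breakAfterA, breakAfterB,
                                         derivedNames = NULL) {
    stA <- structureSegments(karyotype, chromA)
    stB <- structureSegments(karyotype, chromB)
    stopifnot(breakAfterA >= 1, breakAfterA < nrow(stA),
              breakAfterB >= 1, breakAfterB < nrow(stB))
    if (is.null(derivedNames)) {
        a <- sub("^chr", "", chromA); b <- sub("^chr", "", chromB)
        derivedNames <- c(paste0(a, "T", b), paste0(b, "T", a))
    }
    dA <- rbind(stA[seq_len(breakAfterA), ],
                stB[-seq_len(breakAfterB), ])
    dB <- rbind(stB[seq_len(breakAfterB), ],
                stA[-seq_len(breakAfterA), ])
    structures <- karyotype@structures
    structures[[derivedNames[1L]]] <- dA
    structures[[derivedNames[2L]]] <- dB
    groups <- karyotype@groups
    groups[[paste(chromA, chromB, sep = "/")]] <-
        list(ref = c(chromA, chromB), alt = derivedNames)
    new("KaryotypeModel", segments = karyotype@segments,
        structures = structures, groups = groups)
}

#' Karyotype JSON and BED interchange
#'
#' \code{writeKaryotypeJSON}/\code{readKaryotypeJSON} round-trip a
#' [KaryotypeModel-class] through a plain JSON document
#' (\code{segments}, \code{structures}, \code{groups}).
#' \code{karyotypeSegmentBED} lays each structure's segments out as
#' 0-based half-open intervals on its template sequence, suitable for BED
#' export via [utils::write.table()].
#'
#' @param karyotype a \code{KaryotypeModel}.
#' @param path file path.
#' @return \code{readKaryotypeJSON}: a \code{KaryotypeModel};
#'   \code{karyotypeSegmentBED}: \code{data.frame} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{name}.
#' @name karyotype-io
NULL

#' @rdname karyotype-io
#' @export
writeKaryotypeJSON <- function(karyotype, path) {
    doc <- list(
        segments = karyotype@segments,
        structures = lapply(names(karyotype@structures), function(nm) {
            st <- karyotype@structures[[nm]]
            list(name = nm, segments = st$segment, orient = st$orient)
        }),
        groups = lapply(names(karyotype@groups), function(g) {
            c(list(name = g), karyotype@groups[[g]])
        }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname karyotype-io
#' @export
readKaryotypeJSON <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    structures <- stats::setNames(
        lapply(seq_len(nrow(doc$structures)), function(i) {
            data.frame(segment = unlist(doc$structures$segments[[i]]),
                       orient = unlist(doc$structures$orient[[i]]))
        }), doc$structures$name)
    groups <- list()
    if (!is.null(doc$groups) && length(doc$groups)) {
        gdf <- doc$groups
        for (i in seq_along(gdf$name)) {
            g <- list(ref = unlist(gdf$ref[[i]]), alt = unlist(gdf$alt[[i]]))
            ab <- unlist(gdf$absent[[i]])
            if (length(ab)) g$absent <- ab
            groups[[gdf$name[[i]]]] <- g
        }
    }
    karyotypeModel(doc$segments, structures, groups)
}

#' @rdname karyotype-io
#' @export
karyotypeSegmentBED <- function(karyotype) {
    lens <- stats::setNames(karyotype@segments$length,
                            karyotype@segments$name)
    out <- lapply(names(karyotype@structures), function(nm) {
        st <- karyotype@structures[[nm]]
        w <- lens[st$segment]
        end <- cumsum(w)
        data.frame(chrom = nm, start = end - w, end = end,
                   name = st$segment, row.names = NULL)
    })
    do.call(rbind, out)
}
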