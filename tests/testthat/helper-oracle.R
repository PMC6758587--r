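# Brute-force reconstruction oracle: enumerate every permutation of every
# subset of the active segments, filter complete sequences by direct
# constraint checking, then test all unordered n-tuples.  Shares the
# constraint semantics of reconstructStructures() but none of its search
# machinery (no anchor deductions, no bitmask pruning, no suffix bounds).
bruteForceReconstruct <- function(segments, constraints, nChromosomes) {
    kinds <- vapply(constraints, function(ct) ct$kind, "")
    segs <- lapply(constraints, function(ct) ct$segments)
    absent <- unique(unlist(segs[kinds == "absent_segment"]))
    hetdel <- unique(unlist(segs[kinds == "heterozygous_deletion"]))
    aStart <- unique(unlist(segs[kinds == "anchor_start"]))
    aEnd <- unique(unlist(segs[kinds == "anchor_end"]))
    runs <- segs[kinds == "required_run"]
    req <- segs[kinds == "required_adjacency"]
    active <- setdiff(segments, absent)

    adjOf <- function(p) if (length(p) > 1L)
        paste(p[-length(p)], p[-1L], sep = "|") else character()
    allowed <- unique(c(vapply(req, paste, "", collapse = "|"),
                        unlist(lapply(runs, function(r)
                            paste(r[-length(r)], r[-1L], sep = "|")))))

    # all permutations of all subsets
    perms <- list()
    rec <- function(p, rest) {
        if (length(p)) perms[[length(perms) + 1L]] <<- p
        for (s in rest) rec(c(p, s), setdiff(rest, s))
    }
    rec(character(), active)

    okPath <- function(p) {
        if (length(p) > 1L && any(p[-1L] %in% aStart)) return(FALSE)
        if (any(p[-length(p)] %in% aEnd)) return(FALSE)
        all(adjOf(p) %in% allowed)
    }
    cand <- Filter(okPath, perms)
    if (!length(cand)) return(list())

    hasRun <- function(p, r) {
        m <- length(r)
        if (length(p) < m) return(FALSE)
        for (j in seq_len(length(p) - m + 1L))
            if (identical(p[j:(j + m - 1L)], r)) return(TRUE)
        FALSE
    }
    okSolution <- function(sel) {
        segsUsed <- unlist(sel)
        if (length(setdiff(active, segsUsed))) return(FALSE)
        adjs <- unlist(lapply(sel, adjOf))
        for (rq in req)
            if (!paste(rq, collapse = "|") %in% adjs) return(FALSE)
        for (r in runs)
            if (!any(vapply(sel, hasRun, NA, r = r))) return(FALSE)
        for (hseg in hetdel)
            if (sum(vapply(sel, function(p) hseg %in% p, NA)) != 1L)
                return(FALSE)
        starts <- vapply(sel, `[`, "", 1L)
        ends <- vapply(sel, function(p) p[length(p)], "")
        all(aStart %in% starts) && all(aEnd %in% ends)
    }

    # unordered n-tuples with repetition
    sols <- list()
    pick <- function(idx, from) {
        if (length(idx) == nChromosomes) {
            sel <- cand[idx]
            if (okSolution(sel)) {
                sel <- sel[order(vapply(sel, `[`, "", 1L),
                                 vapply(sel, paste, "", collapse = "|"))]
                sols[[length(sols) + 1L]] <<- sel
            }
            return()
        }
        for (i in from:length(cand)) pick(c(idx, i), i)
    }
    pick(integer(), 1L)
    unique(sols)
}

canonicalSolutions <- function(sols) {
    keys <- vapply(sols, function(s)
        paste(vapply(s, paste, "", collapse = "|"), collapse = " / "), "")
    sort(keys)
}
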