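#' Describe a sequencing library
#'
#' @param insertMean,insertSd fragment (outer) insert size model in bp;
#'   inserts are drawn Normal and re-drawn while below
#'   \code{2 * readLength}.
#' @param readLength read length in bp.
#' @param orientation expected relative orientation of a concordant pair
#'   after post-processing; only \code{"FR"} (forward-reverse, first mate
#'   leftmost) is generated, but the code classifying pairs consumes this
#'   declared expectation rather than assuming a chemistry.
#' @param errorRate per-base substitution probability in [0, 0.1).
#' @param coverage fold coverage of the diploid genome.
#' @return a list of class \code{"LibraryModel"}.
#' @examples
#' matePair5k <- libraryModel(5000, 300, 150, coverage = 30)
#' pairedEnd  <- libraryModel(500, 50, 150, coverage = 20)
#' @export
libraryModel <- function(insertMean, insertSd, readLength,
                         orientation = "FR", errorRate = 0,
                         coverage = 30) {
    stopifnot(insertMean > 2 * readLength, insertSd > 0,
              errorRate >= 0, errorRate < 0.1, coverage >= 0)
    orientation <- match.arg(orientation, "FR")
    structure(list(insertMean = insertMean, insertSd = insertSd,
                   readLength = readLength, orientation = orientation,
                   errorRate = errorRate, coverage = coverage),
              class = "LibraryModel")
}

# Layout of every structure of the full fixture karyotype: per structure,
# segment names and cumulative 0-based starts.
.structureLayout <- function(karyotype) {
    bed <- karyotypeSegmentBED(karyotype)
    split(bed[c("start", "end", "name")], bed$chrom)
}

# All occurrences of each segment on a template genome, ordered by
# structure name then position (deterministic multi-copy resolution).
.templateOccurrences <- function(template) {
    sc <- segmentCoords(template)
    sc <- sc[order(sc$structure, sc$start), ]
    split(sc, sc$segment)
}

#' Simulate read pairs with truth alignments against a template
#'
#' Draws fragments from the accession's two haplotype chromosome sets in
#' proportion to structure length, with Normal insert sizes truncated at
#' twice the read length, and computes each mate's alignment on the
#' template genome by coordinate arithmetic (not sequence search): a mate
#' maps where its source segments occur, contiguously and in order, on
#' the template.  Mates lying in segments absent from the template, or
#' crossing a junction the template does not share, are emitted as
#' unmapped.  When a segment occurs several times on the template the
#' pair is placed like a pair-aware aligner would: the combination of
#' candidate placements that is concordant (same structure, expected
#' orientation, insert closest to the library mean) wins; ties and
#' discordant leftovers resolve to the first occurrence in structure-name
#' order.
#'
#' @param fixture result of [buildFixtureKaryotype()].
#' @param accession an [accessionSpec()].
#' @param library a [libraryModel()].
#' @param seed integer seed.
#' @param template a [SimulatedGenome-class] to align against (default
#'   the fixture's reference genome).
#' @param regions optional \code{data.frame(structure, start, end)} in
#'   source coordinates; only fragments overlapping a region of their
#'   source structure are kept (used to confine panel read sets to
#'   breakpoint neighbourhoods).
#' @param emitSequences if TRUE, attach read sequences (with
#'   substitution errors at the library error rate) as attributes
#'   \code{"seq1"}/\code{"seq2"}.
#' @return \code{data.frame}, one row per pair: \code{qname},
#'   \code{srcStructure}, \code{srcStart}, \code{insert}, \code{hap},
#'   and per mate \code{tmpl}, \code{start} (0-based), \code{end},
#'   \code{strand}, \code{mapq} (60 mapped, 0 unmapped with NA
#'   coordinates).
#' @export
simulateReadPairs <- function(fixture, accession, library, seed,
                              template = fixture$reference,
                              regions = NULL, emitSequences = FALSE) {
    stopifnot(inherits(accession, "AccessionSpec"),
              inherits(library, "LibraryModel"))
    set.seed(seed)
    rl <- library$readLength
    haps <- haplotypeStructures(fixture, accession)
    layout <- .structureLayout(fixture$karyotype)
    structLen <- vapply(layout, function(x) max(x$end), 0)
    if (!length(unlist(haps)))
        stop("accession resolves to no structures on this fixture")

    draw <- list()
    for (h in 1:2) {
        sts <- haps[[h]]
        gsize <- sum(structLen[sts])
        nPairs <- rpois(1L, (library$coverage / 2) * gsize / (2 * rl))
        if (nPairs == 0L) next
        src <- sample(sts, nPairs, replace = TRUE,
                      prob = structLen[sts])
        ins <- round(rnorm(nPairs, library$insertMean, library$insertSd))
        while (any(bad <- ins < 2 * rl))
            ins[bad] <- round(rnorm(sum(bad), library$insertMean,
                                    library$insertSd))
        ins <- pmin(ins, structLen[src])
        start <- floor(runif(nPairs) * (structLen[src] - ins + 1))
        draw[[h]] <- data.frame(hap = h, srcStructure = src,
                                srcStart = start, insert = ins)
    }
    pairs <- do.call(rbind, draw)
    if (is.null(pairs) || !nrow(pairs)) {
        out <- data.frame(qname = character(), srcStructure = character(),
                          srcStart = numeric(), insert = numeric(),
                          hap = integer(),
                          tmpl1 = character(), start1 = numeric(),
                          end1 = numeric(), strand1 = character(),
                          mapq1 = numeric(),
                          tmpl2 = character(), start2 = numeric(),
                          end2 = numeric(), strand2 = character(),
                          mapq2 = numeric())
        return(out)
    }
    if (!is.null(regions)) {
        keep <- rep(FALSE, nrow(pairs))
        for (i in seq_len(nrow(regions))) {
            r <- regions[i, ]
            keep <- keep | (pairs$srcStructure == r$structure &
                            pairs$srcStart < r$end &
                            pairs$srcStart + pairs$insert > r$start)
        }
        pairs <- pairs[keep, , drop = FALSE]
    }
    rownames(pairs) <- NULL
    n <- nrow(pairs)
    pairs$qname <- sprintf("%s_%07d", accession$name, seq_len(n))

    m1s <- pairs$srcStart
    m1e <- m1s + rl
    m2e <- pairs$srcStart + pairs$insert
    m2s <- m2e - rl
    map1 <- .mapMates(pairs$srcStructure, m1s, m1e, layout, template)
    map2 <- .mapMates(pairs$srcStructure, m2s, m2e, layout, template)
    res <- .resolvePairs(map1, map2, library)
    pairs$tmpl1 <- res$tmpl1; pairs$start1 <- res$start1
    pairs$end1 <- res$end1
    pairs$strand1 <- ifelse(is.na(res$tmpl1), NA, "+")
    pairs$mapq1 <- ifelse(is.na(res$tmpl1), 0, 60)
    pairs$tmpl2 <- res$tmpl2; pairs$start2 <- res$start2
    pairs$end2 <- res$end2
    pairs$strand2 <- ifelse(is.na(res$tmpl2), NA, "-")
    pairs$mapq2 <- ifelse(is.na(res$tmpl2), 0, 60)

    if (emitSequences) {
        seqs <- as.character(genomeSequences(.seqSource(fixture, pairs)))
        s1 <- substring(seqs[pairs$srcStructure], m1s + 1, m1e)
        s2raw <- substring(seqs[pairs$srcStructure], m2s + 1, m2e)
        s2 <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(s2raw)))
        if (library$errorRate > 0) {
            s1 <- .addErrors(s1, library$errorRate)
            s2 <- .addErrors(s2, library$errorRate)
        }
        attr(pairs, "seq1") <- stats::setNames(s1, pairs$qname)
        attr(pairs, "seq2") <- stats::setNames(s2, pairs$qname)
    }
    pairs
}

# a DNAStringSet holding every structure the pairs were drawn from
.seqSource <- function(fixture, pairs) {
    all <- c(genomeSequences(fixture$reference),
             genomeSequences(fixture$translocated))
    new("SimulatedGenome", karyotype = fixture$karyotype,
        sequences = all,
        segmentCoords = rbind(segmentCoords(fixture$reference),
                              segmentCoords(fixture$translocated)))
}

.addErrors <- function(reads, rate) {
    alphabet <- c("A", "C", "G", "T")
    nerr <- rbinom(length(reads), nchar(reads), rate)
    for (i in which(nerr > 0)) {
        pos <- sample.int(nchar(reads[i]), nerr[i])
        for (p in pos) {
            cur <- substr(reads[i], p, p)
            substr(reads[i], p, p) <- sample(setdiff(alphabet, cur), 1)
        }
    }
    reads
}

# Candidate template placements for each mate interval.  Fast path:
# mates inside one source segment.  Rare junction-crossing mates are
# matched as segment runs.  Returns a list: $tmpl/$start (first
# candidate) and $alts (list of candidate data.frames for mates with
# several placements).
.mapMates <- function(srcStruct, s, e, layout, template) {
    occ <- .templateOccurrences(template)
    tmplStructs <- lapply(genomeKaryotype(template)@structures,
                          function(x) x$segment)
    n <- length(s)
    tmpl <- rep(NA_character_, n)
    pos <- rep(NA_real_, n)
    alts <- vector("list", n)

    for (st in unique(srcStruct)) {
        idx <- which(srcStruct == st)
        lay <- layout[[st]]
        i1 <- findInterval(s[idx], lay$start)
        i2 <- findInterval(e[idx] - 1, lay$start)
        single <- i1 == i2
        # single-segment mates
        for (segi in unique(i1[single])) {
            rows <- idx[single & i1 == segi]
            seg <- lay$name[segi]
            o <- occ[[seg]]
            if (is.null(o)) next
            off <- s[rows] - lay$start[segi]
            tmpl[rows] <- o$structure[1L]
            pos[rows] <- o$start[1L] + off
            if (nrow(o) > 1L)
                for (k in seq_along(rows))
                    alts[[rows[k]]] <- data.frame(
                        tmpl = o$structure, start = o$start + off[k])
        }
        # junction-crossing mates: match the segment run on the template
        for (r in idx[!single]) {
            runSegs <- lay$name[findInterval(s[r], lay$start):
                                findInterval(e[r] - 1, lay$start)]
            offset <- s[r] - lay$start[findInterval(s[r], lay$start)]
            hits <- NULL
            for (tn in names(tmplStructs)) {
                tsegs <- tmplStructs[[tn]]
                m <- length(runSegs)
                if (length(tsegs) < m) next
                for (p in seq_len(length(tsegs) - m + 1L)) {
                    if (identical(tsegs[p:(p + m - 1L)], runSegs)) {
                        sc <- segmentCoords(template)
                        st0 <- sc$start[sc$structure == tn &
                                        sc$segment == runSegs[1L]][1L]
                        hits <- rbind(hits, data.frame(
                            tmpl = tn, start = st0 + offset))
                    }
                }
            }
            if (!is.null(hits)) {
                tmpl[r] <- hits$tmpl[1L]
                pos[r] <- hits$start[1L]
                if (nrow(hits) > 1L) alts[[r]] <- hits
            }
        }
    }
    list(tmpl = tmpl, start = pos, len = e - s, alts = alts)
}

# Pair-aware placement: if either mate has alternative placements, pick
# the concordant combination with insert closest to the library mean.
.resolvePairs <- function(map1, map2, library) {
    n <- length(map1$tmpl)
    t1 <- map1$tmpl; p1 <- map1$start
    t2 <- map2$tmpl; p2 <- map2$start
    multi <- which(!vapply(map1$alts, is.null, NA) |
                   !vapply(map2$alts, is.null, NA))
    for (r in multi) {
        c1 <- map1$alts[[r]]
        if (is.null(c1) && !is.na(t1[r]))
            c1 <- data.frame(tmpl = t1[r], start = p1[r])
        c2 <- map2$alts[[r]]
        if (is.null(c2) && !is.na(t2[r]))
            c2 <- data.frame(tmpl = t2[r], start = p2[r])
        if (is.null(c1) || is.null(c2)) next
        best <- Inf; bi <- bj <- 1L
        for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
            if (c1$tmpl[i] != c2$tmpl[j]) next
            if (c1$start[i] > c2$start[j]) next  # expected FR order
            span <- c2$start[j] + map2$len[r] - c1$start[i]
            dev <- abs(span - library$insertMean)
            if (dev < best) { best <- dev; bi <- i; bj <- j }
        }
        if (is.finite(best) && best <= 4 * library$insertSd) {
            t1[r] <- c1$tmpl[bi]; p1[r] <- c1$start[bi]
            t2[r] <- c2$tmpl[bj]; p2[r] <- c2$start[bj]
        }
    }
    list(tmpl1 = t1, start1 = p1, end1 = p1 + map1$len,
         tmpl2 = t2, start2 = p2, end2 = p2 + map2$len)
}

#' Write simulated read pairs as gzipped FASTQ
#'
#' @param pairs result of [simulateReadPairs()] with
#'   \code{emitSequences = TRUE}.
#' @param prefix output prefix; writes \code{<prefix>_1.fastq.gz} and
#'   \code{<prefix>_2.fastq.gz}.
#' @return the two paths, invisibly.
#' @export
writeReadPairsFASTQ <- function(pairs, prefix) {
    s1 <- attr(pairs, "seq1"); s2 <- attr(pairs, "seq2")
    if (is.null(s1))
        stop("pairs carry no sequences; rerun with emitSequences = TRUE")
    paths <- paste0(prefix, c("_1", "_2"), ".fastq.gz")
    for (m in 1:2) {
        seqs <- if (m == 1) s1 else s2
        con <- gzfile(paths[m], "wb")
        writeLines(as.vector(rbind(paste0("@", names(seqs), "/", m),
                                   unname(seqs),
                                   "+",
                                   strrep("I", nchar(seqs)))), con)
        close(con)
    }
    invisible(paths)
}

#' Minimal SAM export / import of alignment pairs
#'
#' \code{writeAlignmentSAM} writes the truth alignments of
#' [simulateReadPairs()] as a minimal SAM file (header \code{@SQ} lines
#' plus the eleven mandatory columns, 1-based positions);
#' \code{readAlignmentSAM} reads such a file (or any name-sorted SAM
#' subset of paired 150 bp alignments) back into the pair
#' \code{data.frame} contract, so externally aligned data can enter the
#' pipeline in place of simulator truth.
#'
#' @param pairs pair \code{data.frame}.
#' @param template the [SimulatedGenome-class] the alignments refer to.
#' @param path SAM file path.
#' @return \code{readAlignmentSAM}: a pair \code{data.frame} with the
#'   columns of [simulateReadPairs()] output (source-truth columns NA).
#' @name sam-io
NULL

#' @rdname sam-io
#' @export
writeAlignmentSAM <- function(pairs, template, path) {
    seqs <- genomeSequences(template)
    hdr <- c("@HD\tVN:1.6\tSO:queryname",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqs),
                     Biostrings::width(seqs)))
    flag <- function(unmapped, mateUnmapped, rev, mateRev, first) {
        1L + 4L * unmapped + 8L * mateUnmapped + 16L * rev +
            32L * mateRev + (if (first) 64L else 128L)
    }
    rows <- function(tmpl, start, end, strand, mapq,
                     mtmpl, mstart, mstrand, first) {
        un <- is.na(tmpl); mun <- is.na(mtmpl)
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                pairs$qname,
                flag(un, mun, !un & strand == "-",
                     !mun & mstrand == "-", first),
                ifelse(un, "*", tmpl),
                ifelse(un, 0L, as.integer(start) + 1L),
                ifelse(un, 0L, as.integer(mapq)),
                ifelse(un, "*", sprintf("%dM", as.integer(end - start))),
                ifelse(mun, "*", mtmpl),
                ifelse(mun, 0L, as.integer(mstart) + 1L))
    }
    body <- as.vector(rbind(
        rows(pairs$tmpl1, pairs$start1, pairs$end1, pairs$strand1,
             pairs$mapq1, pairs$tmpl2, pairs$start2, pairs$strand2, TRUE),
        rows(pairs$tmpl2, pairs$start2, pairs$end2, pairs$strand2,
             pairs$mapq2, pairs$tmpl1, pairs$start1, pairs$strand1,
             FALSE)))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname sam-io
#' @export
readAlignmentSAM <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "@")]
    f <- strsplit(ln, "\t")
    df <- data.frame(
        qname = vapply(f, `[`, "", 1L),
        flag = as.integer(vapply(f, `[`, "", 2L)),
        tmpl = vapply(f, `[`, "", 3L),
        pos = as.numeric(vapply(f, `[`, "", 4L)),
        mapq = as.numeric(vapply(f, `[`, "", 5L)),
        cigar = vapply(f, `[`, "", 6L))
    df$unmapped <- bitwAnd(df$flag, 4L) > 0L
    df$first <- bitwAnd(df$flag, 64L) > 0L
    df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
    df$len <- suppressWarnings(as.numeric(sub("M$", "", df$cigar)))
    m1 <- df[df$first, ]; m2 <- df[!df$first, ]
    m2 <- m2[match(m1$qname, m2$qname), ]
    mk <- function(m) list(
        tmpl = ifelse(m$unmapped, NA, m$tmpl),
        start = ifelse(m$unmapped, NA, m$pos - 1),
        end = ifelse(m$unmapped, NA, m$pos - 1 + m$len),
        strand = ifelse(m$unmapped, NA, m$strand),
        mapq = ifelse(m$unmapped, 0, m$mapq))
    a <- mk(m1); b <- mk(m2)
    data.frame(qname = m1$qname, srcStructure = NA, srcStart = NA,
               insert = NA, hap = NA,
               tmpl1 = a$tmpl, start1 = a$start, end1 = a$end,
               strand1 = a$strand, mapq1 = a$mapq,
               tmpl2 = b$tmpl, start2 = b$start, end2 = b$end,
               strand2 = b$strand, mapq2 = b$mapq)
}
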