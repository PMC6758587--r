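#' Pairwise recombination fractions and LOD scores for a selfed F2
#'
#' For every marker pair, estimates the recombination fraction by
#' maximum likelihood for phase-unknown codominant F2 data: an EM
#' algorithm over the 3 x 3 genotype table treats the double
#' heterozygote as a mixture of parental and recombinant gamete pairs,
#' is run under both linkage phases (the repulsion table is the coupling
#' table with one marker's dosage flipped), and the phase with the
#' higher likelihood wins.  LOD = log10 L(r_hat) / L(0.5).  Pairs are
#' handled pairwise-complete: individuals missing either call are
#' dropped; pairs with no complete observations get r_hat = 0.5, LOD 0.
#'
#' All pairs are estimated simultaneously (the nine pair-count matrices
#' are cross products of genotype indicator matrices and the EM update
#' is elementwise), so dense marker sets remain fast.
#'
#' @param x a [GenotypeMatrix-class] with dosage calls 0/1/2/NA.
#' @param maxIter,tol EM iteration cap and convergence tolerance on r.
#' @return a [LinkageMatrix-class].
#' @export
pairwiseLinkage <- function(x, maxIter = 100L, tol = 1e-08) {
    G <- genotypeCalls(x)
    m <- nrow(G)
    if (m < 2) stop("need at least 2 markers")
    I <- lapply(0:2, function(g) {
        M <- (G == g) * 1
        M[is.na(M)] <- 0
        M
    })
    # N[[g]][[h]][i, j] = individuals with marker i = g and marker j = h
    N <- lapply(I, function(A) lapply(I, function(B) tcrossprod(A, B)))
    n00 <- N[[1]][[1]]; n01 <- N[[1]][[2]]; n02 <- N[[1]][[3]]
    n10 <- N[[2]][[1]]; n11 <- N[[2]][[2]]; n12 <- N[[2]][[3]]
    n20 <- N[[3]][[1]]; n21 <- N[[3]][[2]]; n22 <- N[[3]][[3]]
    tot <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22

    em <- function(c2, c4, dbl, tot) {
        # c2: classes with 1 recombinant gamete, c4: 2 recombinants,
        # dbl: double heterozygotes (parental/recombinant mixture)
        r <- matrix(0.25, nrow(tot), ncol(tot))
        for (it in seq_len(maxIter)) {
            p2 <- ((1 - r) / 2)^2
            q2 <- (r / 2)^2
            post <- 2 * q2 / (p2 + q2)     # E[rec gametes | double het]
            rnew <- (c2 + 2 * c4 + dbl * post) / (2 * pmax(tot, 1))
            rnew <- pmin(pmax(rnew, 1e-07), 0.5)
            if (max(abs(rnew - r)) < tol) { r <- rnew; break }
            r <- rnew
        }
        r
    }
    loglik <- function(r, n00, n01, n02, n10, n11, n12, n20, n21, n22) {
        p <- (1 - r) / 2; q <- r / 2
        (n00 + n22) * log(p^2) + (n01 + n10 + n12 + n21) * log(2 * p * q) +
            (n02 + n20) * log(q^2) + n11 * log(2 * p^2 + 2 * q^2)
    }
    ll <- function(r, swap) {
        if (!swap) loglik(r, n00, n01, n02, n10, n11, n12, n20, n21, n22)
        else loglik(r, n02, n01, n00, n12, n11, n10, n22, n21, n20)
    }
    safe <- function(M) { M[!is.finite(M)] <- 0; M }

    # coupling: recombinants are the anti-diagonal corners
    rC <- em(c2 = n01 + n10 + n12 + n21,
             c4 = n02 + n20, dbl = n11, tot = tot)
    # repulsion: flip marker B's dosage
    rR <- em(c2 = n01 + n10 + n12 + n21,
             c4 = n00 + n22, dbl = n11, tot = tot)
    llC <- safe(ll(rC, FALSE)); llR <- safe(ll(rR, TRUE))
    useR <- llR > llC
    rhat <- ifelse(useR, rR, rC)
    llBest <- pmax(llC, llR)
    ll0 <- safe(ll(matrix(0.5, m, m), FALSE))
    lod <- pmax((llBest - ll0) / log(10), 0)
    rhat[tot == 0] <- 0.5
    lod[tot == 0] <- 0
    rhat <- pmin(pmax((rhat + t(rhat)) / 2, 0), 0.5)
    lod <- pmax((lod + t(lod)) / 2, 0)
    diag(rhat) <- 0
    mk <- markerInfo(x)
    dimnames(rhat) <- dimnames(lod) <- list(mk$id, mk$id)
    new("LinkageMatrix", markers = mk, rhat = rhat, lod = lod)
}

#' Grid-search likelihood oracle for one marker pair
#'
#' Direct maximization of the phase-unknown F2 likelihood over a dense
#' grid of recombination fractions; used as an independent check of the
#' EM estimates.
#'
#' @param gA,gB dosage vectors 0/1/2/NA for the two markers.
#' @param grid candidate recombination fractions.
#' @return list with \code{rhat} and \code{lod}.
#' @export
gridLinkage <- function(gA, gB, grid = seq(0.001, 0.5, by = 0.001)) {
    ok <- !is.na(gA) & !is.na(gB)
    gA <- gA[ok]; gB <- gB[ok]
    if (!length(gA)) return(list(rhat = 0.5, lod = 0))
    tab <- table(factor(gA, 0:2), factor(gB, 0:2))
    llr <- function(r, flip) {
        p <- (1 - r) / 2; q <- r / 2
        P <- matrix(c(p^2, 2 * p * q, q^2,
                      2 * p * q, 2 * p^2 + 2 * q^2, 2 * p * q,
                      q^2, 2 * p * q, p^2), 3, 3, byrow = TRUE)
        if (flip) P <- P[, 3:1]
        sum(tab * log(P))
    }
    best <- -Inf; rbest <- 0.5
    for (r in grid) for (flip in c(FALSE, TRUE)) {
        v <- llr(r, flip)
        if (v > best) { best <- v; rbest <- r }
    }
    list(rhat = rbest, lod = max((best - llr(0.5, FALSE)) / log(10), 0))
}

#' Detect complete linkage breaks along projected chromosomes
#'
#' Scans each chromosome's position-sorted markers and reports a break
#' between consecutive markers when the median LOD of the
#' \code{flank} x \code{flank} cross-boundary pairs falls below
#' \code{minLod} while the median LOD within both flanks stays at or
#' above it.  Runs of consecutive qualifying boundaries (a single
#' physical break can satisfy the test at several adjacent marker gaps)
#' are merged, reporting the boundary with the weakest cross-boundary
#' linkage.
#'
#' @param linkage a [LinkageMatrix-class] (markers sorted by position
#'   within chromosome, as produced from a [GenotypeMatrix-class]).
#' @param minLod LOD threshold separating "linked" from "unlinked".
#' @param flank number of markers examined on each side.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} (the bp interval between the two boundary markers),
#'   \code{crossLod}, \code{leftLod}, \code{rightLod}.  Chromosomes with
#'   fewer than \code{2 * flank} markers are skipped with a warning.
#' @export
detectLinkageBreaks <- function(linkage, minLod = 3, flank = 10L) {
    mk <- linkageMarkers(linkage)
    lod <- linkageLod(linkage)
    out <- list()
    offTri <- function(M) M[upper.tri(M)]
    for (ch in unique(mk$chrom)) {
        idx <- which(mk$chrom == ch)
        if (length(idx) < 2L * flank) {
            warning("chromosome '", ch, "' has fewer than ", 2L * flank,
                    " markers; skipped")
            next
        }
        cand <- NULL
        for (b in seq(flank, length(idx) - flank)) {
            left <- idx[(b - flank + 1L):b]
            right <- idx[(b + 1L):(b + flank)]
            cross <- median(lod[left, right])
            withinL <- median(offTri(lod[left, left]))
            withinR <- median(offTri(lod[right, right]))
            if (cross < minLod && withinL >= minLod && withinR >= minLod)
                cand <- rbind(cand, data.frame(
                    b = b, chrom = ch,
                    start = mk$pos[idx[b]], end = mk$pos[idx[b + 1L]],
                    crossLod = cross, leftLod = withinL,
                    rightLod = withinR,
                    gapLod = lod[idx[b], idx[b + 1L]]))
        }
        if (is.null(cand)) next
        grp <- cumsum(c(1L, diff(cand$b) > 1L))
        for (g in unique(grp)) {
            blk <- cand[grp == g, ]
            # the physical break is the gap whose two flanking markers
            # are themselves unlinked
            out[[length(out) + 1L]] <-
                blk[which.min(blk$gapLod), c(-1L, -ncol(blk)),
                    drop = FALSE]
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), crossLod = numeric(),
                          leftLod = numeric(), rightLod = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Detect trans-chromosome linkage blocks
#'
#' Single-linkage clusters of markers at LOD >= \code{minLod}, formed
#' ignoring chromosome assignment.  A cluster spanning two or more
#' projected reference chromosomes signals a translocation: it is
#' decomposed into per-chromosome blocks (source interval, marker
#' count), each reported with the partner chromosome of the same
#' cluster with which its markers show the strongest median linkage.
#'
#' @param linkage a [LinkageMatrix-class].
#' @param minMarkers smallest reportable block.
#' @param minLod LOD threshold for clustering edges.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{nMarkers}, \code{partner}, \code{medianLod},
#'   \code{cluster}.
#' @export
detectTranslocationSignal <- function(linkage, minMarkers = 3L,
                                      minLod = 3) {
    mk <- linkageMarkers(linkage)
    if (length(unique(mk$chrom)) < 2)
        stop("need markers on at least 2 chromosomes")
    lod <- linkageLod(linkage)
    m <- nrow(mk)
    # union-find single linkage
    parent <- seq_len(m)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    edges <- which(lod >= minLod & upper.tri(lod), arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
        a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
        if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(m), find, 0L)
    out <- list()
    for (cp in unique(comp)) {
        members <- which(comp == cp)
        chs <- unique(mk$chrom[members])
        if (length(chs) < 2) next
        for (ch in chs) {
            mem <- members[mk$chrom[members] == ch]
            if (length(mem) < minMarkers) next
            others <- setdiff(chs, ch)
            med <- vapply(others, function(oc)
                median(lod[mem, members[mk$chrom[members] == oc],
                           drop = FALSE]), 0)
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch, start = min(mk$pos[mem]),
                end = max(mk$pos[mem]), nMarkers = length(mem),
                partner = others[which.max(med)],
                medianLod = max(med), cluster = as.integer(cp))
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), nMarkers = integer(),
                          partner = character(), medianLod = numeric(),
                          cluster = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
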