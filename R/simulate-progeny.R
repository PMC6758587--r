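#' Simulate a selfed progeny genotyped at residual-heterozygosity markers
#'
#' Meiosis is simulated on the parent's true chromosome structures: each
#' gamete receives Poisson-distributed crossovers (Haldane model, no
#' interference) at \code{crossoverRate} Morgan-equivalents per
#' structure.  Marker sites live on segments (uniformly placed), and the
#' parent is heterozygous at every site: one haplotype carries the
#' alternate allele on all its copies of the segment, the other the
#' reference allele.  An offspring's observed genotype is called from
#' the summed allele dosage over \emph{all} copies of the marker's
#' segment it inherits, mimicking a mapping pipeline that piles reads
#' from every copy onto one projected reference position.  Sites in
#' single-copy segments therefore segregate 1:2:1; sites in segments
#' duplicated across translocated chromosomes show collapsed,
#' pseudo-tetrasomic segregation (roughly 1:14:1 for two copies), which
#' the chi-square segregation filter later removes -- emptying the
#' duplicated breakpoint regions of usable markers just as observed in
#' real data.
#'
#' Markers are reported at their projected coordinate on the reference
#' karyotype; markers in novel segments (absent from the reference) are
#' dropped.  Structural heterozygotes are refused: their meiosis
#' (quadrivalent pairing, semi-sterility) is outside the generator's
#' scope.
#'
#' @param fixture result of [buildFixtureKaryotype()].
#' @param parent an [accessionSpec()]; all structural genotypes must be
#'   \code{hom_ref} or \code{hom_alt}.
#' @param nIndividuals number of selfed offspring (>= 10).
#' @param nMarkers number of marker sites (>= 50); refused when it
#'   exceeds genome length / 100 bp.
#' @param seed integer seed.
#' @param crossoverRate expected crossovers per gamete per structure.
#' @return a [GenotypeMatrix-class]; \code{provenanceLog()} carries the
#'   per-marker truth (segment, offset, copy number) under \code{truth}.
#' @export
simulateSelfProgeny <- function(fixture, parent, nIndividuals, nMarkers,
                                seed, crossoverRate = 1) {
    stopifnot(inherits(parent, "AccessionSpec"),
              nIndividuals >= 10, nMarkers >= 50)
    if (any(parent$structuralGenotype == "het"))
        stop("meiosis of structural heterozygotes is not modelled")
    set.seed(seed)
    structs <- haplotypeStructures(fixture, parent)[[1L]]
    layout <- .structureLayout(fixture$karyotype)[structs]
    structLen <- vapply(layout, function(x) max(x$end), 0)
    if (nMarkers > sum(structLen) / 100)
        stop("marker spacing below 100 bp: reduce nMarkers")

    # marker sites on segments, proportional to segment length
    segs <- unique(unlist(lapply(layout, function(x) x$name)))
    segLen <- stats::setNames(segmentCatalog(fixture$karyotype)$length,
                              segmentCatalog(fixture$karyotype)$name)[segs]
    nm <- pmax(round(nMarkers * segLen / sum(segLen)), 1L)
    mk <- do.call(rbind, lapply(segs, function(sg)
        data.frame(segment = sg,
                   offset = sort(floor(runif(nm[[sg]]) * segLen[[sg]])))))

    # occurrences of each marker on the parent's structures
    occ <- do.call(rbind, lapply(names(layout), function(st) {
        lay <- layout[[st]]
        hit <- match(mk$segment, lay$name)
        ok <- !is.na(hit)
        data.frame(marker = which(ok), structure = st,
                   pos = lay$start[hit[ok]] + mk$offset[ok])
    }))
    nCopies <- tabulate(occ$marker, nbins = nrow(mk))

    # meiosis: summed allele dosage over all copies, both gametes
    raw <- matrix(0L, nrow(mk), nIndividuals)
    for (st in names(layout)) {
        rows <- occ[occ$structure == st, ]
        if (!nrow(rows)) next
        posM <- rows$pos / structLen[[st]] * crossoverRate
        for (g in seq_len(2L * nIndividuals)) {
            nxo <- rpois(1L, crossoverRate)
            xo <- sort(runif(nxo, 0, crossoverRate))
            phase <- sample(0:1, 1L)
            allele <- (phase + findInterval(posM, xo)) %% 2L
            ind <- (g + 1L) %/% 2L
            raw[rows$marker, ind] <- raw[rows$marker, ind] + allele
        }
    }

    # observed genotype from the summed allele fraction
    th <- callThresholds()
    altf <- raw / (2L * nCopies)
    maf <- pmin(altf, 1 - altf)
    calls <- matrix(NA_integer_, nrow(raw), ncol(raw))
    calls[maf < th$homMaf & altf <= 0.5] <- 0L
    calls[maf < th$homMaf & altf > 0.5] <- 2L
    calls[maf >= th$homMaf & altf > th$hetAltFreq &
          (1 - altf) > th$hetAltFreq] <- 1L

    # projection onto the reference karyotype; novel segments dropped
    refCoords <- segmentCoords(fixture$reference)
    hit <- match(mk$segment, refCoords$segment)
    keep <- !is.na(hit)
    proj <- data.frame(mk[keep, ],
                       chrom = refCoords$structure[hit[keep]],
                       pos = refCoords$start[hit[keep]] + mk$offset[keep] + 1,
                       copies = nCopies[keep])
    calls <- calls[keep, , drop = FALSE]
    ord <- order(proj$chrom, proj$pos)
    proj <- proj[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    ids <- sprintf("%s_m%04d", proj$chrom, seq_len(nrow(proj)))
    colnames(calls) <- sprintf("ind%03d", seq_len(nIndividuals))
    genotypeMatrix(
        markers = data.frame(chrom = proj$chrom, pos = proj$pos, id = ids),
        calls = calls,
        provenance = list(
            generator = "simulateSelfProgeny",
            seed = seed, parent = parent$name,
            crossoverRate = crossoverRate,
            truth = data.frame(id = ids, segment = proj$segment,
                               offset = proj$offset,
                               copies = proj$copies)))
}
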