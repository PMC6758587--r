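#' Simulate a structured accession panel with genotypes and read sets
#'
#' SNP genotypes follow a two-level allele-frequency model: each site has
#' an ancestral frequency drawn Uniform(0.05, 0.95); each population
#' group perturbs it through a Balding-Nichols Beta distribution with the
#' group's divergence parameter F (an accession's \code{snpDivergence});
#' individual genotypes are Binomial(2, group frequency).  Per-accession
#' read sets are simulated over the breakpoint neighbourhoods of every
#' junction of the fixture karyotype, with the accession's structural
#' genotypes respected, so junction typing and the SNP-based factorial
#' analysis can be cross-validated on the same individuals.
#'
#' @param fixture result of [buildFixtureKaryotype()].
#' @param specs list of [accessionSpec()] objects; at least two distinct
#'   groups, each with at least one member.
#' @param nSnps number of SNP sites (>= 100).
#' @param seed integer seed.
#' @param library a [libraryModel()] for the read sets (default a 2x150
#'   paired-end library at 20x); set to NULL to skip read simulation.
#' @param templates named list of [SimulatedGenome-class] templates to
#'   align read sets against (default the fixture's reference and
#'   translocated genomes).
#' @param flank breakpoint-neighbourhood half-width in bp around each
#'   junction of the accession's own structures.
#' @return list with \code{genotypes} (a complete-call
#'   [GenotypeMatrix-class], accessions as individuals), \code{groups}
#'   (named group label per accession) and \code{readSets} (per
#'   accession, per template, a pair \code{data.frame}).
#' @export
simulateAccessionPanel <- function(fixture, specs, nSnps, seed,
                                   library = libraryModel(500, 50, 150,
                                                          coverage = 20),
                                   templates = list(
                                       reference = fixture$reference,
                                       translocated = fixture$translocated),
                                   flank = 3000) {
    stopifnot(nSnps >= 100, length(specs) >= 2)
    groupsList <- lapply(specs, function(s) s$group)
    groups <- vapply(groupsList, paste, "", collapse = "x")
    parentGroups <- unique(unlist(groupsList))
    if (length(parentGroups) < 2)
        stop("panel needs at least two groups")
    set.seed(seed)

    refCoords <- segmentCoords(fixture$reference)
    bounds <- tapply(refCoords$end, refCoords$structure, max)
    chrom <- sample(names(bounds), nSnps, replace = TRUE,
                    prob = bounds / sum(bounds))
    sitePos <- floor(runif(nSnps) * bounds[chrom]) + 1

    p0 <- runif(nSnps, 0.05, 0.95)
    fOf <- vapply(stats::setNames(nm = parentGroups), function(g)
        max(vapply(specs, function(s)
            if (g %in% s$group) s$snpDivergence else 0, 0)), 0)
    pg <- sapply(parentGroups, function(g) {
        f <- fOf[[g]]
        if (f == 0) p0
        else rbeta(nSnps, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    })
    # single-group accessions draw both alleles from their group; an
    # admixed accession draws one allele per site from each parent group
    calls <- vapply(seq_along(specs), function(i) {
        gs <- groupsList[[i]]
        if (length(gs) == 1L) rbinom(nSnps, 2L, pg[, gs])
        else rbinom(nSnps, 1L, pg[, gs[1L]]) +
            rbinom(nSnps, 1L, pg[, gs[2L]])
    }, integer(nSnps))
    colnames(calls) <- vapply(specs, function(s) s$name, "")

    ord <- order(chrom, sitePos)
    genotypes <- genotypeMatrix(
        markers = data.frame(chrom = chrom[ord], pos = sitePos[ord],
                             id = sprintf("snp%05d", seq_len(nSnps))),
        calls = calls[ord, , drop = FALSE],
        provenance = list(generator = "simulateAccessionPanel",
                          seed = seed, nSnps = nSnps,
                          divergence = as.list(fOf)))

    readSets <- NULL
    if (!is.null(library)) {
        regions <- data.frame(
            structure = fixture$junctions$structure,
            start = pmax(0, fixture$junctions$coord - flank),
            end = fixture$junctions$coord + flank)
        readSets <- lapply(seq_along(specs), function(i) {
            lapply(seq_along(templates), function(t)
                simulateReadPairs(fixture, specs[[i]], library,
                                  seed = seed + 1000L * i + t,
                                  template = templates[[t]],
                                  regions = regions))
        })
        readSets <- lapply(readSets, stats::setNames, names(templates))
        names(readSets) <- colnames(calls)
    }
    list(genotypes = genotypes,
         groups = stats::setNames(groups, colnames(calls)),
         readSets = readSets)
}
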