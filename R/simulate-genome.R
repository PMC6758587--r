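#' Build the two-translocation fixture karyotype and genomes
#'
#' Constructs a desk-scale pair of diploid genomes emulating the study
#' system: a reference-like genome with chromosomes
#' \code{chr2 = a-b-c}, \code{chr8 = d-e-f}, \code{chr1 = g-h-i},
#' \code{chr9 = j-k1-k2-k3-l}, and a doubly translocated genome with
#' \code{2T8 = a-x-f}, \code{8T2 = d-y-c}, \code{1T9 = g-h-k1-k2-k3-l},
#' \code{9T1 = j-k1-k3-h-i}.  Macro-segments get length \code{scale} with
#' a seeded +/-20\% jitter; the micro-segments at the 2/8 breakpoints are
#' fixed at their characterized sizes: b = 1,200 bp and e = 3,000 bp are
#' present only in the reference, the novel breakpoint segments
#' x = 600 bp and y = 1,200 bp only in the translocated genome.  Segment
#' sequences are i.i.d. uniform A/C/G/T and shared between the two
#' genomes wherever a segment appears.
#'
#' @param scale macro-segment length in bp; must be >= 10,000 so that
#'   junction flanking windows cannot overlap each other.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return a list with elements
#'   \describe{
#'     \item{reference, translocated}{[SimulatedGenome-class] objects.}
#'     \item{karyotype}{the full [KaryotypeModel-class] holding all eight
#'       structures and the two alternative-structure groups
#'       (\code{"2/8"}, \code{"1/9"}).}
#'     \item{junctions}{\code{data.frame} of every junction with its
#'       template structure and 0-based coordinate (the truth manifest
#'       for breakpoint localization).}
#'     \item{manifest}{list of the generation parameters (seed, scale,
#'       segment lengths).}
#'   }
#' @examples
#' fx <- buildFixtureKaryotype(scale = 20000, seed = 1)
#' fx$reference
#' head(fx$junctions)
#' @export
buildFixtureKaryotype <- function(scale = 50000, seed = 1) {
    if (scale < 10000)
        stop("scale below 10,000 bp: junction windows would overlap")
    set.seed(seed)
    macro <- c("a", "c", "d", "f", "g", "h", "i", "j", "k1", "k2", "k3", "l")
    lens <- stats::setNames(
        round(scale * runif(length(macro), 0.8, 1.2)), macro)
    lens <- c(lens, b = 1200, e = 3000, x = 600, y = 1200)
    origin <- c(a = "chr2", b = "chr2", c = "chr2",
                d = "chr8", e = "chr8", f = "chr8",
                g = "chr1", h = "chr1", i = "chr1",
                j = "chr9", k1 = "chr9", k2 = "chr9", k3 = "chr9",
                l = "chr9", x = "novel", y = "novel")
    segNames <- names(origin)
    segments <- data.frame(name = segNames,
                           length = as.numeric(lens[segNames]),
                           origin = unname(origin))
    structures <- list(chr1 = c("g", "h", "i"),
                       chr2 = c("a", "b", "c"),
                       chr8 = c("d", "e", "f"),
                       chr9 = c("j", "k1", "k2", "k3", "l"),
                       `1T9` = c("g", "h", "k1", "k2", "k3", "l"),
                       `2T8` = c("a", "x", "f"),
                       `8T2` = c("d", "y", "c"),
                       `9T1` = c("j", "k1", "k3", "h", "i"))
    groups <- list(`2/8` = list(ref = c("chr2", "chr8"),
                                alt = c("2T8", "8T2"),
                                absent = c("b", "e")),
                   `1/9` = list(ref = c("chr1", "chr9"),
                                alt = c("1T9", "9T1")))
    karyotype <- karyotypeModel(segments, structures, groups)

    alphabet <- c("A", "C", "G", "T")
    segSeq <- lapply(stats::setNames(nm = segNames), function(s)
        paste(sample(alphabet, lens[[s]], replace = TRUE), collapse = ""))

    refStructs <- c("chr1", "chr2", "chr8", "chr9")
    altStructs <- c("1T9", "2T8", "8T2", "9T1")
    mk <- function(keep) {
        sub <- karyotypeModel(segments, structures[keep])
        seqs <- Biostrings::DNAStringSet(vapply(keep, function(nm)
            paste(unlist(segSeq[structures[[nm]]]), collapse = ""), ""))
        names(seqs) <- keep
        coords <- karyotypeSegmentBED(sub)
        new("SimulatedGenome", karyotype = sub, sequences = seqs,
            segmentCoords = data.frame(structure = coords$chrom,
                                       segment = coords$name,
                                       start = coords$start,
                                       end = coords$end))
    }
    reference <- mk(refStructs)
    translocated <- mk(altStructs)

    bed <- karyotypeSegmentBED(karyotype)
    jn <- do.call(rbind, lapply(names(structures), function(nm) {
        st <- structures[[nm]]
        if (length(st) < 2) return(NULL)
        data.frame(structure = nm,
                   left = st[-length(st)], right = st[-1L],
                   coord = bed$end[bed$chrom == nm][-length(st)])
    }))
    list(reference = reference, translocated = translocated,
         karyotype = karyotype, junctions = jn,
         manifest = list(seed = seed, scale = scale,
                         segment_lengths = as.list(lens)))
}

#' Describe an accession for simulation
#'
#' @param name accession id.
#' @param group population label (used by the panel simulator's
#'   allele-frequency model); two labels describe an admixed accession
#'   drawing one allele per site from each parent group.
#' @param structuralGenotype named character vector giving, for each
#'   alternative-structure group of the fixture karyotype, one of
#'   \code{"hom_ref"}, \code{"het"}, \code{"hom_alt"}.
#' @param snpDivergence group-level allele-frequency divergence parameter
#'   (Wright's F of a Balding-Nichols model) in [0, 1).
#' @return a list of class \code{"AccessionSpec"}.
#' @examples
#' calcutta4like <- accessionSpec("C4", "burmannica",
#'     c(`2/8` = "hom_alt", `1/9` = "hom_alt"), snpDivergence = 0.15)
#' @export
accessionSpec <- function(name, group, structuralGenotype,
                          snpDivergence = 0.15) {
    stopifnot(all(structuralGenotype %in% c("hom_ref", "het", "hom_alt")),
              !is.null(names(structuralGenotype)),
              length(group) %in% 1:2,
              snpDivergence >= 0, snpDivergence < 1)
    structure(list(name = name, group = group,
                   structuralGenotype = structuralGenotype,
                   snpDivergence = snpDivergence),
              class = "AccessionSpec")
}

#' Resolve an accession's two haplotype structure sets
#'
#' For each alternative-structure group of the fixture, haplotype 1
#' carries the reference structures unless the accession is
#' \code{hom_alt}; haplotype 2 carries the alternative structures unless
#' \code{hom_ref}.  A structural heterozygote therefore has one full
#' reference and one full translocated chromosome set, reflecting that a
#' diploid carrying one translocated chromosome must carry its reciprocal
#' partner (a gamete missing a segment is assumed lethal).
#'
#' @param fixture result of [buildFixtureKaryotype()].
#' @param accession an [accessionSpec()].
#' @return list of two character vectors of structure names.
#' @export
haplotypeStructures <- function(fixture, accession) {
    groups <- structureGroups(fixture$karyotype)
    miss <- setdiff(names(groups), names(accession$structuralGenotype))
    if (length(miss))
        stop("accession '", accession$name,
             "' lacks a structural genotype for group(s): ",
             paste(miss, collapse = ", "))
    hap <- list(character(), character())
    for (g in names(groups)) {
        geno <- accession$structuralGenotype[[g]]
        hap[[1L]] <- c(hap[[1L]],
                       if (geno == "hom_alt") groups[[g]]$alt
                       else groups[[g]]$ref)
        hap[[2L]] <- c(hap[[2L]],
                       if (geno == "hom_ref") groups[[g]]$ref
                       else groups[[g]]$alt)
    }
    hap
}

# internal: the SimulatedGenome carrying a given structure name
.genomeFor <- function(fixture, structure) {
    if (structure %in% names(genomeSequences(fixture$reference)))
        fixture$reference
    else fixture$translocated
}

#' Write genome sequences as FASTA
#'
#' @param genome a [SimulatedGenome-class].
#' @param path output file; 60-column wrapped FASTA.
#' @return the path, invisibly.
#' @export
writeGenomeFASTA <- function(genome, path) {
    Biostrings::writeXStringSet(genomeSequences(genome), path, width = 60L)
    invisible(path)
}
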