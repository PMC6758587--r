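#' Construct a KaryotypeModel
#'
#' @param segments \code{data.frame} with columns \code{name},
#'   \code{length}, \code{origin}; or a list coercible to one.
#' @param structures named \code{list} of structures.  Each structure may be
#'   a character vector of segment names (all forward) or a
#'   \code{data.frame} with columns \code{segment} and \code{orient}.
#' @param groups named \code{list} of
#'   \code{list(ref = , alt = , absent = )} alternative-structure groups
#'   (\code{absent} optional).
#' @return a validated [KaryotypeModel-class].
#' @examples
#' kar <- karyotypeModel(
#'   segments = data.frame(name = c("a", "b", "c"),
#'                         length = c(1000, 1200, 800),
#'                         origin = "chr2"),
#'   structures = list(chr2 = c("a", "b", "c")))
#' structureNames(kar)
#' @export
karyotypeModel <- function(segments, structures, groups = list()) {
    segments <- as.data.frame(segments, stringsAsFactors = FALSE)
    segments$length <- as.numeric(segments$length)
    structures <- lapply(structures, function(s) {
        if (is.character(s))
            s <- data.frame(segment = s, orient = "+",
                            stringsAsFactors = FALSE)
        as.data.frame(s, stringsAsFactors = FALSE)
    })
    new("KaryotypeModel", segments = segments, structures = structures,
        groups = groups)
}

#' @describeIn karyotypeModel segment catalogue as a \code{data.frame}
#' @param x a \code{KaryotypeModel}
#' @export
segmentCatalog <- function(x) x@segments

#' @describeIn karyotypeModel names of the chromosome structures
#' @export
structureNames <- function(x) names(x@structures)

#' @describeIn karyotypeModel ordered segments of one structure
#' @param structure structure name
#' @export
structureSegments <- function(x, structure) {
    if (!structure %in% names(x@structures))
        stop("unknown structure: ", structure)
    x@structures[[structure]]
}

#' @describeIn karyotypeModel alternative-structure groups
#' @export
structureGroups <- function(x) x@groups

setMethod("show", "KaryotypeModel", function(object) {
    cat(sprintf("KaryotypeModel: %d segments, %d structures, %d groups\n",
                nrow(object@segments), length(object@structures),
                length(object@groups)))
    for (nm in names(object@structures)) {
        st <- object@structures[[nm]]
        lab <- ifelse(st$orient == "-", paste0(st$segment, "'"), st$segment)
        cat(sprintf("  %s = %s\n", nm, paste(lab, collapse = "-")))
    }
})

#' Accessors for SimulatedGenome
#'
#' @param x a [SimulatedGenome-class]
#' @return \code{genomeKaryotype}: the [KaryotypeModel-class];
#'   \code{genomeSequences}: the per-structure \code{DNAStringSet};
#'   \code{segmentCoords}: \code{data.frame} of 0-based half-open segment
#'   intervals per structure.
#' @name SimulatedGenome-accessors
NULL

#' @rdname SimulatedGenome-accessors
#' @export
genomeKaryotype <- function(x) x@karyotype

#' @rdname SimulatedGenome-accessors
#' @export
genomeSequences <- function(x) x@sequences

#' @rdname SimulatedGenome-accessors
#' @export
segmentCoords <- function(x) x@segmentCoords

setMethod("show", "SimulatedGenome", function(object) {
    cat(sprintf("SimulatedGenome: %d structures, %s bp total\n",
                length(object@sequences),
                format(sum(Biostrings::width(object@sequences)),
                       big.mark = ",")))
    show(object@karyotype)
})

#' Construct a GenotypeMatrix
#'
#' @param markers \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{id}; rows must be sorted by position within chromosome.
#' @param calls markers x individuals matrix of dosages 0/1/2/NA.
#' @param provenance optional list recording how the matrix was made.
#' @return a validated [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(markers, calls, provenance = list()) {
    storage.mode(calls) <- "integer"
    if (is.null(rownames(calls))) rownames(calls) <- markers$id
    new("GenotypeMatrix", markers = as.data.frame(markers),
        calls = calls, provenance = provenance)
}

#' @describeIn genotypeMatrix marker metadata
#' @param x a \code{GenotypeMatrix}
#' @export
markerInfo <- function(x) x@markers

#' @describeIn genotypeMatrix the dosage matrix (markers x individuals)
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn genotypeMatrix individual ids
#' @export
individualNames <- function(x) colnames(x@calls)

#' @describeIn genotypeMatrix filter/provenance log
#' @export
provenanceLog <- function(x) x@provenance

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d markers x %d individuals (%.2f%% missing)\n",
                nrow(object@calls), ncol(object@calls),
                100 * mean(is.na(object@calls))))
})

#' Accessors for LinkageMatrix
#'
#' @param x a [LinkageMatrix-class]
#' @return \code{linkageRhat} and \code{linkageLod} return the symmetric
#'   pairwise matrices; \code{linkageMarkers} the marker metadata.
#' @name LinkageMatrix-accessors
NULL

#' @rdname LinkageMatrix-accessors
#' @export
linkageRhat <- function(x) x@rhat

#' @rdname LinkageMatrix-accessors
#' @export
linkageLod <- function(x) x@lod

#' @rdname LinkageMatrix-accessors
#' @export
linkageMarkers <- function(x) x@markers

setMethod("show", "LinkageMatrix", function(object) {
    cat(sprintf("LinkageMatrix: %d markers on %d chromosome(s)\n",
                nrow(object@markers), length(unique(object@markers$chrom))))
})

#' Accessors for FactorialResult
#'
#' @param x a [FactorialResult-class]
#' @return \code{factorialCoordinates}: active coordinates (accessions x
#'   axes); \code{factorialEigenvalues}: full spectrum;
#'   \code{factorialVariance}: percent variance per retained axis;
#'   \code{supplementaryCoordinates}: projected accessions.
#' @name FactorialResult-accessors
NULL

#' @rdname FactorialResult-accessors
#' @export
factorialCoordinates <- function(x) x@coordinates

#' @rdname FactorialResult-accessors
#' @export
factorialEigenvalues <- function(x) x@eigenvalues

#' @rdname FactorialResult-accessors
#' @export
factorialVariance <- function(x) x@percentVariance

#' @rdname FactorialResult-accessors
#' @export
supplementaryCoordinates <- function(x) x@supplementary

setMethod("show", "FactorialResult", function(object) {
    k <- ncol(object@coordinates)
    cat(sprintf("FactorialResult: %d active accessions, %d axes\n",
                nrow(object@coordinates), k))
    cat(sprintf("  %% variance: %s\n",
                paste(sprintf("%.1f", object@percentVariance), collapse = ", ")))
    if (nrow(object@supplementary))
        cat(sprintf("  %d supplementary accession(s) projected\n",
                    nrow(object@supplementary)))
})
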