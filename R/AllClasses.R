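#' @import methods
#' @importFrom S4Vectors isSingleNumber
NULL

#' KaryotypeModel: segments ordered into chromosome structures
#'
#' A \code{KaryotypeModel} catalogues named genomic segments and the
#' chromosome structures (ordered, oriented segment lists) built from them.
#' Alternative structures are organised into groups: each group opposes a
#' set of reference chromosomes to the set of derived (e.g. translocated)
#' chromosomes that rearrange the same segments.  A reciprocal translocation
#' between chromosomes 2 and 8 is one group \code{{chr2, chr8}} vs
#' \code{{2T8, 8T2}}.
#'
#' @slot segments \code{data.frame} with columns \code{name} (unique short
#'   label), \code{length} (bp, >= 1) and \code{origin} (reference
#'   chromosome the segment derives from, or \code{"novel"}).
#' @slot structures named \code{list}; each element is a \code{data.frame}
#'   with columns \code{segment} and \code{orient} (\code{"+"}/\code{"-"}),
#'   ordered along the chromosome.  A segment name appears at most once per
#'   structure.
#' @slot groups named \code{list}; each element is
#'   \code{list(ref = <character>, alt = <character>)} naming the
#'   alternative structure sets.
#'
#' @seealso [karyotypeModel()], [enumerateJunctions()], [identifySSJs()]
#' @exportClass KaryotypeModel
setClass("KaryotypeModel",
         representation(segments   = "data.frame",
                        structures = "list",
                        groups     = "list"))

setValidity("KaryotypeModel", function(object) {
    seg <- object@segments
    msg <- character()
    if (!all(c("name", "length", "origin") %in% names(seg)))
        return("segments needs columns name, length, origin")
    if (anyDuplicated(seg$name))
        msg <- c(msg, "segment names must be unique")
    if (any(seg$length < 1))
        msg <- c(msg, "segment lengths must be >= 1")
    for (nm in names(object@structures)) {
        st <- object@structures[[nm]]
        if (!all(c("segment", "orient") %in% names(st))) {
            msg <- c(msg, sprintf("structure '%s' needs segment/orient columns", nm))
            next
        }
        if (nrow(st) < 1)
            msg <- c(msg, sprintf("structure '%s' has no segments", nm))
        if (anyDuplicated(st$segment))
            msg <- c(msg, sprintf("structure '%s' repeats a segment", nm))
        bad <- setdiff(st$segment, seg$name)
        if (length(bad))
            msg <- c(msg, sprintf("structure '%s' references uncatalogued segments: %s",
                                  nm, paste(bad, collapse = ", ")))
    }
    for (g in names(object@groups)) {
        grp <- object@groups[[g]]
        if (!all(c("ref", "alt") %in% names(grp))) {
            msg <- c(msg, sprintf("group '%s' needs ref and alt members", g))
            next
        }
        bad <- setdiff(c(grp$ref, grp$alt), names(object@structures))
        if (length(bad))
            msg <- c(msg, sprintf("group '%s' names unknown structures: %s",
                                  g, paste(bad, collapse = ", ")))
        # completeness: non-novel segments of the alt set must cover the ref
        # set minus segments explicitly absent from the catalogue
        refseg <- unique(unlist(lapply(object@structures[grp$ref],
                                       function(s) s$segment)))
        altseg <- unique(unlist(lapply(object@structures[grp$alt],
                                       function(s) s$segment)))
        novel <- seg$name[seg$origin == "novel"]
        missing <- setdiff(setdiff(refseg, novel), union(altseg, grp$absent))
        if (length(missing))
            msg <- c(msg, sprintf(
                "group '%s' would miss chromosome segment(s) %s; declare them in the group's 'absent' field if genuinely lost",
                g, paste(missing, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' SimulatedGenome: per-structure sequences for a karyotype
#'
#' Couples a [KaryotypeModel-class] with one nucleotide sequence per
#' chromosome structure and the 0-based half-open coordinates of every
#' segment on its structure.  Shared segments carry identical sequence
#' wherever they appear.
#'
#' @slot karyotype a \code{KaryotypeModel}.
#' @slot sequences \code{DNAStringSet}, one entry per structure.
#' @slot segmentCoords \code{data.frame} with columns \code{structure},
#'   \code{segment}, \code{start}, \code{end} (0-based half-open).
#'
#' @exportClass SimulatedGenome
setClass("SimulatedGenome",
         representation(karyotype     = "KaryotypeModel",
                        sequences     = "DNAStringSet",
                        segmentCoords = "data.frame"))

setValidity("SimulatedGenome", function(object) {
    kar <- object@karyotype
    msg <- character()
    sl <- stats::setNames(kar@segments$length, kar@segments$name)
    for (nm in names(kar@structures)) {
        want <- sum(sl[kar@structures[[nm]]$segment])
        if (!nm %in% names(object@sequences)) {
            msg <- c(msg, sprintf("no sequence for structure '%s'", nm))
            next
        }
        if (length(object@sequences[[nm]]) != want)
            msg <- c(msg, sprintf("sequence length for '%s' != sum of segment lengths", nm))
    }
    msg <- c(msg, if (!all(c("structure", "segment", "start", "end") %in%
                           names(object@segmentCoords)))
        "segmentCoords needs structure/segment/start/end columns")
    if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: codominant genotype calls for markers x individuals
#'
#' Markers are rows, individuals columns; calls are dosages of the
#' alternate allele coded 0/1/2 with \code{NA} for missing.  Marker
#' coordinates are positions projected onto a reference karyotype
#' (1-based), non-decreasing within each chromosome.
#'
#' @slot markers \code{data.frame} with columns \code{chrom}, \code{pos}
#'   (1-based), \code{id}.
#' @slot calls integer \code{matrix}, markers x individuals, values in
#'   \code{c(0L, 1L, 2L, NA)}.
#' @slot provenance \code{list}; free-form log of how the matrix was
#'   produced and filtered.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(markers    = "data.frame",
                        calls      = "matrix",
                        provenance = "list"))

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!all(c("chrom", "pos", "id") %in% names(object@markers)))
        return("markers needs columns chrom, pos, id")
    if (nrow(object@markers) != nrow(object@calls))
        msg <- c(msg, "markers and calls row counts differ")
    v <- object@calls
    if (!all(v %in% c(0L, 1L, 2L, NA)))
        msg <- c(msg, "calls must be 0/1/2/NA")
    for (ch in unique(object@markers$chrom)) {
        p <- object@markers$pos[object@markers$chrom == ch]
        if (is.unsorted(p))
            msg <- c(msg, sprintf("positions not non-decreasing on '%s'", ch))
    }
    if (length(msg)) msg else TRUE
})

#' LinkageMatrix: pairwise recombination fractions and LOD scores
#'
#' Symmetric matrices of maximum-likelihood recombination-fraction
#' estimates (\code{rhat}, in [0, 0.5]) and LOD scores (>= 0) for every
#' marker pair of a [GenotypeMatrix-class], with marker metadata carried
#' alongside.
#'
#' @slot markers \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{id}.
#' @slot rhat numeric \code{matrix} of recombination fractions.
#' @slot lod numeric \code{matrix} of LOD scores.
#'
#' @exportClass LinkageMatrix
setClass("LinkageMatrix",
         representation(markers = "data.frame",
                        rhat    = "matrix",
                        lod     = "matrix"))

setValidity("LinkageMatrix", function(object) {
    msg <- character()
    m <- nrow(object@markers)
    if (!all(dim(object@rhat) == c(m, m)) || !all(dim(object@lod) == c(m, m)))
        return("matrix dimensions must match marker count")
    if (max(abs(object@rhat - t(object@rhat)), na.rm = TRUE) > 1e-8 ||
        max(abs(object@lod - t(object@lod)), na.rm = TRUE) > 1e-6)
        msg <- c(msg, "rhat and lod must be symmetric")
    if (any(object@rhat < 0 | object@rhat > 0.5, na.rm = TRUE))
        msg <- c(msg, "rhat outside [0, 0.5]")
    if (any(object@lod < -1e-8, na.rm = TRUE))
        msg <- c(msg, "lod must be non-negative")
    if (any(abs(diag(object@rhat)) > 1e-12))
        msg <- c(msg, "diagonal rhat must be 0")
    if (length(msg)) msg else TRUE
})

#' FactorialResult: principal coordinates of a dissimilarity matrix
#'
#' Holds the classical metric principal-coordinates decomposition of a
#' dissimilarity matrix: coordinates of the active accessions, the full
#' eigenvalue spectrum (negative eigenvalues retained), percent variance
#' per retained axis computed on the positive part of the spectrum, and
#' coordinates of any supplementary (projected) accessions.
#'
#' @slot coordinates numeric \code{matrix}, active accessions x axes.
#' @slot eigenvalues numeric; full non-increasing spectrum.
#' @slot percentVariance numeric; per retained axis.
#' @slot supplementary numeric \code{matrix} (possibly 0-row).
#'
#' @exportClass FactorialResult
setClass("FactorialResult",
         representation(coordinates     = "matrix",
                        eigenvalues     = "numeric",
                        percentVariance = "numeric",
                        supplementary   = "matrix"))

setValidity("FactorialResult", function(object) {
    msg <- character()
    if (is.unsorted(rev(object@eigenvalues)))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (sum(object@percentVariance) > 100 + 1e-8)
        msg <- c(msg, "percent variance exceeds 100 over retained axes")
    if (length(msg)) msg else TRUE
})
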