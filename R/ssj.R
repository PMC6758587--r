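#' Resolve signature-segment-junction loci on their template genomes
#'
#' Combines [identifySSJs()] on the full fixture karyotype with the
#' junction coordinates of the fixture manifest: every SSJ is reported
#' on the template structure that owns it, with its 0-based junction
#' coordinate and flanking-window width.
#'
#' @param fixture result of [buildFixtureKaryotype()].
#' @param window flanking window in bp on each side of the junction
#'   (default 1,000).
#' @return \code{data.frame} with columns \code{structure}, \code{left},
#'   \code{right}, \code{tmpl}, \code{coord}, \code{window}.
#' @export
ssjLoci <- function(fixture, window = 1000) {
    s <- identifySSJs(fixture$karyotype)
    j <- fixture$junctions
    hit <- match(paste(s$structure, s$left, s$right),
                 paste(j$structure, j$left, j$right))
    data.frame(s, tmpl = s$structure, coord = j$coord[hit],
               window = window)
}

#' Count proper pairs flanking a junction
#'
#' Counts concordant pairs with one mate entirely within
#' \code{(coord - window, coord]} and the other entirely within
#' \code{[coord, coord + window)} on the locus template -- reads on
#' either side of the junction.  A mate overlapping the junction point
#' itself is not "on either side" and such pairs are not counted (a
#' spanning-read mode can be enabled where single reads crossing the
#' junction should count too).  Both mates need mapping quality >=
#' \code{minMapq}; each pair counts once.
#'
#' @param pairs pair \code{data.frame} aligned against the template
#'   carrying the junction.
#' @param library the [libraryModel()] of the read set (proper-pair
#'   semantics follow [classifyPairs()]).
#' @param tmpl,coord template name and 0-based junction coordinate.
#' @param window flanking window, must be >= the read length.
#' @param minMapq mapping-quality floor.
#' @param countSpanningReads if TRUE, also count proper pairs with a
#'   mate overlapping the junction point (default off).
#' @param classes optional precomputed [classifyPairs()] labels.
#' @return integer support count.
#' @export
countJunctionSupport <- function(pairs, library, tmpl, coord,
                                 window = 1000, minMapq = 10,
                                 countSpanningReads = FALSE,
                                 classes = NULL) {
    if (window < library$readLength)
        stop("window smaller than the read length")
    if (is.null(classes)) classes <- classifyPairs(pairs, library)
    ok <- classes == "concordant" & pairs$tmpl1 == tmpl &
        pairs$mapq1 >= minMapq & pairs$mapq2 >= minMapq
    ok[is.na(ok)] <- FALSE
    p <- pairs[ok, , drop = FALSE]
    ls <- pmin(p$start1, p$start2); le <- pmin(p$end1, p$end2)
    rs <- pmax(p$start1, p$start2); re <- pmax(p$end1, p$end2)
    leftIn <- ls >= coord - window & le <= coord
    rightIn <- rs >= coord & re <= coord + window
    n <- sum(leftIn & rightIn)
    if (countSpanningReads) {
        crosses <- (ls < coord & le > coord) | (rs < coord & re > coord)
        inWin <- ls >= coord - window & re <= coord + window
        n <- n + sum(crosses & inWin)
    }
    as.integer(n)
}

#' Genotype one alternative-structure group from SSJ detections
#'
#' Applies the positive-evidence decision table to per-SSJ support
#' counts: an SSJ is detected when its support reaches
#' \code{minSupport}; a structure is detected when any of its SSJs is.
#' All alternative structures detected with no reference SSJ gives
#' \code{hom_alt}; every reference chromosome detected gives
#' \code{hom_ref} (no alternative signal) or \code{het} (alternative
#' signal too); detections leaving one chromosome of the group without
#' any evidence give \code{partial}; no detections at all give
#' \code{undetermined}.  Whenever one member of a reciprocal pair is
#' detected without its partner, the partner is recorded in
#' \code{inferredComplement}: a diploid missing it would lack a
#' chromosome segment, so its presence is inferred -- as inference,
#' never as detection.
#'
#' @param support \code{data.frame} with columns \code{structure},
#'   \code{left}, \code{right}, \code{support} (and optionally
#'   \code{detected}, which is recomputed).
#' @param group one alternative-structure group,
#'   \code{list(ref = , alt = )}.
#' @param minSupport pairs needed to call an SSJ detected.
#' @return list of class \code{"StructuralGenotype"}: \code{call},
#'   \code{detections}, \code{structureDetected},
#'   \code{inferredComplement}.
#' @export
genotypeStructure <- function(support, group, minSupport = 3L) {
    stopifnot(all(c("structure", "support") %in% names(support)))
    members <- c(group$ref, group$alt)
    sup <- support[support$structure %in% members, , drop = FALSE]
    if (!nrow(sup)) stop("no SSJs supplied for this group")
    sup$detected <- sup$support >= minSupport
    det <- vapply(stats::setNames(nm = members), function(st)
        any(sup$detected[sup$structure == st]), NA)
    hasSSJ <- vapply(stats::setNames(nm = members), function(st)
        any(sup$structure == st), NA)
    refDet <- det[group$ref]; altDet <- det[group$alt]
    allAlt <- all(altDet | !hasSSJ[group$alt]) && any(altDet)
    allRef <- all(refDet | !hasSSJ[group$ref]) && any(refDet)
    call <- if (!any(det)) "undetermined"
        else if (allAlt && !any(refDet)) "hom_alt"
        else if (allRef && any(altDet)) "het"
        else if (allRef) "hom_ref"
        else "partial"
    inferred <- character()
    for (pair in list(group$ref, group$alt))
        if (length(pair) == 2 && xor(det[pair[1]], det[pair[2]]))
            inferred <- c(inferred, pair[!det[pair]])
    structure(list(call = call, detections = sup,
                   structureDetected = det,
                   inferredComplement = inferred,
                   minSupport = minSupport),
              class = "StructuralGenotype")
}

#' Type an accession's structural genotype across several templates
#'
#' Counts junction support against each template independently and ORs
#' the per-SSJ detections across templates: small structural variants
#' near a junction can abolish mapping on one template while another
#' template of the same macrostructure still captures the pairs, so a
#' junction detected on any template counts as present.  Support counts
#' are reported per template, never summed.
#'
#' @param readSets named list (one per template) of pair
#'   \code{data.frame}s for one accession.
#' @param loci \code{data.frame} of SSJ loci: columns \code{structure},
#'   \code{left}, \code{right}, \code{tmpl}, \code{coord},
#'   \code{window}, and \code{template} naming which read set each
#'   locus row applies to (defaults to all read sets whose template
#'   carries \code{tmpl}).
#' @param group alternative-structure group to genotype.
#' @param library the [libraryModel()] of the read sets.
#' @param minSupport detection threshold per SSJ.
#' @return a \code{"StructuralGenotype"} (see [genotypeStructure()])
#'   with a \code{perTemplate} support matrix attached.
#' @export
multiTemplateTyping <- function(readSets, loci, group, library,
                                minSupport = 3L) {
    stopifnot(length(readSets) >= 1)
    key <- paste(loci$structure, loci$left, loci$right)
    ssjs <- unique(data.frame(structure = loci$structure,
                              left = loci$left, right = loci$right))
    skey <- paste(ssjs$structure, ssjs$left, ssjs$right)
    supTab <- matrix(NA_integer_, nrow(ssjs), length(readSets),
                     dimnames = list(skey, names(readSets)))
    for (tn in names(readSets)) {
        pr <- readSets[[tn]]
        if (is.null(pr) || !nrow(pr)) next
        classes <- classifyPairs(pr, library)
        sub <- if ("template" %in% names(loci))
            loci[loci$template == tn, , drop = FALSE]
        else loci[loci$tmpl %in% unique(c(pr$tmpl1, pr$tmpl2)), ,
                  drop = FALSE]
        for (r in seq_len(nrow(sub))) {
            k <- paste(sub$structure[r], sub$left[r], sub$right[r])
            supTab[k, tn] <- countJunctionSupport(
                pr, library, sub$tmpl[r], sub$coord[r],
                window = sub$window[r], classes = classes)
        }
    }
    merged <- apply(supTab, 1L, function(v)
        if (all(is.na(v))) 0L else max(v, na.rm = TRUE))
    support <- data.frame(ssjs, support = as.integer(merged))
    gt <- genotypeStructure(support, group, minSupport)
    gt$perTemplate <- supTab
    gt
}

#' Type every accession of a simulated panel at every group
#'
#' @param panel result of [simulateAccessionPanel()].
#' @param fixture result of [buildFixtureKaryotype()].
#' @param library the panel's [libraryModel()].
#' @param window,minSupport see [countJunctionSupport()] and
#'   [genotypeStructure()].
#' @return nested list: per accession, per group, a
#'   \code{"StructuralGenotype"}.
#' @export
typePanelSSJs <- function(panel, fixture,
                          library = libraryModel(500, 50, 150,
                                                 coverage = 20),
                          window = 1000, minSupport = 3L) {
    loci <- ssjLoci(fixture, window = window)
    groups <- structureGroups(fixture$karyotype)
    lapply(panel$readSets, function(rs)
        lapply(groups, function(g)
            multiTemplateTyping(rs, loci, g, library,
                                minSupport = minSupport)))
}

#' @export
print.StructuralGenotype <- function(x, ...) {
    cat("StructuralGenotype:", x$call, "\n")
    det <- x$detections
    cat(sprintf("  %s %s-%s: support %d%s\n", det$structure, det$left,
                det$right, det$support,
                ifelse(det$detected, " *", "")), sep = "")
    if (length(x$inferredComplement))
        cat("  inferred complement (not detected):",
            paste(x$inferredComplement, collapse = ", "), "\n")
    invisible(x)
}
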