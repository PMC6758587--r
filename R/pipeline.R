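#' Default accession panel for a pipeline run
#'
#' A small structured panel mirroring the study design: one group
#' carrying both translocations (hom_alt), two translocation-free wild
#' groups, and a set of cultivated accessions (including structural
#' heterozygotes for the 2/8 event) that the diversity stage projects
#' as supplementary points.
#'
#' @param nPerWildGroup wild accessions per group.
#' @param snpDivergence group divergence parameter.
#' @return list with \code{specs} (list of [accessionSpec()]) and
#'   \code{cultivated} (names of the supplementary accessions).
#' @export
defaultPanelSpecs <- function(nPerWildGroup = 4L, snpDivergence = 0.15) {
    mk <- function(prefix, group, g28, g19, n = nPerWildGroup)
        lapply(seq_len(n), function(i)
            accessionSpec(sprintf("%s%02d", prefix, i), group,
                          c(`2/8` = g28, `1/9` = g19), snpDivergence))
    wild <- c(mk("BUR", "burmannica_like", "hom_alt", "hom_alt"),
              mk("STD", "standard_like", "hom_ref", "hom_ref"),
              mk("ZEB", "zebrina_like", "hom_ref", "hom_ref"))
    cult <- c(mk("HET", "cultivated", "het", "hom_ref", n = 2L),
              mk("CVR", "cultivated", "hom_ref", "hom_ref", n = 2L))
    list(specs = c(wild, cult),
         cultivated = vapply(cult, function(s) s$name, ""))
}

#' Assemble a pipeline run configuration
#'
#' One object holds every stage's parameters with the package defaults;
#' it round-trips losslessly through JSON via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param scale fixture macro-segment length in bp.
#' @param matePair,pairedEnd [libraryModel()]s for the two library
#'   types.
#' @param nIndividuals,nMarkers selfed-progeny design.
#' @param nSnps panel SNP count.
#' @param nPerWildGroup panel size parameter (see
#'   [defaultPanelSpecs()]).
#' @param thresholds named list of analysis thresholds; missing entries
#'   take the defaults shown in the usage.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 42L, scale = 50000,
                      matePair = libraryModel(5000, 300, 150,
                                              coverage = 30),
                      pairedEnd = libraryModel(500, 50, 150,
                                               coverage = 20),
                      nIndividuals = 100L, nMarkers = 400L,
                      nSnps = 300L, nPerWildGroup = 4L,
                      thresholds = list()) {
    def <- list(alpha = 4e-06, markerMissingMax = 0.025,
                individualMissingMax = 0.01,
                minLod = 3, flank = 10L, minMarkers = 3L,
                clusterMinSupport = 5L, minSpan = 3L, mergeTol = 500,
                uncoveredMinLen = 500, ssjWindow = 1000,
                ssjMinSupport = 3L, nAxes = 3L, crossoverRate = 1)
    bad <- setdiff(names(thresholds), names(def))
    if (length(bad))
        stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    def[names(thresholds)] <- thresholds
    structure(list(seed = as.integer(seed), scale = scale,
                   matePair = matePair, pairedEnd = pairedEnd,
                   nIndividuals = nIndividuals, nMarkers = nMarkers,
                   nSnps = nSnps, nPerWildGroup = nPerWildGroup,
                   thresholds = def),
              class = "RunConfig")
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
    jsonlite::write_json(.plainList(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

# strip S3 classes from nested lists for JSON serialization
.plainList <- function(x)
    if (is.list(x)) lapply(unclass(x), .plainList) else x

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    lm <- function(x) do.call(libraryModel, x[c("insertMean", "insertSd",
                                                "readLength",
                                                "orientation",
                                                "errorRate", "coverage")])
    runConfig(seed = doc$seed, scale = doc$scale,
              matePair = lm(doc$matePair), pairedEnd = lm(doc$pairedEnd),
              nIndividuals = doc$nIndividuals, nMarkers = doc$nMarkers,
              nSnps = doc$nSnps, nPerWildGroup = doc$nPerWildGroup,
              thresholds = doc$thresholds)
}

#' Run the full translocation-detection pipeline
#'
#' Executes simulate, filter-snps, linkage, matepair-sv, ssj-type and
#' diversity in dependency order from one configuration, writing every
#' stage's outputs and a consolidated JSON report (cross-referenced
#' against the simulator truth manifest) into \code{outdir}.  Reruns
#' with the same configuration and seed reproduce the report exactly.
#'
#' @param config a [runConfig()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the consolidated report, invisibly (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, outdir = tempfile("transloMap_run_"),
                        quiet = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    th <- config$thresholds
    report <- list(config = .plainList(config), stages = list())
    say <- function(...) if (!quiet) message(...)
    logFile <- file.path(outdir, "run.log")
    cat("", file = logFile)
    stage <- function(name, fn) {
        say("stage: ", name)
        t0 <- Sys.time()
        out <- tryCatch(fn(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        # timing goes to the log, not the report, which must be
        # byte-identical across reruns of the same config + seed
        cat(sprintf("%s: %.2f s\n", name,
                    as.numeric(Sys.time() - t0, units = "secs")),
            file = logFile, append = TRUE)
        report$stages[[name]] <<- out
        out
    }

    # -- simulate --------------------------------------------------------
    fixture <- NULL
    parent <- accessionSpec("parent_hom_alt", "burmannica_like",
                            c(`2/8` = "hom_alt", `1/9` = "hom_alt"))
    sim <- stage("simulate", function() {
        fixture <<- buildFixtureKaryotype(config$scale, config$seed)
        writeKaryotypeJSON(fixture$karyotype,
                           file.path(outdir, "karyotype.json"))
        utils::write.table(
            karyotypeSegmentBED(fixture$karyotype),
            file.path(outdir, "segments.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
        utils::write.table(fixture$junctions,
                           file.path(outdir, "junctions_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(genome_bp = sum(Biostrings::width(
                 genomeSequences(fixture$reference))),
             junctions = nrow(fixture$junctions))
    })

    # -- filter-snps -----------------------------------------------------
    filtered <- NULL
    stage("filter_snps", function() {
        gm <- simulateSelfProgeny(fixture, parent, config$nIndividuals,
                                  config$nMarkers, config$seed + 1L,
                                  crossoverRate = th$crossoverRate)
        vcf <- file.path(outdir, "progeny.vcf")
        writeGenotypeVCF(gm, vcf, seed = config$seed + 2L)
        called <- readGenotypeVCF(vcf)
        seg <- applySegregationFilter(called, alpha = th$alpha)
        filtered <<- filterGenotypeMatrix(seg, th$markerMissingMax,
                                          th$individualMissingMax)
        writeGenotypeTSV(filtered, file.path(outdir, "genotypes.tsv"))
        writeFilterReportJSON(filtered,
                              file.path(outdir, "filter_report.json"))
        list(markers_raw = nrow(genotypeCalls(gm)),
             markers_kept = nrow(genotypeCalls(filtered)),
             individuals_kept = ncol(genotypeCalls(filtered)))
    })

    # -- linkage ---------------------------------------------------------
    truthBoundaries <- local({
        j <- fixture$junctions
        j[j$structure %in% names(genomeSequences(fixture$reference)), ]
    })
    stage("linkage", function() {
        lk <- pairwiseLinkage(filtered)
        breaks <- detectLinkageBreaks(lk, minLod = th$minLod,
                                      flank = th$flank)
        blocks <- detectTranslocationSignal(lk,
                                            minMarkers = th$minMarkers,
                                            minLod = th$minLod)
        utils::write.table(breaks, file.path(outdir, "linkage_breaks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(blocks, file.path(outdir, "trans_blocks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        atBoundary <- vapply(seq_len(nrow(breaks)), function(i)
            any(truthBoundaries$structure == breaks$chrom[i] &
                truthBoundaries$coord >= breaks$start[i] &
                truthBoundaries$coord <= breaks$end[i]), NA)
        list(breaks = nrow(breaks),
             breaks_at_true_boundaries = sum(atBoundary),
             trans_blocks = nrow(blocks),
             chrom_pairs = unique(paste(
                 pmin(blocks$chrom, blocks$partner),
                 pmax(blocks$chrom, blocks$partner), sep = "/")))
    })

    # -- matepair-sv -----------------------------------------------------
    mpAccessions <- list(
        accessionSpec("mp_hom_alt", "burmannica_like",
                      c(`2/8` = "hom_alt", `1/9` = "hom_alt")),
        accessionSpec("mp_het", "cultivated",
                      c(`2/8` = "het", `1/9` = "hom_ref")),
        accessionSpec("mp_hom_ref", "standard_like",
                      c(`2/8` = "hom_ref", `1/9` = "hom_ref")))
    stage("matepair_sv", function() {
        out <- lapply(mpAccessions, function(acc) {
            pr <- simulateReadPairs(fixture, acc, config$matePair,
                                    seed = config$seed + 10L +
                                        match(acc$name, vapply(
                                            mpAccessions,
                                            function(a) a$name, "")))
            cls <- classifyPairs(pr, config$matePair)
            clu <- clusterDiscordant(pr, config$matePair, cls,
                                     minSupport = th$clusterMinSupport)
            unc <- detectUncoveredSegments(pr, fixture$reference,
                                           minLen = th$uncoveredMinLen)
            ic <- interpretClusters(clu, unc, fixture$reference, pr,
                                    config$matePair,
                                    minSpan = th$minSpan,
                                    mergeTol = th$mergeTol)
            utils::write.table(
                clu, file.path(outdir, paste0("clusters_", acc$name,
                                              ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            list(accession = acc$name,
                 clusters = nrow(clu), uncovered = nrow(unc),
                 calls = lapply(ic$calls, function(cl) list(
                     type = cl$type, templates = cl$templates,
                     zygosity = cl$zygosity,
                     n_solutions = length(cl$structures),
                     structures = lapply(cl$structures[1], function(s)
                         vapply(s, paste, "", collapse = "-")))))
        })
        names(out) <- vapply(mpAccessions, function(a) a$name, "")
        jsonlite::write_json(out, file.path(outdir,
                                            "matepair_calls.json"),
                             auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        list(accessions = names(out),
             reciprocal_calls = vapply(out, function(o)
                 sum(vapply(o$calls, function(cl)
                     cl$type == "reciprocal_translocation", NA)), 0L))
    })

    # -- ssj-type --------------------------------------------------------
    panel <- NULL
    panelSpec <- defaultPanelSpecs(config$nPerWildGroup)
    stage("ssj_type", function() {
        panel <<- simulateAccessionPanel(fixture, panelSpec$specs,
                                         config$nSnps,
                                         config$seed + 100L,
                                         library = config$pairedEnd,
                                         flank = th$ssjWindow + 2000)
        ty <- typePanelSSJs(panel, fixture, config$pairedEnd,
                            window = th$ssjWindow,
                            minSupport = th$ssjMinSupport)
        calls <- lapply(ty, function(byGroup)
            lapply(byGroup, function(gt) list(
                call = gt$call,
                inferred_complement = gt$inferredComplement)))
        jsonlite::write_json(calls,
                             file.path(outdir, "ssj_calls.json"),
                             auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        sup <- do.call(rbind, lapply(names(ty), function(a)
            do.call(rbind, lapply(names(ty[[a]]), function(g) {
                det <- ty[[a]][[g]]$detections
                data.frame(accession = a, group = g, det)
            }))))
        utils::write.table(sup, file.path(outdir, "ssj_support.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        truthCall <- function(spec, g) {
            geno <- spec$structuralGenotype[[g]]
            if (g == "1/9")    # reference chromosomes 1/9 carry no SSJs
                switch(geno, hom_alt = "hom_alt", het = "hom_alt",
                       hom_ref = "undetermined")
            else geno
        }
        match <- vapply(panelSpec$specs, function(spec)
            all(vapply(names(structureGroups(fixture$karyotype)),
                       function(g)
                           ty[[spec$name]][[g]]$call == truthCall(spec, g),
                       NA)), NA)
        list(accessions = length(panelSpec$specs),
             calls_matching_truth = sum(match))
    })

    # -- diversity -------------------------------------------------------
    stage("diversity", function() {
        G <- panel$genotypes
        wild <- setdiff(individualNames(G), panelSpec$cultivated)
        D <- dissimilarityMatrix(G)
        fa <- factorialAnalysis(D[wild, wild], nAxes = th$nAxes)
        fa <- projectSupplementary(fa, D[panelSpec$cultivated, wild,
                                         drop = FALSE])
        coords <- rbind(
            data.frame(accession = rownames(factorialCoordinates(fa)),
                       role = "active", factorialCoordinates(fa)),
            data.frame(accession = rownames(supplementaryCoordinates(fa)),
                       role = "supplementary",
                       supplementaryCoordinates(fa)))
        utils::write.table(coords, file.path(outdir, "factorial.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(eigenvalues = factorialEigenvalues(fa),
                 percent_variance = factorialVariance(fa)),
            file.path(outdir, "factorial_eigen.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
        sil <- groupSilhouette(
            factorialCoordinates(fa)[, 1:2, drop = FALSE],
            panel$groups[wild])
        list(axes = ncol(factorialCoordinates(fa)),
             percent_variance = round(factorialVariance(fa), 2),
             wild_group_silhouette = round(sil, 3))
    })

    report$seed <- config$seed
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report: ", file.path(outdir, "report.json"))
    invisible(report)
}

#' Mean silhouette width of labelled points
#'
#' Simple Euclidean silhouette (mean over points of
#' \code{(b - a) / max(a, b)}) used to quantify how well factorial axes
#' separate population groups.
#'
#' @param coords numeric matrix, points x dimensions.
#' @param labels group label per point.
#' @return mean silhouette width.
#' @export
groupSilhouette <- function(coords, labels) {
    D <- as.matrix(stats::dist(coords))
    n <- nrow(D)
    s <- vapply(seq_len(n), function(i) {
        own <- labels == labels[i]
        own[i] <- FALSE
        if (!any(own)) return(0)
        a <- mean(D[i, own])
        b <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(g) mean(D[i, labels == g]), 0))
        (b - a) / max(a, b)
    }, 0)
    mean(s)
}
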