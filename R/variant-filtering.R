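#' Default genotype-calling thresholds
#'
#' Depth and allele-frequency rules for calling one sample's genotype at
#' a diallelic site from its ref/alt read depths: sites with total depth
#' below \code{minDepth} or above \code{maxDepth} are excluded; a minor
#' allele frequency below \code{homMaf} calls the major-allele
#' homozygote; an alternate-allele frequency above \code{hetAltFreq}
#' supported by at least \code{hetMinReads} reads calls a heterozygote;
#' anything else is missing.
#'
#' @return named list of thresholds.
#' @export
callThresholds <- function() {
    list(minDepth = 10, maxDepth = 1000, homMaf = 0.05,
         hetAltFreq = 0.15, hetMinReads = 3)
}

#' Call a genotype from ref/alt read depths
#'
#' Vectorized total function of the two depths: every depth pair maps to
#' exactly one of \code{excluded}, \code{hom_ref}, \code{hom_alt},
#' \code{het}, \code{missing}.  Rules apply in precedence order: depth
#' exclusion, then the minor-allele-frequency homozygote rule, then the
#' heterozygote rule; the 5-15\% alternate-frequency dead zone becomes
#' missing data.  Depth bounds are strict (totals of exactly
#' \code{minDepth} or \code{maxDepth} are retained).
#'
#' @param refDepth,altDepth non-negative integer read counts (vectors).
#' @param thresholds see [callThresholds()].
#' @return character vector of calls.
#' @examples
#' callSiteGenotype(c(5, 96, 80, 90), c(3, 4, 20, 10))
#' @export
callSiteGenotype <- function(refDepth, altDepth,
                             thresholds = callThresholds()) {
    if (any(refDepth < 0) || any(altDepth < 0))
        stop("negative read depth")
    th <- thresholds
    total <- refDepth + altDepth
    maf <- ifelse(total > 0, pmin(refDepth, altDepth) / total, 0)
    altf <- ifelse(total > 0, altDepth / total, 0)
    out <- rep("missing", length(total))
    out[maf < th$homMaf & altf <= 0.5] <- "hom_ref"
    out[maf < th$homMaf & altf > 0.5] <- "hom_alt"
    het <- !(maf < th$homMaf) & altf > th$hetAltFreq &
        altDepth >= th$hetMinReads
    out[het] <- "het"
    out[total < th$minDepth | total > th$maxDepth] <- "excluded"
    out
}

#' Chi-square segregation filter for a codominant F2 marker
#'
#' Pearson chi-square of observed genotype counts against an expected
#' ratio (1:2:1 for a selfed heterozygous parent), df = 2, asymptotic
#' p-value, no continuity correction.  A marker is kept when p >= alpha;
#' the extreme default alpha only removes grossly distorted markers.
#'
#' @param counts numeric length 3: counts of the two homozygotes and the
#'   heterozygote as (n_AA, n_Aa, n_aa).
#' @param expectedRatio expected segregation ratio (default 1:2:1).
#' @param alpha rejection threshold on the p-value.
#' @return list with \code{keep}, \code{chi2}, \code{p} (and
#'   \code{reason} when dropped).
#' @examples
#' chiSquareSegregationFilter(c(17, 33, 17))   # keep, p ~ 0.993
#' chiSquareSegregationFilter(c(50, 15, 2))    # drop, chi2 ~ 89.2
#' @export
chiSquareSegregationFilter <- function(counts, expectedRatio = c(1, 2, 1),
                                       alpha = 4e-06) {
    stopifnot(length(counts) == 3, length(expectedRatio) == 3)
    n <- sum(counts)
    if (n < 1)
        return(list(keep = FALSE, chi2 = NA_real_, p = NA_real_,
                    reason = "no observations"))
    expected <- n * expectedRatio / sum(expectedRatio)
    chi2 <- sum((counts - expected)^2 / expected)
    p <- pchisq(chi2, df = length(counts) - 1, lower.tail = FALSE)
    list(keep = p >= alpha, chi2 = chi2, p = p)
}

#' Filter markers by segregation ratio
#'
#' Applies [chiSquareSegregationFilter()] to every marker of a
#' [GenotypeMatrix-class] (counts taken over non-missing calls, dosage 0
#' and 2 as the homozygote classes) and drops rejected markers.
#'
#' @param x a \code{GenotypeMatrix}.
#' @inheritParams chiSquareSegregationFilter
#' @return filtered \code{GenotypeMatrix}; the provenance log gains a
#'   \code{segregation_filter} entry with per-marker chi2/p and drop
#'   reasons.
#' @export
applySegregationFilter <- function(x, expectedRatio = c(1, 2, 1),
                                   alpha = 4e-06) {
    calls <- genotypeCalls(x)
    res <- apply(calls, 1L, function(v) {
        ct <- c(sum(v == 0L, na.rm = TRUE), sum(v == 1L, na.rm = TRUE),
                sum(v == 2L, na.rm = TRUE))
        r <- chiSquareSegregationFilter(ct, expectedRatio, alpha)
        c(keep = as.numeric(r$keep), chi2 = r$chi2, p = r$p)
    })
    keep <- res["keep", ] == 1
    prov <- provenanceLog(x)
    prov$segregation_filter <- list(
        alpha = alpha, tested = ncol(res), dropped = sum(!keep),
        chi2 = unname(res["chi2", ]), p = unname(res["p", ]))
    genotypeMatrix(markerInfo(x)[keep, , drop = FALSE],
                   calls[keep, , drop = FALSE], prov)
}

#' Remove markers and individuals with excess missing data
#'
#' Markers above the marker missing-rate ceiling are removed first; then
#' individual missing rates are recomputed on the marker-filtered matrix
#' and individuals above their ceiling removed.  The filter log records
#' counts at each step; the operation is idempotent.
#'
#' @param x a [GenotypeMatrix-class].
#' @param markerMissingMax maximum fraction of missing calls per marker.
#' @param individualMissingMax maximum fraction per individual.
#' @return filtered \code{GenotypeMatrix}.
#' @export
filterGenotypeMatrix <- function(x, markerMissingMax = 0.025,
                                 individualMissingMax = 0.01) {
    calls <- genotypeCalls(x)
    if (!length(calls)) stop("empty genotype matrix")
    mMiss <- rowMeans(is.na(calls))
    keepM <- mMiss <= markerMissingMax
    calls2 <- calls[keepM, , drop = FALSE]
    if (!nrow(calls2))
        stop("all markers exceed the missing-data ceiling of ",
             markerMissingMax)
    iMiss <- colMeans(is.na(calls2))
    keepI <- iMiss <= individualMissingMax
    if (!any(keepI))
        stop("all individuals exceed the missing-data ceiling of ",
             individualMissingMax)
    prov <- provenanceLog(x)
    prov$missing_filter <- list(
        markerMissingMax = markerMissingMax,
        individualMissingMax = individualMissingMax,
        markersBefore = nrow(calls), markersDropped = sum(!keepM),
        individualsBefore = ncol(calls), individualsDropped = sum(!keepI))
    genotypeMatrix(markerInfo(x)[keepM, , drop = FALSE],
                   calls2[, keepI, drop = FALSE], prov)
}

#' Genotype-matrix VCF, TSV and report interchange
#'
#' \code{writeGenotypeVCF} writes a [GenotypeMatrix-class] as VCF v4.2
#' with \code{GT:DP:AD} per sample, simulating read depths
#' Poisson(\code{meanDepth}) and allocating ref/alt reads binomially
#' from the dosage with a small cross-contamination
#' \code{errorRate} (so the file exercises the depth-based caller).
#' \code{readGenotypeVCF} reads VCF with per-sample AD back into a
#' \code{GenotypeMatrix}, calling genotypes from depths via
#' [callSiteGenotype()] (\code{perSample = TRUE}, the default, applies
#' the depth bounds to each sample call; \code{perSample = FALSE}
#' instead excludes whole sites whose summed depth violates the bounds).
#' \code{writeGenotypeTSV}/\code{readGenotypeTSV} exchange the plain
#' dosage matrix, and \code{writeFilterReportJSON} dumps the provenance
#' log.
#'
#' @param x a \code{GenotypeMatrix}.
#' @param path output file.
#' @param meanDepth,errorRate,seed depth-simulation parameters.
#' @param thresholds see [callThresholds()].
#' @param perSample apply depth bounds per sample call (TRUE) or per
#'   site (FALSE).
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypeVCF <- function(x, path, meanDepth = 30, errorRate = 0.005,
                             seed = 1) {
    set.seed(seed)
    mk <- markerInfo(x)
    calls <- genotypeCalls(x)
    n <- length(calls)
    dp <- matrix(rpois(n, meanDepth), nrow(calls))
    altp <- matrix(c(errorRate, 0.5, 1 - errorRate)[calls + 1L],
                   nrow(calls))
    ad <- matrix(rbinom(n, as.vector(dp), as.vector(altp)), nrow(calls))
    gt <- matrix(c("0/0", "0/1", "1/1")[calls + 1L], nrow(calls))
    gt[is.na(calls)] <- "./."
    field <- matrix(sprintf("%s:%d:%d,%d", gt, dp, dp - ad, ad),
                    nrow(calls))
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", colnames(calls)),
                   collapse = "\t"))
    body <- apply(cbind(mk$chrom, mk$pos, mk$id, "A", "T", ".", ".",
                        ".", "GT:DP:AD", field), 1L, paste,
                  collapse = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname genotype-io
#' @export
readGenotypeVCF <- function(path, thresholds = callThresholds(),
                            perSample = TRUE) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, "AD")
    refd <- matrix(as.numeric(sub(",.*", "", ad)), nrow(ad))
    altd <- matrix(as.numeric(sub(".*,", "", ad)), nrow(ad))
    refd[is.na(refd)] <- 0; altd[is.na(altd)] <- 0
    lab <- matrix(callSiteGenotype(as.vector(refd), as.vector(altd),
                                   thresholds), nrow(ad))
    if (!perSample) {
        siteTotal <- rowSums(refd + altd)
        bad <- siteTotal < thresholds$minDepth * ncol(ad) |
            siteTotal > thresholds$maxDepth * ncol(ad)
        lab[bad, ] <- "excluded"
    }
    calls <- matrix(NA_integer_, nrow(lab), ncol(lab))
    calls[lab == "hom_ref"] <- 0L
    calls[lab == "het"] <- 1L
    calls[lab == "hom_alt"] <- 2L
    colnames(calls) <- colnames(ad)
    fix <- vcfR::getFIX(v)
    genotypeMatrix(
        markers = data.frame(chrom = fix[, "CHROM"],
                             pos = as.numeric(fix[, "POS"]),
                             id = fix[, "ID"]),
        calls = calls,
        provenance = list(source = path, thresholds = thresholds,
                          perSample = perSample,
                          excluded = sum(lab == "excluded"),
                          missing = sum(lab == "missing")))
}

#' @rdname genotype-io
#' @export
writeGenotypeTSV <- function(x, path) {
    df <- cbind(markerInfo(x), as.data.frame(genotypeCalls(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname genotype-io
#' @export
readGenotypeTSV <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    calls <- as.matrix(df[, -(1:3), drop = FALSE])
    genotypeMatrix(df[, 1:3], calls, list(source = path))
}

#' @rdname genotype-io
#' @export
writeFilterReportJSON <- function(x, path) {
    jsonlite::write_json(provenanceLog(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
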