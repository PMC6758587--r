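#' Allele-mismatch dissimilarity matrix
#'
#' Pairwise dissimilarity between accessions as the proportion of
#' unmatching alleles over complete diallelic sites: identical genotypes
#' contribute 0, a heterozygote against either homozygote 0.5, opposite
#' homozygotes 1.  With dosage coding this is the mean of
#' \code{|g_i - g_j| / 2}, i.e. a scaled Manhattan distance.
#'
#' @param x a [GenotypeMatrix-class] with no missing calls (filter
#'   first; missing genotypes raise an error).
#' @return symmetric \code{matrix} in [0, 1], zero diagonal, accession
#'   ids as dimnames.
#' @export
dissimilarityMatrix <- function(x) {
    G <- genotypeCalls(x)
    if (anyNA(G))
        stop("missing genotypes present; apply filterGenotypeMatrix ",
             "with a zero missing-data ceiling first")
    D <- as.matrix(stats::dist(t(G), method = "manhattan")) / (2 * nrow(G))
    dimnames(D) <- list(colnames(G), colnames(G))
    D
}

#' Factorial analysis (classical principal coordinates)
#'
#' Double-centers \code{-D^2 / 2}, eigendecomposes, and scales the
#' eigenvectors by the square roots of their eigenvalues.  Negative
#' eigenvalues (non-Euclidean input) are reported with a warning and
#' excluded from the percent-variance denominator, never silently
#' dropped from the spectrum.
#'
#' @param D symmetric dissimilarity matrix (e.g. from
#'   [dissimilarityMatrix()]).
#' @param nAxes number of axes to retain (capped at the number of
#'   positive eigenvalues).
#' @return a [FactorialResult-class].
#' @export
factorialAnalysis <- function(D, nAxes = 3L) {
    D <- as.matrix(D)
    if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix not symmetric")
    stopifnot(nAxes >= 1)
    n <- nrow(D)
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% (D * D) %*% J
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    lambda <- eg$values
    if (any(lambda < -1e-8 * max(abs(lambda))))
        warning("negative eigenvalues: dissimilarities are not Euclidean; ",
                "percent variance uses the positive part only")
    pos <- which(lambda > 1e-12 * max(abs(lambda)))
    k <- min(nAxes, length(pos))
    coords <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
        diag(sqrt(lambda[pos[seq_len(k)]]), k)
    rownames(coords) <- rownames(D)
    colnames(coords) <- paste0("Axis", seq_len(k))
    res <- new("FactorialResult",
               coordinates = coords,
               eigenvalues = lambda,
               percentVariance = 100 * lambda[pos[seq_len(k)]] /
                   sum(lambda[pos]),
               supplementary = matrix(numeric(), 0, k,
                                      dimnames = list(NULL,
                                                      colnames(coords))))
    attr(res, "eigenvectors") <- eg$vectors[, pos[seq_len(k)], drop = FALSE]
    attr(res, "diag2") <- diag(B)
    res
}

#' Project supplementary accessions onto existing factorial axes
#'
#' Places accessions that took no part in the decomposition (e.g.
#' cultivated hybrids projected into a wild-accession space) on the
#' axes of a [factorialAnalysis()] result from their dissimilarities to
#' the active accessions, using the standard principal-coordinates
#' supplementary-point formula (projection of the centered squared
#' dissimilarity profile onto the active eigenvectors).  An active
#' accession supplied as supplementary recovers its own coordinates.
#'
#' @param result a [FactorialResult-class].
#' @param dSup numeric matrix (or vector) of dissimilarities of each
#'   supplementary accession (rows) to all active accessions (columns,
#'   in the active order).
#' @return the \code{FactorialResult} with \code{supplementary}
#'   coordinates filled in.
#' @export
projectSupplementary <- function(result, dSup) {
    if (is.null(dim(dSup))) dSup <- matrix(dSup, nrow = 1)
    V <- attr(result, "eigenvectors")
    if (is.null(V))
        stop("result carries no eigenvectors; rerun factorialAnalysis")
    lambda <- result@eigenvalues[seq_len(ncol(V))]
    if (any(lambda <= 0))
        stop("cannot project onto axes with non-positive eigenvalues")
    diag2 <- attr(result, "diag2")      # squared lengths |x_i|^2
    n <- length(diag2)
    if (ncol(dSup) != n)
        stop("dSup must give dissimilarities to all ", n,
             " active accessions")
    d2 <- dSup^2
    # y . x_i = -(d_si^2 - mean_i d_si^2 - (|x_i|^2 - mean |x_i|^2)) / 2
    b <- -0.5 * sweep(sweep(d2, 1L, rowMeans(d2)), 2L,
                      diag2 - mean(diag2))
    coords <- b %*% V %*% diag(1 / sqrt(lambda), length(lambda))
    rownames(coords) <- rownames(dSup)
    colnames(coords) <- colnames(result@coordinates)
    out <- result
    out@supplementary <- coords
    attr(out, "eigenvectors") <- V
    attr(out, "diag2") <- diag2
    out
}
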