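## Core estimators: per-site pairwise diversity, Watterson's theta,
## Tajima's D, and Weir-Cockerham (1984) FST variance components.
## All are written to vectorise over sites/windows; the scan layer calls
## the vectorised forms directly.

#' Harmonic-number constant a1(n) = sum_{i=1}^{n-1} 1/i
#'
#' The denominator of Watterson's theta and the first of Tajima's
#' constants; vectorised over `n`.
#'
#' @param n haploid sample size(s), `n >= 2`.
#' @return numeric vector of a1 values.
#' @export
harmonicA1 <- function(n) {
    vapply(n, function(k) {
        if (is.na(k) || k < 2) return(NA_real_)
        sum(1 / seq_len(k - 1))
    }, numeric(1))
}

#' Per-site pairwise nucleotide diversity
#'
#' The fraction of distinct chromosome pairs that differ at a biallelic
#' site: `2 j (n - j) / (n (n - 1))`, where `n` is the number of sampled
#' chromosomes and `j` the alternate-allele count. Summing over the sites
#' of a window gives the window's theta-pi.
#'
#' @param n haploid sample size(s) at the site, `n >= 2`; vectorised.
#' @param j alternate-allele count(s), `0 <= j <= n`.
#' @return per-site diversity in `[0, 1]`.
#' @examples
#' sitePi(4, 2)  # 4 of the 6 chromosome pairs differ -> 2/3
#' @export
sitePi <- function(n, j) {
    if (any(n < 2, na.rm = TRUE))
        stop("sitePi needs n >= 2 chromosomes")
    if (any(j < 0 | j > n, na.rm = TRUE))
        stop("allele count j must satisfy 0 <= j <= n")
    2 * j * (n - j) / (n * (n - 1))
}

#' Watterson's theta from segregating sites
#'
#' `S / a1(n)`: the expected-SFS estimator of the scaled mutation rate
#' from the count of segregating sites.
#'
#' @param S number of segregating sites (vectorised).
#' @param n haploid sample size, `n >= 2`.
#' @return Watterson's theta for the region that yielded `S`.
#' @export
wattersonTheta <- function(S, n) {
    if (any(n < 2, na.rm = TRUE))
        stop("wattersonTheta needs n >= 2 chromosomes")
    if (any(S < 0, na.rm = TRUE)) stop("S must be non-negative")
    S / harmonicA1(n)
}

#' Tajima's variance constants for sample size n
#'
#' The a1..e2 constants of the D statistic's standard-error term.
#'
#' @param n haploid sample size, `n >= 4` (the variance term is unstable
#'   below that).
#' @return a list with elements `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajimaConstants <- function(n) {
    if (any(n < 4, na.rm = TRUE))
        stop("tajimaConstants needs n >= 4")
    a1 <- harmonicA1(n)
    a2 <- vapply(n, function(k) sum(1 / seq_len(k - 1)^2), numeric(1))
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' The normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta:
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Negative values signal
#' an excess of rare variants, the footprint of a sweep or expansion.
#' With `S = 0` the statistic is undefined and `NA` is returned
#' (deliberately distinct from 0).
#'
#' @param S number of segregating sites in the region (vectorised).
#' @param piSum summed per-site diversity ([sitePi()]) over the region.
#' @param n haploid sample size, `n >= 4`; may be a vector matching `S`.
#' @return Tajima's D, or `NA` where `S = 0`.
#' @examples
#' tajimasD(3, 1.5, 4)  # about -0.754
#' @export
tajimasD <- function(S, piSum, n) {
    if (any(n < 4, na.rm = TRUE))
        stop("tajimasD needs n >= 4 (variance constants unstable)")
    k <- tajimaConstants(n)
    num <- piSum - S / k$a1
    v <- k$e1 * S + k$e2 * S * (S - 1)
    out <- ifelse(S > 0 & v > 0, num / sqrt(v), NA_real_)
    out
}

#' Weir-Cockerham per-site variance components
#'
#' Computes the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) components of allele-frequency
#' variance for one biallelic site observed in `r >= 2` populations,
#' following Weir & Cockerham's (1984) diploid moment estimator. The
#' inputs per population are the number of genotyped diploids, the
#' alternate-allele frequency and the observed heterozygote fraction, so
#' the components remain informative for partially inbred samples.
#'
#' @param nDip integer vector (length r) of genotyped diploids per
#'   population, all `>= 1` and `mean(nDip) > 1`.
#' @param p numeric vector of alternate-allele frequencies per population.
#' @param h numeric vector of observed heterozygote fractions per
#'   population.
#' @return named numeric vector `c(a=, b=, c=)`.
#' @seealso [wcFstRatio()] for the multi-locus ratio-of-averages.
#' @export
wcSiteComponents <- function(nDip, p, h) {
    r <- length(nDip)
    if (r < 2L) stop("need at least two populations")
    if (length(p) != r || length(h) != r)
        stop("nDip, p and h must have one entry per population")
    if (any(nDip < 1)) stop("each population needs >= 1 genotyped diploid")
    comp <- .wcComponents(matrix(nDip, 1L), matrix(p, 1L), matrix(h, 1L))
    c(a = comp$a, b = comp$b, c = comp$c)
}

## vectorised W&C components: each argument is a sites x r matrix
.wcComponents <- function(nMat, pMat, hMat) {
    r <- ncol(nMat)
    nbar <- rowMeans(nMat)
    sumN <- rowSums(nMat)
    nc <- (sumN - rowSums(nMat^2) / sumN) / (r - 1)
    pbar <- rowSums(nMat * pMat) / sumN
    s2 <- rowSums(nMat * (pMat - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(nMat * hMat) / sumN
    ok <- !is.na(nbar) & !is.na(nc) & nbar > 1 & nc > 0
    a <- b <- cc <- rep(NA_real_, nrow(nMat))
    nb <- nbar[ok]; ncv <- nc[ok]; pb <- pbar[ok]; s2v <- s2[ok]
    hb <- hbar[ok]
    a[ok] <- (nb / ncv) *
        (s2v - (pb * (1 - pb) - (r - 1) / r * s2v - hb / 4) / (nb - 1))
    b[ok] <- (nb / (nb - 1)) *
        (pb * (1 - pb) - (r - 1) / r * s2v -
             (2 * nb - 1) / (4 * nb) * hb)
    cc[ok] <- hb / 2
    list(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham FST (ratio of averages)
#'
#' `sum(a) / sum(a + b + c)` over contributing sites. Negative estimates
#' are returned as computed (not truncated at zero); when the denominator
#' is zero (e.g. an all-monomorphic window) the estimate is undefined and
#' `NA` is returned.
#'
#' @param a,b,c numeric vectors of per-site components from
#'   [wcSiteComponents()]; `NA` sites are dropped pairwise.
#' @return the multi-locus FST estimate, or `NA`.
#' @export
wcFstRatio <- function(a, b, c) {
    keep <- is.finite(a) & is.finite(b) & is.finite(c)
    if (!any(keep)) return(NA_real_)
    den <- sum(a[keep] + b[keep] + c[keep])
    if (den == 0) return(NA_real_)
    sum(a[keep]) / den
}

#' Per-site allele and genotype summaries for a genotype matrix
#'
#' Internal workhorse shared by the filter and scan layers: per site, the
#' number of genotyped chromosomes, alternate-allele count, observed
#' heterozygote fraction and genotype-class counts.
#'
#' @param gt integer genotype-code matrix (sites x samples).
#' @return data.frame with columns `nChrom`, `altCount`, `het`, `nAA`,
#'   `nAa`, `naa`.
#' @keywords internal
siteAlleleCounts <- function(gt) {
    miss <- gt == -1L
    nDip <- rowSums(!miss)
    g <- gt
    g[miss] <- 0L
    alt <- rowSums(g)
    nAa <- rowSums(gt == 1L)
    naa <- rowSums(gt == 2L)
    data.frame(nChrom = 2L * nDip, altCount = alt,
               het = ifelse(nDip > 0, nAa / nDip, NA_real_),
               nAA = nDip - nAa - naa, nAa = nAa, naa = naa)
}

#' Weir-Cockerham components for every site of a genotype matrix
#'
#' Splits the samples by population label and evaluates
#' [wcSiteComponents()] at each site, vectorised. Sites where any
#' population has zero genotyped diploids yield `NA` components and are
#' counted.
#'
#' @param gt integer genotype-code matrix (sites x samples).
#' @param popIndex factor or character vector of population labels, one
#'   per sample (ncol(gt)); exactly the populations to contrast.
#' @return a list with numeric vectors `a`, `b`, `c` (one entry per site)
#'   and `nSkipped`, the count of sites lacking data in some population.
#' @export
wcComponentsMatrix <- function(gt, popIndex) {
    popIndex <- as.factor(popIndex)
    pops <- levels(popIndex)
    r <- length(pops)
    if (r < 2L) stop("need at least two populations")
    nMat <- pMat <- hMat <- matrix(NA_real_, nrow(gt), r)
    for (k in seq_len(r)) {
        sub <- gt[, popIndex == pops[k], drop = FALSE]
        cnt <- siteAlleleCounts(sub)
        nMat[, k] <- cnt$nChrom / 2
        pMat[, k] <- ifelse(cnt$nChrom > 0, cnt$altCount / cnt$nChrom,
                            NA_real_)
        hMat[, k] <- cnt$het
    }
    empty <- rowSums(nMat < 1 | is.na(pMat)) > 0
    nMat[empty, ] <- NA_real_
    comp <- .wcComponents(nMat, pMat, hMat)
    comp$a[empty] <- comp$b[empty] <- comp$c[empty] <- NA_real_
    list(a = comp$a, b = comp$b, c = comp$c, nSkipped = sum(empty))
}
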