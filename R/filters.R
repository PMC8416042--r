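## Hard-filter chain for raw SNP tables. Rules are evaluated in a fixed
## order and each removed site is attributed to the first rule it fails,
## so the report counts always satisfy input = output + sum(removed).

#' Hard-filter thresholds for SNP site filtering
#'
#' Defaults correspond to a stringent resequencing pipeline: total depth
#' summed over samples within `[135, 1800]`, RMS mapping quality `>= 10`,
#' distance to the nearest indel `>= 5` bp, Hardy-Weinberg equilibrium
#' p-value `>= 5e-3`, site quality `>= 30`, quality-by-depth within
#' `[3, 30]` and observed heterozygosity `< 0.6`.
#'
#' @param minTotalDepth,maxTotalDepth bounds on INFO `DP` (depth summed
#'   over all samples).
#' @param minMqRms minimum RMS mapping quality (INFO `MQ`).
#' @param minIndelDistanceBp minimum distance (bp) from a SNP to the
#'   nearest indel; sites closer than this are removed.
#' @param hwePMin minimum Hardy-Weinberg chi-squared p-value; sites with
#'   smaller p (stronger HWE violation) are removed.
#' @param minSiteQual minimum VCF `QUAL`.
#' @param qdMin,qdMax bounds on quality-by-depth (INFO `QD`).
#' @param maxHo sites are kept only when observed heterozygosity is
#'   strictly below this value.
#' @return a classed list of validated thresholds.
#' @export
filterConfig <- function(minTotalDepth = 135L, maxTotalDepth = 1800L,
                         minMqRms = 10, minIndelDistanceBp = 5L,
                         hwePMin = 5e-3, minSiteQual = 30,
                         qdMin = 3.0, qdMax = 30.0, maxHo = 0.6) {
    stopifnot(minTotalDepth <= maxTotalDepth, qdMin <= qdMax,
              hwePMin > 0, hwePMin < 1, maxHo > 0)
    structure(list(minTotalDepth = minTotalDepth,
                   maxTotalDepth = maxTotalDepth,
                   minMqRms = minMqRms,
                   minIndelDistanceBp = minIndelDistanceBp,
                   hwePMin = hwePMin, minSiteQual = minSiteQual,
                   qdMin = qdMin, qdMax = qdMax, maxHo = maxHo),
              class = "filterConfig")
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Pearson chi-squared (1 df) of observed genotype counts against the
#' Hardy-Weinberg expectations `N p^2`, `2 N p q`, `N q^2` with the
#' allele frequency estimated from the counts themselves. Monomorphic
#' sites return `chi2 = 0, p = 1`.
#'
#' @param nAA,nAa,naa genotype-class counts (hom-ref, het, hom-alt);
#'   vectorised.
#' @return a data.frame with columns `chi2` and `p`.
#' @examples
#' hweChi2Test(25, 50, 25)  # exact HWE proportions: chi2 = 0, p = 1
#' hweChi2Test(50, 0, 50)   # chi2 = 100
#' @export
hweChi2Test <- function(nAA, nAa, naa) {
    if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be >= 0")
    N <- nAA + nAa + naa
    if (any(N < 1)) stop("at least one genotyped individual required")
    p <- (2 * nAA + nAa) / (2 * N)
    q <- 1 - p
    eAA <- N * p^2
    eAa <- 2 * N * p * q
    eaa <- N * q^2
    mono <- p == 0 | p == 1
    term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
    chi2 <- term(nAA, eAA) + term(nAa, eAa) + term(naa, eaa)
    chi2[mono] <- 0
    pval <- ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
    data.frame(chi2 = chi2, p = pval)
}

#' Observed heterozygosity of a site
#'
#' Fraction of heterozygous calls among non-missing genotypes.
#'
#' @param codes integer genotype codes for one site (values in
#'   \{-1,0,1,2\}); missing (-1) calls are excluded from the denominator.
#' @return observed heterozygosity in `[0, 1]`.
#' @export
observedHeterozygosity <- function(codes) {
    ok <- codes != -1L
    if (!any(ok)) stop("all genotypes missing at the site")
    mean(codes[ok] == 1L)
}

#' Apply the hard-filter chain to a VariantTable
#'
#' A site survives iff, in order: summed depth (INFO `DP`) lies within
#' `[minTotalDepth, maxTotalDepth]`; `MQ >= minMqRms`; its distance to
#' the nearest indel is `>= minIndelDistanceBp`; the Hardy-Weinberg
#' chi-squared p-value is `>= hwePMin`; `QUAL >= minSiteQual`;
#' `qdMin <= QD <= qdMax`; and observed heterozygosity is `< maxHo`.
#' Each removed site is attributed to the first rule it fails. Rules
#' that depend on an optional metric (`DP`, `MQ`, `QD`) are skipped, with
#' a one-time warning, at sites where the metric is absent, so VCFs
#' without those INFO keys still pass through the chain.
#'
#' Filtering is idempotent and conserves counts:
#' `input = output + sum(removed)`.
#'
#' @param x a [VariantTable-class].
#' @param config a [filterConfig()].
#' @param indels data.frame of indel positions (`scaffold`, `pos`);
#'   defaults to those carried by `x` from [readVariants()].
#' @return a list with `table` (the filtered `VariantTable`) and
#'   `report` (class `filterReport`: input/output counts and the per-rule
#'   removal counts, in rule order).
#' @export
applyFilters <- function(x, config = filterConfig(),
                         indels = indelPositions(x)) {
    stopifnot(is(x, "VariantTable"), inherits(config, "filterConfig"))
    si <- siteInfo(x)
    gt <- genotypes(x)
    n <- nrow(si)
    cnt <- siteAlleleCounts(gt)
    rules <- c("depth", "mapping_quality", "indel_distance", "hwe",
               "site_quality", "quality_by_depth", "heterozygosity")

    passDepth <- is.na(si$dp) |
        (si$dp >= config$minTotalDepth & si$dp <= config$maxTotalDepth)
    passMq <- is.na(si$mq) | si$mq >= config$minMqRms
    for (metric in c("dp", "mq", "qd"))
        if (n > 0 && anyNA(si[[metric]]))
            warning("INFO ", toupper(metric),
                    " absent at some sites; that rule is skipped there",
                    call. = FALSE)
    dist <- .indelDistance(si$scaffold, si$pos, indels)
    passIndel <- is.na(dist) | dist >= config$minIndelDistanceBp
    allMiss <- cnt$nChrom == 0L
    hwe <- if (n > 0)
        hweChi2Test(pmax(ifelse(allMiss, 1L, cnt$nAA), 0), cnt$nAa,
                    cnt$naa)
    else data.frame(chi2 = numeric(), p = numeric())
    passHwe <- hwe$p >= config$hwePMin & !allMiss
    passQual <- is.na(si$qual) | si$qual >= config$minSiteQual
    passQd <- is.na(si$qd) |
        (si$qd >= config$qdMin & si$qd <= config$qdMax)
    passHo <- !allMiss & !is.na(cnt$het) & cnt$het < config$maxHo

    passMat <- cbind(passDepth, passMq, passIndel, passHwe, passQual,
                     passQd, passHo)
    firstFail <- if (n == 0L) integer() else
        apply(!passMat, 1L, function(f) if (any(f)) which(f)[1L] else 0L)
    keep <- firstFail == 0L
    removed <- setNames(tabulate(firstFail, nbins = length(rules)), rules)
    report <- structure(list(input = n, removed = removed,
                             output = sum(keep)),
                        class = "filterReport")
    list(table = x[keep, ], report = report)
}

## distance from each site to the nearest indel on its scaffold
.indelDistance <- function(scaffold, pos, indels) {
    out <- rep(NA_real_, length(pos))
    if (is.null(indels) || nrow(indels) == 0L) return(out)
    for (sc in unique(indels$scaffold)) {
        ip <- sort(indels$pos[indels$scaffold == sc])
        sel <- scaffold == sc
        if (!any(sel)) next
        out[sel] <- vapply(pos[sel],
                           function(p) min(abs(p - ip)), numeric(1))
    }
    out
}

#' @export
print.filterReport <- function(x, ...) {
    cat(sprintf("SNP filter report: %d sites in, %d out\n",
                x$input, x$output))
    for (r in names(x$removed))
        cat(sprintf("  %-18s removed %d\n", r, x$removed[[r]]))
    invisible(x)
}

#' Write a filter report as a two-column TSV (rule, removed)
#'
#' @param report a `filterReport` from [applyFilters()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFilterReport <- function(report, path) {
    df <- data.frame(rule = c(names(report$removed), "input", "output"),
                     count = c(unname(report$removed), report$input,
                               report$output))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
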