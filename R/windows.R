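## Sliding-window layout, per-window statistics, empirical-tail outlier
## calling, region merging and gene overlap.
##
## Windows are half-open [start, end) in 0-based coordinates at the
## interfaces (BED convention); internally they are held as 1-based
## GRanges so that a VCF site at position p falls in window [s, e) iff
## s < p <= e, which is exactly a GRanges overlap.

#' Sliding-window layout parameters
#'
#' @param sizeBp window size in bp (default 20 kb).
#' @param stepBp step between window starts in bp (default 10 kb;
#'   `0 < stepBp <= sizeBp`).
#' @param minSnps minimum SNP count for a window to be eligible for
#'   threshold estimation and outlier calling (default 11, i.e. windows
#'   with more than 10 SNPs).
#' @return a classed list of validated parameters.
#' @export
windowSpec <- function(sizeBp = 20000L, stepBp = 10000L, minSnps = 11L) {
    stopifnot(stepBp > 0, stepBp <= sizeBp, minSnps >= 1)
    structure(list(sizeBp = as.integer(sizeBp),
                   stepBp = as.integer(stepBp),
                   minSnps = as.integer(minSnps)),
              class = "windowSpec")
}

#' Lay out sliding windows over a scaffold index
#'
#' Per scaffold of length `L`, windows start at 0, step, 2*step, ... while
#' the start is `< L`; each window ends at `min(start + size, L)`, so
#' trailing short windows are kept. The total count is
#' `sum(ceiling(L / step))` over scaffolds.
#'
#' @param index named integer vector of scaffold lengths
#'   ([readScaffoldIndex()]).
#' @param spec a [windowSpec()].
#' @return a `GRanges` of windows in scaffold order (1-based internally;
#'   subtract 1 from `start()` for the BED coordinate).
#' @examples
#' makeWindows(c(s1 = 25000L), windowSpec())  # 3 windows
#' @export
makeWindows <- function(index, spec = windowSpec()) {
    stopifnot(inherits(spec, "windowSpec"), length(index) > 0)
    parts <- lapply(names(index), function(sc) {
        L <- index[[sc]]
        start0 <- seq.int(0L, L - 1L, by = spec$stepBp)
        GRanges(sc, IRanges(start0 + 1L,
                            pmin(start0 + spec$sizeBp, L)))
    })
    gr <- suppressWarnings(do.call(c, parts))
    GenomeInfoDb::seqlevels(gr) <- names(index)
    GenomeInfoDb::seqlengths(gr) <- index
    gr
}

#' Aggregate diversity and differentiation statistics per window
#'
#' For every window: the SNP count `nSnps`, per-bp nucleotide diversity
#' `piPerBp` (summed [sitePi()] over the window's sites divided by the
#' window span), per-bp Watterson's theta `thetaWPerBp`, and Tajima's D
#' (constants evaluated at the per-window median of per-site chromosome
#' counts; exact for complete data). When a two-population map is given,
#' each window additionally carries per-population diversity, the
#' Weir-Cockerham multi-locus FST and the two log2 diversity ratios
#' `log2RatioPop1 = log2(pi2/pi1)` (high when population 1 has lost
#' diversity) and `log2RatioPop2 = -log2RatioPop1`. Zero-diversity
#' denominators are regularised by adding one minimal diversity quantum
#' (the smallest nonzero per-site diversity at the window's median
#' chromosome count, divided by the span) to both populations of the
#' affected ratio, which keeps the strongest candidate windows finite and
#' monotone in the underlying ratio.
#'
#' Windows with fewer than `spec$minSnps` SNPs are emitted but flagged
#' `eligible = FALSE`; they are excluded both from empirical-threshold
#' estimation and from outlier calling.
#'
#' @param x a filtered [VariantTable-class].
#' @param windows `GRanges` from [makeWindows()].
#' @param popmap optional named character vector (sample -> population)
#'   as from [readPopulationMap()]; exactly two populations are
#'   contrasted.
#' @param pops optional length-2 character vector choosing and ordering
#'   the two populations; defaults to the sorted unique labels.
#' @param spec a [windowSpec()]; only `minSnps` is used here.
#' @return the `windows` GRanges with statistic metadata columns.
#' @export
scanWindows <- function(x, windows, popmap = NULL, pops = NULL,
                        spec = windowSpec()) {
    stopifnot(is(x, "VariantTable"))
    nw <- length(windows)
    sites <- rowRanges(x)
    hits <- findOverlaps(sites, windows)
    wIdx <- S4Vectors::subjectHits(hits)
    sIdx <- S4Vectors::queryHits(hits)
    gt <- genotypes(x)
    cnt <- siteAlleleCounts(gt)
    poly <- cnt$nChrom >= 2L
    piSite <- rep(0, nrow(cnt))
    piSite[poly] <- sitePi(cnt$nChrom[poly], cnt$altCount[poly])

    span <- width(windows)
    nSnps <- tabulate(wIdx, nbins = nw)
    piSum <- .sumBy(piSite[sIdx], wIdx, nw)
    medN <- rep(NA_real_, nw)
    has <- nSnps > 0L
    if (any(has)) {
        med <- tapply(cnt$nChrom[sIdx], wIdx, median)
        medN[as.integer(names(med))] <- as.numeric(med)
    }
    a1 <- ifelse(!is.na(medN) & medN >= 2, harmonicA1(pmax(medN, 2)),
                 NA_real_)
    out <- windows
    mcols(out)$nSnps <- nSnps
    mcols(out)$piPerBp <- piSum / span
    mcols(out)$thetaWPerBp <- ifelse(is.na(a1), 0, nSnps / a1) / span
    okD <- nSnps > 0L & !is.na(medN) & medN >= 4
    D <- rep(NA_real_, nw)
    if (any(okD))
        D[okD] <- tajimasD(nSnps[okD], piSum[okD], medN[okD])
    mcols(out)$tajimaD <- D
    mcols(out)$eligible <- nSnps >= spec$minSnps

    if (!is.null(popmap)) {
        samp <- colnames(x)
        popmap <- popmap[names(popmap) %in% samp]
        if (is.null(pops)) pops <- sort(unique(unname(popmap)))
        if (length(pops) != 2L)
            stop("exactly two populations must be contrasted; got: ",
                 paste(pops, collapse = ", "))
        if (!all(pops %in% popmap))
            stop("population absent from the sample map: ",
                 paste(setdiff(pops, popmap), collapse = ", "))
        popOf <- popmap[samp]
        use <- !is.na(popOf) & popOf %in% pops
        comp <- wcComponentsMatrix(gt[, use, drop = FALSE],
                                   factor(popOf[use], levels = pops))
        fst <- vapply(seq_len(nw), function(i) NA_real_, numeric(1))
        aS <- .sumBy(.z(comp$a)[sIdx], wIdx, nw)
        abcS <- .sumBy(.z(comp$a + comp$b + comp$c)[sIdx], wIdx, nw)
        fst <- ifelse(abcS > 0, aS / abcS, NA_real_)
        piPop <- matrix(0, nw, 2L)
        for (k in 1:2) {
            sub <- gt[, use & popOf == pops[k], drop = FALSE]
            ck <- siteAlleleCounts(sub)
            pk <- rep(0, nrow(ck))
            ok <- ck$nChrom >= 2L
            pk[ok] <- sitePi(ck$nChrom[ok], ck$altCount[ok])
            piPop[, k] <- .sumBy(pk[sIdx], wIdx, nw)
        }
        pi1 <- piPop[, 1L] / span
        pi2 <- piPop[, 2L] / span
        ## minimal diversity quantum at the window's median n
        nq <- pmax(medN, 2)
        quantum <- ifelse(is.na(nq), NA_real_, 2 / nq / span)
        degen <- (pi1 == 0 | pi2 == 0) & !is.na(quantum)
        r1n <- ifelse(degen, pi2 + quantum, pi2)
        r1d <- ifelse(degen, pi1 + quantum, pi1)
        lr1 <- ifelse(r1d > 0 & r1n > 0, log2(r1n / r1d), NA_real_)
        mcols(out)$piPop1PerBp <- pi1
        mcols(out)$piPop2PerBp <- pi2
        mcols(out)$fst <- fst
        mcols(out)$log2RatioPop1 <- lr1
        mcols(out)$log2RatioPop2 <- -lr1
        attr(out, "pops") <- pops
    }
    out
}

.sumBy <- function(v, g, n) {
    out <- numeric(n)
    if (length(v)) {
        s <- rowsum(v, g)
        out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
}

## NA components contribute nothing to window sums
.z <- function(v) ifelse(is.finite(v), v, 0)

#' Empirical tail threshold (nearest-rank order statistic)
#'
#' Lower side: the k-th smallest finite value with
#' `k = ceiling(tailFraction * m)`; upper side: the k-th largest.
#' Interpolation-free, hence deterministic and implementation-independent;
#' ties at the threshold are included downstream by `<=` / `>=`
#' comparisons.
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @param tailFraction tail mass in (0, 1), e.g. 0.05.
#' @param side `"lower"` or `"upper"`.
#' @return the threshold value.
#' @examples
#' empiricalThreshold(1:100, 0.05, "lower")  # 5
#' empiricalThreshold(1:100, 0.05, "upper")  # 96
#' @export
empiricalThreshold <- function(values, tailFraction,
                               side = c("lower", "upper")) {
    side <- match.arg(side)
    v <- values[is.finite(values)]
    m <- length(v)
    if (m < 20L)
        stop("need >= 20 finite values for an empirical threshold; got ",
             m)
    if (tailFraction <= 0 || tailFraction >= 1)
        stop("tailFraction must lie in (0, 1)")
    k <- ceiling(tailFraction * m)
    v <- sort(v, decreasing = (side == "upper"))
    v[k]
}

#' Species-wide sweep scan: joint low-diversity, low-D outliers
#'
#' Flags eligible windows lying at or below both the lower
#' `tail`-quantile of per-bp diversity and the lower `tail`-quantile of
#' Tajima's D. Both thresholds are nearest-rank order statistics over
#' eligible windows only.
#'
#' @param stats window `GRanges` from [scanWindows()].
#' @param tail tail fraction (default 0.05).
#' @return a list with `flags` (logical per window), `thresholds`
#'   (named: `pi`, `tajimaD`) and `flagged` (the flagged windows).
#' @export
speciesSweepScan <- function(stats, tail = 0.05) {
    el <- mcols(stats)$eligible
    pi <- mcols(stats)$piPerBp
    D <- mcols(stats)$tajimaD
    thrPi <- empiricalThreshold(pi[el], tail, "lower")
    thrD <- empiricalThreshold(D[el], tail, "lower")
    flags <- el & pi <= thrPi & !is.na(D) & D <= thrD
    list(flags = flags,
         thresholds = c(pi = thrPi, tajimaD = thrD),
         flagged = stats[flags])
}

#' Local-adaptation scan: joint high-FST, high-log2-ratio outliers
#'
#' Flags eligible windows at or above the upper `tail`-quantile of FST
#' and of the population-directed log2 diversity ratio (population 1:
#' `log2(pi2/pi1)`; population 2: symmetric). The FST quantile is
#' computed once on the shared FST values.
#'
#' @param stats window `GRanges` from [scanWindows()] run with a
#'   population map.
#' @param tail tail fraction (default 0.05).
#' @return a list with `flagsPop1`, `flagsPop2` (logical per window),
#'   `thresholds` (named: `fst`, `log2RatioPop1`, `log2RatioPop2`) and
#'   `flaggedPop1`, `flaggedPop2`.
#' @export
localScan <- function(stats, tail = 0.05) {
    mc <- mcols(stats)
    if (is.null(mc$fst))
        stop("stats carry no FST column; run scanWindows with a popmap")
    el <- mc$eligible
    thrFst <- empiricalThreshold(mc$fst[el], tail, "upper")
    thr1 <- empiricalThreshold(mc$log2RatioPop1[el], tail, "upper")
    thr2 <- empiricalThreshold(mc$log2RatioPop2[el], tail, "upper")
    okF <- !is.na(mc$fst) & mc$fst >= thrFst
    f1 <- el & okF & !is.na(mc$log2RatioPop1) & mc$log2RatioPop1 >= thr1
    f2 <- el & okF & !is.na(mc$log2RatioPop2) & mc$log2RatioPop2 >= thr2
    list(flagsPop1 = f1, flagsPop2 = f2,
         thresholds = c(fst = thrFst, log2RatioPop1 = thr1,
                        log2RatioPop2 = thr2),
         flaggedPop1 = stats[f1], flaggedPop2 = stats[f2])
}

#' Merge flagged windows into candidate regions
#'
#' Overlapping or book-ended windows on the same scaffold merge into one
#' region spanning their union. Idempotent.
#'
#' @param flagged `GRanges` of flagged windows.
#' @return `GRanges` of regions with metadata column `nWindows`.
#' @export
mergeRegions <- function(flagged) {
    rr <- reduce(sort(flagged), with.revmap = TRUE)
    mcols(rr)$nWindows <- lengths(mcols(rr)$revmap)
    mcols(rr)$revmap <- NULL
    rr
}

#' Attach overlapping genes to regions
#'
#' A gene is reported for a region iff their spans share at least one
#' base pair; gene lists are deduplicated per region.
#'
#' @param regions `GRanges` of regions ([mergeRegions()]).
#' @param genes gene `GRanges` from [readGenes()].
#' @return `regions` with an added `genes` CharacterList column.
#' @export
genesInRegions <- function(regions, genes) {
    hits <- findOverlaps(regions, genes)
    ids <- split(mcols(genes)$gene_id[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_along(regions)))
    mcols(regions)$genes <-
        unname(CharacterList(lapply(ids, unique)))
    regions
}
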