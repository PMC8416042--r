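## Synthetic-data generator: neutral coalescent windows, star-genealogy
## post-sweep windows, and Balding-Nichols two-population differentiation,
## written out in the pipeline's input formats together with a
## machine-readable truth table.
##
## Windows are simulated as independent non-overlapping blocks of
## `windowSizeBp` (free recombination between blocks, none within), the
## unit at which the scan operates. All randomness flows through R's
## global RNG, seeded once per dataset, so outputs are byte-reproducible
## for a given seed.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the generator's reference regime: two 500 kb
#' scaffolds tiled by 20 kb windows, one or two populations of 20
#' diploids, a neutral scaled mutation rate of 10 per window, 5% of
#' windows carrying a signal. Sweep windows use a star genealogy of
#' total depth 1 coalescent unit with the mutation rate divided by
#' `sweepThetaFactor`; differentiated windows (two-population mode) are
#' drawn from a Balding-Nichols model at `sweepF` with within-population
#' diversity of the selected population reduced by the same factor.
#'
#' @param populations character vector of population labels; one label
#'   gives single-population (species-wide sweep) mode, two give
#'   two-population (local adaptation) mode.
#' @param nDiploids diploids per population (recycled over populations).
#' @param scaffoldLengths named or unnamed integer vector of scaffold
#'   lengths in bp.
#' @param windowSizeBp simulated window (block) size in bp.
#' @param thetaPerWindow neutral scaled mutation rate for one window.
#' @param sweepFraction fraction of windows simulated under selection.
#' @param sweepThetaFactor diversity-reduction factor for selected
#'   windows (>= 1).
#' @param sweepStarDepth total depth of the post-sweep star genealogy in
#'   coalescent units.
#' @param backgroundF,sweepF Balding-Nichols differentiation for neutral
#'   and selected windows (two-population mode), each in `[0, 1)`.
#' @param selectedPop index (1 or 2) of the population under selection
#'   in differentiated windows.
#' @param seed integer seed fixing the whole dataset.
#' @return a classed list of validated parameters.
#' @export
simulationConfig <- function(populations = c("P1", "P2"),
                             nDiploids = 20L,
                             scaffoldLengths = c(scaf1 = 500000L,
                                                 scaf2 = 500000L),
                             windowSizeBp = 20000L,
                             thetaPerWindow = 10,
                             sweepFraction = 0.05,
                             sweepThetaFactor = 10,
                             sweepStarDepth = 1.0,
                             backgroundF = 0.05,
                             sweepF = 0.8,
                             selectedPop = 1L,
                             seed = 1L) {
    stopifnot(length(populations) %in% 1:2,
              sweepFraction >= 0, sweepFraction <= 1,
              thetaPerWindow > 0, sweepThetaFactor >= 1,
              sweepStarDepth > 0,
              backgroundF >= 0, backgroundF < 1,
              sweepF >= 0, sweepF < 1,
              selectedPop %in% seq_along(populations) ||
                  length(populations) == 1L,
              windowSizeBp >= 1000)
    nDiploids <- rep_len(as.integer(nDiploids), length(populations))
    if (any(nDiploids < 2L))
        stop("need at least 2 diploids per population")
    if (is.null(names(scaffoldLengths)))
        names(scaffoldLengths) <-
            paste0("scaf", seq_along(scaffoldLengths))
    structure(list(populations = populations, nDiploids = nDiploids,
                   scaffoldLengths = scaffoldLengths,
                   windowSizeBp = as.integer(windowSizeBp),
                   thetaPerWindow = thetaPerWindow,
                   sweepFraction = sweepFraction,
                   sweepThetaFactor = sweepThetaFactor,
                   sweepStarDepth = sweepStarDepth,
                   backgroundF = backgroundF, sweepF = sweepF,
                   selectedPop = as.integer(selectedPop),
                   seed = as.integer(seed)),
              class = "simulationConfig")
}

#' Simulate a neutral coalescent genealogy
#'
#' Standard n-coalescent: successive coalescence of uniformly chosen
#' lineage pairs, with the waiting time while k lineages remain drawn
#' from Exponential(rate k(k-1)/2) (time in units of 2N generations).
#'
#' @param nHaploids number of sampled chromosomes, `>= 2`.
#' @return a `genealogy` object: a list with `nLeaves`, `edgeLengths`
#'   (length 2n-2), `edgeLeaves` (leaf index sets below each edge) and
#'   `rootTime`.
#' @export
coalescentTree <- function(nHaploids) {
    n <- as.integer(nHaploids)
    if (n < 2L) stop("coalescentTree needs >= 2 chromosomes")
    times <- numeric(2L * n - 1L)   # node birth times; leaves at 0
    active <- seq_len(n)
    leafSets <- c(as.list(seq_len(n)), vector("list", n - 1L))
    edgeLengths <- numeric(2L * n - 2L)
    edgeLeaves <- vector("list", 2L * n - 2L)
    t <- 0
    e <- 0L
    nextNode <- n
    while (length(active) > 1L) {
        k <- length(active)
        t <- t + rexp(1L, rate = k * (k - 1L) / 2)
        pair <- sample(k, 2L)
        ch <- active[pair]
        nextNode <- nextNode + 1L
        times[nextNode] <- t
        leafSets[[nextNode]] <- c(leafSets[[ch[1L]]],
                                  leafSets[[ch[2L]]])
        for (child in ch) {
            e <- e + 1L
            edgeLengths[e] <- t - times[child]
            edgeLeaves[[e]] <- leafSets[[child]]
        }
        active <- c(active[-pair], nextNode)
    }
    structure(list(nLeaves = n, edgeLengths = edgeLengths,
                   edgeLeaves = edgeLeaves, rootTime = t),
              class = "genealogy")
}

#' Build a star genealogy (post-sweep caricature)
#'
#' All leaves attach at total depth `depth` through zero-length internal
#' structure, so every pairwise coalescence time is `depth`, total branch
#' length is `n * depth`, and mutations dropped on the tree are almost
#' all singletons -- the rare-variant excess that drives Tajima's D
#' strongly negative after a completed sweep.
#'
#' @param nHaploids number of chromosomes, `>= 2`.
#' @param depth total genealogy depth in coalescent units.
#' @return a `genealogy` object as in [coalescentTree()].
#' @export
starTree <- function(nHaploids, depth) {
    n <- as.integer(nHaploids)
    if (n < 2L) stop("starTree needs >= 2 chromosomes")
    if (depth <= 0) stop("depth must be positive")
    edgeLengths <- c(rep(depth, n), rep(0, n - 2L))
    edgeLeaves <- c(as.list(seq_len(n)),
                    lapply(seq_len(n - 2L) + 1L, seq_len))
    structure(list(nLeaves = n, edgeLengths = edgeLengths,
                   edgeLeaves = edgeLeaves, rootTime = depth),
              class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
    cat(sprintf(
        "genealogy: %d leaves, root time %.3f, total length %.3f\n",
        x$nLeaves, x$rootTime, sum(x$edgeLengths)))
    invisible(x)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The mutation count is Poisson with mean `theta/2` times the total
#' branch length; each mutation lands on a branch with probability
#' proportional to its length and is carried by the leaves below it.
#' Every mutation is a distinct biallelic site.
#'
#' @param tree a `genealogy` from [coalescentTree()] or [starTree()].
#' @param theta scaled mutation rate (`4 N mu` per window), `> 0`.
#' @return a list of integer vectors, one per site, giving the leaf
#'   indices carrying the derived allele.
#' @export
dropMutations <- function(tree, theta) {
    stopifnot(inherits(tree, "genealogy"), theta > 0)
    L <- sum(tree$edgeLengths)
    k <- rpois(1L, theta / 2 * L)
    if (k == 0L) return(list())
    idx <- sample.int(length(tree$edgeLengths), k, replace = TRUE,
                      prob = tree$edgeLengths)
    tree$edgeLeaves[idx]
}

#' Simulate genotypes at independent sites under the Balding-Nichols model
#'
#' Per site, an ancestral frequency `p ~ Uniform(0.05, 0.95)` is drawn;
#' each population's frequency is `Beta(p(1-F)/F, (1-p)(1-F)/F)` (equal
#' to `p` when `F = 0`), and diploid genotypes are Binomial(2, p_i)
#' within populations (Hardy-Weinberg within demes). Sites monomorphic
#' in the pooled sample are resampled.
#'
#' @param F differentiation parameter in `[0, 1)`; the expected FST
#'   between the populations.
#' @param nDip integer vector of diploids per population (length >= 2).
#' @param S number of polymorphic sites to return.
#' @return an integer genotype-code matrix (S x sum(nDip)), columns
#'   grouped by population.
#' @export
simulateTwoPopSites <- function(F, nDip, S) {
    stopifnot(F >= 0, F < 1, S >= 1, length(nDip) >= 2L,
              all(nDip >= 1L))
    total <- sum(nDip)
    out <- matrix(0L, 0L, total)
    while (nrow(out) < S) {
        m <- S - nrow(out)
        p <- runif(m, 0.05, 0.95)
        g <- matrix(0L, m, total)
        col0 <- 0L
        for (k in seq_along(nDip)) {
            pk <- if (F == 0) p else
                rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
            g[, col0 + seq_len(nDip[k])] <-
                rbinom(m * nDip[k], 2L, rep(pk, nDip[k]))
            col0 <- col0 + nDip[k]
        }
        ac <- rowSums(g)
        keep <- ac > 0L & ac < 2L * total
        out <- rbind(out, g[keep, , drop = FALSE])
    }
    out
}

#' Generate a complete synthetic dataset on disk
#'
#' Tiles each scaffold into non-overlapping windows of `windowSizeBp`
#' and simulates every window according to its class, drawn with
#' probability `sweepFraction`:
#' \describe{
#'   \item{neutral}{[coalescentTree()] + [dropMutations()] at
#'     `thetaPerWindow` (single-population mode), or Balding-Nichols
#'     sites at `backgroundF` (two-population mode).}
#'   \item{sweep}{(single-population mode) [starTree()] at depth
#'     `sweepStarDepth` with mutations at
#'     `thetaPerWindow / sweepThetaFactor`.}
#'   \item{differentiated}{(two-population mode) Balding-Nichols sites
#'     at `sweepF`; the selected population's within-population
#'     diversity is additionally reduced by `sweepThetaFactor` by fixing
#'     each site in that population with probability
#'     `1 - 1/sweepThetaFactor`.}
#' }
#' Haploids are paired into diploids uniformly at random per window;
#' site positions are uniform within the window, deduplicated and
#' sorted. Toy gene models tile each scaffold (one 2 kb gene per 10 kb)
#' and get annotation terms such that the designated term
#' `GO:TESTSWEEP` is enriched among genes inside selected windows. All
#' outputs are byte-reproducible for a given seed.
#'
#' Emitted files (under `outDir`): `sim.vcf`, `sim.fai`, `genes.gff3`,
#' `annotation.tsv`, `popmap.tsv` and `truth.tsv` (per window: scaffold,
#' 0-based half-open start/end, class, selected population).
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory, created if needed.
#' @return invisibly, a list with the file paths plus `truthTable` (the
#'   truth data.frame) and `table` (the in-memory
#'   [VariantTable-class]).
#' @export
simulateDataset <- function(config, outDir) {
    stopifnot(inherits(config, "simulationConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    twoPop <- length(config$populations) == 2L
    nDip <- config$nDiploids
    totDip <- sum(nDip)
    nHap <- 2L * totDip
    samples <- unlist(lapply(seq_along(config$populations), function(k)
        sprintf("%s_%02d", config$populations[k],
                seq_len(nDip[k]))))
    popOf <- rep(config$populations, nDip)

    lens <- config$scaffoldLengths
    size <- config$windowSizeBp
    rows <- list()
    truth <- list()
    for (sc in names(lens)) {
        nWin <- lens[[sc]] %/% size
        for (w in seq_len(nWin)) {
            start0 <- (w - 1L) * size
            isSel <- runif(1L) < config$sweepFraction
            cls <- if (!isSel) "neutral" else
                if (twoPop) "differentiated" else "sweep"
            geno <- .simulateWindowGenotypes(cls, config, nDip, nHap)
            S <- nrow(geno)
            truth[[length(truth) + 1L]] <- data.frame(
                scaffold = sc, start = start0, end = start0 + size,
                class = cls,
                selectedPop = if (cls == "differentiated")
                    config$populations[config$selectedPop]
                else NA_character_)
            if (S == 0L) next
            pos <- sort(sample.int(size, S)) + start0
            rows[[length(rows) + 1L]] <- list(scaffold = sc, pos = pos,
                                              geno = geno)
        }
    }
    truth <- do.call(rbind, truth)

    scaffold <- unlist(lapply(rows, function(r)
        rep(r$scaffold, length(r$pos))))
    pos <- unlist(lapply(rows, function(r) r$pos))
    geno <- do.call(rbind, lapply(rows, function(r) r$geno))
    nSite <- length(pos)
    refalt <- .randomAlleles(nSite)
    vt <- VariantTable(
        scaffold = scaffold, pos = pos,
        ref = refalt$ref, alt = refalt$alt,
        geno = geno, samples = samples,
        qual = round(runif(nSite, 60, 200), 1),
        mq = round(runif(nSite, 40, 60), 1),
        qd = round(runif(nSite, 10, 25), 1),
        dp = as.integer(round(30 * totDip * runif(nSite, 0.8, 1.2))),
        seqlens = lens)

    paths <- list(
        vcf = file.path(outDir, "sim.vcf"),
        fai = file.path(outDir, "sim.fai"),
        gff = file.path(outDir, "genes.gff3"),
        annotation = file.path(outDir, "annotation.tsv"),
        popmap = file.path(outDir, "popmap.tsv"),
        truth = file.path(outDir, "truth.tsv"))
    writeVariants(vt, paths$vcf)
    writeLines(sprintf("%s\t%d", names(lens), lens), paths$fai)
    genes <- .tileGenes(lens)
    .writeGff(genes, paths$gff)
    ann <- .annotateGenes(genes, truth)
    writeLines(sprintf("%s\t%s", ann$gene,
                       vapply(ann$terms, paste, character(1),
                              collapse = ";")),
               paths$annotation)
    writeLines(sprintf("%s\t%s", samples, popOf), paths$popmap)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(paths, list(truthTable = truth, table = vt)))
}

## one window's genotype matrix (sites x samples) by class
.simulateWindowGenotypes <- function(cls, config, nDip, nHap) {
    if (cls == "neutral" && length(config$populations) == 2L) {
        S <- rpois(1L, config$thetaPerWindow * harmonicA1(nHap))
        if (S == 0L) return(matrix(0L, 0L, sum(nDip)))
        return(simulateTwoPopSites(config$backgroundF, nDip, S))
    }
    if (cls == "differentiated") {
        S <- rpois(1L, config$thetaPerWindow * harmonicA1(nHap))
        if (S == 0L) return(matrix(0L, 0L, sum(nDip)))
        g <- .simulateDifferentiated(config, nDip, S)
        return(g)
    }
    tree <- if (cls == "sweep")
        starTree(nHap, config$sweepStarDepth)
    else coalescentTree(nHap)
    theta <- if (cls == "sweep")
        config$thetaPerWindow / config$sweepThetaFactor
    else config$thetaPerWindow
    muts <- dropMutations(tree, theta)
    .pairHaploids(muts, nHap)
}

## Balding-Nichols sites with diversity reduction in the selected pop:
## each site is fixed there (frequency rounded to 0/1 by a Bernoulli
## draw at the site's frequency) with probability 1 - 1/factor, which
## divides expected heterozygosity by exactly the factor.
.simulateDifferentiated <- function(config, nDip, S) {
    F <- config$sweepF
    total <- sum(nDip)
    sel <- config$selectedPop
    selCols <- if (sel == 1L) seq_len(nDip[1L]) else
        nDip[1L] + seq_len(nDip[2L])
    out <- matrix(0L, 0L, total)
    while (nrow(out) < S) {
        m <- S - nrow(out)
        p <- runif(m, 0.05, 0.95)
        pPop <- lapply(seq_along(nDip), function(k)
            if (F == 0) p else
                rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F))
        fix <- runif(m) < 1 - 1 / config$sweepThetaFactor
        pSel <- pPop[[sel]]
        pPop[[sel]] <- ifelse(fix,
                              as.numeric(runif(m) < pSel), pSel)
        g <- matrix(0L, m, total)
        col0 <- 0L
        for (k in seq_along(nDip)) {
            g[, col0 + seq_len(nDip[k])] <-
                rbinom(m * nDip[k], 2L, rep(pPop[[k]], nDip[k]))
            col0 <- col0 + nDip[k]
        }
        ac <- rowSums(g)
        keep <- ac > 0L & ac < 2L * total
        out <- rbind(out, g[keep, , drop = FALSE])
    }
    out
}

## infinite-sites leaf sets -> diploid genotype matrix with random
## haploid pairing (without replacement) per window
.pairHaploids <- function(muts, nHap) {
    nDipTot <- nHap %/% 2L
    if (!length(muts)) return(matrix(0L, 0L, nDipTot))
    perm <- sample.int(nHap)
    pairOf <- integer(nHap)
    pairOf[perm] <- rep(seq_len(nDipTot), each = 2L)
    t(vapply(muts, function(carriers)
        tabulate(pairOf[carriers], nbins = nDipTot), integer(nDipTot)))
}

.randomAlleles <- function(n) {
    nuc <- c("A", "C", "G", "T")
    ref <- sample(nuc, n, replace = TRUE)
    shift <- sample.int(3L, n, replace = TRUE)
    alt <- nuc[(match(ref, nuc) - 1L + shift) %% 4L + 1L]
    list(ref = ref, alt = alt)
}

## one 2 kb gene per 10 kb of scaffold
.tileGenes <- function(lens) {
    parts <- lapply(names(lens), function(sc) {
        k <- seq_len(lens[[sc]] %/% 10000L) - 1L
        data.frame(gene = sprintf("g_%s_%03d", sc, k + 1L),
                   scaffold = sc, start = k * 10000L + 4001L,
                   end = k * 10000L + 6000L)
    })
    do.call(rbind, parts)
}

.writeGff <- function(genes, path) {
    lines <- c("##gff-version 3",
               sprintf("%s\tdivscan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$scaffold, genes$start, genes$end,
                       genes$gene))
    writeLines(lines, path)
}

## background terms at random; GO:TESTSWEEP enriched in genes inside
## selected windows
.annotateGenes <- function(genes, truth) {
    pool <- sprintf("GO:%07d", 1:10)
    selWin <- truth[truth$class != "neutral", , drop = FALSE]
    inSel <- vapply(seq_len(nrow(genes)), function(i) {
        w <- selWin[selWin$scaffold == genes$scaffold[i], , drop = FALSE]
        any(genes$start[i] <= w$end & genes$end[i] > w$start)
    }, logical(1))
    terms <- lapply(seq_len(nrow(genes)), function(i) {
        t <- sample(pool, 2L)
        pSweep <- if (inSel[i]) 0.8 else 0.05
        if (runif(1L) < pSweep) t <- c(t, "GO:TESTSWEEP")
        sort(t)
    })
    list(gene = genes$gene, terms = terms)
}
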