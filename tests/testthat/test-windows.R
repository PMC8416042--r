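library(GenomicRanges)

test_that("window layout follows the start<L rule with trailing windows kept", {
    w <- makeWindows(c(A = 25000L), windowSpec())
    expect_equal(length(w), 3L)
    expect_equal(start(w) - 1L, c(0L, 10000L, 20000L))
    expect_equal(end(w), c(20000L, 25000L, 25000L))
    w <- makeWindows(c(A = 10000L), windowSpec())
    expect_equal(length(w), 1L)
    expect_equal(c(start(w) - 1L, end(w)), c(0L, 10000L))
    w <- makeWindows(c(A = 100000L, B = 5000L), windowSpec())
    expect_equal(length(w), 11L)
})

test_that("window count equals sum(ceiling(L/step)) on random indices", {
    set.seed(23)
    for (i in 1:100) {
        nsc <- sample(1:6, 1)
        lens <- setNames(sample(1000:300000, nsc),
                         paste0("sc", seq_len(nsc)))
        step <- sample(c(5000L, 10000L, 20000L), 1)
        size <- step * sample(1:3, 1)
        w <- makeWindows(lens, windowSpec(size, step))
        expect_equal(length(w), sum(ceiling(lens / step)))
        ## enumeration agreement per scaffold
        for (sc in names(lens)) {
            starts <- seq(0L, lens[[sc]] - 1L, by = step)
            ws <- w[as.character(seqnames(w)) == sc]
            expect_equal(start(ws) - 1L, starts)
            expect_equal(end(ws), pmin(starts + size, lens[[sc]]))
        }
    }
})

## small hand-built table: 7 sites on one scaffold, 4 samples
make_tiny_table <- function() {
    VariantTable(
        scaffold = rep("A", 7L),
        pos = c(500L, 5000L, 9999L, 10000L, 10001L, 15000L, 19999L),
        ref = rep("A", 7L), alt = rep("G", 7L),
        geno = matrix(c(0L, 1L, 0L, 2L), 7L, 4L, byrow = TRUE),
        samples = paste0("s", 1:4))
}

test_that("sites are assigned to windows by the start<pos<=end rule", {
    vt <- make_tiny_table()
    w <- makeWindows(c(A = 20000L), windowSpec(10000L, 10000L,
                                               minSnps = 1L))
    st <- scanWindows(vt, w, spec = windowSpec(10000L, 10000L, 1L))
    ## window [0,10000): pos 500,5000,9999,10000; window [10000,20000):
    ## pos 10001,15000,19999
    expect_equal(st$nSnps, c(4L, 3L))
    ## overlapping layout double-counts boundary-straddling sites
    w2 <- makeWindows(c(A = 20000L), windowSpec(10000L, 5000L, 1L))
    st2 <- scanWindows(vt, w2, spec = windowSpec(10000L, 5000L, 1L))
    expect_equal(sum(st2$nSnps) > sum(st$nSnps), TRUE)
})

test_that("window diversity equals the hand-summed per-site values", {
    vt <- make_tiny_table()
    w <- makeWindows(c(A = 20000L), windowSpec(20000L, 20000L, 1L))
    st <- scanWindows(vt, w, spec = windowSpec(20000L, 20000L, 1L))
    ## every site: n=8 chromosomes, j=3 -> sitePi = 2*3*5/(8*7)
    piSite <- 2 * 3 * 5 / (8 * 7)
    expect_equal(st$piPerBp, 7 * piSite / 20000)
    expect_equal(st$thetaWPerBp, 7 / sum(1 / (1:7)) / 20000)
    expect_equal(st$tajimaD, tajimasD(7L, 7 * piSite, 8L))
    ## a window with no sites is ineligible with zero diversity
    w0 <- makeWindows(c(A = 50000L), windowSpec(20000L, 20000L, 1L))
    st0 <- scanWindows(vt, w0, spec = windowSpec(20000L, 20000L, 1L))
    expect_equal(st0$nSnps[3], 0L)
    expect_equal(st0$piPerBp[3], 0)
    expect_true(is.na(st0$tajimaD[3]))
    expect_false(st0$eligible[3])
})

test_that("log2 ratios are directed and degenerate denominators regularised", {
    set.seed(77)
    ## pop2 diverse, pop1 with diversity -> ratio1 = log2(pi2/pi1)
    g <- cbind(matrix(rep(c(0L, 1L), each = 4), 10L, 8L, byrow = TRUE),
               matrix(sample(0:2, 80, TRUE), 10L, 8L))
    vt <- VariantTable(rep("A", 10L), seq(100L, 1000L, by = 100L),
                       rep("A", 10L), rep("G", 10L), g,
                       samples = paste0("s", 1:16))
    pm <- setNames(rep(c("p1", "p2"), each = 8), paste0("s", 1:16))
    w <- makeWindows(c(A = 1000L), windowSpec(1000L, 1000L, 1L))
    st <- scanWindows(vt, w, popmap = pm,
                      spec = windowSpec(1000L, 1000L, 1L))
    expect_equal(st$log2RatioPop1,
                 log2(st$piPop2PerBp / st$piPop1PerBp))
    expect_equal(st$log2RatioPop2, -st$log2RatioPop1)
    ## zero-diversity denominator: finite, large ratio
    g2 <- cbind(matrix(0L, 10L, 8L), matrix(sample(0:2, 80, TRUE), 10L, 8L))
    vt2 <- VariantTable(rep("A", 10L), seq(100L, 1000L, by = 100L),
                        rep("A", 10L), rep("G", 10L), g2,
                        samples = paste0("s", 1:16))
    st2 <- scanWindows(vt2, w, popmap = pm,
                       spec = windowSpec(1000L, 1000L, 1L))
    expect_true(is.finite(st2$log2RatioPop1))
    expect_gt(st2$log2RatioPop1, 0)
})

test_that("empirical thresholds are nearest-rank order statistics", {
    expect_equal(empiricalThreshold(1:100, 0.05, "lower"), 5)
    expect_equal(empiricalThreshold(1:100, 0.05, "upper"), 96)
    expect_equal(empiricalThreshold(rep(3.5, 40), 0.05, "lower"), 3.5)
    expect_equal(empiricalThreshold(rep(3.5, 40), 0.05, "upper"), 3.5)
    ## k = ceiling(tail*m): 0.05 * 30 = 1.5 -> 2nd smallest
    expect_equal(empiricalThreshold(1:30, 0.05, "lower"), 2)
    expect_error(empiricalThreshold(1:19, 0.05, "lower"), ">= 20")
    expect_error(empiricalThreshold(1:100, 0, "lower"), "tailFraction")
    ## non-finite values are ignored
    expect_equal(empiricalThreshold(c(1:100, NA, Inf), 0.05, "upper"), 96)
})

test_that("at least ceiling(tail*m) eligible windows sit beyond each threshold", {
    set.seed(6)
    for (i in 1:20) {
        m <- sample(25:400, 1)
        vals <- rnorm(m)
        if (i %% 3 == 0) vals <- round(vals, 1)  # force ties
        tail <- runif(1, 0.01, 0.2)
        lo <- empiricalThreshold(vals, tail, "lower")
        hi <- empiricalThreshold(vals, tail, "upper")
        expect_gte(sum(vals <= lo), ceiling(tail * m))
        expect_gte(sum(vals >= hi), ceiling(tail * m))
    }
})

test_that("joint criteria flag subsets of single-statistic tails", {
    set.seed(8)
    n <- 200L
    w <- GRanges("A", IRanges(seq(1L, by = 1000L, length.out = n),
                              width = 1000L))
    mcols(w)$nSnps <- rep(20L, n)
    mcols(w)$piPerBp <- runif(n)
    mcols(w)$thetaWPerBp <- runif(n)
    mcols(w)$tajimaD <- rnorm(n)
    mcols(w)$eligible <- rep(TRUE, n)
    sw <- speciesSweepScan(w, 0.05)
    expect_true(all(mcols(w)$piPerBp[sw$flags] <= sw$thresholds["pi"]))
    expect_true(all(mcols(w)$tajimaD[sw$flags] <= sw$thresholds["tajimaD"]))
    expect_lte(sum(sw$flags), ceiling(0.05 * n) + sum(
        mcols(w)$piPerBp == sw$thresholds["pi"]))
    ## ineligible windows are never flagged even when extreme
    mcols(w)$eligible[which.min(mcols(w)$piPerBp)] <- FALSE
    sw2 <- speciesSweepScan(w, 0.05)
    expect_false(sw2$flags[which.min(mcols(w)$piPerBp)])
    ## local scan joint rule
    mcols(w)$fst <- runif(n)
    mcols(w)$log2RatioPop1 <- rnorm(n)
    mcols(w)$log2RatioPop2 <- -mcols(w)$log2RatioPop1
    mcols(w)$eligible <- rep(TRUE, n)
    ls <- localScan(w, 0.05)
    expect_true(all(mcols(w)$fst[ls$flagsPop1] >= ls$thresholds["fst"]))
    expect_true(all(mcols(w)$log2RatioPop1[ls$flagsPop1] >=
                        ls$thresholds["log2RatioPop1"]))
    expect_true(all(ls$flagsPop1 <=
        (mcols(w)$fst >= ls$thresholds["fst"])))
})

test_that("region merging unions overlapping and book-ended windows", {
    gr <- GRanges("A", IRanges(c(1L, 10001L), c(20000L, 30000L)))
    r <- mergeRegions(gr)
    expect_equal(length(r), 1L)
    expect_equal(c(start(r), end(r)), c(1L, 30000L))
    expect_equal(r$nWindows, 2L)
    gr <- GRanges("A", IRanges(c(1L, 30001L), c(20000L, 50000L)))
    expect_equal(length(mergeRegions(gr)), 2L)
    ## book-ended ([0,20000) + [20000,40000) in bed terms)
    gr <- GRanges("A", IRanges(c(1L, 20001L), c(20000L, 40000L)))
    expect_equal(length(mergeRegions(gr)), 1L)
    ## chain of 5 step-offset windows -> one 60 kb region
    gr <- GRanges("A", IRanges(seq(1L, by = 10000L, length.out = 5L),
                               width = 20000L))
    r <- mergeRegions(gr)
    expect_equal(length(r), 1L)
    expect_equal(width(r), 60000L)
    ## idempotent; union length bounded by the sum of window spans
    expect_identical(granges(mergeRegions(r)), granges(r))
    expect_lte(sum(width(r)), sum(width(gr)))
})

test_that("genes attach to regions by >= 1 bp overlap, deduplicated", {
    f <- withr::local_tempfile(fileext = ".gff3")
    write_fixture_gff(f)
    genes <- readGenes(f)
    ## regions in 1-based internal coordinates: [0,200) and [2400,9100)
    ## on fixA -> g1 overlaps first; g2 and g3 the second
    regions <- GRanges("fixA", IRanges(c(1L, 2401L), c(200L, 9100L)))
    out <- genesInRegions(regions, genes)
    expect_equal(as.list(out$genes),
                 list("g1", c("g2", "g3")))
    ## gene [600,800] does not touch region [0,200)
    far <- GRanges("fixA", IRanges(601L, 800L))
    mcols(far)$gene_id <- "gx"
    out2 <- genesInRegions(regions[1], far)
    expect_equal(lengths(out2$genes), 0L)
})
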