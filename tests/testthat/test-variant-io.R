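test_that("VCF reading maps genotype strings to codes, phase-insensitively", {
    f <- withr::local_tempfile(fileext = ".vcf")
    write_fixture_vcf(f, nSites = 4L, tweak = function(df, geno) {
        geno[1L, ] <- c(-1L, 0L, 1L, 2L)   # ./. 0/0 0/1 1/1
        list(df = df, geno = geno)
    })
    ## rewrite line 1 with phased separators and an extra FORMAT field
    lines <- readLines(f)
    i <- grep("^fixA\t1000\t", lines)
    rec <- strsplit(lines[i], "\t")[[1]]
    rec[9] <- "GT:DP"
    rec[10:13] <- c(".|.:9", "0|0:9", "0|1:9", "1|1:9")
    lines[i] <- paste(rec, collapse = "\t")
    writeLines(lines, f)
    vt <- readVariants(f)
    expect_equal(nSites(vt), 4L)
    expect_equal(unname(genotypes(vt)[1L, ]), c(-1L, 0L, 1L, 2L))
    si <- siteInfo(vt)
    expect_true(all(tapply(si$pos, si$scaffold, function(p)
        all(diff(p) > 0))))
    expect_equal(si$dp[1L], 500)
    expect_equal(si$mq[1L], 60)
})

test_that("non-diploid GT is a content error naming the record", {
    f <- withr::local_tempfile(fileext = ".vcf")
    write_fixture_vcf(f, nSites = 2L)
    lines <- readLines(f)
    lines[grep("^fixA\t1000\t", lines)] <-
        sub("0/0", "0/0/0", lines[grep("^fixA\t1000\t", lines)])
    writeLines(lines, f)
    expect_error(readVariants(f), "fixA:1000")
})

test_that("multiallelic records are skipped; indels go to the side list", {
    f <- withr::local_tempfile(fileext = ".vcf")
    write_fixture_vcf(f, nSites = 6L, indelLines = c(
        "fixA\t1500\t.\tAT\tA\t100\tPASS\tDP=500\tGT\t0/0\t0/0\t0/0\t0/1",
        "fixB\t2500\t.\tC\tCGG\t100\tPASS\tDP=500\tGT\t0/0\t0/0\t0/1\t0/0",
        "fixA\t2600\t.\tA\tG,T\t100\tPASS\tDP=500\tGT\t0/0\t0/1\t0/0\t0/0"))
    expect_message(vt <- readVariants(f), "multiallelic")
    expect_equal(nSites(vt), 6L)
    ind <- indelPositions(vt)
    expect_equal(nrow(ind), 2L)
    expect_setequal(ind$pos, c(1500L, 2500L))
})

test_that("VCF round trip is lossless for genotypes, sites and metrics", {
    f1 <- withr::local_tempfile(fileext = ".vcf")
    f2 <- withr::local_tempfile(fileext = ".vcf")
    set.seed(42)
    write_fixture_vcf(f1, nSites = 30L, tweak = function(df, geno) {
        geno[] <- sample(c(-1L, 0L, 1L, 2L), length(geno),
                         replace = TRUE)
        df$qual <- round(runif(30, 30, 200), 1)
        list(df = df, geno = geno)
    })
    vt1 <- readVariants(f1)
    writeVariants(vt1, f2)
    vt2 <- readVariants(f2)
    expect_identical(unname(genotypes(vt2)), unname(genotypes(vt1)))
    expect_identical(siteInfo(vt2)[c("scaffold", "pos", "ref", "alt")],
                     siteInfo(vt1)[c("scaffold", "pos", "ref", "alt")])
    expect_equal(siteInfo(vt2)[c("qual", "mq", "qd", "dp")],
                 siteInfo(vt1)[c("qual", "mq", "qd", "dp")])
})

test_that("empty table writes a valid header-only VCF and reads back", {
    f <- withr::local_tempfile(fileext = ".vcf")
    vt0 <- VariantTable(character(), integer(), character(), character(),
                        matrix(integer(), 0L, 3L),
                        samples = c("a", "b", "c"))
    writeVariants(vt0, f)
    vt <- readVariants(f)
    expect_equal(nSites(vt), 0L)
    expect_equal(colnames(vt), c("a", "b", "c"))
})

test_that("VariantTable validity rejects bad codes and unsorted sites", {
    expect_error(VariantTable("s1", 1L, "A", "G",
                              matrix(3L, 1L, 1L), "a"),
                 "genotype codes")
    expect_error(VariantTable(c("s1", "s1"), c(5L, 5L), c("A", "C"),
                              c("G", "T"), matrix(0L, 2L, 1L), "a"),
                 "strictly increasing")
})

test_that("GFF3 reading ingests only gene rows and keeps coordinates", {
    f <- withr::local_tempfile(fileext = ".gff3")
    write_fixture_gff(f)
    g <- readGenes(f)
    expect_equal(length(g), 5L)
    expect_setequal(g$gene_id, paste0("g", 1:5))
    g1 <- g[g$gene_id == "g1"]
    expect_equal(GenomicRanges::start(g1), 100L)
    expect_equal(GenomicRanges::end(g1), 500L)
    expect_equal(as.character(GenomicRanges::strand(g1)), "+")
})

test_that("scaffold index and population map readers enforce uniqueness", {
    f <- withr::local_tempfile()
    writeLines(c("scaf1\t100000", "scaf2\t5000\t12\t60\t61"), f)
    idx <- readScaffoldIndex(f)
    expect_identical(idx, c(scaf1 = 100000L, scaf2 = 5000L))
    writeLines(c("scaf1\t100", "scaf1\t200"), f)
    expect_error(readScaffoldIndex(f), "duplicate")
    writeLines(c("s1\tY1", "s2\tY4"), f)
    pm <- readPopulationMap(f)
    expect_identical(pm, c(s1 = "Y1", s2 = "Y4"))
    writeLines(c("s1\tY1", "s1\tY4"), f)
    expect_error(readPopulationMap(f), "duplicate")
})
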