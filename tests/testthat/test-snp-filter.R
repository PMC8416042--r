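test_that("HWE chi-squared matches hand expectations and the oracle", {
    r <- hweChi2Test(25, 50, 25)
    expect_equal(r$chi2, 0)
    expect_equal(r$p, 1)
    r <- hweChi2Test(50, 0, 50)
    expect_equal(r$chi2, 100)
    expect_equal(r$p, unname(oracle_hwe(50, 0, 50)["p"]),
                 tolerance = 1e-12)
    ## monomorphic site
    r <- hweChi2Test(10, 0, 0)
    expect_equal(r$chi2, 0)
    expect_equal(r$p, 1)
    set.seed(7)
    for (i in 1:50) {
        cnt <- rmultinom(1, sample(10:200, 1), prob = runif(3))[, 1]
        if (sum(cnt) == 0) next
        got <- hweChi2Test(cnt[1], cnt[2], cnt[3])
        want <- oracle_hwe(cnt[1], cnt[2], cnt[3])
        expect_equal(got$chi2, unname(want["chi2"]), tolerance = 1e-10)
        expect_equal(got$p, unname(want["p"]), tolerance = 1e-10)
    }
    expect_error(hweChi2Test(0, 0, 0), "at least one")
})

test_that("observed heterozygosity counts hets over non-missing calls", {
    expect_equal(observedHeterozygosity(c(0L, 1L, 1L, 2L)), 0.5)
    expect_equal(observedHeterozygosity(c(1L, 1L, 1L, 1L)), 1.0)
    expect_equal(observedHeterozygosity(c(0L, -1L, 1L, -1L)), 0.5)
    expect_error(observedHeterozygosity(c(-1L, -1L)), "missing")
})

test_that("filter chain removes the engineered violations, first rule wins", {
    f <- withr::local_tempfile(fileext = ".vcf")
    make_violations_vcf(f)
    vt <- readVariants(f)
    res <- applyFilters(vt)
    rep <- res$report
    expect_equal(rep$input, 30L)
    expect_equal(nSites(res$table), 23L)
    expect_equal(unname(rep$removed["depth"]), 3L)
    expect_equal(unname(rep$removed["site_quality"]), 2L)
    expect_equal(unname(rep$removed["hwe"]), 1L)
    expect_equal(unname(rep$removed["heterozygosity"]), 1L)
    expect_equal(sum(rep$removed), 7L)
    ## brute-force per-site check of survivors
    si <- siteInfo(vt)
    keepTruth <- vapply(seq_len(30), function(i) {
        g <- genotypes(vt)[i, ]
        hwe <- hweChi2Test(sum(g == 0), sum(g == 1), sum(g == 2))$p
        si$dp[i] >= 135 && si$dp[i] <= 1800 && si$mq[i] >= 10 &&
            hwe >= 5e-3 && si$qual[i] >= 30 &&
            si$qd[i] >= 3 && si$qd[i] <= 30 &&
            mean(g[g != -1] == 1) < 0.6
    }, logical(1))
    expect_equal(nSites(res$table), sum(keepTruth))
    expect_equal(siteInfo(res$table)$pos,
                 siteInfo(vt)$pos[keepTruth])
})

test_that("the engineered genotype layouts sit on the right side of the
           HWE and heterozygosity thresholds", {
    expect_lt(hweChi2Test(5, 0, 5)$p, 5e-3)
    expect_gte(hweChi2Test(3, 7, 0)$p, 5e-3)
    expect_gte(observedHeterozygosity(c(rep(1L, 7), rep(0L, 3))), 0.6)
})

test_that("indel proximity boundary is inclusive at the configured distance", {
    f <- withr::local_tempfile(fileext = ".vcf")
    ## SNPs at 1000..6000; indels at 1004 (4 bp from 1000) and
    ## 2005 (5 bp from 2000), both on fixA
    write_fixture_vcf(f, nSites = 12L, indelLines = c(
        "fixA\t1004\t.\tAT\tA\t100\tPASS\tDP=500\tGT\t0/0\t0/0\t0/0\t0/1",
        "fixA\t2005\t.\tA\tAGG\t100\tPASS\tDP=500\tGT\t0/0\t0/0\t0/1\t0/0"))
    vt <- suppressMessages(readVariants(f))
    res <- applyFilters(vt)
    expect_equal(unname(res$report$removed["indel_distance"]), 1L)
    pos <- siteInfo(res$table)
    expect_false(any(pos$scaffold == "fixA" & pos$pos == 1000L))
    expect_true(any(pos$scaffold == "fixA" & pos$pos == 2000L))
})

test_that("report conserves counts and filtering is idempotent", {
    f <- withr::local_tempfile(fileext = ".vcf")
    make_violations_vcf(f)
    vt <- readVariants(f)
    res1 <- applyFilters(vt)
    expect_equal(res1$report$input,
                 res1$report$output + sum(res1$report$removed))
    res2 <- applyFilters(res1$table)
    expect_equal(res2$report$output, res1$report$output)
    expect_equal(sum(res2$report$removed), 0L)
    expect_identical(unname(genotypes(res2$table)),
                     unname(genotypes(res1$table)))
})

test_that("vacuous thresholds keep every site", {
    f <- withr::local_tempfile(fileext = ".vcf")
    make_violations_vcf(f)
    vt <- readVariants(f)
    cfg <- filterConfig(minTotalDepth = 0L, maxTotalDepth = .Machine$integer.max,
                        minMqRms = 0, minIndelDistanceBp = 0L,
                        hwePMin = 1e-300, minSiteQual = 0,
                        qdMin = 0, qdMax = Inf, maxHo = 1.0001)
    res <- applyFilters(vt, cfg)
    expect_equal(res$report$output, res$report$input)
})

test_that("sites lacking optional metrics pass those rules with a warning", {
    f <- withr::local_tempfile(fileext = ".vcf")
    write_fixture_vcf(f, nSites = 4L)
    lines <- readLines(f)
    body <- grep("^fix", lines)
    lines[body] <- sub("DP=\\d+;MQ=[0-9.]+;QD=[0-9.]+", "MQ=60",
                       lines[body])
    writeLines(lines, f)
    vt <- readVariants(f)
    w <- capture_warnings(res <- applyFilters(vt))
    expect_true(any(grepl("DP", w)))
    expect_true(any(grepl("QD", w)))
    expect_equal(res$report$output, 4L)
})
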