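## Fixture builders: small VCF/GFF/table files written at test time.

## A 30-site, 4-sample VCF on two scaffolds with benign defaults; the
## `tweak` callback can modify the per-site fields before writing.
## Sites are laid out at positions 1000, 2000, ... so the indel-distance
## rule is inert unless indel records are injected.
write_fixture_vcf <- function(path, nSites = 30L, nSamples = 4L,
                              tweak = NULL, indelLines = character()) {
    scaffold <- rep(c("fixA", "fixB"), length.out = nSites)
    posWithin <- ave(seq_len(nSites), scaffold, FUN = seq_along)
    df <- data.frame(
        scaffold = scaffold, pos = posWithin * 1000L,
        ref = "A", alt = "G", qual = 100,
        dp = 500L, mq = 60, qd = 20,
        stringsAsFactors = FALSE)
    geno <- matrix(rep_len(c(0L, 1L, 0L, 2L), nSites * nSamples),
                   nrow = nSites, byrow = TRUE)
    if (!is.null(tweak)) {
        out <- tweak(df, geno)
        df <- out$df; geno <- out$geno
    }
    gtStr <- matrix(c("./.", "0/0", "0/1", "1/1")[geno + 2L],
                    nrow = nSites)
    hdr <- c("##fileformat=VCFv4.2",
             '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
             '##INFO=<ID=MQ,Number=1,Type=Float,Description="m">',
             '##INFO=<ID=QD,Number=1,Type=Float,Description="q">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT",
                     sprintf("smp%02d", seq_len(nSamples))),
                   collapse = "\t"))
    body <- paste(df$scaffold, df$pos, ".", df$ref, df$alt, df$qual,
                  "PASS",
                  sprintf("DP=%d;MQ=%g;QD=%g", df$dp, df$mq, df$qd),
                  "GT", apply(gtStr, 1L, paste, collapse = "\t"),
                  sep = "\t")
    ## VCF records must be position-sorted within scaffold; keep file
    ## grouped by scaffold
    ord <- order(df$scaffold, df$pos)
    writeLines(c(hdr, sort_vcf_lines(c(body, indelLines))), path)
    invisible(df[ord, ])
}

## order body lines by (CHROM, POS) so injected indels interleave
sort_vcf_lines <- function(lines) {
    if (!length(lines)) return(lines)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    lines[order(chrom, pos)]
}

## 30 sites x 10 samples with exactly one rule violated by chosen sites
## (3 depth, 2 qual, 1 HWE, 1 Ho) -> 23 survivors
make_violations_vcf <- function(path) {
    write_fixture_vcf(path, nSites = 30L, nSamples = 10L,
                      tweak = function(df, geno) {
        df$dp[c(1, 5, 9)] <- c(50L, 2500L, 100L)   # depth rule
        df$qual[c(2, 12)] <- 25                     # quality rule
        ## HWE: 5 hom-ref + 5 hom-alt, no hets -> chi2 = 10, p ~ 1.6e-3
        geno[3, ] <- rep(c(0L, 2L), each = 5L)
        ## het excess but HWE-compatible: Ho = 0.7 >= 0.6, HWE p ~ 0.09
        geno[4, ] <- c(rep(1L, 7L), rep(0L, 3L))
        list(df = df, geno = geno)
    })
}

write_fixture_gff <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "fixA\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
        "fixA\ttest\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
        "fixA\ttest\tgene\t2500\t3500\t.\t-\t.\tID=g2",
        "fixA\ttest\tgene\t9000\t9500\t.\t+\t.\tID=g3",
        "fixB\ttest\tgene\t100\t1500\t.\t+\t.\tID=g4",
        "fixB\ttest\tgene\t7000\t8000\t.\t+\t.\tID=g5"), path)
    invisible(path)
}

## small annotation: 100 genes, term T1 concentrated in the first 10
write_fixture_annotation <- function(path) {
    genes <- sprintf("gene%03d", 1:100)
    terms <- ifelse(seq_along(genes) <= 10, "T1;T2", "T2")
    writeLines(sprintf("%s\t%s", genes, terms), path)
    invisible(genes)
}
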