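## VCF / GFF3 / index / map readers and the VCF writer.
## Sites keep their native 1-based VCF coordinates inside the package;
## conversion to 0-based half-open happens only when writing BED-style
## output (see writeRegionsBed).

.GT_SPLIT <- "[/|]"

#' Read a multi-sample VCF into a VariantTable
#'
#' Parses a VCF 4.x file with vcfR and converts diploid GT calls into
#' integer genotype codes (0 hom-ref, 1 het, 2 hom-alt, -1 missing).
#' Phased (`|`) and unphased (`/`) separators are treated identically and
#' extra FORMAT fields are ignored. Only biallelic SNP records enter the
#' table: multiallelic records are skipped with a message, and indel
#' records are diverted to a companion position list used by the
#' indel-proximity filter rule (see [applyFilters()]).
#'
#' INFO keys `MQ`, `QD` and `DP` populate the per-site metric columns when
#' present; they are `NA` otherwise.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @return a [VariantTable-class]; skipped record counts are reported via
#'   `message()` and indel positions are available through
#'   [indelPositions()].
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' vt0 <- VariantTable(scaffold = "s1", pos = 5L, ref = "A", alt = "T",
#'                     geno = matrix(c(0L, 1L), 1), samples = c("a", "b"))
#' writeVariants(vt0, f)
#' vt <- readVariants(f)
#' genotypes(vt)
#' @export
readVariants <- function(path) {
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix)))
        fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    n <- nrow(fix)
    if (n == 0L)
        return(VariantTable(character(), integer(), character(),
                            character(),
                            matrix(integer(), 0L,
                                   length(colnames(v@gt)) - 1L),
                            samples = colnames(v@gt)[-1L]))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
    isSnp <- !multi & !is.na(alt) &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    isIndel <- !multi & !isSnp & !is.na(alt)
    if (any(multi))
        message(sum(multi), " multiallelic record(s) skipped")
    if (any(isIndel))
        message(sum(isIndel),
                " indel record(s) diverted to the indel position list")
    indels <- data.frame(scaffold = fix[isIndel, "CHROM"],
                         pos = as.integer(fix[isIndel, "POS"]))
    gtRaw <- v@gt[isSnp, -1L, drop = FALSE]
    samples <- colnames(v@gt)[-1L]
    fmt <- v@gt[isSnp, 1L]
    gtField <- .extractGtField(gtRaw, fmt)
    codes <- .gtCodes(gtField, fix[isSnp, "CHROM"], fix[isSnp, "POS"])
    info <- fix[isSnp, "INFO"]
    vt <- VariantTable(
        scaffold = fix[isSnp, "CHROM"],
        pos = as.integer(fix[isSnp, "POS"]),
        ref = ref[isSnp], alt = alt[isSnp],
        geno = codes, samples = samples,
        qual = suppressWarnings(as.numeric(fix[isSnp, "QUAL"])),
        mq = .infoKey(info, "MQ"), qd = .infoKey(info, "QD"),
        dp = .infoKey(info, "DP"),
        indels = indels)
    vt
}

## pull the GT subfield out of sample strings given per-record FORMAT
.extractGtField <- function(gtRaw, fmt) {
    if (nrow(gtRaw) == 0L) return(gtRaw)
    idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) match("GT", f), integer(1))
    if (anyNA(idx))
        stop("malformed VCF: record without GT in FORMAT")
    out <- gtRaw
    for (i in seq_len(nrow(gtRaw))) {
        row <- gtRaw[i, ]
        if (any(grepl(":", row, fixed = TRUE)) || idx[i] != 1L)
            out[i, ] <- vapply(strsplit(row, ":", fixed = TRUE),
                               function(x) x[idx[i]], character(1))
    }
    out
}

## map GT strings to integer codes; errors name the offending record
.gtCodes <- function(gt, chrom, pos) {
    if (length(gt) == 0L)
        return(matrix(integer(), nrow(gt), ncol(gt),
                      dimnames = dimnames(gt)))
    u <- unique(as.vector(gt))
    codeOf <- vapply(u, function(s) {
        if (is.na(s)) return(-1L)
        al <- strsplit(s, .GT_SPLIT)[[1]]
        if (length(al) != 2L) return(NA_integer_)
        if (any(al == ".")) return(-1L)
        ai <- suppressWarnings(as.integer(al))
        if (anyNA(ai) || any(ai < 0L | ai > 1L)) return(NA_integer_)
        sum(ai)
    }, integer(1))
    m <- matrix(codeOf[match(as.vector(gt), u)], nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
        stop(sprintf("bad GT '%s' (ploidy != 2?) at %s:%s sample %s",
                     gt[bad[1L], bad[2L]], chrom[bad[1L]], pos[bad[1L]],
                     colnames(gt)[bad[2L]]))
    }
    storage.mode(m) <- "integer"
    m
}

.infoKey <- function(info, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    m <- regmatches(info, regexpr(pat, info, perl = TRUE))
    out <- rep(NA_real_, length(info))
    hit <- grepl(pat, info, perl = TRUE)
    out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\1",
        regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)))
    out
}

#' Write a VariantTable as VCF 4.2
#'
#' Inverse of [readVariants()]: genotype codes become `0/0`, `0/1`, `1/1`
#' and `./.`; `MQ`, `QD` and `DP` are emitted into INFO where non-missing.
#' A round trip through [readVariants()] reproduces the genotype matrix,
#' positions, alleles and tracked INFO metrics exactly.
#'
#' @param x a [VariantTable-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeVariants <- function(x, path) {
    stopifnot(is(x, "VariantTable"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=divscan")
    sl <- seqlengths(rowRanges(x))
    sl <- sl[!is.na(sl)]
    if (length(sl))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), sl))
    hdr <- c(hdr,
        '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
        '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
        '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(x)), collapse = "\t"))
    writeLines(hdr, con)
    if (nrow(x) == 0L) return(invisible(path))
    si <- siteInfo(x)
    num <- function(v) ifelse(is.na(v), NA,
                              sub("\\.0+$", "", format(v, trim = TRUE,
                                                       scientific = FALSE)))
    infoParts <- cbind(
        ifelse(is.na(si$dp), NA, paste0("DP=", num(si$dp))),
        ifelse(is.na(si$mq), NA, paste0("MQ=", num(si$mq))),
        ifelse(is.na(si$qd), NA, paste0("QD=", num(si$qd))))
    info <- apply(infoParts, 1L, function(p) {
        p <- p[!is.na(p)]
        if (length(p)) paste(p, collapse = ";") else "."
    })
    gtStr <- matrix(c("./.", "0/0", "0/1", "1/1")[genotypes(x) + 2L],
                    nrow = nrow(x))
    body <- paste(si$scaffold, si$pos, ".", si$ref, si$alt,
                  ifelse(is.na(si$qual), ".", num(si$qual)), "PASS",
                  info, "GT",
                  apply(gtStr, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
    invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only rows of type `gene` are ingested; coordinates stay 1-based
#' inclusive as in GFF3 and the gene identifier is taken from the `ID`
#' attribute.
#'
#' @param path path to a GFF3 file.
#' @return a [GenomicRanges::GRanges] with metadata column `gene_id` (and
#'   `ortholog` when a `tair_locus` attribute is present).
#' @export
readGenes <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    ids <- gr$ID
    if (length(gr) && (is.null(ids) || anyNA(ids) || any(ids == "")))
        stop("gene row without an ID attribute in ", path)
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr))
    mcols(out)$gene_id <- as.character(ids)
    if (!is.null(gr$tair_locus))
        mcols(out)$ortholog <- as.character(gr$tair_locus)
    out
}

#' Read a scaffold-length index
#'
#' Accepts a two-column whitespace/tab-delimited file of scaffold name and
#' length; extra columns (as in a FASTA `.fai`) are ignored. Order of
#' first appearance is preserved.
#'
#' @param path path to the index file.
#' @return a named integer vector of scaffold lengths.
#' @export
readScaffoldIndex <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(tab) < 2L)
        stop("scaffold index needs at least two columns: ", path)
    nm <- as.character(tab[[1]])
    if (anyDuplicated(nm))
        stop("duplicate scaffold name in index: ",
             nm[duplicated(nm)][1L])
    len <- as.integer(tab[[2]])
    if (anyNA(len) || any(len < 1L))
        stop("scaffold lengths must be positive integers")
    setNames(len, nm)
}

#' Read a sample-to-population assignment table
#'
#' Two-column whitespace/tab-delimited text: sample id, population label.
#'
#' @param path path to the map file.
#' @return a named character vector mapping sample id to population label.
#' @export
readPopulationMap <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("population map needs two columns: ", path)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate sample id in population map: ",
             ids[duplicated(ids)][1L])
    setNames(as.character(tab[[2]]), ids)
}

#' Read a gene-to-term annotation table
#'
#' Tab-delimited with two or three columns: gene id, `;`-separated term
#' ids and, optionally, a term description column (one description per
#' row applies to the first term listed; a separate two-column
#' term-description file may also be supplied).
#'
#' @param path path to the annotation table.
#' @param descPath optional two-column TSV of term id and description.
#' @return a list with `gene2terms` (named list of character vectors) and
#'   `termDesc` (named character vector, possibly empty strings).
#' @export
readAnnotation <- function(path, descPath = NULL) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
    gene2terms <- strsplit(as.character(tab[[2]]), ";", fixed = TRUE)
    names(gene2terms) <- as.character(tab[[1]])
    terms <- unique(unlist(gene2terms))
    termDesc <- setNames(rep("", length(terms)), terms)
    if (!is.null(descPath)) {
        dt <- read.table(descPath, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
        termDesc[as.character(dt[[1]])] <- as.character(dt[[2]])
    }
    list(gene2terms = gene2terms, termDesc = termDesc)
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions a `GRanges` (1-based, as used internally).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRegionsBed <- function(regions, path) {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
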