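#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle runValue
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps reduce countOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay
#'   colData
#' @importFrom stats median pchisq rbeta rbinom rexp rpois runif setNames
#'   chisq.test wilcox.test cor.test complete.cases p.adjust quantile
#' @importFrom utils read.table write.table
NULL

#' Container for a biallelic SNP genotype matrix with per-site metadata
#'
#' `VariantTable` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with a single `"GT"` assay: an integer matrix of diploid genotype codes,
#' sites in rows and samples in columns. Codes are 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) and -1 (missing call). The
#' `rowRanges` hold one width-1 range per site (1-based VCF coordinates)
#' with metadata columns `ref`, `alt`, `qual` and, when present in the
#' source VCF INFO field, `mq` (RMS mapping quality), `qd`
#' (quality-by-depth) and `dp` (total depth over samples).
#'
#' Validity requires every genotype code to be in \{-1, 0, 1, 2\}, single
#' nucleotide `ref`/`alt` alleles, and positions strictly increasing within
#' each scaffold.
#'
#' Indel positions parsed from the source VCF (needed by the indel-proximity
#' filter rule) are kept out of the genotype table, in
#' `metadata(x)$indels`, a data.frame with columns `scaffold` and `pos`.
#'
#' @aliases VariantTable
#' @seealso [readVariants()], [applyFilters()], [scanWindows()]
#' @exportClass VariantTable
setClass("VariantTable", contains = "RangedSummarizedExperiment")

.validVariantTable <- function(object) {
    msg <- character()
    if (!"GT" %in% SummarizedExperiment::assayNames(object))
        return("assay 'GT' is required")
    gt <- assay(object, "GT")
    if (!is.numeric(gt) && !is.integer(gt))
        msg <- c(msg, "'GT' assay must be an integer matrix")
    bad <- !(gt %in% c(-1L, 0L, 1L, 2L))
    if (any(bad))
        msg <- c(msg, sprintf("%d genotype codes outside {-1,0,1,2}",
                              sum(bad)))
    rr <- rowRanges(object)
    need <- c("ref", "alt", "qual")
    miss <- setdiff(need, names(mcols(rr)))
    if (length(miss))
        msg <- c(msg, paste("missing site columns:",
                            paste(miss, collapse = ", ")))
    if (length(rr) > 1L) {
        sc <- as.character(seqnames(rr))
        pos <- start(rr)
        same <- sc[-1L] == sc[-length(sc)]
        if (any(same & diff(pos) <= 0L))
            msg <- c(msg, "positions must be strictly increasing within scaffold")
    }
    if (length(msg)) msg else TRUE
}
setValidity("VariantTable", .validVariantTable)

#' Construct a VariantTable from parsed site and genotype data
#'
#' @param scaffold character vector of scaffold names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character nucleotide vectors.
#' @param geno integer matrix of genotype codes (sites x samples) in
#'   \{-1,0,1,2\}.
#' @param samples character vector of sample identifiers (column names).
#' @param qual numeric site quality (VCF QUAL), `NA` allowed.
#' @param mq,qd,dp optional numeric site metrics (INFO MQ, QD, DP); `NA`
#'   where absent.
#' @param indels optional data.frame of indel positions (columns
#'   `scaffold`, `pos`) stored in `metadata()`.
#' @param seqlens optional named integer vector of scaffold lengths.
#' @return a [VariantTable-class] object.
#' @examples
#' vt <- VariantTable(scaffold = c("s1", "s1"), pos = c(10L, 20L),
#'                    ref = c("A", "C"), alt = c("G", "T"),
#'                    geno = rbind(c(0, 1, 2), c(0, 0, -1)),
#'                    samples = c("a", "b", "c"))
#' nSites(vt)
#' @export
VariantTable <- function(scaffold, pos, ref, alt, geno, samples,
                         qual = NA_real_, mq = NA_real_, qd = NA_real_,
                         dp = NA_real_, indels = NULL, seqlens = NULL) {
    geno <- matrix(as.integer(geno), nrow = length(scaffold),
                   ncol = length(samples),
                   dimnames = list(NULL, samples))
    n <- length(scaffold)
    rr <- GRanges(scaffold, IRanges(as.integer(pos), width = 1L))
    mcols(rr) <- DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        qual = rep_len(as.numeric(qual), n),
        mq = rep_len(as.numeric(mq), n),
        qd = rep_len(as.numeric(qd), n),
        dp = rep_len(as.numeric(dp), n))
    if (!is.null(seqlens)) {
        lev <- union(names(seqlens), seqlevels(rr))
        GenomeInfoDb::seqlevels(rr) <- lev
        GenomeInfoDb::seqlengths(rr) <- seqlens[lev]
    }
    se <- SummarizedExperiment(
        assays = list(GT = geno), rowRanges = rr,
        colData = DataFrame(row.names = samples))
    obj <- new("VariantTable", se)
    if (is.null(indels))
        indels <- data.frame(scaffold = character(), pos = integer())
    metadata(obj)$indels <- indels
    validObject(obj)
    obj
}

#' @describeIn VariantTable the integer genotype code matrix (sites x
#'   samples).
#' @param x a `VariantTable`.
#' @export
genotypes <- function(x) assay(x, "GT")

#' @describeIn VariantTable number of sites.
#' @export
nSites <- function(x) nrow(x)

#' @describeIn VariantTable per-site table (scaffold, pos, ref, alt, qual,
#'   mq, qd, dp) as a data.frame.
#' @export
siteInfo <- function(x) {
    rr <- rowRanges(x)
    data.frame(scaffold = as.character(seqnames(rr)), pos = start(rr),
               as.data.frame(mcols(rr)))
}

#' @describeIn VariantTable indel positions carried from the source VCF.
#' @export
indelPositions <- function(x) metadata(x)$indels

setMethod("show", "VariantTable", function(object) {
    cat(sprintf("VariantTable: %d sites x %d samples on %d scaffold(s)\n",
                nrow(object), ncol(object),
                length(unique(as.character(seqnames(rowRanges(object)))))))
    gt <- assay(object, "GT")
    cat(sprintf("  missing genotype rate: %.3f\n", mean(gt == -1L)))
    ni <- nrow(metadata(object)$indels)
    if (!is.null(ni) && ni > 0)
        cat(sprintf("  %d companion indel position(s) recorded\n", ni))
    invisible(NULL)
})
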