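## Stage runners tying the modules into file-to-file commands, plus a
## provenance manifest. All thresholds are recomputed from the data at
## hand (empirical quantiles); none are hard-coded.

#' Filter a VCF on disk
#'
#' Reads, filters ([applyFilters()]) and rewrites a VCF, emitting the
#' per-rule removal report as TSV.
#'
#' @param vcf input VCF path.
#' @param out output VCF path.
#' @param report output report TSV path.
#' @param config a [filterConfig()].
#' @return invisibly, the `filterReport`.
#' @export
runFilter <- function(vcf, out, report, config = filterConfig()) {
    res <- applyFilters(readVariants(vcf), config)
    writeVariants(res$table, out)
    writeFilterReport(res$report, report)
    invisible(res$report)
}

#' Run a window scan on disk inputs
#'
#' Lays out sliding windows over the scaffold index, aggregates window
#' statistics, derives empirical-tail thresholds, calls outlier windows
#' (species-wide sweep scan, plus the two-population local scan when a
#' population map is given), merges them into regions and attaches
#' genes. Writes: `<prefix>_windows.tsv` (per-window statistics,
#' 0-based half-open coordinates), `<prefix>_thresholds.json`,
#' `<prefix>_regions.bed` and `<prefix>_genes.tsv`; the local scan adds
#' per-population region BEDs and gene lists.
#'
#' @param vcf filtered VCF path.
#' @param fai scaffold index path ([readScaffoldIndex()]).
#' @param gff optional GFF3 path of gene models.
#' @param outPrefix path prefix for outputs.
#' @param spec a [windowSpec()].
#' @param tail empirical tail fraction (default 0.05).
#' @param popmap optional population map path; switches on the local
#'   scan.
#' @param pops optional length-2 character vector ordering the two
#'   populations.
#' @return invisibly, a list with the window `GRanges`, thresholds,
#'   regions and written paths.
#' @export
runScan <- function(vcf, fai, gff = NULL, outPrefix, spec = windowSpec(),
                    tail = 0.05, popmap = NULL, pops = NULL) {
    vt <- readVariants(vcf)
    idx <- readScaffoldIndex(fai)
    wins <- makeWindows(idx, spec)
    pm <- if (!is.null(popmap)) readPopulationMap(popmap) else NULL
    stats <- scanWindows(vt, wins, popmap = pm, pops = pops, spec = spec)
    sweep <- speciesSweepScan(stats, tail)
    thresholds <- list(pi = unname(sweep$thresholds["pi"]),
                       tajimaD = unname(sweep$thresholds["tajimaD"]))
    regions <- genesList <- NULL
    genes <- if (!is.null(gff)) readGenes(gff) else NULL
    regions <- mergeRegions(sweep$flagged)
    if (!is.null(genes)) regions <- genesInRegions(regions, genes)
    paths <- list(windows = paste0(outPrefix, "_windows.tsv"),
                  thresholds = paste0(outPrefix, "_thresholds.json"),
                  regions = paste0(outPrefix, "_regions.bed"),
                  genes = paste0(outPrefix, "_genes.tsv"))
    .writeWindowStats(stats, paths$windows)
    writeRegionsBed(regions, paths$regions)
    local <- NULL
    if (!is.null(pm)) {
        local <- localScan(stats, tail)
        thresholds <- c(thresholds,
                        as.list(local$thresholds))
        for (k in 1:2) {
            fl <- if (k == 1L) local$flaggedPop1 else local$flaggedPop2
            reg <- mergeRegions(fl)
            if (!is.null(genes)) reg <- genesInRegions(reg, genes)
            bed <- paste0(outPrefix, "_regions_pop", k, ".bed")
            writeRegionsBed(reg, bed)
            paths[[paste0("regionsPop", k)]] <- bed
            if (!is.null(genes))
                .writeGeneList(reg,
                               paste0(outPrefix, "_genes_pop", k,
                                      ".tsv"))
        }
    }
    jsonlite::write_json(thresholds, paths$thresholds,
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(genes)) .writeGeneList(regions, paths$genes)
    invisible(list(stats = stats, sweep = sweep, local = local,
                   regions = regions, thresholds = thresholds,
                   paths = paths))
}

.writeWindowStats <- function(stats, path) {
    mc <- as.data.frame(mcols(stats))
    df <- data.frame(scaffold = as.character(seqnames(stats)),
                     start = start(stats) - 1L, end = end(stats), mc)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.writeGeneList <- function(regions, path) {
    df <- data.frame(
        scaffold = as.character(seqnames(regions)),
        start = start(regions) - 1L, end = end(regions),
        genes = vapply(mcols(regions)$genes, paste, character(1),
                       collapse = ";"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run term enrichment for a candidate gene list on disk
#'
#' @param genesFile text file with one selected gene id per line.
#' @param annotationFile gene-to-term table ([readAnnotation()]).
#' @param out output TSV path.
#' @param backgroundFile optional file of background gene ids (defaults
#'   to all annotated genes).
#' @param alpha raw p-value significance cutoff.
#' @return invisibly, the enrichment data.frame.
#' @export
runEnrich <- function(genesFile, annotationFile, out,
                      backgroundFile = NULL, alpha = 0.05) {
    ann <- readAnnotation(annotationFile)
    sel <- readLines(genesFile)
    sel <- sel[nzchar(sel)]
    bg <- if (!is.null(backgroundFile)) {
        b <- readLines(backgroundFile)
        b[nzchar(b)]
    } else names(ann$gene2terms)
    res <- chi2Enrichment(sel, ann, background = bg, alpha = alpha)
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(res)
}

#' Run the full synthetic-data pipeline end to end
#'
#' simulate -> filter -> scan (-> local scan) -> enrichment, under one
#' output directory, recording a run manifest
#' (`manifest.json`: parameters, derived thresholds, and md5 checksums
#' of every written file). Rerunning with the same configuration and
#' seed reproduces the checksums exactly.
#'
#' @param outDir output directory.
#' @param simConfig a [simulationConfig()].
#' @param spec a [windowSpec()]; for scanning simulated data the step
#'   defaults to the simulated block size so that scan windows coincide
#'   with the generator's independent blocks.
#' @param tail empirical tail fraction.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(outDir, simConfig = simulationConfig(),
                        spec = windowSpec(
                            sizeBp = simConfig$windowSizeBp,
                            stepBp = simConfig$windowSizeBp),
                        tail = 0.05) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateDataset(simConfig, outDir)
    filtered <- file.path(outDir, "filtered.vcf")
    repPath <- file.path(outDir, "filter_report.tsv")
    rep <- runFilter(sim$vcf, filtered, repPath)
    twoPop <- length(simConfig$populations) == 2L
    scan <- runScan(filtered, sim$fai, sim$gff,
                    outPrefix = file.path(outDir, "scan"),
                    spec = spec, tail = tail,
                    popmap = if (twoPop) sim$popmap else NULL)
    selGenes <- unique(unlist(mcols(scan$regions)$genes))
    enrich <- NULL
    enrichPath <- file.path(outDir, "enrichment.tsv")
    if (length(selGenes)) {
        ann <- readAnnotation(sim$annotation)
        enrich <- chi2Enrichment(selGenes, ann)
        write.table(enrich, enrichPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    files <- list.files(outDir, full.names = TRUE, recursive = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
        package = as.character(utils::packageVersion("divscan")),
        seed = simConfig$seed,
        parameters = list(
            populations = simConfig$populations,
            nDiploids = simConfig$nDiploids,
            thetaPerWindow = simConfig$thetaPerWindow,
            sweepFraction = simConfig$sweepFraction,
            windowSizeBp = spec$sizeBp, stepBp = spec$stepBp,
            minSnps = spec$minSnps, tail = tail),
        thresholds = scan$thresholds,
        checksums = as.list(tools::md5sum(files)))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(sim = sim, filterReport = rep, scan = scan,
                   enrichment = enrich, manifest = manifest))
}
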