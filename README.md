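# divscan

Genome scans for selective sweeps and local adaptation from population
resequencing data.

`divscan` is an R package for population geneticists who have a
multi-sample VCF of biallelic SNPs and want the classical
diversity-based scan: which windows of the genome show the footprint of
a selective sweep in the whole sample, and which windows differentiate
two populations strongly enough to suggest local adaptation?

## What it computes

After a hard-filter chain (total depth, RMS mapping quality, indel
proximity, Hardy–Weinberg equilibrium, site quality, quality-by-depth,
observed heterozygosity), the genome is tiled with sliding windows
(default 20 kb / 10 kb step) and each window with more than 10 SNPs
gets:

* **θπ/bp** — average pairwise nucleotide diversity,
  Σ 2j(n−j)/(n(n−1)) over sites, per bp of window span;
* **θW/bp** — Watterson's estimator S/a₁(n) per bp, with
  a₁(n) = Σ_{i<n} 1/i;
* **Tajima's D** — (θπ − S/a₁) / √(e₁S + e₂S(S−1)); negative D means
  an excess of rare variants, the signature of a sweep;
* with two populations: **Weir–Cockerham F_ST** as the ratio of
  averages Σa / Σ(a+b+c) of the 1984 diploid variance components, and
  the directed diversity ratios **log2(π₂/π₁)** and **log2(π₁/π₂)**.

Outlier windows are called by *joint empirical tails* — nearest-rank
5% quantiles computed from the data at hand, never hard-coded: sweeps
need both lowest-5% θπ and lowest-5% D; local adaptation needs both
highest-5% F_ST and highest-5% directed log2 ratio. Flagged windows
merge into regions, overlapping genes are attached, and candidate gene
sets are tested for term enrichment with a 2×2 Pearson chi-squared
(raw p < 0.05, as in the classical pipelines this reproduces).

A built-in simulator (standard coalescent for neutral windows, star
genealogies for post-sweep windows, Balding–Nichols allele frequencies
for two-population differentiation, plus toy gene models and
annotations) generates full input datasets with a truth table, so the
entire pipeline is testable end to end with no external data.

## Worked example

Simulate two 1 Mb scaffolds (20 diploids, θ = 10 per 20 kb window, 5%
of windows carrying a star-genealogy sweep at θ/10), then filter,
scan and test enrichment in one call:

```r
library(divscan)

cfg <- simulationConfig(populations = "P1",
                        scaffoldLengths = c(scaf1 = 1000000L,
                                            scaf2 = 1000000L),
                        sweepFraction = 0.05, seed = 42)
res <- runPipeline("readme_demo", cfg)
print(res$filterReport)
#> SNP filter report: 4129 sites in, 3878 out
#>   depth              removed 0
#>   mapping_quality    removed 0
#>   indel_distance     removed 0
#>   hwe                removed 51
#>   site_quality       removed 0
#>   quality_by_depth   removed 0
#>   heterozygosity     removed 200

str(res$scan$thresholds)
#> List of 2
#>  $ pi     : num 4.75e-05
#>  $ tajimaD: num -2.59

res$scan$regions
#> GRanges object with 2 ranges and 2 metadata columns:
#>       seqnames        ranges strand |  nWindows                   genes
#>   [1]    scaf1 720001-740000      * |         1 g_scaf1_073,g_scaf1_074
#>   [2]    scaf2 600001-620000      * |         1 g_scaf2_061,g_scaf2_062
```

The derived thresholds are this dataset's empirical 5% quantiles: a
window is called only if its diversity is at or below 4.75×10⁻⁵ per bp
*and* its Tajima's D at or below −2.59. The two surviving regions are
the strongest joint outliers; each lists the gene models it overlaps.
The enrichment table then ranks annotation terms of those genes — here
the simulator's planted sweep-associated term tops the list:

```r
head(res$enrichment, 1)
#>           term selWith selWithout bgWith bgWithout     chi2            p significant
#> 1 GO:TESTSWEEP       4          0     19       177 31.41082 2.088134e-08        TRUE
```

Every stage is also exposed as a function (`readVariants`,
`applyFilters`, `makeWindows`, `scanWindows`, `speciesSweepScan`,
`localScan`, `mergeRegions`, `genesInRegions`, `chi2Enrichment`) and as
a shell command (`inst/scripts/divscan simulate|filter|scan|local-scan|enrich`)
for file-to-file use on real VCF/GFF3 inputs. See the methods vignette
(`vignettes/divscan-methods.Rmd`) for the statistical details and
design choices.

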