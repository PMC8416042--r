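---
title: "Methods: sliding-window sweep and local-adaptation scans"
author: "divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window sweep and local-adaptation scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`divscan` detects candidate selective sweeps and local adaptation from
multi-sample diploid SNP genotypes. It covers the steps downstream of
variant calling: hard filtering of a raw SNP table, sliding-window
summary statistics (nucleotide diversity, Watterson's estimator,
Tajima's D, Weir–Cockerham F~ST~, log2 diversity ratios), joint
empirical-tail outlier calling, region merging and gene overlap, and
chi-squared term enrichment of the candidate genes. A built-in
coalescent / Balding–Nichols simulator produces datasets with known
truth so that the whole chain can be validated without external data.

Read mapping, variant calling, phylogenetics and LD-based analyses are
out of scope; the pipeline consumes a VCF.

# Data model

Genotypes are held in a `VariantTable`, a
`RangedSummarizedExperiment` with a single integer `GT` assay (0
hom-ref, 1 het, 2 hom-alt, −1 missing) and per-site metadata (alleles,
`QUAL`, and the INFO metrics `MQ`, `QD`, `DP` when present). Sites keep
1-based VCF coordinates internally; windows and regions are written out
as 0-based half-open BED, and the conversion happens only in the
writers. Indel records never enter the table but their positions are
retained for the proximity filter rule.

# Filter chain

`applyFilters()` applies, in order: total-depth bounds (INFO `DP`,
summed over samples, default 135–1800), RMS mapping quality (≥ 10),
distance to the nearest indel (≥ 5 bp, boundary inclusive),
Hardy–Weinberg equilibrium (Pearson chi-squared with 1 df against
expectations from the pooled allele frequency; sites with p < 5×10^−3^
removed), site quality (≥ 30), quality-by-depth (3–30) and observed
heterozygosity (kept only when strictly < 0.6). Each removed site is
attributed to the *first* failing rule, so the report conserves counts
(input = output + removals) and the chain is idempotent.

Design choices in ambiguous corners:

* the quality-by-depth bound is applied to the site-level INFO `QD`;
  per-individual QD is not representable in standard VCF INFO;
* HWE is tested on the pooled sample, as the filter stage precedes any
  population split;
* sites lacking an optional metric (`DP`, `MQ`, `QD`) pass that rule
  with a warning instead of being dropped, so third-party VCFs without
  those keys survive;
* `Ho < 0.6` is a strict inequality for keeping;
* a site with every genotype missing cannot be tested and is removed at
  the first genotype-based rule (HWE).

# Window statistics

Windows are laid out per scaffold with starts at 0, `step`, `2·step`, …
while the start is inside the scaffold; the trailing short windows are
kept, so a scaffold of length L contributes ⌈L/step⌉ windows. Defaults
are 20 kb windows with a 10 kb step. A VCF site at position p belongs
to window [s, e) iff s < p ≤ e; with step < size a site intentionally
contributes to up to ⌈size/step⌉ overlapping windows.

Per window with S sites:

* θ~π~/bp — the summed per-site pairwise diversity
  2j(n−j)/(n(n−1)) divided by the **window span** (end − start), not by
  a callable-site count. This matches the per-bp magnitude of
  empirically derived thresholds of the order 5×10^−4^;
* θ~W~/bp — S/a₁(n) divided by the span;
* Tajima's D — (θ~π~ − S/a₁) normalised by the usual
  √(e₁S + e₂S(S−1)) standard-error term. With S = 0 the statistic is
  undefined and reported as missing, deliberately distinct from 0.

Missing genotypes: π is summed per site with each site's own
chromosome count n. The D constants are evaluated at the per-window
*median* of the per-site n; with complete data this reduces exactly to
the textbook formula, which is the regime the oracle tests pin down.

Windows with fewer than `minSnps` SNPs (default 11, i.e. "more than 10
SNPs") are emitted but ineligible: they enter neither the empirical
quantiles nor the outlier calls.

# Differentiation statistics

For a two-population contrast, each site contributes the
Weir–Cockerham (1984) variance components a (among populations), b
(among individuals within populations) and c (within individuals),
computed from per-population sample sizes, allele frequencies and
*observed* heterozygote fractions. The diploid form is used rather than
the haploid shortcut because the heterozygosity term stays informative
for partially inbred (e.g. selfing) samples. The per-window F~ST~ is
the ratio of averages Σa / Σ(a+b+c) over the window's sites — not the
average of per-site ratios — and negative estimates are retained as
computed; truncation would be cosmetic since only the upper tail is
thresholded.

The directed log2 diversity ratios are `log2(π₂/π₁)` (large when
population 1 lost diversity) and its negative. When either population
has zero window diversity, one minimal diversity quantum — the smallest
nonzero per-site π at the window's median chromosome count (2/n),
divided by the span — is added to both numerator and denominator of the
affected ratio. This keeps the strongest sweep candidates finite and
exactly antisymmetric between the two directions, and is monotone in
the underlying ratio. (The alternative of regularising only
zero denominators would leave the opposite direction at −∞.)

# Outlier calling

Empirical thresholds are nearest-rank order statistics: the k-th
smallest (or largest) eligible value with k = ⌈tail·m⌉. No
interpolation is used, so thresholds are deterministic,
implementation-independent and reproducible across languages; ties at
the threshold are included by the ≤ / ≥ comparisons.

* **Species-wide sweep scan** — flag eligible windows in the joint
  lower 5% tail of both θ~π~/bp and Tajima's D.
* **Local-adaptation scan** — flag windows in the joint upper 5% tail
  of F~ST~ and of the population-directed log2 ratio; the F~ST~
  quantile is computed once and shared by both directions.

Because the criteria are joint, the flagged fraction is at most the
tail mass on signal-free data. Flagged windows merge into regions when
they overlap or are book-ended; genes overlap a region when they share
at least one base pair.

# Enrichment

Candidate genes are tested per term with a Pearson chi-squared (1 df,
no continuity correction) on the 2×2 table (selected vs non-selected) ×
(with vs without term), significance being a raw p < 0.05 — no
multiple-testing correction, though a Benjamini–Hochberg column is
reported for reference. The background defaults to all annotated genes
and is overridable. Mann–Whitney U (exact for ≤ 20 untied observations
per group, tie-corrected normal approximation otherwise) and Pearson
correlation round out the auxiliary tests; by convention the U test is
wired to compare flagged versus unflagged windows' F~ST~ values.

# The simulator

The generator produces the statistical structure the scan assumes,
window by window:

* **neutral** windows — a standard n-coalescent genealogy (pair
  coalescence at rate k(k−1)/2) with infinite-sites mutations dropped
  at rate θ/2 per unit branch length. Calibration: E[S] = θ·a₁(n),
  E[π] = θ;
* **sweep** windows (single-population mode) — a star genealogy of
  total depth 1 coalescent unit with θ divided by 10 (defaults).
  Mutations on a star are singletons, giving the depressed diversity
  and strongly negative Tajima's D of a just-completed sweep. The
  depth default of 1.0 keeps the expected SNP count of a sweep window
  (n·depth·θ/(2·factor) = 20 at the defaults) above the eligibility
  cutoff while preserving the ~10× diversity depression; a much
  shallower star would make sweep windows ineligible rather than
  detectable;
* **differentiated** windows (two-population mode) — Balding–Nichols
  sites: ancestral frequency Uniform(0.05, 0.95), population
  frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), genotypes Binomial(2, pᵢ).
  Neutral background uses F = 0.05, selected windows F = 0.8, and the
  selected population's per-site frequency is additionally fixed by a
  Bernoulli draw with probability 1 − 1/factor, which divides its
  expected heterozygosity by exactly the diversity-reduction factor.

Windows are simulated as independent, non-overlapping blocks (free
recombination between blocks, none within) — the unit of analysis of
the scan — so the generator's block size doubles as the scan window
size in the validation runs. Haploids are paired into diploids at
random per window; positions are uniform, distinct and sorted within
the block. Toy gene models tile each scaffold (one 2 kb gene per
10 kb) and a designated term is planted at 0.8 frequency in genes
inside selected windows versus 0.05 elsewhere, giving the enrichment
stage a recoverable signal. A single seeded RNG stream makes every
output byte-reproducible.

What the simulator does *not* emulate: within-window linkage beyond a
single genealogy, recombination gradients, demographic history,
inbreeding/selfing (real salt-cress-like samples are highly selfing),
sequencing error or depth variation. Passing recovery tests therefore
demonstrates the statistical machinery, not robustness to every
property of real resequencing data. Two consequences worth knowing:
pooling two Balding–Nichols demes skews the SFS toward intermediate
frequencies, so two-population *neutral* windows show positive D (the
local scan never uses D); and conditioning sites on polymorphism is
neutral for the F~ST~ ratio-of-averages since monomorphic sites
contribute zero to both numerator and denominator.

# Validation problem sizes

The shipped validation uses: exhaustive π checks for n ≤ 12; 200-point
random oracle sweeps for D and the variance components; 2,000 neutral
windows at n = 40, θ = 20 for calibration (S and π within 2%); F~ST~
recovery within ±0.02 at F ∈ {0.1, 0.3, 0.5} from 5,000 sites with
20+20 diploids; 1,000-window scans with 5% planted sweeps (≥ 70%
recovery; ≤ 5% flagged when nothing is planted); 600-window
two-population scans with 5% planted differentiation; and byte-level
determinism of the full pipeline. One calibration subtlety: Tajima's D
has a small negative finite-sample expectation (its normalisation only
approximately centres it), close to −0.1 at these settings, so the
mean D of a neutral batch sits near that value rather than at 0.

# Known limitations

* Tajima's D constants at the per-window median n are exact only for
  complete data; with heavy, uneven missingness a per-site-n weighting
  would be preferable.
* The HWE filter tests the pooled sample; in strongly structured data
  the Wahlund effect removes genuinely differentiated sites. This
  mirrors the upstream pipeline being reproduced and is visible in the
  simulator's two-population runs.
* Enrichment ignores the annotation term graph (no ancestor
  propagation).
* The scan's empirical thresholds are relative to the dataset at hand;
  they are recomputed for every input and never hard-coded.
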