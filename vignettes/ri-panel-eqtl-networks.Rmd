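---
title: "Mapping expression QTLs and co-expression networks in RI panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping expression QTLs and co-expression networks in RI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bxdnet)
library(dplyr)
```

bxdnet implements a systems-genetics workflow for array-style expression data
measured across a recombinant inbred (RI) strain panel, such as the BXD family
derived from C57BL/6J (B haplotype) and DBA/2J (D haplotype). The chain is:
per-array global normalization, per-strain summarization, per-transcript
genome scans by likelihood ratio statistic (LRS), cis/trans classification,
trait collections and their QTL heat maps with signature-band calling,
correlation and partial-correlation network tools, and a candidate-gene
search/refinement for dissecting trans bands. A synthetic panel generator
with a fully recorded architecture provides ground truth for all of it.

## The measurement model

Each array (one sample hybridized to one chip) is assumed to deliver strictly
positive signal per probe, already background-adjusted and rank-invariant
normalized by the vendor pipeline; that upstream step is proprietary and is
*not* reimplemented here — `normalize_arrays()` takes its output as the raw
input. Normalization is then the four-step global procedure: log2 the
signal, compute each array's mean and standard deviation, and map each array
through `2z + 8`, where `z` is the within-array z-score. Every array ends up
with mean exactly 8 and SD exactly 2, so one unit equals half a within-array
SD of log2 signal, and a mean of 8 marks the array-average expression level.
The z-score uses the sample (n−1) SD; the mean-8/SD-2 contract holds under
either convention, so the choice is recorded rather than consequential. No
batch correction is applied.

Two properties of this transform matter in practice:

* it is invariant to per-array positive rescaling of the raw signal (chip
  brightness cancels), and
* it removes any signal *shared by most probes on an array*. A biological
  effect that shifts a large fraction of the measured probes in the same
  direction is absorbed into the array mean. Genome-wide arrays measure tens
  of thousands of probes, so any one genetic module is a negligible fraction
  and survives; small targeted panels would not. The synthetic fixtures used
  in the test suite therefore carry a background of unaffected probes, which
  is also why a trans hotspot driving, say, 40 of 50 measured probes is not a
  realistic test case under global normalization.

Technical replicates are averaged before biological replicates
(`strain_means()`), so each independent biological sample carries equal
weight regardless of how many times it was re-hybridized; sexes are pooled
into a single strain mean.

## Marker regression and the LRS

For a trait (a probe's strain means) and a marker, strains with homozygous
calls are coded B = 0, D = 1; H and U calls are dropped at that marker, a
reasonable policy for nominally fully inbred RI strains. The scan statistic
is

$$\mathrm{LRS} = n \,\ln\!\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1} = -n\,\ln(1 - R^2),$$

the likelihood ratio between the mean-only and one-marker regression models.
This is plain single-marker regression, not interval mapping: it is the
simplest model consistent with "linkage between expression differences and a
DNA sequence difference", and RI genotypes are dense enough here that
interval-mapping refinement is out of scope. LRS is invariant under affine
transformation of the trait; the allele direction (which haplotype carries
the higher expression) is the sign of the regression slope and flips under
trait negation. Markers with fewer than three informative strains are
skipped with a warning; monomorphic markers score 0. The conventional
thresholds are kept as defaults: LRS ≥ 15 for the genome-wide "significant
QTL" census, LRS ≥ 17 (p ≤ 0.05) for candidate filtering.

The peak of a scan is the maximal-LRS marker, with ties broken toward the
smallest cumulative genome coordinate; the tie-break is arbitrary but fixed
and documented, which keeps repeated runs byte-identical. A peak is **cis**
when it falls on the transcript's own chromosome within a window of the
transcript position (default 20 Mb, matching the candidate search's
exclusion buffer; boundary inclusive), **trans** otherwise, and **none** for
probes without a genomic annotation. Cumulative coordinates lay the
chromosomes end to end in Mb; each chromosome is padded by one median
inter-marker gap so the coordinate is strictly increasing across boundaries.

```{r lrs-example}
geno <- simulate_ri_genotypes(
  sim_config(n_strains = 40, chromosomes = c(`1` = 100, `2` = 100),
             marker_spacing = 10, seed = 42)
)
arch <- true_architecture(
  c("target", "bystander"),
  cis_effects = tibble::tibble(probe = "target", marker = "m1_003", beta = 1.5),
  noise_sd = 0.5
)
sim <- simulate_expression(geno, arch, n_biological = 2, seed = 43)
summ <- strain_means(normalize_arrays(sim$expression), sim$samples)
scan <- lrs_scan(geno, setNames(summ$target, summ$strain))
peak_qtl(scan)
```

## Trait collections, heat maps and signature bands

A trait collection is a seed transcript plus its top-N correlates over
strain means (`top_correlates()`, N = 100 by default, following the common
usage; 80 is equally defensible and N is a parameter). Ranking uses |r| so
strong negative correlates are retained; a signed ranking is available.
Scanning every member of a collection gives the heat-map matrix
(`qtl_heatmap()`): rows in collection order, markers in genome order, and
each cell the scan LRS signed by allele direction — positive for
D-haplotype-high, negative for B-haplotype-high, mirroring the warm/cool
colour convention of QTL cluster maps.

Published signature bands are read off such heat maps by eye. `detect_bands()`
makes that judgement explicit and reproducible: bin the genome at a fixed
width (default 25 Mb), score each collection probe by its maximal |LRS|
inside the bin, call a bin supported when at least a fraction of probes
(default 0.3) reach the LRS threshold (default 15), and merge adjacent
qualifying bins on a chromosome with no gap tolerance. Support statistics
for merged bands are recomputed over the merged interval. These three
defaults are this package's operationalization — chosen so that a hotspot
regulating roughly a third of a collection at significant LRS is called, and
validated against implanted hotspots in the test suite (recovery of a single
implanted hotspot as exactly one containing band in at least 18 of 20 seeded
replicates) — not published constants.

## Correlation and partial-correlation networks

`pearson_matrix()` computes probe-by-probe Pearson correlations over strain
means with pairwise-complete observations (panels routinely miss strains for
some probes); zero-variance probes are flagged and excluded rather than
silently yielding NaN. `network_graph()` thresholds on |r| (default 0.5) and
keeps the signed weight, so negative modulators remain visible in the graph.

`partial_correlation()` removes the linear dependence of two traits on a
control set via the precision matrix of the correlation submatrix:
$r_{xy\cdot Z} = -\Omega_{xy}/\sqrt{\Omega_{xx}\Omega_{yy}}$. The same
quantity computed by correlating residuals from regressions on the controls
agrees to 1e−9 (a property the test suite checks on random data), but the
inversion form needs only the correlation matrix, which is often all that is
published. Reported output carries the raw correlation, the partial
correlation and their difference; the package deliberately does not reduce
these to a single "delta value" because published delta conventions are
ambiguous — with both components in hand the reader can apply any of them.
A singular submatrix (collinear controls) is an explicit error, not a
silent pseudo-inverse.

```{r partial}
cm <- retina_network_cor()
partial_correlation(cm, "Pax6", "Neurod1", "Pcna")
```

## Candidate-gene search and refinement

To dissect a trans band, `search_cis_candidates()` looks for genes inside the
band region whose own expression is under strong local (cis) control — the
logic being that a polymorphic, cis-regulated gene at the band locus is a
plausible upstream driver of the band. The search keeps probes whose gene
lies in the region, whose peak is cis within the exclusion buffer (20 Mb),
and whose peak LRS and mean expression fall in broad sanity ranges (15–2000
and 7.5–60); all bounds inclusive, coordinates 1-based Mb as printed in
GeneNetwork-style tables. The buffer is interpreted as the maximal
gene-to-peak distance for a cis call; every record in the packaged printed
tables sits well inside it (max ≈ 3.4 Mb).

`refine_candidates()` then applies the refinement rules:

1. drop records without a proper gene annotation — missing symbols, RIKEN
   `…Rik` clone ids, bare EST accessions;
2. drop records with LRS < 17 or mean expression < 8;
3. drop explicitly excluded genes (e.g. a gene already treated as part of
   the network under study);
4. collapse duplicate probes per gene, keeping the maximal-LRS probe.

The record-level drops (1–3) commute, so their order is immaterial;
deduplication deliberately runs **last**. Running it first would let a
gene's strongest probe — possibly one that fails the expression floor —
shadow a weaker probe that passes, eliminating genes that plainly satisfy
the criteria through another probe. On the packaged printed tables this
ordering reproduces the published final gene lists exactly (seven genes for
the distal chromosome 2 band; eleven for the chromosome 15 band after
excluding the network member Zbed4). Manual exceptions — genes retained
despite failing a numeric rule, as published analyses sometimes do for
strong cis genes just under the expression floor — are supported only
through an explicit `keep` allow-list, never automatically. A
coefficient-of-variation filter ("highly variable across the panel") is
available but off by default since no numeric cut is conventional.
`prioritize_by_network()` finishes by keeping candidates correlated (|r| ≥
0.5) with at least one network gene, annotated with signed correlations so
negative modulators are identifiable.

```{r refine}
refine_candidates(retina_candidates("chr2"))$symbol
```

## The synthetic panel generator

`simulate_ri_genotypes()` draws each strain as an independent two-state
Markov chain along each chromosome. The stationary allele frequency is 1/2;
the adjacent-marker switching probability is the RI map expansion of the
Haldane recombination fraction: $R = 4r/(1+6r)$ for sib-mated lines (the
default — BXD-type panels are sib-mated), $R = 2r/(1+2r)$ for selfed lines.
Physical distance converts to genetic distance at 0.5 cM/Mb by default, a
reasonable mouse genome-wide average; both the scaling and the map function
are configurable. Defaults emulate a BXD-like panel: 75 strains, 19
autosomes of approximately mouse lengths (~2,560 Mb of genome), markers
every 5 Mb. Strains are fully inbred (B/D only); an option injects unknown
(U) calls at a given rate to exercise missing-data handling.

`simulate_expression()` writes raw signal as
$2^{(\mu_j + \sum\beta x + \sum \lambda\,\ell + \varepsilon)}$ per sample,
so the downstream log2 recovers an additive linear model: cis and trans
genetic effects ($\beta$, in log2 units per D allele), strain-level latent
module factors ($\ell \sim N(0,1)$ shared by all samples of a strain), and
per-sample Gaussian noise. Every implanted effect is recorded in a truth
table, which makes recovery scoring exact. Under this generative model a
single effect's expected trait–genotype correlation is
$\beta\,\mathrm{sd}(x)/\sqrt{\beta^2\mathrm{var}(x)+\sigma^2}$ with the 0/1
genotype coding, the closed form the simulation tests check against; with
$\beta = 2\sigma$ and one sample per strain the marker explains half the
strain-level variance ($h^2 = 0.5$), the regime used for the cis-recovery
test (60 strains, 50 implanted cis effects, ≥90% recovered at LRS ≥ 15
within 10 Mb of the true marker).

What the generator does *not* emulate: real BXD linkage disequilibrium and
marker maps, array hybridization artifacts beyond lognormal noise, batch
structure, sex effects, or probe-level cross-hybridization. Passing recovery
tests on this generator therefore demonstrates that the statistical chain is
correct under its stated model, not that real retinal data would yield any
particular count of significant QTLs; database-scale census numbers are not
reproducible at desk scale and are not targeted.

## Numerical conventions and degenerate inputs

* Sample (n−1) SDs throughout.
* $R^2$ is clamped below 1 (at $1-10^{-12}$) before the log, so a perfectly
  fitting marker yields a large finite LRS instead of infinity.
* Pearson correlations use pairwise-complete observations; correlations
  undefined through missingness propagate as NA and are excluded from
  thresholded sets.
* Peak ties go to the smallest cumulative coordinate; correlate-rank ties go
  to lexicographic probe id.
* All thresholds and interval bounds are inclusive.
* Degenerate inputs fail loudly: non-positive raw signal, zero-variance
  arrays, seeds without variance, singular control submatrices, samples
  without strain assignments, malformed genotype files (with line numbers).

Problem sizes in the test suite are kept at desk scale by design — panels of
15–60 strains, tens to a couple of hundred probes, markers every 5–10 Mb,
and 20-replicate detection experiments — which is ample for the contracts
being checked (exact oracle agreement, closed-form frequencies within 3 SE,
and high-heritability recovery).

## Known limitations

* The vendor's rank-invariant pre-normalization is assumed, not performed.
* Single-marker regression only; no interval mapping, composite mapping, or
  permutation-based genome-wide significance calibration — fixed LRS
  thresholds are used as published conventions, not re-derived.
* Band calling depends on bin placement: a hotspot straddling a bin edge is
  still found (adjacent qualifying bins merge), but support fractions can
  shift slightly with the binning phase.
* Literature-based candidate prioritization is out of scope; the report
  leaves that slot to the analyst.
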