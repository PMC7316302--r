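---
title: "Mapping tumor superenhancer landscapes and their dependencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tumor superenhancer landscapes and their dependencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selandscape)
```

## The problem

Triple-negative breast cancer lacks recurrent coding drivers, but its
cell state is shaped by the non-coding regulatory genome. Active
enhancers carry H3K27Ac, and in every sample a small minority of
enhancer clusters — superenhancers (SEs) — carry disproportionately
large H3K27Ac signal and concentrate on lineage- and oncogene-regulating
loci. `selandscape` implements the full analysis path from per-sample
H3K27Ac peak calls and coverage to: per-sample SE calls, a cross-sample
consensus SE map, SE-based sample clustering, SE-to-gene association,
tumor-specific SE identification, and CRISPR dropout-screen scoring of
the genes those SEs putatively drive. A synthetic-study generator with
planted ground truth validates every stage end to end.

## Per-sample superenhancer calling

Peaks within 12.5 kb of each other (inclusive gap, the conventional
"within 12.5 kb" reading) are stitched into candidate regions. Each
region is scored as

\[ s = \max\!\big(0,\; c_{\mathrm{ChIP}}/(L_{\mathrm{ChIP}}/10^6) -
      c_{\mathrm{input}}/(L_{\mathrm{input}}/10^6)\big), \]

reads per million with the paired input subtracted and negative values
floored at zero — background in excess of ChIP is not meaningful
enhancer signal, and the floor keeps downstream log transforms defined.
Regions are ranked ascending by signal (ties broken by genomic
position, so the ordering is deterministic), ranks and signals are
min-max scaled to the unit square, and the SE cutoff is the rank
maximizing \(x - y\). This is the exact discrete equivalent of the
slope-one tangent to the ranked-signal "hockey stick": beyond that point
the curve rises faster than one unit of signal per unit of rank, and
every region above it is a superenhancer. When all signals are equal the
curve is degenerate and no SEs are called (with a warning). A TSS
exclusion window is implemented but defaults to 0 bp: SE regions overlap
TSSs and gene bodies extensively, and excluding them would discard real
signal.

```{r rose}
peaks <- data.frame(chrom = "chr1",
                    start = c(0, 5e3, 11e3, 40e3, 80e3),
                    end   = c(2e3, 7e3, 13e3, 42e3, 82e3))
regions <- stitch_peaks(peaks, stitch_distance = 12500)
regions[, c("chrom", "start", "end", "n_constituents")]
scored <- score_regions(regions,
                        chip_counts = c(5000, 120, 80),
                        input_counts = c(300, 60, 50),
                        chip_lib = 1e7, input_lib = 1e7)
classify_superenhancers(scored)
```

## Consensus maps and scoring

Per-sample calls are consolidated across samples: two SEs merge when
they share at least 5000 bp, typical enhancers when they share at least
10 bp. "Minimum overlap distance" is read as required shared bases (the
negative-distance form of `bedtools merge`), merging is transitive, and
the consensus interval is the span of the merged set. Consensus
enhancers overlapping a TSS by even one base are removed whole —
trimming would change element counts unpredictably — while SEs retain
TSS overlaps. Each consensus SE is split into 20 kb bins (final short
bin kept, so binning conserves territory), samples are scored against
the bins as input-subtracted RPKM, and binning is the default order
(bin, then score) since scoring normalizes by length either way.

Two element-level summaries serve different purposes:

* **Element RPKM** — the length-weighted mean of bin RPKMs, identical to
  the RPKM of the whole element because counts are additive over the bin
  partition. The SE presence call lives on this scale: an element is
  present in a sample iff \(\log_2(\mathrm{RPKM}+1) \ge 6\) (inclusive,
  reading the published "= > 6" as \(\ge\)). Variance-based element
  selection and sample correlation also use this scale, which keeps the
  fixed per-element length out of across-element comparisons.
* **SE size** — the plain sum of bin values, a signal-mass surrogate
  used wherever the analysis speaks of the "size" of an SE in a sample
  (gene-association correlations, tumor/normal fold comparisons).
  Genomic width is fixed per consensus element, so signal is the only
  sample-varying size.

## Clustering and cluster-defining SEs

The top 10% most variable elements (ceiling rule, so the selection is
never empty; variance across tumor cell lines) feed a sample-sample
Pearson correlation on log2 scores; distance is \(1 - r\) and linkage is
average (UPGMA). The cluster count `k` is a configuration parameter:
elbow, silhouette and gap-statistic diagnostics are reported
(`cluster_diagnostics()`) but never silently override it, since cluster
number in practice also reflects prior knowledge of the samples. The gap
reference permutes each element's values across samples — appropriate
for a correlation-derived distance, where a uniform-box reference has no
meaning. Clusters smaller than 3 samples dissolve to unassigned,
mirroring samples whose SE profile resembles no other.

A cluster-defining SE is one whose high-scoring clusters separate
cleanly from the rest: clusters are ordered by mean score, and the
smallest leading set whose every member satisfies
\(\mathrm{mean} - \mathrm{SD} > \mathrm{mean}_{\text{other}}\) for all
outside clusters is taken. A singleton set marks a cluster-specific SE;
a larger set marks an SE shared among those clusters while distinct from
the rest. The smallest qualifying set is used because any clean
separation of the single top cluster should be reported as specific,
with sharing only when the top clusters fail to separate from one
another. SDs are sample SDs (n−1); one-member clusters are skipped.

## SE-to-gene association

For each SE, genes whose span lies within 10 Mb (inclusive boundary;
span rather than TSS, the conservative superset) are candidates. The
Pearson correlation of \(\log_2(\text{SE size}+1)\) with
\(\log_2(\mathrm{RPKM}+1)\) is computed across tumor cell lines —
primaries are excluded by default as they lack matched culture
conditions, though the sample set is configurable. All genes at
\(r \ge 0.6\) are associated, and every SE additionally receives its two
highest-correlation genes regardless of r (flagged `mandatory` when
below threshold). Zero-variance expression gets \(r = 0\) rather than an
error, keeping batch runs alive; such genes remain eligible for
mandatory slots.

## Tumor-specific SEs and the dropout screen

An SE is tumor-specific when present in at least 4 tumor cell lines and
at least 1 primary tumor and absent from every normal (acquired mode),
or present in normals but with mean tumor signal at least 2× the mean
normal signal (enlarged mode, inclusive), under the same presence
requirements. The fold compares mean input-subtracted scores rather than
raw read totals, which would be depth-confounded. Genes associated with
any tumor-specific SE form the screen library.

Screen scoring: guide log2 fold-changes between the reference and late
timepoints are computed on counts-per-million with a 0.5 pseudocount
(the pseudocount is applied after depth normalization so that doubling
counts and library together is a no-op); the gene LFC is the mean of its
3 most depleted guides (the standard dropout reading of "top" guides, an
|LFC| option is provided); normalization anchors the essential-gene mean
at −1 and the NTC mean at 0 via an affine map, making scores comparable
across lines with different Cas9 activity; hits are genes at or below
−0.5. Dependency classification from CERES-like scores uses the same
inclusive −0.5 cutoff.

The dependency signature correlates each element's log2 score across
cell lines with the dependency indicator and keeps the top and bottom
600 (or all available) elements. Its `separation_p` — a Mann-Whitney
comparison of per-line summed signature scores (positive arm minus
negative arm) between classes — is descriptive, not inferential: the
signature is selected to separate the very labels being tested, so on
pure-noise data it reaches the minimum attainable p for any labeling.
The calibrated use, exercised in the test suite, fixes the signature and
permutes labels; `signature_size_sweep()` reproduces the empirical
size-selection workflow.

## The synthetic study

`simulate_landscape()` generates the desk-scale study all recovery tests
run on: 16 tumor cell lines in 4 clusters of 4, 8 primaries in 2
clusters, and 6 normals on a 2 × 16 Mb genome, sized so the full
pipeline completes in seconds. Elements are placed with inter-element
gaps above the stitch distance, so every planted element maps to exactly
one consensus element; SEs are clusters of 3–10 peaks with sub-stitch
internal gaps, typical enhancers single peaks. Coverage is uniform
background plus boxcar enrichment over owned peaks — downstream methods
consume only interval sums, so summit shape would add nothing — with
ChIP and input sharing the background rate and library size, making
input subtraction cancel background exactly and per-sample enrichment
equal the planted amplitude (times ~5% lognormal jitter).

Amplitudes encode the design: typical enhancers 5–50 RPKM, shared /
tumor-specific / enlarged / normal-only SEs 200–600 (tumor-specific
capped at 350), cluster-specific SEs 700–880. Two consequences follow by
construction. First, within each sample the sorted signal curve climbs
from the typical plateau through a spread-out SE range, so the
rank-curve inflection always falls at the typical/SE boundary and every
owned SE-class element is called. Second, among tumor cell lines the
on/off variance of cluster-specific elements (≥ ~0.19 × 700²) strictly
dominates tumor-specific on/off variance (≤ ~0.23 × 350²) and the jitter
variance of ubiquitous elements, so with 240 SE-class elements the
top-10% selection (24 elements) recovers exactly the 24 line-cluster
defining SEs. Enlarged SEs give normals 1/(1.5 × 2) of the tumor
amplitude, so they sit above the presence cutoff in normals yet clear
the 2× rule with margin. Clustering recovery (adjusted Rand index = 1)
is defined over the cell-line panel with k equal to the planted line
cluster count of 4 — the same prior-knowledge choice of k the published
analysis made — since primary tumors, as in real data, cluster apart
from lines.

Expression is generated from the pipeline's own realized SE sizes:
\(\log_2 \mathrm{RPKM} = a + b \log_2(\text{size}+1) + \varepsilon\)
with \(\mathrm{sd}(\varepsilon) = b\,\mathrm{sd}(x)\sqrt{1/r^2 - 1}\)
for a target correlation r (default 0.9; at the noiseless setting the
planted pairs correlate at exactly 1). Screen counts are negative
binomial (mean 400, size 100) with multiplicative depletion
\(2^{\text{effect} \times \text{efficacy}}\); half of each gene's 8
guides draw efficacy 0.85–1 and half 0.05–0.4, so top-3 selection is
meaningful. Essential genes deplete everywhere; planted dependency genes
deplete only in tumor lines.

What passing recovery tests do and do not show: they demonstrate that
every rule — boundaries, thresholds, set operations — is implemented
exactly, under a generator whose planted effects are well separated from
its noise. They do not show performance on real data, where copy-number
confounds signal, enrichment has summit structure and GC bias, peak
callers err, SE amplitude is continuous rather than stratified, and
clusters are not balanced. The generator deliberately omits those
features (as stated non-goals), so real-data behavior is bounded only by
the method definitions, not by these tests. With a few non-planted
SE–gene associations arising from chance correlations above 0.6 across
16 lines — exactly as in real data — recovery is asserted as recall of
the planted truth, not set equality.

## Numerical choices and edge cases

* Ties in signal rank break by genomic position; ties in association r
  break by distance, then gene id; ties in variance break by element id.
  All orderings are deterministic.
* Degenerate inputs are handled explicitly: all-equal signal curves call
  no SEs (warning); zero-variance samples are flagged and excluded from
  clustering (warning); zero-variance expression gets r = 0; missing
  guides are excluded with a warning; an empty dependency table yields
  empty labels.
* The inclusive/exclusive reading of every published boundary is fixed
  and tested: gap ≤ 12 500; overlap ≥ 5000 / ≥ 10; presence ≥ 6; hits
  ≤ −0.5; dependency ≤ −0.5; fold ≥ 2; window boundary inclusive;
  association threshold ≥ 0.6.
* All randomness flows through per-call seeds; generators restore the
  caller's RNG state.

The problem sizes used throughout the test and acceptance runs — the
30-sample, 240-SE synthetic study, oracle instances of up to 500
intervals, and 25-seed screen replications — were chosen as the smallest
sizes at which every planted structure is represented and every rule is
exercised away from its boundary.

## Limitations

Coverage inputs are bedGraph or count tables, not BAM; peak calling and
alignment are upstream of this package. No copy-number correction is
applied to ChIP signal or guide effects. The consensus map is unweighted
(presence, not signal, drives consolidation). The optional peak-size /
enrichment pre-filter on input peaks has no default: the empirical rule
used upstream of the published analysis is not stated, so none is
guessed.
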