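---
title: "Methods: building and mining meta-regulation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and mining meta-regulation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaregnet)
```

# The model

`metaregnet` works on a three-class graph. Nodes are transcription
factors (TF), microRNA genes (miRNA) and protein-coding genes (gene); a
TF and the gene encoding it are deliberately collapsed into a single
node of type TF, because that one locus is simultaneously a DNA target
of other TFs, a messenger target of miRNAs, and a protein regulator.
Directed edges carry one of three regulation levels — `TF_GENE` and
`TF_MIRNA` at the DNA level, `MIRNA_GENE` at the RNA level — each with a
score on a common 0–1 scale. Undirected protein–protein interaction
edges are carried as a separate decorative layer and never participate
in motif templates.

Two score cursors control the working graph: transcriptional edges are
kept at `score >= tf_threshold` (default 0.85) and post-transcriptional
edges at `score >= mirna_threshold` (default 0.8). The defaults are the
stringencies used throughout the packaged presets; the database-wide
integration floor for predicted binding sites is 0.65.

# Binding-site scanning

## From counts to log-odds

A position frequency matrix with counts $n_{b,j}$ (base $b$, column $j$,
column depth $N_j$) becomes a weight matrix under background $q_b$ and
total per-column pseudocount $c$ (default 1, allocated proportionally to
the background):

$$w_{b,j} = \log_2 \frac{(n_{b,j} + c\,q_b) / (N_j + c)}{q_b}.$$

The background defaults to uniform 0.25 per base; it can be set from the
composition of the scanned sequence set when that is more appropriate.
A window's raw score is the sum of its per-position weights, and is
reported on the relative scale
$(S - S_{\min})/(S_{\max} - S_{\min})$ where $S_{\min}$ and $S_{\max}$
are the sums of per-column minima and maxima. This rescaling is what
makes a single threshold meaningful across profiles of different length
and information content: the consensus sequence of any profile scores
exactly 1 and the anti-consensus exactly 0.

## Scanning conventions

Both strands are scanned; minus-strand windows are scored on the
reverse complement but reported in forward-sequence coordinates
(0-based, half-open), with the binding sequence given as read on the hit
strand. All windows passing the threshold are reported — there is no
greedy masking of overlaps, since adjacent and overlapping sites are
biologically meaningful (clustered E-boxes, for example). Windows
containing `N` are skipped rather than scored against the background:
an unsequenced position gives no evidence for or against binding. Hits
are ordered by `(target_id, start, strand)`, a total deterministic
order.

Upstream regions default to 10 kb windows 5′ of the pre-miRNA (or gene)
start, read on the feature's strand. The genomic anchor stores the
1-based coordinate of the region's 5′ end, so on the minus strand
increasing sequence offsets walk leftwards along the chromosome; hit
spans are reported 1-based inclusive, and CpG-island / promoter flags
are set when the genomic span overlaps a BED interval by at least 1 bp
(half-open BED semantics — an abutting interval does not flag).

## Empirical p-values

Relative scores are given a significance scale by exceedance counting
on a reference sequence: $\hat p(s)$ is the fraction of reference
windows (both strands) scoring at least $s$, tabulated on an ascending
grid (default step 0.01). The table is non-increasing by construction
and $\hat p(0) = 1$. The original score-to-p-value correspondence was
established on an unpublished reference, so the package's default
reference is a seed-fixed i.i.d. random sequence of configurable length
(default 100,000 bp) and GC content (default 0.41, a typical mammalian
genomic composition) from the fixture generator; users with a preferred
genomic background can supply their own FASTA. Calibrated p-values for
individual hits use the step function of the grid — the value at the
largest grid point not exceeding the query — which never understates
the exceedance fraction.

Numerical choices: the relative score is mathematically confined to
$[0,1]$, so the scanner clamps floating-point drift (at the $10^{-16}$
level, arising from different summation orders) back into the interval;
and exceedance counting uses a $10^{-9}$ tie tolerance so that a window
whose score mathematically equals a grid point counts as exceeding it
regardless of rounding. PWM score lattices are many orders of magnitude
coarser than both tolerances.

# Unified target scores

MicroCosm and microRNA.org both derive from the same alignment
algorithm but print incommensurable scales (13–23 and 140–205). The
package maps each source through the empirical CDF of a fitting sample
under the midpoint rank convention — the $i$-th of $n$ sorted scores
maps to $(2i-1)/2n$, ties receiving the mean of their ranks — which is
the canonical monotone transform producing values uniformly spread on
(0, 1). Evaluation between sample points is piecewise-linear on the
breakpoint table; the source bounds act as hard clamps (with a warning)
for raw scores outside their scale, which keeps the transform robust to
newer source releases. When a bound coincides with an observed sample
value, the sample's midpoint rank wins over the bound anchor:
exactness on the fitting sample is the contract the rest of the package
relies on.

Whether the original unified score was an ECDF over the full database
or a parametric transform cannot be settled from the published
description; the ECDF is provided as the default realization because it
is the canonical map with the documented uniformity property, and the
breakpoint serialization (`write_transform()`) makes any fitted
transform reproducible.

Multi-source evidence combines by the mean of the per-source quantiles
(equal weights) by default, with `max` available by configuration; the
combined value always lies between the smallest and largest per-source
quantile. Two stringency presets expose documented raw-score
equivalents so filters can be applied on either scale: *stringent*
(unified ≥ 0.8; MicroCosm ≥ 17 with p ≤ 0.01, microRNA.org ≥ 152) and
*medium* (MicroCosm ≥ 16 with p ≤ 0.05, microRNA.org ≥ 150, at least
two miRNAs per gene).

# Regulator enrichment

Candidate regulators of a query list are ranked by the exact one-sided
hypergeometric tail $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$,
computed via `stats::phyper`. Three definitional choices matter and are
deliberately explicit:

* **Sidedness.** One-sided enrichment. The ranking asks which
  regulators are over-represented; depletion is not of interest here.
* **Universe.** $N$ counts the target-side entities present in the
  score-filtered table at the queried level — the database itself, not
  the genome, is the statistical background. This is a user-visible
  choice because it changes p-values: a genome-wide universe would make
  every regulator look enriched merely for being in the database.
* **Multiple testing.** Raw p-values by default, matching the
  `p ≤ 0.05` filter convention of this analysis style; a
  Benjamini–Hochberg column is available behind the `adjust` flag.

Rows are filtered by minimum overlap and p-value cap, and sorted by
`(fisher_p, -best_score, regulator_id)` — a total order, so output is
reproducible even under ties. The reverse direction (`targets_of`)
transposes the roles to rank common targets of a regulator list.
Contextual filtering against an expression-derived list (for instance,
keeping only targets up-regulated when the querying miRNA family is
down) is plain set intersection, in `keep` or `annotate` mode.

TF-ranking presets: *stringent* (edge score ≥ 0.85, ≥ 3 query miRNAs
per TF, p ≤ 0.05) and *permissive* (score ≥ 0.65, site length ≥ 6,
≥ 1 miRNA per TF).

# Motif extraction

Four loop templates are enumerated exhaustively on the thresholded
graph:

| kind | members | edges |
|------|---------|-------|
| FBL | (t, m) | t→m, m→t |
| FFL-miRNA | (m, t, g) | m→t, m→g, t→g |
| FFL-TF | (t, m, g) | t→m, t→g, m→g |
| FFL-indirect | (t1, t2, m, g) | t1→t2, t2→m, t1→g, m→g |

where t is a TF, m a miRNA and g any target node (possibly TF-coding —
the miRNA→TF edge of the FBL is simply a `MIRNA_GENE` edge onto a TF
node). Enumeration is by indexed joins over the level-split edge
layers, which is exhaustive and duplicate-free by construction; the
test suite re-verifies it against typed brute-force tuple enumeration.
Output order is lexicographic on the role-ordered member ids.

Interpretation choices: the indirect template is fixed at exactly one
intermediate TF (longer chains explode combinatorially and lose
interpretability), with all four members required pairwise distinct —
the collapse t1 = t2 is precisely the direct FFL-TF and is reported
only as such. Regulatory sign (activation vs repression) is not
modeled; a "double-negative" reading of any loop is interpretation, not
computation. Validated TF→miRNA interaction lists act as a gate:
only motifs whose TF→miRNA constituent is validated survive, which by
construction removes all FFL-miRNA instances (they contain no such
edge) — the conservative reading of a validated-only filter.

# The synthetic generator

`gen_network()` emulates the structure of a real multi-level regulation
database at a default scale of 30 TFs, 100 miRNAs and 500 genes with 1%
background edge density per level — sized so that even the $O(V^4)$
brute-force verification oracles run in seconds. Its central design
property is *score separation*: background edges draw scores uniformly
on [0.1, 0.6], strictly below every analysis threshold, while planted
motif edges draw from [0.9, 1], strictly above. Planted motifs occupy
mutually disjoint node sets. Together these guarantees make motif
recovery an exact check (precision = recall = 1, any deviation is a
detector bug) instead of a statistical one. The generated expression
table assigns anti-correlated directions — planted miRNAs down,
their planted targets and reciprocal TFs up — emulating the
configuration of a repressed miRNA family whose targets escape
silencing, the scenario in which contextual filtering is most useful.

`gen_pfm()` solves each column's dominant-base probability numerically
so the realized information content matches the request (to the
tolerance of the root finder); `gen_region_with_sites()` plants
profile consensus sequences at block-separated offsets, which makes
non-overlap deterministic rather than probabilistic.

What the generator does *not* emulate, and what passing tests therefore
do not show: real upstream sequence is not i.i.d. (repeats, CpG
islands, compositional heterogeneity inflate false-positive rates
relative to the calibration reference); real edge scores are not
bimodally separated, so real motif calls inherit the uncertainty of
their constituent predictions; and real databases carry identifier
noise and cross-species asymmetries that the clean synthetic namespace
avoids. Benchmarks here validate the *machinery* — exhaustiveness,
exactness, determinism — not biological accuracy of any particular
source database.

# Determinism and degenerate inputs

All generators are integer-seeded (`withr::with_seed`, no time-based
state) and every ranking and enumeration has a deterministic total
order, so identical inputs give byte-identical outputs — including
through the CLI, whose subcommands are thin wrappers over the same
functions. Degenerate inputs have defined behaviour: an empty
interaction file is an empty table, not an error; duplicate dump rows
drop with a warning (robust ingestion of concatenated dumps); a region
shorter than the motif scans to an empty hit list with a warning; a
constant score sample cannot be uniformized and errors; an empty query
list errors, while a query disjoint from the universe warns and
returns an empty ranking.

# Limitations

* TF→gene edges are ingested from tables, not recomputed: conservation
  filtering and promoter modeling belong to upstream producers, as do
  CpG-island calls (ingested as BED).
* The background model is zeroth-order (i.i.d.); higher-order models
  would sharpen p-values on real sequence.
* Species handling is single-table; cross-species queries go through
  explicit symbol remapping (`remap_species()`), never implicit joins.
* The calibration reference is synthetic by default and labelled as
  such; score-to-p anchors computed on it are not comparable to anchors
  computed on any specific genomic reference.
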