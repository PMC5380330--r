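---
title: "Methods: miRNA microarray screening, genomic clustering and target networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA microarray screening, genomic clustering and target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cikmir)
```

## The analysis

`cikmir` implements the analysis chain used to profile miRNA expression
changes when peripheral blood mononuclear cells (PBMC) are expanded into
cytokine-induced killer (CIK) cells under IL-2 or IL-15. The chain is:
quantile normalization of probe intensities; per-contrast differential
expression screening with fold-change, t-test and detection-flag
criteria; comparison of the two CIK contrasts' DEM sets; genomic
clustering of DEM loci; over-representation analysis of predicted
target genes; and a bipartite miRNA–target network over cytotoxicity
genes. Raw arrays for the motivating study are not publicly deposited,
so the package pairs every stage with a synthetic generator that plants
known structure and returns the plan as a first-class truth table.

## Normalization

`quantile_normalize()` maps the value at rank $r$ in each column to the
across-column mean of rank-$r$ values, so all arrays share one
intensity distribution. Ties within a column receive the mean of the
reference values over the tied rank span; this is deterministic and
symmetric, but note that when ties are present the "identical column
multisets" property holds only approximately — two columns with
different tie patterns average different spans. All exact
multiset/idempotence assertions in the test suite therefore run on
tie-free matrices, which is the generic case for continuous
fluorescence data.

Normalization runs on the **linear** scale and fold changes are taken
from linear normalized values, so the screening thresholds FC > 2 and
FC < 0.5 stay on the scale they were stated on. The t-test runs on
`log2(value + 1)`; the offset of 1 linear fluorescence unit guards
zeros and is recorded in the result's provenance attribute.

## The DEM screen

A probe is called differentially expressed in a contrast
(test vs reference group, e.g. CIK_IL2 vs PBMC) iff all three hold,
with strict inequalities:

* fold change $\mathrm{FC} = \bar{x}_{\text{test}} / \bar{x}_{\text{ref}}$
  (ratio of linear group means) is $> 2$ (up) or $< 0.5$ (down);
* the unpaired pooled-variance Student t-test on log2 values gives
  $P < 0.05$ (two-sided, $n_A + n_B - 2$ df). Pooled rather than Welch
  variance is used deliberately: the stated method is the classic
  Student test;
* detection flags are consistent: within **each** compared group all
  replicate flags are identical, and at least one group's common flag
  is Present. Probes Absent in every replicate of both groups are
  unmeasured and excluded. The published criterion — identical flags
  across the replicates — does not say whether identity is required per
  group or across all arrays of the contrast; the per-group reading keeps genuinely switched-off probes
  (consistently Absent in one condition, Present in the other) —
  biologically the most interesting case — and is the package's
  interpretation, not an assertion about the original intent.

No multiple-testing correction is applied in the screen, matching the
stated raw-P criterion; `bh_fdr()` can be applied to the p-value column
by callers who want it.

Fold change is ratio-of-means rather than mean-of-ratios (the source
does not say which; ratio-of-means is what array suites of that era
computed). Degenerate probes (zero pooled variance) are flagged:
equal means give $t=0, P=1$; unequal means give $P=0$ with a
`degenerate` marker rather than a silent infinity.

`compare_contrasts()` expresses shared DEM counts as percentages of
each contrast's totals **truncated** (not rounded) to two decimals,
computed in integer arithmetic. Truncation is deliberate: 130 shared of
150 upregulated is 86.666…%, printed as 86.66 in the motivating study,
and truncation reproduces all four published percentages where rounding
would not.

`hierarchical_order()` orders DEM profiles by average-linkage (UPGMA)
agglomeration on $1 - r$ (Pearson) distance, implemented directly so
ties break deterministically by lexicographic probe id. Zero-variance
profiles have undefined correlation; their distance to everything is
defined as 1.

## Genomic clustering

miRNA loci that lie close together on a chromosome are often
co-transcribed; the package groups features by single-linkage closure
of the relation "interval gap $\le$ 5000 bp" (inclusive, reading
"no longer than 5000 bp" as $\le$), with the gap defined as
(later low) − (earlier high), 0 for overlapping or touching intervals,
and $\infty$ across chromosomes. Strand is ignored: published cluster
tables do not condition on it. Groups below `min_size = 2` are
discarded because only multi-member clusters are reported as clusters.
Input rows printed in the minus-strand dialect (start > end) are
normalized to $low \le high$ with the strand inferred from coordinate
order. Clusters are labelled C1…Cn by chromosome (autosomes
numerically, then X, Y) and lowest coordinate; on the packaged
37-record coordinate fixture this ordering reproduces the published
C1–C17 labels exactly.

The sweep implementation (sorted by low coordinate with a running
maximum high) is provably equivalent to all-pairs union-find on
intervals; the test suite checks that equivalence on random instances
up to 200 features, plus permutation invariance and the refinement
property in the gap threshold.

## Over-representation analysis

For a selected gene list $S$ against term $T$ in background $B$ the
2×2 table is $a = |S \cap T|$, $b = |S \setminus T|$,
$c = |T \setminus S|$, $d = |B| - a - b - c$ (term membership is
intersected with $B$ first). Significance uses the one-sided Fisher
tail $P(X \ge a)$, $X \sim \mathrm{Hypergeom}(|B|, a+c, a+b)$ — the
over-representation convention of enrichment tools; the Pearson
chi-squared p (optionally Yates-corrected) is computed and reported but
does not govern calls. FDR is Benjamini–Hochberg step-up over the whole
tested family; a term is significant iff $P < 0.05$ **and**
$q_{BH} < 0.05$, both strict. The default background is the annotated
universe (all genes in the interaction table), configurable.

Gene symbols are uppercased and a small alias table maps protein names
(FasL → FASLG, Trail → TNFSF10, CD94 → KLRD1, TNF-α → TNF) onto gene
symbols, since curated interaction lists mix the two.

## miRNA–target networks

`build_network()` assembles a strictly bipartite directed graph
miRNA → gene from a filtered interaction table; duplicate edges
collapse. `classify_genes_by_regulators()` labels each gene
`down_only` (≥ 1 edge, all regulators co-downregulated), `up_only`
(symmetric), `mixed` (regulators from both sets) or `none`. A gene
regulated only by miRNAs outside both DEM sets also maps to `none`:
the classes describe DEM-driven regulation, and such a gene carries no
DEM evidence. Exports are GraphML (with node `type` and `dem_status`
attributes, via igraph) and SIF (`mirna targets gene`), both
round-tripping node and edge sets.

The packaged cytotoxicity fixture (`cytotox_fixture()`) encodes the
text-stated relations for this system — let-7c targeting FASLG,
TNFSF10 and OSM; miR-199a/b-5p targeting GZMB — plus invented,
clearly-marked synthetic edges chosen so the fixture exhibits the
reported regulator classes (PRF1, GZMB, TNFSF10, FASLG down-only; OSM,
TNF, CD40LG mixed). It is a contract-test fixture, not a claim about
any interaction database, and the reported "10 distinct co-down
regulators" figure is not reconstructible from text alone, so it is
not asserted anywhere.

## The synthetic world

`generate_expression_dataset()` states the world the screen assumes:

* 2,006 probes (the array's human miRNA content), 3 groups × 3
  replicates;
* probe baselines $\log_2 I \sim N(8, 2)$ — a log-normal intensity
  model spanning the typical 4–5 decades of fluorescence;
* planted DEMs shift the test-group mean by ±2 on the log2 scale
  (linear FC 4), 5% up and 5% down per contrast, 90% of planted sets
  shared between the two CIK contrasts (matching the > 90% observed
  co-regulation);
* replicate noise $N(0, 0.25)$ on log2 — typical technical-replicate
  spread for single-channel arrays;
* detection flags: measurements below the bottom decile of all values
  lose their flag with probability 0.05. The failure probability is the
  package's choice (nothing published to match): detection calls are
  highly reproducible across technical replicates, so a 5% failure
  rate for near-background signals is a realistic stress that exercises
  the flag filter without dominating the screen.

What the generator does **not** emulate: inter-array batch effects, dye
or spatial artifacts, probe-specific affinity differences, or
correlated miRNA co-expression beyond the planted shifts. A green
recovery test therefore establishes that the screen implements its
stated criteria and recovers planted structure under idealized noise —
not that the original biological DEM counts are reproducible (they are
not, absent the raw arrays; the acceptance suite says so explicitly and
substitutes planted-truth recovery and null calibration).

`generate_annotation()` plants cluster geometries (gaps below
threshold inside clusters, ≥ 1 Mb between entities) with about half the
rows emitted in the minus-strand printed dialect.
`generate_target_db()` wires a designated miRNA subset to genes of
designated terms at an odds multiplier; multiplier 1 is an exact
hypergeometric null (empirical Fisher type-I ≈ α, slightly conservative
through discreteness — the calibration test uses term sizes of
150–250 in a universe of 4,000 genes so the discreteness gap stays
within ±0.02), and large multipliers give essentially full power.

All generators derive every draw from a single integer seed and return
truth tables, so recovery scoring never re-derives ground truth from
the generated data.

## Numerical and design choices

* Percentages: floor-truncation at two decimals, integer arithmetic.
* Quantile-normalization ties: mean reference value over the tied span.
* t-test degeneracy: $P = 0$ + flag (unequal means), $P = 1$ (equal).
* Hierarchical ties: lexicographic by smallest member id; left branch =
  lexicographically smaller branch.
* Cluster gap: coordinate difference, not base-counts-between; the
  packaged fixture satisfies the 5000 bp rule under this definition
  with every printed cluster intact and no cross-cluster pair within
  threshold.
* Enrichment calibration band: the package asserts empirical type-I
  within 0.05 ± 0.02, adopting the same band stated for the t-test
  calibration, since only "≈ α" is stated for enrichment.
* Pipeline seeds: one config seed, per-stage substreams derived by a
  fixed integer hash, all < 2^31.
* The pipeline restricts clustering to co-downregulated DEM loci when
  the coordinate table covers them, and otherwise clusters the full
  annotation (the synthetic annotation is a standalone geometry).

## Known limitations

* The flag vocabulary of real feature-extraction output is richer than
  Present/Absent; any non-Present token collapses to Absent.
* No background subtraction, baseline-to-median transform, or
  alternative normalizations (the original GeneSpring settings beyond
  quantile normalization are unstated and not replicated).
* Enrichment does not propagate GO ancestors and does not implement the
  EASE-adjusted Fisher variant.
* The headline DEM counts (261 / 249) depend on the unavailable raw
  arrays and are out of reach by design; the package's claims are
  calibration and recovery on its stated synthetic world.
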