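---
title: "Depth-ratio assignment of scaffolds to autosomes and the Z chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-ratio assignment of scaffolds to autosomes and the Z chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adratio)
library(data.table)
```

## The model

In ZW sex-determination systems (Lepidoptera, birds), males are homogametic
(ZZ) and females heterogametic (ZW). A whole-genome shotgun library therefore
samples each genomic fragment in proportion to its copy number in the
sequenced individual: autosomes at 2 copies in both sexes, the Z at 2 in
males but 1 in females, the W at 0 in males and 1 in females. For a scaffold
$s$, let $d_{s\ell}$ be its mean sequencing depth in library $\ell$ and
$N_\ell$ the library's mapped-read count. The standardized depth is
$\tilde d_{s\ell} = 10^6\, d_{s\ell} / N_\ell$ and the AD-ratio for a
male/female library pair $(m, f)$ is

$$ R_s = \frac{\tilde d_{sm}}{\tilde d_{sf}}, $$

with expectation 1 for autosomal scaffolds, 2 for Z-linked scaffolds, and 0
for W-linked scaffolds. Standardizing by mapped reads removes library-size
differences; the constant $10^6$ cancels in the ratio and only keeps the
reported depths on a readable scale.

Mean depth is always taken over the **full scaffold length**: positions
missing from the pileup-derived input count as depth 0. This makes sparsely
covered scaffolds *fall below* the minimum-depth filter instead of looking
deep over their few covered bases.

## From ratio to label

A single noisy ratio is banded into a provisional label, symmetric on the
log2 scale:

* autosomal when $|\log_2 R| \le 0.5$, i.e. $R \in [2^{-1/2},\, 2^{1/2}]$;
* Z when $|\log_2 (R/2)| \le 0.5$, i.e. $R \in [2^{1/2},\, 2^{3/2}]$;
* W when $R \le 0.3$;
* unclassified otherwise, and also when the ratio is undefined (female depth
  exactly 0 with male depth positive) — an undefined ratio is never taken as
  evidence for Z or W.

Bands are closed intervals. The autosomal and Z defaults share the boundary
$\sqrt 2$; the autosomal band is tested first, so a ratio of exactly
$\sqrt 2$ resolves to autosomal. All four bounds are exposed in
`classifier_config()`; since only the expectations 1/2/0 are dictated by the
copy-number model, the half-unit log2 half-widths are this package's design
choice (each band reaches the geometric midpoint between neighbouring
expectations), and the W cut-off of 0.3 keeps a gap between the W and
autosomal bands.

The final 5-way label per scaffold combines the replicate pairs:

1. **unannotated** — raw mean depth below `min_mean_depth_x` (default 4X) in
   one or several libraries. The filter uses *raw* depth, in coverage units,
   not standardized depth: "4X" is a statement about how many reads support
   each base.
2. the common provisional label, when all pairs agree and none is
   unclassified;
3. **ambiguous** otherwise — the replicate pairs do not reproduce each
   other's call. Ambiguity is one class regardless of which labels disagree;
   in partition summaries it is also shown under its common alias
   "putatively Z-heterosomal".

Replicates are paired male-with-female following the sequencing-pool design
(one male plus one female library per pool, `replicate_pair_id` in the
library metadata); an all-pairs mode crossing every male with every female is
available (`pairing = "all"`) but non-default. With a single pair the
reproducibility rule is inoperative and `annotate_genome()` warns: two
independent biological replicates are what makes the ambiguous class
meaningful. Note an asymmetry that follows directly from the rules: simulated
W scaffolds have zero male coverage, so at any positive depth filter they are
*unannotated*, never W; the W label is only reachable with the filter
disabled. A real male-derived reference contains no W scaffolds at all, so
the W band mostly guards against W-derived repetitive sequence attracting
reads.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_mean_depth_x` | 4 | X (raw coverage) | un-annotation threshold, any library |
| `autosomal_band` | $[2^{-1/2}, 2^{1/2}]$ | ratio | autosomal call |
| `z_band` | $[2^{1/2}, 2^{3/2}]$ | ratio | Z call |
| `w_max_ratio` | 0.3 | ratio | W call |
| normalization constant | $10^6$ | — | reporting scale only; cancels in ratios |

## What the simulator emulates

`sim_spec()` / `simulate_depth()` generate per-base depth over a toy genome
of autosomal, Z and W scaffolds with known truth, emitting the same
synchronized allele-count format (`scaffold`, 1-based position, reference
base, per-library `A:T:C:G:N:del`) the real pipeline consumes, so every
stage downstream of read mapping runs identically on synthetic and real
input. Per base and library, depth is drawn independently with mean
$c \cdot \mathrm{copy\ number}/2 \cdot \mathrm{multiplier}$, Poisson for
`overdispersion = 0` or negative-binomial with variance
$\mu(1 + \mathrm{overdispersion})$ otherwise (`size` $= \mu/$
`overdispersion`). Defaults, chosen once as the simulated study conditions:

* two male + two female libraries in two pools (`P1`, `P2`), matching a
  two-replicate design;
* target coverage 20X, overdispersion 0.2, so tests always exercise
  non-Poisson noise;
* read length 125 bp (paired-end short-read scale) used only to derive
  mapped-read counts from emitted depth totals, keeping normalization
  consistent with the data;
* a 5% fraction of scaffolds simulated at 2X to exercise the un-annotation
  rule;
* default karyotype 50 autosomal / 10 Z / 5 W scaffolds of 5–20 kb — the Z a
  small minority of the genome, as in a 30-autosome + Z karyotype; tests and
  the acceptance script override the counts where a balanced design is
  needed;
* zero depth on the W in males is exact (copy number 0), not sampled;
* per-library depth multipliers emulate unequal library sizes, with
  mapped-read counts scaling along, to exercise the normalization path;
* scaffold ids are opaque and the class assignment shuffled, so nothing
  downstream can read the truth off an id.

What it deliberately does **not** emulate: read-level structure (no
read-length autocorrelation of depth — irrelevant to scaffold means at the
tested lengths), mapping artifacts, multi-mapping in repeats, GC bias, and
gametologous Z/W sequence similarity. Passing the recovery tests therefore
shows the statistic and the rules are implemented correctly and behave as
designed under count noise; it does not show robustness to mapping bias in
real libraries — on real data those effects are exactly what the replicate
pairs and the ambiguous class are for.

## Numerical choices and degenerate inputs

* Depth at a base is the sum of the A, T, C, G counts only. The N column
  holds bases masked for low quality upstream — rejected evidence — and
  deletions are not sequenced bases; whether the original analyses counted
  those columns is unknowable from the outside, so the exclusion is a
  declared convention of this package.
* Positions absent from a sync file are depth 0 (pileups emit only covered
  positions); sync positions are 1-based, BED export is 0-based half-open.
* An empty gene table or no assessable genes yields an explicit `NA`
  ("undefined") concordance, never 0/0.
* Annotation tables are written with 4 decimal places for ratios and
  normalized depths; undefined ratios serialize as `NA`.
* Scale invariance is exact, not approximate: multiplying one library's
  every count and its mapped-read count by the same constant leaves every
  ratio bit-identical (the factor cancels before banding).

## Validation against known genes

`concordance_report()` reproduces the a posteriori check against genes whose
autosomal or Z location is known independently (consumed as a precomputed
gene-to-scaffold table; locating genes by alignment is out of scope). Genes
on ambiguous or unannotated scaffolds are non-assessable and excluded from
the strict denominator. Because an ambiguous scaffold still carries per-pair
labels, the report also gives a lenient figure in which such a gene counts
as concordant when at least one replicate pair's label matches its known
class — whether those cases "count" is a judgement call, so both numbers are
shown rather than deciding silently.

## Problem sizes

The reference simulation used throughout the test suite and the acceptance
script is 50 scaffolds per class at 10 kb and 20X — 1.5 Mb of genome and
about 6 million count draws — which gives per-scaffold ratio standard errors
of well under 1% and runs in seconds. The brute-force oracle comparison uses
100 random miniature datasets (at most 10 scaffolds of at most 100 bp) where
an independent flat loop recomputation is feasible and exact.

## A worked run

```{r, eval = FALSE}
spec <- sim_spec(n_autosomal = 50, n_z = 10, n_w = 5, length_bp = 10000,
                 seed = 1)
sim <- simulate_depth(spec = spec)
depth <- sync_scaffold_depth(sim$sync, sim$index, sim$libraries)
ann <- annotate_genome(depth)
summarize_partition(ann)
merge(ann, sim$truth, by = "scaffold_id")[, table(true_class, final_label)]
```

## Known limitations

* Scaffold-level only: no windowed, sub-scaffold assignment, so chimeric
  scaffolds spanning an autosome-Z breakpoint land in the ambiguous class at
  best.
* No significance testing on ratios; the bands are fixed thresholds, not a
  model-based decision rule.
* The W label is structurally unreachable under a positive depth filter (see
  above) — on a male-derived reference this is the intended behaviour.
* The simulator's independence assumptions make its error rates optimistic
  relative to real mapped data.
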