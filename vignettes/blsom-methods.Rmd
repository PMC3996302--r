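---
title: "Genome signatures on a batch-learning SOM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome signatures on a batch-learning SOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blsom)
```

## The model

A genome's *signature* is the species-specific bias of its short
oligonucleotide frequencies: fragments of roughly 50–100 kb drawn anywhere
in a genome carry nearly the same k-mer profile, and profiles differ
between species. The package represents each fragment as a composition
vector and organizes those vectors on a two-dimensional lattice with a
batch-learning self-organizing map (BLSOM), so that composition space is
laid out topologically: species become contiguous territories, the G+C
gradient becomes a smooth axis, and outlier sequence classes become
isolated zones.

### Composition vectors

For oligonucleotide length $k$ (default 5), every fragment is scanned with
a sliding window of width $k$ and step 1. Because sequence databases store
an arbitrary strand, each k-mer is pooled with its reverse complement into
one *degenerate* slot; for odd $k$ this halves the dimensionality exactly
(512 slots for pentanucleotides). Windows containing any non-ACGT character
contribute nothing, and counts are divided by the fragment's *effective*
length (its non-N length), so partially undetermined fragments remain
comparable. Fragments whose non-ACGT content exceeds 20% of the window are
excluded outright.

Three rules in this area are package decisions where the method statement
is silent:

* **Ambiguity codes** (R, Y, W, ...) are pooled with N for counting and
  filtering; they carry no usable composition signal at fragment scale.
* **Window skipping vs. length normalization**: a window touching an N is
  skipped entirely (no fractional attribution); dividing by the non-N
  length then approximates the per-valid-window rate well for moderate N
  content. An alternative normalization to row sum 1 is available
  (`to_frequencies(..., normalize = "total")`).
* **Even $k$**: self-complementary words (e.g. `ACGT`) occupy singleton
  slots and are not double-counted in expectations. The canonical analyses
  use odd $k$, where the case never arises.

### Lattice initialization and sizing

Weights start on the plane of the first two principal axes of the data:

$$\mathbf{w}_{ij} = \mathbf{x}_{av} + \frac{5\sigma_1}{I}\left[
  \mathbf{b}_1\left(i - \tfrac{I}{2}\right) +
  \mathbf{b}_2\left(j - \tfrac{J}{2}\right)\right],
  \qquad i \in \{0,\dots,I-1\},\; j \in \{0,\dots,J-1\}$$

with $\mathbf{x}_{av}$ the mean composition, $\mathbf{b}_1, \mathbf{b}_2$
unit eigenvectors of the covariance and $\sigma_1 \ge \sigma_2$ the
standard deviations of the first two principal components, so the first
lattice dimension spans five standard deviations of the dominant axis. PCA
is computed on the covariance (centered, unscaled): the relevant spread is
the literal one in frequency space, and rescaling slots would distort it.
Two conventions close gaps the formula leaves open:

* **Index origin.** Indices are 0-based, which offsets the grid by half a
  lattice step from perfect centering when $I$ or $J$ is even; this affects
  only the starting geometry, never the trained topology.
* **Eigenvector sign.** Each eigenvector's largest-magnitude component is
  made positive, otherwise mathematically equivalent inputs could produce
  mirrored maps.
* **Degenerate spread.** If the input cloud has (numerically) no second
  axis, $J$ collapses to 1 with a warning; if it has no variance at all,
  training falls back to a $2 \times 1$ lattice at the mean.

The lattice is sized from an occupancy target of approximately four
fragments per lattice point: $I = \operatorname{round}\sqrt{n /
(4\,\rho)}$ with $\rho = \sigma_2/\sigma_1$, and $J$ is the smallest
integer *strictly* greater than $\rho I$. The occupancy target is stated
by the method; the explicit formula for $I$ is the package's solution of
the two constraints (occupancy and aspect ratio) jointly.

### Batch training

Each epoch assigns every fragment to its nearest weight (Euclidean
distance; exact ties go to the smallest $(i,j)$ in row-major order) and
then replaces each weight by

$$\mathbf{w}_{ij} \leftarrow \mathbf{w}_{ij} + \alpha(r)\,
  (\bar{\mathbf{x}}_{N_{ij}} - \mathbf{w}_{ij})$$

where $\bar{\mathbf{x}}_{N_{ij}}$ is the mean of all fragments whose best
match lies within Chebyshev radius $\beta(r)$ of $(i,j)$; lattice points
with an empty neighborhood are left unchanged that epoch. The published
description of the update defers to earlier work without printing the
schedules, so the package fixes the standard batch-SOM choices and exposes
them as arguments: $\alpha(r)$ decreasing linearly from 0.6 to 0.01 over
$T$ epochs (default $T = 100$), $\beta(r) = \max(1, \beta_0 - r)$ with
$\beta_0 = \lceil I/10 \rceil$.

**Exact order invariance.** The defining property of the batch scheme is
that the trained map does not depend on input order. Mathematically the
update is order-free, but floating-point accumulation is not: summing the
same rows in a different order changes the last bits, and those bits
diverge over 100 epochs. The package therefore processes rows in a
canonical (lexicographically sorted) order internally — including the PCA
step — which makes training *bit-exactly* invariant under any permutation
of the input. The suite asserts `identical()` weights, not approximate
agreement.

Mean quantization error (mean distance of each fragment to its best-match
weight) is logged per epoch; at the default schedules it is stationary to
well below $10^{-9}$ relative over the final epochs.

## Derived lattice layers

* **U-matrix**: mean distance from each weight to its existing neighbors
  (8-neighborhood by default, 4 as an option; edges average over what
  exists). Rendered dark-for-large, it draws cluster borders. Display
  scaling is linear min–max.
* **Category coloring**: single-category lattice points take the category
  color, mixed points are black, empty points white.
* **G+C bins**: the G+C fraction implied by each weight vector, shown in
  21 rank-based equal-count bins (counts differ by at most one; ties and
  remainders resolve in row-major order so renders are reproducible).
* **Observed/expected ratios**: each lattice point's slot value divided by
  the value expected from that point's *own* mononucleotide composition
  (product of base frequencies, summed over the complement pair). The
  mononucleotide composition is derived from the weight vector itself by
  expanding slots into their member k-mers — weights have no underlying
  sequence to recount. Sentinels keep the layer total: $0/0 \mapsto 1$,
  positive/0 $\mapsto \infty$ (clipped to deepest red when rendered).
  Display cutoffs are symmetric on $\log_2$ at $\pm 0.263$ (ratio 1.2).
* **Specific zones**: the visual criterion "compact dark zones, or
  occupied pockets fenced by empty points" is operationalized as connected
  components (8-connectivity) of occupied points that are either above the
  90th percentile of the occupied U-matrix or whose entire outer border is
  empty, discarding components below 2 points. Percentile, minimum size
  and connectivity are arguments.

## Query mapping and the two prediction rules

New fragments (built with the training k-mer index) are assigned to their
nearest weight and inherit the majority category of the training fragments
there. Two rules govern queries whose best match is an *empty* lattice
point:

* `rule = "strict"` (default) labels them `"unassigned"`, mirroring the
  display convention that lattice points without training data stay white.
* `rule = "occupied"` searches the best match among occupied points only,
  so every query resolves to its nearest labeled territory.

On production-scale maps the rules coincide, because training sets far
exceed lattice sizes and empty points are rare. At desk scale they diverge
sharply: with 600 training fragments on a ~150-point lattice, half the
lattice is empty, and hold-out experiments here show the strict rule
rejecting the majority of queries (coverage ~40%) while misclassifying
none of the accepted, and the occupied rule classifying 100% correctly.
The strict rule is kept as the default because rejection is informative
(it flags compositions the map has not seen); the occupied rule is what a
classification benchmark should measure, and it is what the acceptance
checks use.

## The synthetic-data generator

`genome_spec()` / `generate_genome()` sample sequences from a Markov chain
(default order 0 or 1, arbitrary order supported), because a low-order
compositional bias is exactly what a genome signature is. Knobs: target
G+C, CpG suppression (multiplies the probability of G after C, renormalizes;
0 removes CG entirely), soft-masking and N injection in random runs (mean
run length 300 nt). `species_panel()` derives related "species" from one
backbone matrix by multiplying each transition probability by
$\exp(d \cdot z)$, $z \sim \mathcal{N}(0,1)$, where $d$ is the divergence
knob — at $d = 0$ species are statistically identical; at $d = 0.5$,
100 kb fragments separate into clean territories. All generation is
seeded and bit-reproducible, and the caller's RNG state is left untouched.

What the generator does *not* emulate: isochore-scale G+C heterogeneity,
interspersed repeats, or any within-genome substructure — each synthetic
genome is compositionally homogeneous. Passing tests therefore demonstrate
the machinery (counting, training, invariance, layer statistics) and
between-genome separation; they do not demonstrate within-genome
territory splitting on real isochores, which homogeneous chains cannot
produce. One consequence is quantitative: homogeneous 100 kb fragments
cluster much more tightly than real ones, which makes sparse-lattice
effects (the empty-point rejections above) *more* pronounced here than on
real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise the method's standard conditions where it matters and
small fixtures elsewhere: the headline runs use 100 kb windows with
degenerate pentanucleotides (500–750 fragments, 512 dimensions, 100
epochs); unit and property tests use 2–10 kb windows and $k \le 4$.
Tolerances in tests reflect a priori sampling noise (e.g. binomial
standard deviations of slot frequencies at the simulated lengths), not
observed slack. Other numerical conventions: distances use the squared
expansion $\lvert x\rvert^2 - 2x\cdot w + \lvert w\rvert^2$ clamped at 0;
weight vectors are clamped at 0 before composition-derived layers (early
epochs can leave small negatives from the PCA-plane initialization);
equal-count binning and all tie-breaks are deterministic.

## Known limitations

* Pure-R training is comfortable to a few thousand fragments and $k \le 6$;
  the millions-of-fragments regime the batch algorithm enables requires
  parallel hardware out of scope here.
* The map-sizing rule assumes an elongated data cloud ($\sigma_2 > 0$);
  degenerate geometries fall back as described above.
* Soft-masked repeat splitting consumes existing masking; the package never
  computes masking itself.
* `read_fasta()` loads sequences into memory; chromosome-scale multi-GB
  inputs should be pre-fragmented externally or streamed per record.
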