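# blsom

Batch-learning self-organizing maps for alignment-free clustering of genomic
sequence fragments by their oligonucleotide composition.

## The problem

Every genome carries a species-specific bias in its short oligonucleotide
frequencies — its *genome signature*. Fragments of 50–100 kb taken anywhere
in a genome share that signature, so fragments from different species can be
separated, with no alignment and no annotation, purely from their k-mer
composition. The self-organizing map (SOM) is the natural instrument: it
projects the high-dimensional composition vectors onto a two-dimensional
lattice while preserving topology, so species form contiguous colored
territories, G+C% gradients and within-genome substructure become visible,
and compositionally peculiar sequence classes (e.g. pericentromeric repeats)
stand out as isolated zones. The batch-learning variant (BLSOM) replaces
Kohonen's sequential update with a full-batch one, which makes the trained
map independent of the order in which fragments are presented — a
prerequisite for reproducible genomics work and for parallel scaling.

The package serves sequence analysts who want composition-based clustering
or phylotype assignment (e.g. binning metagenomic fragments) without
reference alignments, entirely in R.

## Method

Fragments are composition vectors `x_k`: counts of all k-mers (default
k = 5), with each reverse-complement pair summed into one slot ("DegPenta",
512 dimensions) because only one strand of a genome is ever deposited;
counts are normalized by the fragment's non-N length. Windows containing an
undetermined base contribute nothing, and fragments whose N content exceeds
20% are excluded.

Training initializes the lattice weights on the PCA plane of the data:

    w_ij = x_av + (5 sigma1 / I) * [ b1 (i - I/2) + b2 (j - J/2) ]

where `x_av` is the mean composition, `b1`, `b2` the first two eigenvectors
of the covariance, and `sigma1`, `sigma2` the corresponding standard
deviations. The lattice width `I` is chosen so the average occupancy is
about four fragments per lattice point, and `J` is the smallest integer
strictly greater than `(sigma2/sigma1) I`. Each epoch then (1) assigns every
fragment to its best-matching weight (minimal Euclidean distance,
deterministic tie-break) and (2) moves each weight toward the mean of all
fragments assigned within a shrinking Chebyshev neighborhood, by a learning
coefficient decreasing linearly from 0.6 to 0.01. Internally rows are
processed in a canonical order, so training is *bit-exactly* invariant
under permutation of the input.

Diagnostics on the trained map: the U-matrix (mean distance between
neighboring weights; dark ridges are cluster borders), three-way category
coloring (single category / multi = black / empty = white), 21 equal-count
G+C% bins, and per-lattice observed/expected ratios — each lattice point's
k-mer content divided by the value implied by its own mononucleotide
composition, which reads out motif-level preference independent of the G+C
gradient (CpG suppression, for instance, shows every CG-containing slot
below 1). New fragments are classified by mapping them onto the trained
lattice and inheriting the majority category of their territory.

A Markov-chain genome simulator (`genome_spec()`, `species_panel()`)
generates FASTA-ready test genomes with controllable signatures, CpG
suppression, soft-masking and N content, so the whole workflow runs without
external downloads.

## Worked example

```r
library(blsom)

# three synthetic species, 10 kb fragments, degenerate tetranucleotides
panel <- species_panel(3, divergence = 0.5, length = 2e6, seed = 1)
comp  <- genome_composition(panel, window = 10000, k = 4)
comp
#> genome composition: 600 fragments (600 included), window 10000 nt, degenerate k=4 (136 slots)

# hold 10 fragments per species out, train on the rest
labs <- comp$manifest$category[comp$manifest$included]
set.seed(42)
hold <- unlist(lapply(split(seq_along(labs), labs), sample, 10))
fit <- blsom(comp$matrix[-hold, ], categories = labs[-hold],
             epochs = 100, index = comp$index)
summary(fit)
#> 19 x 8 lattice (152 points, 125 nonempty)
#> fragments: 570 (3.75 per lattice point)
#> final quantization error: 0.00884582
#> lattice purity (single-category nonempty points): 1.000

pred <- predict(fit, comp$matrix[hold, ], rule = "occupied")
table(pred$category, labs[hold])
#>       sp1 sp2 sp3
#>   sp1  10   0   0
#>   sp2   0  10   0
#>   sp3   0   0  10

plot(fit, type = "category")   # species territories
plot(fit, type = "umatrix")    # composition borders
plot(fit, type = "oe", kmer = "AACG")
```

The summary shows the lattice sized to ≈4 fragments per point and perfect
single-species purity of the occupied lattice; the prediction table shows
every held-out fragment classified to its source species.

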