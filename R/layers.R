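#' U-matrix of a trained map
#'
#' For every lattice point, the mean Euclidean distance between its weight
#' vector and those of its neighboring lattice points (8-neighborhood by
#' default; corners and edges average over the neighbors that exist).
#' Rendered as gray levels, high values draw dark borders between map
#' territories of distinct composition, and compact dark or enclosed zones
#' mark sequences whose composition is peculiar relative to the bulk.
#'
#' @param fit A [blsom()] fit, or a weight matrix (then `I`, `J` required).
#' @param neighbors 8 (default) or 4 (von Neumann neighborhood).
#' @param I,J Lattice dimensions when `fit` is a plain matrix.
#' @return Numeric `I` x `J` matrix (rows = first lattice dimension `i`).
#' @export
umatrix <- function(fit, neighbors = 8L, I = NULL, J = NULL) {
  if (inherits(fit, "blsom")) { W <- fit$weights; I <- fit$I; J <- fit$J }
  else W <- fit
  stopifnot(neighbors %in% c(4L, 8L), !is.null(I), !is.null(J))
  offsets <- if (neighbors == 8L)
    expand.grid(di = -1:1, dj = -1:1) else
    data.frame(di = c(-1L, 1L, 0L, 0L), dj = c(0L, 0L, -1L, 1L))
  offsets <- offsets[offsets$di != 0L | offsets$dj != 0L, ]
  dsum <- numeric(I * J)
  dcnt <- numeric(I * J)
  coords <- lattice_coords(I, J)
  for (r in seq_len(nrow(offsets))) {
    di <- offsets$di[r]; dj <- offsets$dj[r]
    ok <- coords[, "i"] + di >= 0L & coords[, "i"] + di <= I - 1L &
          coords[, "j"] + dj >= 0L & coords[, "j"] + dj <= J - 1L
    src <- which(ok)
    nb <- (coords[src, "i"] + di) * J + (coords[src, "j"] + dj) + 1L
    d <- sqrt(rowSums((W[src, , drop = FALSE] - W[nb, , drop = FALSE])^2))
    dsum[src] <- dsum[src] + d
    dcnt[src] <- dcnt[src] + 1
  }
  matrix(dsum / pmax(dcnt, 1), nrow = I, ncol = J, byrow = TRUE)
}

#' Category color class per lattice point
#'
#' The three-way coloring convention of genome-signature maps: a lattice
#' point holding fragments of a single category is colored for that
#' category, one holding fragments of multiple categories is `"multi"`
#' (drawn black), and one holding no fragment is `"empty"` (left white).
#'
#' @param fit A [blsom()] fit trained with category labels.
#' @return Character `I` x `J` matrix with entries `"empty"`, `"multi"`, or
#'   the category name.
#' @export
category_layer <- function(fit) {
  stopifnot(inherits(fit, "blsom"))
  if (is.null(fit$categories))
    stop("the map was trained without category labels")
  tab <- table(fit$assignment$cell, fit$categories)
  layer <- rep("empty", fit$I * fit$J)
  occupied <- as.integer(rownames(tab))
  ncat <- rowSums(tab > 0)
  layer[occupied] <- ifelse(ncat > 1L, "multi",
                            colnames(tab)[apply(tab, 1L, which.max)])
  matrix(layer, nrow = fit$I, ncol = fit$J, byrow = TRUE)
}

#' G+C content per lattice point
#'
#' G+C fraction implied by each lattice weight vector (via its
#' mononucleotide expansion). Empty lattice points still carry a weight
#' vector and thus a value; use [category_layer()] to mask them if needed.
#'
#' @param fit A [blsom()] fit carrying a [kmer_index()].
#' @return Numeric `I` x `J` matrix of G+C fractions.
#' @export
gc_layer <- function(fit) {
  stopifnot(inherits(fit, "blsom"))
  if (is.null(fit$index)) stop("the fit carries no k-mer index")
  vals <- apply(fit$weights, 1L, function(w) gc_content(pmax(w, 0), fit$index))
  matrix(vals, nrow = fit$I, ncol = fit$J, byrow = TRUE)
}

#' Equal-count quantile bins
#'
#' Rank-based binning into `n_bins` classes holding equal numbers of lattice
#' points (counts differ by at most one; remainders go to the lowest bins).
#' This is the display convention for the G+C layer: 21 equal-count
#' categories from the lowest (green) through the middle (white) to the
#' highest (wine red). Ties are broken by position (row-major lattice
#' order), keeping renders reproducible.
#'
#' @param values Numeric vector (or matrix) of per-lattice values.
#' @param n_bins Number of bins (default 21).
#' @return Integer bin ids (1 = lowest) with the shape of `values`.
#' @export
gc_quantile_bins <- function(values, n_bins = 21L) {
  if (n_bins < 2L) stop("'n_bins' must be at least 2")
  v <- as.vector(if (is.matrix(values)) t(values) else values)  # row-major
  n <- length(v)
  if (n < n_bins) stop("fewer lattice points than bins")
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bins <- integer(n)
  bins[order(v, seq_len(n))] <- rep.int(seq_len(n_bins), sizes)
  if (is.matrix(values))
    matrix(bins, nrow = nrow(values), ncol = ncol(values), byrow = TRUE)
  else bins
}

#' Observed/expected layer for one oligonucleotide pair
#'
#' For every lattice point, the ratio of the observed slot value of the
#' weight vector to the value expected from that lattice point's *own*
#' mononucleotide composition. Because the expectation is recomputed per
#' lattice point, the layer reads out oligonucleotide preference independent
#' of the simple mononucleotide (G+C) gradient across the map. Layers of
#' diagnostic oligonucleotides switch between over- (> 1, red) and
#' under-representation (< 1, blue) exactly at territory borders.
#'
#' @param fit A [blsom()] fit carrying a degenerate or plain [kmer_index()].
#' @param kmer A k-mer naming the slot; either member of a complementary
#'   pair is accepted (e.g. `"AAAAC"` or `"GTTTT"`).
#' @return Numeric `I` x `J` matrix of ratios.
#' @export
oe_layer <- function(fit, kmer) {
  stopifnot(inherits(fit, "blsom"))
  if (is.null(fit$index)) stop("the fit carries no k-mer index")
  kmer <- toupper(kmer)
  if (!kmer %in% names(fit$index$slot_of))
    stop("unknown k-mer for this index: ", kmer)
  slot <- fit$index$slot_of[[kmer]]
  vals <- apply(fit$weights, 1L, function(w) {
    w <- pmax(w, 0)
    expd <- expected_frequency(mono_composition(w, fit$index), fit$index)
    oe_ratio(w, expd, fit$index)[slot]
  })
  matrix(vals, nrow = fit$I, ncol = fit$J, byrow = TRUE)
}

#' Detect specific zones (Sz) of peculiar composition
#'
#' Operationalizes the visual reading of a genome-signature map: compact
#' zones whose sequences differ sharply in composition from the bulk of
#' their genome appear either as dark U-matrix islands or as occupied
#' pockets fenced in by empty (white) lattice points. A lattice point is a
#' candidate when it is nonempty and its U-matrix value exceeds the `q`-th
#' percentile of nonempty points; additionally, any connected component of
#' nonempty points whose entire outer border is empty qualifies. Candidate
#' components (8-connectivity) smaller than `min_size` are discarded.
#'
#' @param fit A [blsom()] fit.
#' @param q Percentile (0-100) of the U-matrix defining "dark" (default 90).
#' @param min_size Minimum component size in lattice points (default 2).
#' @param neighbors Neighborhood for the U-matrix (default 8).
#' @return A list with `labels` (integer `I` x `J` matrix, 0 = no zone) and
#'   `zones` (data frame: `zone`, `size`, `categories` summary).
#' @export
detect_sz_zones <- function(fit, q = 90, min_size = 2L, neighbors = 8L) {
  stopifnot(inherits(fit, "blsom"))
  I <- fit$I; J <- fit$J
  um <- umatrix(fit, neighbors = neighbors)
  occ <- tabulate(fit$assignment$cell, nbins = I * J) > 0
  um_v <- as.vector(t(um))                       # row-major
  dark <- occ & um_v > stats::quantile(um_v[occ], q / 100)

  comp_occ <- connected_components(occ, I, J)
  enclosed <- logical(I * J)
  coords <- lattice_coords(I, J)
  for (id in setdiff(unique(comp_occ), 0L)) {
    cells <- which(comp_occ == id)
    border <- lattice_neighbors(cells, I, J)
    outside <- setdiff(border, cells)
    if (length(outside) == 0L) next        # component fills the whole map
    if (all(!occ[outside])) enclosed[cells] <- TRUE
  }

  cand <- dark | enclosed
  comp <- connected_components(cand, I, J)
  keep <- table(comp[comp > 0L])
  keep <- as.integer(names(keep)[keep >= min_size])
  labels <- integer(I * J)
  for (z in seq_along(keep)) labels[comp == keep[z]] <- z

  zones <- if (length(keep) > 0L) {
    do.call(rbind, lapply(seq_along(keep), function(z) {
      cells <- which(labels == z)
      frs <- fit$assignment$cell %in% cells
      cats <- if (!is.null(fit$categories))
        paste(sort(unique(fit$categories[frs])), collapse = ",") else NA
      data.frame(zone = z, size = length(cells), n_fragments = sum(frs),
                 categories = cats, stringsAsFactors = FALSE)
    }))
  } else data.frame(zone = integer(), size = integer(),
                    n_fragments = integer(), categories = character())
  list(labels = matrix(labels, nrow = I, ncol = J, byrow = TRUE),
       zones = zones)
}

## 8-connected components over a logical mask given in row-major cell order;
## returns an integer label per cell (0 for FALSE cells).
connected_components <- function(mask, I, J) {
  labels <- integer(I * J)
  cells <- which(mask)
  if (length(cells) == 0L) return(labels)
  coords <- lattice_coords(I, J)
  edges <- NULL
  for (di in 0:1) for (dj in -1:1) {
    if (di == 0L && dj <= 0L) next       # each undirected pair once
    src <- cells
    ni <- coords[src, "i"] + di; nj <- coords[src, "j"] + dj
    ok <- ni <= I - 1L & nj >= 0L & nj <= J - 1L
    nb <- ni[ok] * J + nj[ok] + 1L
    inmask <- mask[nb]
    edges <- rbind(edges, cbind(src[ok][inmask], nb[inmask]))
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(if (is.null(edges))
      matrix(integer(), ncol = 2L) else edges),
    directed = FALSE,
    vertices = data.frame(name = as.character(cells)))
  memb <- igraph::components(g)$membership
  labels[as.integer(names(memb))] <- as.integer(memb)
  labels
}

## all lattice neighbors (8-conn) of a set of row-major cell indices
lattice_neighbors <- function(cells, I, J) {
  coords <- lattice_coords(I, J)
  out <- integer(0)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ni <- coords[cells, "i"] + di; nj <- coords[cells, "j"] + dj
    ok <- ni >= 0L & ni <= I - 1L & nj >= 0L & nj <= J - 1L
    out <- c(out, ni[ok] * J + nj[ok] + 1L)
  }
  unique(out)
}
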