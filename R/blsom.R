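#' PCA frame of a composition matrix
#'
#' Computes the mean vector and the first two principal axes of the input
#' cloud in oligonucleotide-frequency space. The lattice is initialized on
#' the plane of widest spread, so training starts from the large-scale
#' structure of the data instead of from random weights — this is the first
#' ingredient of the order-independent batch scheme. PCA is performed on the
#' covariance of the raw frequency vectors (centered, unscaled): the spread
#' that matters is the literal one in frequency space.
#'
#' The sign of each eigenvector is fixed so that its largest-magnitude
#' component is positive; without a convention the map could mirror
#' arbitrarily between runs on mathematically equivalent inputs.
#'
#' @param x Numeric matrix, rows = fragments, columns = composition slots
#'   (frequency form), or a [genome_composition()] result.
#' @return An object of class `"blsom_pca"`: list with `x_av` (mean
#'   vector), `b1`, `b2` (unit eigenvectors), `sigma1`, `sigma2` (standard
#'   deviations of the first two principal components).
#' @export
fit_pca <- function(x) {
  x <- composition_values(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 composition rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  if (length(pc$sdev) < 2L || pc$sdev[1L] <= 0) {
    ## zero spread (e.g. one vector repeated): fall back to canonical axes
    warning("input has no variance; principal axes are arbitrary")
    b1 <- b2 <- numeric(ncol(x)); b1[1L] <- 1; b2[2L] <- 1
    return(structure(list(x_av = colMeans(x), b1 = b1, b2 = b2,
                          sigma1 = 0, sigma2 = 0), class = "blsom_pca"))
  }
  b1 <- fix_sign(pc$rotation[, 1L])
  b2 <- fix_sign(pc$rotation[, 2L])
  structure(list(x_av = colMeans(x), b1 = b1, b2 = b2,
                 sigma1 = pc$sdev[1L], sigma2 = pc$sdev[2L]),
            class = "blsom_pca")
}

fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Lattice dimensions from data spread and occupancy target
#'
#' Sizes the map so that (a) the aspect ratio of the lattice matches the
#' aspect ratio `sigma2/sigma1` of the data cloud and (b) the average number
#' of fragments per lattice point (neuron) is approximately `per_neuron`,
#' four by default. The second dimension `J` is the smallest integer
#' *strictly* greater than `sigma2/sigma1 * I`.
#'
#' @param n_fragments Number of fragments to be mapped.
#' @param frame A [fit_pca()] result (or any list with `sigma1`, `sigma2`).
#' @param per_neuron Target mean fragments per lattice point (default 4).
#' @return Integer vector `c(I, J)`.
#' @examples
#' size_map(1000, list(sigma1 = 1, sigma2 = 0.5))  # c(22, 12)
#' @export
size_map <- function(n_fragments, frame, per_neuron = 4) {
  if (n_fragments < per_neuron)
    stop("fewer fragments than the per-neuron target")
  if (frame$sigma1 <= 0) stop("sigma1 must be positive")
  rho <- frame$sigma2 / frame$sigma1
  if (rho <= 1e-12) {   # numerically rank-1 spread
    warning("sigma2 = 0: second map dimension fixed to 1")
    I <- max(2L, as.integer(round(sqrt(n_fragments / per_neuron))))
    return(c(I = I, J = 1L))
  }
  I <- max(2L, as.integer(round(sqrt(n_fragments / (per_neuron * rho)))))
  J <- as.integer(floor(rho * I)) + 1L
  c(I = I, J = J)
}

#' Initialize lattice weights on the principal plane
#'
#' Places the initial weight vectors on a regular grid in the PCA plane:
#' `w_ij = x_av + (5 sigma1 / I) * (b1 (i - I/2) + b2 (j - J/2))` with
#' `i` in `0..I-1`, `j` in `0..J-1`, so the first lattice dimension spans a
#' width of five standard deviations of the first principal component. With
#' 0-based indices the grid is offset by half a lattice step from perfect
#' centering when `I` or `J` is even; this affects only the initial
#' geometry, not the trained topology.
#'
#' @param frame A [fit_pca()] result.
#' @param I,J Lattice dimensions, e.g. from [size_map()].
#' @return Numeric matrix of dimension `I*J` x `length(x_av)`; rows are
#'   lattice points in row-major order (`i` major, `j` minor).
#' @export
pca_init <- function(frame, I, J) {
  stopifnot(I >= 1L, J >= 1L)
  step <- 5 * frame$sigma1 / I
  ij <- lattice_coords(I, J)
  sweep(((ij[, "i"] - I / 2) %o% frame$b1 +
         (ij[, "j"] - J / 2) %o% frame$b2) * step, 2L,
        frame$x_av, "+")
}

## 0-based lattice coordinates in row-major order: cell = i*J + j + 1
lattice_coords <- function(I, J) {
  cbind(i = rep(0:(I - 1L), each = J), j = rep.int(0:(J - 1L), I))
}

#' Best-matching lattice point per fragment
#'
#' Assigns each composition row to the lattice point whose weight vector has
#' minimal Euclidean distance. Ties are broken toward the smallest `(i, j)`
#' in row-major order, which keeps every downstream result deterministic.
#'
#' @param x Composition matrix (rows = fragments) or [genome_composition()].
#' @param weights Weight matrix (rows = lattice points, row-major).
#' @return List with `cell` (1-based row-major lattice index per fragment)
#'   and `dist` (Euclidean distance to the best-matching weight).
#' @export
assign_bmu <- function(x, weights) {
  x <- composition_values(x)
  stopifnot(ncol(x) == ncol(weights))
  ## squared distances via the expansion |x|^2 - 2 x.w + |w|^2; each row is
  ## computed independently of the others, so assignment is order-invariant
  cross <- x %*% t(weights)
  d2 <- sweep(-2 * cross, 2L, rowSums(weights^2), "+") + rowSums(x^2)
  cell <- max.col(-d2, ties.method = "first")
  list(cell = cell, dist = sqrt(pmax(d2[cbind(seq_len(nrow(x)), cell)], 0)))
}

#' One batch weight update
#'
#' For each lattice point, gathers every fragment whose best match lies
#' within Chebyshev (chessboard) radius `beta` of it and moves the weight a
#' fraction `alpha` toward the mean of that neighborhood set; lattice points
#' with an empty neighborhood are left unchanged. Because the set mean does
#' not depend on the order in which fragments were presented, the epoch —
#' and hence the whole training — is independent of input order.
#'
#' @param weights Weight matrix (lattice row-major).
#' @param x Composition matrix.
#' @param cell Best-match cell per row of `x`, as from [assign_bmu()].
#' @param alpha Learning coefficient in `[0, 1]`.
#' @param beta Neighborhood radius (Chebyshev), a nonnegative integer.
#' @param I,J Lattice dimensions.
#' @return Updated weight matrix.
#' @export
batch_update <- function(weights, x, cell, alpha, beta, I, J) {
  x <- composition_values(x)
  IJ <- I * J
  sums <- matrix(0, IJ, ncol(x))
  hit <- rowsum(x, cell)
  sums[as.integer(rownames(hit)), ] <- hit
  counts <- tabulate(cell, nbins = IJ)

  nb_sums <- matrix(0, IJ, ncol(x))
  nb_counts <- numeric(IJ)
  b <- as.integer(beta)
  for (di in -b:b) {
    ivalid_t <- max(0L, -di):(I - 1L - max(0L, di))   # target i range
    if (length(ivalid_t) == 0L || ivalid_t[1L] > ivalid_t[length(ivalid_t)])
      next
    for (dj in -b:b) {
      jt0 <- max(0L, -dj); jt1 <- J - 1L - max(0L, dj)
      if (jt0 > jt1) next
      tgt <- outer((ivalid_t) * J, jt0:jt1, "+") + 1L
      src <- outer((ivalid_t + di) * J, (jt0:jt1) + dj, "+") + 1L
      nb_sums[tgt, ] <- nb_sums[tgt, ] + sums[src, ]
      nb_counts[tgt] <- nb_counts[tgt] + counts[src]
    }
  }
  nonempty <- nb_counts > 0
  target <- weights
  target[nonempty, ] <- nb_sums[nonempty, , drop = FALSE] / nb_counts[nonempty]
  weights + alpha * (target - weights)
}

#' Fit a batch-learning self-organizing map to composition data
#'
#' Trains a two-dimensional lattice of weight vectors on fragment
#' composition vectors: the lattice is sized from the data
#' ([size_map()]), initialized on the first two principal axes
#' ([pca_init()]), and then refined by alternating full-batch best-match
#' assignment and neighborhood-mean updates for `epochs` rounds. The batch
#' scheme, deterministic tie-breaking and a canonical internal processing
#' order make the result exactly invariant under permutation of the input
#' rows — the defining property of the BLSOM as opposed to Kohonen's
#' sequential SOM.
#'
#' The learning coefficient decreases linearly from `alpha[1]` to
#' `alpha[2]` over the epochs; the neighborhood radius starts at `beta0`
#' (default `ceiling(I / 10)`) and shrinks by one per epoch to a floor of 1.
#'
#' @param x Composition matrix in frequency form (rows = fragments), a
#'   [genome_composition()] object, or a count matrix from [count_kmers()]
#'   (used as-is).
#' @param categories Optional character vector of per-fragment category
#'   labels (species, repeat/unique, ...); taken from the composition object
#'   when available. Labels play no role in training — they only annotate
#'   the trained map for coloring and prediction.
#' @param epochs Number of assignment/update rounds (default 100).
#' @param per_neuron Target mean fragments per lattice point (default 4).
#' @param alpha Length-2 numeric: initial and final learning coefficient
#'   (default `c(0.6, 0.01)`).
#' @param beta0 Initial neighborhood radius; default `ceiling(I / 10)`.
#' @param size Optional explicit `c(I, J)` overriding [size_map()].
#' @param index Optional [kmer_index()] describing the columns of a plain
#'   matrix input; taken from a [genome_composition()] automatically. Needed
#'   only for the composition-derived layers (G+C, o/e).
#' @return An object of class `"blsom"` with components `weights`
#'   (`I*J` x slots, row-major), `I`, `J`, `pca`, `assignment` (data frame
#'   `fragment`, `i`, `j`, `cell`, `dist` in input row order), `categories`,
#'   `cell_category` (majority label per lattice point, `NA` where empty),
#'   `qe` (per-epoch mean quantization error), `index` (the
#'   [kmer_index()] when known), and the training hyperparameters.
#' @examples
#' panel <- species_panel(2, divergence = 0.8, length = 2e5, seed = 1)
#' comp <- genome_composition(panel, window = 5000, k = 3)
#' fit <- blsom(comp, epochs = 30)
#' fit
#' @export
blsom <- function(x, categories = NULL, epochs = 100L, per_neuron = 4,
                  alpha = c(0.6, 0.01), beta0 = NULL, size = NULL,
                  index = NULL) {
  if (inherits(x, "genome_composition")) {
    if (is.null(categories)) categories <- x$manifest$category[x$manifest$included]
    if (is.null(index)) index <- x$index
    x <- x$matrix
  }
  x <- composition_values(x)
  if (!is.null(categories) && length(categories) != nrow(x))
    stop("'categories' must have one label per composition row")
  if (epochs < 1L) stop("'epochs' must be >= 1")
  n <- nrow(x)

  ## canonical processing order: sorting rows lexicographically removes any
  ## dependence of floating-point accumulation (PCA means, neighborhood
  ## sums) on the order rows arrived in, so training is exactly
  ## permutation-invariant
  ord <- do.call(order, as.data.frame(unname(x)))
  xs <- x[ord, , drop = FALSE]

  frame <- fit_pca(xs)
  if (is.null(size))
    size <- if (frame$sigma1 <= 0) c(2L, 1L) else
      size_map(n, frame, per_neuron)
  I <- as.integer(size[1L]); J <- as.integer(size[2L])
  W <- pca_init(frame, I, J)
  if (is.null(beta0)) beta0 <- ceiling(I / 10)

  qe <- numeric(epochs)
  cell_s <- NULL
  for (r in seq_len(epochs) - 1L) {
    a <- if (epochs == 1L) alpha[1L] else
      alpha[1L] + (alpha[2L] - alpha[1L]) * r / (epochs - 1L)
    b <- max(1L, as.integer(beta0) - r)
    asg <- assign_bmu(xs, W)
    qe[r + 1L] <- mean(asg$dist)
    W <- batch_update(W, xs, asg$cell, a, b, I, J)
    if (any(!is.finite(W)))
      stop("numeric failure: non-finite weights at epoch ", r + 1L)
  }
  final <- assign_bmu(x, W)
  coords <- lattice_coords(I, J)
  assignment <- data.frame(
    fragment = if (!is.null(rownames(x))) rownames(x) else seq_len(n),
    i = coords[final$cell, "i"], j = coords[final$cell, "j"],
    cell = final$cell, dist = final$dist, stringsAsFactors = FALSE)

  cell_category <- rep(NA_character_, I * J)
  if (!is.null(categories)) {
    tab <- table(cell = final$cell, category = categories)
    occupied <- as.integer(rownames(tab))
    ## majority label per cell; ties toward the alphabetically first label
    cell_category[occupied] <- colnames(tab)[apply(tab, 1L, which.max)]
  }

  structure(list(weights = W, I = I, J = J, pca = frame,
                 assignment = assignment, categories = categories,
                 cell_category = cell_category, qe = qe, epochs = epochs,
                 alpha = alpha, beta0 = beta0, per_neuron = per_neuron,
                 index = index, n = n),
            class = "blsom")
}

## Accept a genome_composition, a matrix, or anything matrix-like.
composition_values <- function(x) {
  if (inherits(x, "genome_composition")) x <- x$matrix
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' @export
print.blsom <- function(x, ...) {
  cat(sprintf("Batch-learning SOM: %d x %d lattice, %d fragments, %d slots\n",
              x$I, x$J, x$n, ncol(x$weights)))
  cat(sprintf("  epochs: %d  alpha: %.2f -> %.2f  beta0: %d\n",
              x$epochs, x$alpha[1L], x$alpha[2L], as.integer(x$beta0)))
  cat(sprintf("  final quantization error: %.6g\n", x$qe[x$epochs]))
  if (!is.null(x$categories))
    cat("  categories:", paste(sort(unique(x$categories)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Summarize a trained map
#'
#' Reports lattice occupancy, the fragments-per-neuron average the sizing
#' rule targets, quantization error, and — when category labels are known —
#' the lattice purity: the fraction of nonempty lattice points whose
#' fragments all share one category.
#'
#' @param object A [blsom()] fit.
#' @param ... Unused.
#' @return A list of class `"summary.blsom"`.
#' @export
summary.blsom <- function(object, ...) {
  occ <- tabulate(object$assignment$cell, nbins = object$I * object$J)
  out <- list(I = object$I, J = object$J, n = object$n,
              nonempty = sum(occ > 0),
              per_neuron = object$n / (object$I * object$J),
              qe = object$qe[object$epochs],
              purity = lattice_purity(object))
  class(out) <- "summary.blsom"
  out
}

#' @export
print.summary.blsom <- function(x, ...) {
  cat(sprintf("%d x %d lattice (%d points, %d nonempty)\n",
              x$I, x$J, x$I * x$J, x$nonempty))
  cat(sprintf("fragments: %d (%.2f per lattice point)\n", x$n, x$per_neuron))
  cat(sprintf("final quantization error: %.6g\n", x$qe))
  if (!is.na(x$purity))
    cat(sprintf("lattice purity (single-category nonempty points): %.3f\n",
                x$purity))
  invisible(x)
}

#' Fraction of nonempty lattice points holding a single category
#'
#' @param fit A [blsom()] fit trained with category labels.
#' @return Purity in `[0, 1]`, or `NA` when no labels were supplied.
#' @export
lattice_purity <- function(fit) {
  if (is.null(fit$categories)) return(NA_real_)
  tab <- table(fit$assignment$cell, fit$categories)
  mean(rowSums(tab > 0) == 1L)
}

#' @export
coef.blsom <- function(object, ...) object$weights

#' @export
residuals.blsom <- function(object, ...) object$assignment$dist

#' @export
fitted.blsom <- function(object, ...)
  object$weights[object$assignment$cell, , drop = FALSE]

#' Map new fragments onto a trained map
#'
#' Assigns query composition vectors (built with the *same* k-mer index as
#' the training data) to their nearest lattice weight and predicts a
#' category as the majority label of the training fragments at that lattice
#' point. This is the phylotype-prediction use of a pre-trained map:
#' species-unknown sequences inherit the label of the map territory they
#' land in.
#'
#' Two rules are offered for queries whose best-matching lattice point
#' received no training fragment. Under `rule = "strict"` (the default,
#' matching the map-display convention that empty lattice points stay
#' white) such queries are labelled `"unassigned"`. Under
#' `rule = "occupied"` the best match is searched among occupied lattice
#' points only, so every query inherits the label of its nearest territory
#' — the behavior wanted of a classifier. On densely occupied maps
#' (training sets much larger than the lattice) the two rules coincide;
#' they diverge on sparse maps, where "strict" trades coverage for an
#' explicit rejection signal.
#'
#' @param object A [blsom()] fit.
#' @param newdata Composition matrix or [genome_composition()] with the same
#'   slots as the training data.
#' @param rule `"strict"` or `"occupied"` (see Details).
#' @param ... Unused.
#' @return A data frame with `i`, `j`, `cell`, `dist` and `category` per
#'   query row.
#' @export
predict.blsom <- function(object, newdata, rule = c("strict", "occupied"),
                          ...) {
  rule <- match.arg(rule)
  if (inherits(newdata, "genome_composition")) {
    if (!is.null(object$index) &&
        !identical(newdata$index$slot_kmer, object$index$slot_kmer))
      stop("query k-mer index does not match the training index")
    newdata <- newdata$matrix
  }
  newdata <- composition_values(newdata)
  if (ncol(newdata) != ncol(object$weights))
    stop("query dimensionality does not match the training index")
  occupied <- which(tabulate(object$assignment$cell,
                             nbins = object$I * object$J) > 0L)
  if (rule == "occupied" && length(occupied) > 0L) {
    sub <- assign_bmu(newdata, object$weights[occupied, , drop = FALSE])
    asg <- list(cell = occupied[sub$cell], dist = sub$dist)
  } else {
    asg <- assign_bmu(newdata, object$weights)
  }
  coords <- lattice_coords(object$I, object$J)
  category <- object$cell_category[asg$cell]
  category[is.na(category)] <- "unassigned"
  data.frame(i = coords[asg$cell, "i"], j = coords[asg$cell, "j"],
             cell = asg$cell, dist = asg$dist, category = category,
             stringsAsFactors = FALSE)
}
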