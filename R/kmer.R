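#' Build a (degenerate) k-mer index
#'
#' Constructs the coordinate system used for every composition vector: a
#' mapping from all `4^k` oligonucleotides onto column slots. In `degenerate`
#' mode each oligonucleotide shares a slot with its reverse complement, so the
#' counts of a complementary pair (e.g. `AAAAC` and `GTTTT`) are summed and
#' the representation becomes strand-independent. Only one strand of a genome
#' is deposited in sequence databases, and for genome-signature work the
#' strand is arbitrary, which is why the degenerate form is the default
#' throughout the package ("DegPenta" for k = 5).
#'
#' Slots are ordered lexicographically by their canonical member (the
#' alphabetically smaller oligonucleotide of the pair), which makes the
#' column order of every composition matrix deterministic. For odd `k` no
#' oligonucleotide is its own reverse complement, so there are exactly
#' `4^k / 2` slots (512 for pentanucleotides); for even `k` the
#' self-complementary words (such as `ACGT`) occupy singleton slots.
#'
#' @param k Oligonucleotide length, between 1 and 8.
#' @param degenerate Logical; sum reverse-complement pairs into one slot
#'   (default `TRUE`). With `FALSE` every oligonucleotide keeps its own slot
#'   (`4^k` columns, e.g. 4096 for hexa-, 16384 for heptanucleotides).
#' @return An object of class `"kmer_index"`: a list with elements `k`,
#'   `degenerate`, `n_slots`, `slot_of` (named integer vector over all `4^k`
#'   k-mers), `slot_kmer` (canonical k-mer naming each slot), `members`
#'   (per-slot character vector of 1 or 2 k-mers) and `slot_base` (n_slots x 4
#'   matrix of per-slot positional base content used to derive mononucleotide
#'   composition).
#' @examples
#' idx <- kmer_index(5)
#' idx$n_slots                       # 512
#' idx$slot_of["AAAAC"] == idx$slot_of["GTTTT"]
#' @export
kmer_index <- function(k, degenerate = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 8 || k != round(k))
    stop("'k' must be a single integer between 1 and 8")
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  ## all 4^k k-mers in lexicographic order (first position most significant)
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  kmers <- do.call(paste0, grid)
  letter_mat <- as.matrix(grid)          # n_kmers x k letters

  if (degenerate) {
    rc <- revcomp(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    slot_kmer <- sort(unique(canon))
    slot_of <- match(canon, slot_kmer)
  } else {
    slot_kmer <- kmers
    slot_of <- seq_along(kmers)
  }
  names(slot_of) <- kmers
  n_slots <- length(slot_kmer)
  members <- split(kmers, slot_of)
  names(members) <- slot_kmer

  ## positional base content per slot: each member of a pair carries half
  ## weight, a self-complementary singleton carries full weight; rows sum to 1
  base_counts <- vapply(bases, function(b) rowSums(letter_mat == b),
                        numeric(length(kmers)))
  w <- 1 / (k * vapply(members, length, integer(1L))[slot_of])
  slot_base <- rowsum(base_counts * w, slot_of)
  rownames(slot_base) <- slot_kmer

  structure(list(k = k, degenerate = degenerate, n_slots = n_slots,
                 slot_of = slot_of, slot_kmer = slot_kmer,
                 members = members, slot_base = slot_base),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k = %d, %s, %d slots\n", x$k,
              if (x$degenerate) "degenerate (reverse-complement summed)"
              else "plain", x$n_slots))
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings (case-insensitive; other
#'   letters are complemented to themselves after the standard IUPAC rules do
#'   not apply -- only ACGT input is expected here).
#' @return Character vector of reverse complements, upper case.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

## Replace everything outside A/C/G/T (case-insensitive) by N and upper-case.
## Ambiguity codes (R, Y, W, ...) carry no usable composition signal at the
## fragment scale, so they are pooled with N for counting and filtering.
sanitize_seq <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

#' Count k-mers in sequences
#'
#' Slides a width-`k` window with step 1 over each sequence and tallies
#' occurrences per index slot. Matching is case-insensitive; any window that
#' contains a non-ACGT character (undetermined `N` or an ambiguity code)
#' contributes nothing. In degenerate mode each window increments the shared
#' slot of its k-mer and that k-mer's reverse complement.
#'
#' @param seqs Character vector of sequences (one composition row each).
#' @param index A [kmer_index()].
#' @return An integer matrix with one row per sequence and `index$n_slots`
#'   columns, named by canonical k-mer, plus an attribute `total_windows`
#'   (valid window count per row, equal to the row sums).
#' @examples
#' idx <- kmer_index(5)
#' count_kmers("AAAAC", idx)[, "AAAAC"]   # 1
#' @export
count_kmers <- function(seqs, index) {
  stopifnot(inherits(index, "kmer_index"))
  dss <- Biostrings::DNAStringSet(sanitize_seq(seqs))
  raw <- Biostrings::oligonucleotideFrequency(dss, width = index$k)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L,
                                       dimnames = list(NULL, names(raw)))
  stopifnot(identical(colnames(raw), names(index$slot_of)))
  counts <- t(rowsum(t(raw), index$slot_of))
  colnames(counts) <- index$slot_kmer
  storage.mode(counts) <- "integer"
  attr(counts, "total_windows") <- rowSums(raw)
  counts
}

#' Convert k-mer counts to frequencies
#'
#' Frequencies are normalized per nucleotide of *effective* length, i.e. the
#' fragment length excluding Ns, so that fragments with moderate N content
#' remain comparable to complete ones. Normalizing each row to sum 1 instead
#' is available through `normalize = "total"`.
#'
#' @param counts Count matrix from [count_kmers()] (or a single row vector).
#' @param effective_length Numeric vector of non-N lengths, recycled along
#'   rows; required for `normalize = "effective_length"`.
#' @param normalize `"effective_length"` (default) divides each row by its
#'   effective length; `"total"` divides by the row sum (valid windows).
#' @return Numeric matrix of the same shape as `counts`.
#' @export
to_frequencies <- function(counts, effective_length = NULL,
                           normalize = c("effective_length", "total")) {
  normalize <- match.arg(normalize)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  if (normalize == "effective_length") {
    if (is.null(effective_length))
      stop("'effective_length' is required for per-length normalization")
    if (any(effective_length <= 0))
      stop("'effective_length' must be positive for every fragment")
    div <- effective_length
  } else {
    div <- rowSums(counts)
    if (any(div <= 0))
      stop("cannot normalize rows with zero valid k-mer windows")
  }
  freq <- counts / div
  attr(freq, "total_windows") <- attr(counts, "total_windows")
  freq
}

#' Mononucleotide composition implied by a composition vector
#'
#' Derives base frequencies from the k-mer vector itself (expanding every
#' slot into its member k-mers at equal weight and tallying letters), rather
#' than recounting the underlying sequence. This is what makes the
#' observed/expected diagnostic applicable to lattice weight vectors, which
#' have no underlying sequence. In degenerate mode A and T frequencies are
#' equal by construction, as are C and G.
#'
#' @param v Nonnegative numeric vector over the slots of `index` (counts,
#'   frequencies, or a lattice weight vector).
#' @param index The [kmer_index()] the vector is expressed in.
#' @return Named numeric vector of A, C, G, T frequencies summing to 1.
#' @export
mono_composition <- function(v, index) {
  stopifnot(inherits(index, "kmer_index"), length(v) == index$n_slots)
  v <- pmax(v, 0)
  tot <- sum(v)
  if (tot <= 0) stop("composition undefined for an all-zero vector")
  drop(v %*% index$slot_base) / tot
}

#' Slot frequencies expected from a mononucleotide composition
#'
#' Under an i.i.d. base model the expected frequency of a k-mer is the
#' product of its base frequencies; a degenerate slot's expectation sums over
#' both members of the complementary pair (self-complementary words are
#' counted once). The result is a probability vector over slots (sums to 1);
#' [oe_ratio()] rescales it to the total of the observed vector it divides.
#'
#' @param mono Named or positional frequencies of A, C, G, T summing to 1.
#' @param index A [kmer_index()].
#' @return Numeric vector of expected slot frequencies, named by canonical
#'   k-mer.
#' @export
expected_frequency <- function(mono, index) {
  stopifnot(inherits(index, "kmer_index"), length(mono) == 4L)
  if (abs(sum(mono) - 1) > 1e-6)
    stop("'mono' must sum to 1")
  if (!is.null(names(mono))) mono <- mono[c("A", "C", "G", "T")]
  bases <- c("A", "C", "G", "T")
  kmers <- names(index$slot_of)
  letters_mat <- matrix(unlist(strsplit(kmers, "", fixed = TRUE)),
                        ncol = index$k, byrow = TRUE)
  p <- rep(1, length(kmers))
  for (j in seq_len(index$k)) p <- p * mono[match(letters_mat[, j], bases)]
  exp_slot <- drop(rowsum(p, index$slot_of))
  names(exp_slot) <- index$slot_kmer
  exp_slot
}

#' Observed/expected ratio per slot
#'
#' Elementwise ratio of an observed composition vector to its expectation,
#' after rescaling the expectation to the observed total so the two are on a
#' common scale. A ratio above 1 marks over-representation of that
#' oligonucleotide (pair), below 1 under-representation — e.g. the
#' well-known CpG suppression of vertebrate genomes depresses every
#' CG-containing slot. Slots where both observed and expected are 0 are
#' reported as 1; a positive observation against zero expectation yields
#' `Inf`.
#'
#' @param observed Numeric vector over the slots of `index`.
#' @param expected Expected slot frequencies, e.g. from
#'   [expected_frequency()]; any positive scaling is accepted.
#' @param index The shared [kmer_index()].
#' @return Numeric vector of per-slot ratios.
#' @export
oe_ratio <- function(observed, expected, index) {
  stopifnot(inherits(index, "kmer_index"),
            length(observed) == index$n_slots,
            length(expected) == index$n_slots)
  tot_obs <- sum(observed)
  tot_exp <- sum(expected)
  if (tot_exp > 0 && tot_obs > 0) expected <- expected * (tot_obs / tot_exp)
  ratio <- observed / expected
  ratio[expected == 0 & observed == 0] <- 1
  ratio[expected == 0 & observed > 0] <- Inf
  names(ratio) <- index$slot_kmer
  ratio
}

#' G+C content implied by a composition vector
#'
#' @inheritParams mono_composition
#' @return Fraction of C plus G in `[0, 1]`.
#' @export
gc_content <- function(v, index) {
  mono <- mono_composition(v, index)
  unname(mono["C"] + mono["G"])
}
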