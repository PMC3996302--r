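# Independent brute-force oracles used across the suite. They deliberately
# share no code with the package internals: dictionary tallies, scalar
# loops, and Biostrings where it provides a reference (reverseComplement).

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# reference reverse complement via Biostrings
bs_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# dictionary-based k-mer tally: walk every window, skip any with non-ACGT
naive_count <- function(seq, index) {
  seq <- toupper(seq)
  k <- index$k
  out <- setNames(numeric(index$n_slots), index$slot_kmer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < k) return(out)
  for (p in 1:(length(chars) - k + 1L)) {
    w <- paste(chars[p:(p + k - 1L)], collapse = "")
    if (grepl("[^ACGT]", w)) next
    slot <- index$slot_of[[w]]
    out[slot] <- out[slot] + 1
  }
  out
}

# expand every slot into its member k-mers at equal weight, tally letters
expansion_mono <- function(v, index) {
  tally <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seq_len(index$n_slots)) {
    mem <- index$members[[s]]
    for (m in mem) {
      letters_m <- strsplit(m, "", fixed = TRUE)[[1L]]
      for (b in letters_m) tally[b] <- tally[b] + v[s] / length(mem)
    }
  }
  tally / sum(tally)
}

# product-of-base-frequencies expectation by full enumeration
enum_expected <- function(mono, index) {
  names(mono) <- c("A", "C", "G", "T")
  out <- setNames(numeric(index$n_slots), index$slot_kmer)
  for (w in names(index$slot_of)) {
    p <- prod(mono[strsplit(w, "", fixed = TRUE)[[1L]]])
    out[index$slot_of[[w]]] <- out[index$slot_of[[w]]] + p
  }
  out
}

# all-pairs nearest-weight assignment, scalar loops
brute_assign <- function(x, W) {
  n <- nrow(x)
  cell <- integer(n); dist <- numeric(n)
  for (r in 1:n) {
    d <- apply(W, 1L, function(w) sqrt(sum((x[r, ] - w)^2)))
    cell[r] <- which.min(d)
    dist[r] <- d[cell[r]]
  }
  list(cell = cell, dist = dist)
}

# slot-by-slot batch update oracle: for each lattice point collect the
# fragments whose best match is within Chebyshev radius beta, move toward
# their mean by alpha
brute_update <- function(W, x, cell, alpha, beta, I, J) {
  coords <- cbind(i = rep(0:(I - 1L), each = J), j = rep(0:(J - 1L), I))
  out <- W
  for (c0 in seq_len(I * J)) {
    members <- which(abs(coords[cell, "i"] - coords[c0, "i"]) <= beta &
                     abs(coords[cell, "j"] - coords[c0, "j"]) <= beta)
    if (length(members) == 0L) next
    mu <- colMeans(x[members, , drop = FALSE])
    out[c0, ] <- W[c0, ] + alpha * (mu - W[c0, ])
  }
  out
}

# small trained-map stand-in for layer tests: a blsom object built by hand
fake_fit <- function(W, I, J, cell, categories = NULL, index = NULL) {
  coords <- cbind(i = rep(0:(I - 1L), each = J), j = rep(0:(J - 1L), I))
  cell_category <- rep(NA_character_, I * J)
  if (!is.null(categories)) {
    tab <- table(cell, categories)
    occ <- as.integer(rownames(tab))
    cell_category[occ] <- colnames(tab)[apply(tab, 1L, which.max)]
  }
  structure(list(weights = W, I = I, J = J,
                 assignment = data.frame(fragment = seq_along(cell),
                                         i = coords[cell, "i"],
                                         j = coords[cell, "j"],
                                         cell = cell, dist = 0),
                 categories = categories, cell_category = cell_category,
                 qe = 0, epochs = 1L, alpha = c(0.6, 0.01), beta0 = 1L,
                 per_neuron = 4, index = index, n = length(cell)),
            class = "blsom")
}

# shared small panel -> composition, cached per test run
panel_composition <- local({
  cache <- new.env()
  function(n_species = 3L, divergence = 0.5, length = 3e5, seed = 2L,
           window = 5000L, k = 4L) {
    key <- paste(n_species, divergence, length, seed, window, k, sep = "_")
    if (is.null(cache[[key]])) {
      panel <- species_panel(n_species, divergence, length, seed = seed)
      cache[[key]] <- genome_composition(panel, window = window, k = k)
    }
    cache[[key]]
  }
})
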