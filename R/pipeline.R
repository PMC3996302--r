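#' From sequences to a fragment composition matrix
#'
#' The standard preparation pipeline in one call: read (or accept)
#' sequences, optionally split repeat from unique regions by letter case,
#' cut into fixed windows, apply the N-content filter, count (degenerate)
#' k-mers in the included fragments and normalize to effective length.
#'
#' @param x A FASTA path or a `source_seqs` data frame.
#' @param window Fragment window length, nt (default 100000).
#' @param k Oligonucleotide length (default 5, i.e. DegPenta when
#'   `degenerate = TRUE`).
#' @param degenerate Sum reverse-complement pairs (default `TRUE`).
#' @param max_n_frac N-content exclusion threshold (default 0.20).
#' @param split_repeats Split soft-masked (lower-case) repeat runs from
#'   unique runs and treat the concatenations as separate sources
#'   (default `FALSE`).
#' @param normalize Passed to [to_frequencies()].
#' @return An object of class `"genome_composition"`: list with `manifest`
#'   (fragment table including the `included` flag), `matrix` (frequency
#'   rows for included fragments, named by fragment id), `index`, `window`.
#' @export
genome_composition <- function(x, window = 100000L, k = 5L,
                               degenerate = TRUE, max_n_frac = 0.20,
                               split_repeats = FALSE,
                               normalize = c("effective_length", "total")) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x))
    read_fasta(x) else x
  stopifnot(is.data.frame(seqs))
  if (split_repeats) seqs <- split_by_case(seqs)
  frags <- apply_n_filter(fragment_genome(seqs, window), max_n_frac)
  index <- kmer_index(k, degenerate)
  inc <- frags$included
  mat <- if (any(inc)) {
    counts <- count_kmers(frags$sequence[inc], index)
    rownames(counts) <- frags$fragment_id[inc]
    to_frequencies(counts, frags$effective_length[inc], match.arg(normalize))
  } else matrix(numeric(), 0L, index$n_slots,
                dimnames = list(NULL, index$slot_kmer))
  manifest <- frags[, setdiff(names(frags), "sequence")]
  structure(list(manifest = manifest, matrix = mat, index = index,
                 window = as.integer(window)),
            class = "genome_composition")
}

#' @export
print.genome_composition <- function(x, ...) {
  cat(sprintf(
    "genome composition: %d fragments (%d included), window %d nt, %s k=%d (%d slots)\n",
    nrow(x$manifest), sum(x$manifest$included), x$window,
    if (x$index$degenerate) "degenerate" else "plain", x$index$k,
    x$index$n_slots))
  invisible(x)
}

#' Write a composition matrix as TSV
#'
#' One row per included fragment: the manifest columns followed by one
#' column per slot, headed by the canonical k-mer.
#'
#' @param comp A [genome_composition()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  man <- comp$manifest[comp$manifest$included, , drop = FALSE]
  out <- cbind(man[, c("fragment_id", "source_id", "start", "end",
                       "category", "n_count")],
               as.data.frame(comp$matrix, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fragment-to-lattice assignment as TSV
#'
#' @param fit A [blsom()] fit (or a prediction data frame from
#'   [predict.blsom()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(fit, path) {
  tab <- if (inherits(fit, "blsom")) fit$assignment else fit
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
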