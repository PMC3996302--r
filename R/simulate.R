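#' Specification for a simulated genome
#'
#' Describes a Markov-chain sequence generator. Low-order Markov structure
#' is exactly the kind of compositional signal a genome signature is: a
#' species-specific bias in short oligonucleotide frequencies. The chain
#' order and the per-species perturbation of the transition matrix are the
#' two knobs that make clustering behavior tunable in tests.
#'
#' @param label Category name attached to the generated sequence.
#' @param length Sequence length in nucleotides.
#' @param order Markov order `m >= 0` (0 = i.i.d. bases).
#' @param trans Optional transition matrix, `4^m` rows (contexts in
#'   lexicographic order; 1 row for order 0) by 4 columns (A, C, G, T), each
#'   row summing to 1. Defaults to rows implied by `gc_target` (uniform when
#'   that is `NULL`).
#' @param gc_target Optional stationary G+C fraction used to build default
#'   transition rows (A and T share `1 - gc`, C and G share `gc`).
#' @param cg_suppression Optional factor in `[0, 1]` multiplying the
#'   probability of G following C (then renormalizing), mimicking the CpG
#'   suppression of vertebrate genomes; 0 removes CG dinucleotides entirely.
#'   Requires (or promotes the spec to) order >= 1.
#' @param soft_mask_fraction Fraction of the sequence to lower-case in
#'   random runs (repeat-masking emulation), default 0.
#' @param n_fraction Fraction to replace by `N` in random runs, default 0.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `"genome_spec"`.
#' @export
genome_spec <- function(label, length, order = 0L, trans = NULL,
                        gc_target = NULL, cg_suppression = NULL,
                        soft_mask_fraction = 0, n_fraction = 0, seed = 1L) {
  if (length < 1) stop("'length' must be positive")
  if (order < 0 || order != round(order)) stop("'order' must be >= 0")
  order <- as.integer(order)
  if (!is.null(cg_suppression) && order == 0L) order <- 1L
  if (is.null(trans)) {
    gc <- if (is.null(gc_target)) 0.5 else gc_target
    row <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    trans <- matrix(row, nrow = 4^order, ncol = 4L, byrow = TRUE)
    colnames(trans) <- names(row)
  }
  if (nrow(trans) != 4^order || ncol(trans) != 4L)
    stop("'trans' must be a 4^order x 4 matrix")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("each transition row must be a probability vector summing to 1")
  if (!is.null(cg_suppression)) {
    if (cg_suppression < 0 || cg_suppression > 1)
      stop("'cg_suppression' must be in [0, 1]")
    ## contexts ending in C are those with (ctx-1) %% 4 == 1 (A,C,G,T order)
    endC <- which((seq_len(4^order) - 1L) %% 4L == 1L)
    trans[endC, 3L] <- trans[endC, 3L] * cg_suppression
    trans[endC, ] <- trans[endC, ] / rowSums(trans[endC, , drop = FALSE])
  }
  if (soft_mask_fraction < 0 || n_fraction < 0 ||
      soft_mask_fraction + n_fraction > 1)
    stop("mask and N fractions must be nonnegative and sum to at most 1")
  structure(list(label = label, length = as.integer(length), order = order,
                 trans = trans, soft_mask_fraction = soft_mask_fraction,
                 n_fraction = n_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

## run `expr` under a local RNG stream; the caller's .Random.seed survives
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a genome sequence from a spec
#'
#' Samples a sequence from the Markov chain of a [genome_spec()], then
#' applies soft-masking and N injection if requested. Deterministic given
#' the spec (including its seed).
#'
#' @param spec A [genome_spec()].
#' @return A one-row `source_seqs` data frame (`id`, `category`,
#'   `sequence`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  bases <- c("A", "C", "G", "T")
  seq_chars <- with_seed(spec$seed, {
    n <- spec$length
    m <- spec$order
    if (m == 0L) {
      out <- sample.int(4L, n, replace = TRUE, prob = spec$trans[1L, ])
    } else {
      ## cumulative rows + one runif draw per position; context id is the
      ## base-4 encoding of the previous m bases (A=0 .. T=3), 1-based
      cum <- t(apply(spec$trans, 1L, cumsum))
      c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
      out <- integer(n)
      u <- stats::runif(n)
      ## burn-in start context drawn uniformly
      ctx_digits <- sample.int(4L, m, replace = TRUE) - 1L
      ctx <- sum(ctx_digits * 4L^((m - 1L):0)) + 1L
      pow <- 4L^(m - 1L)
      for (t in seq_len(n)) {
        ut <- u[t]
        b <- 1L + (ut > c1[ctx]) + (ut > c2[ctx]) + (ut > c3[ctx])
        out[t] <- b
        ctx <- (ctx - 1L) %% pow * 4L + b       # shift context left, append b
      }
      out
    }
    s <- bases[out]
    if (spec$n_fraction > 0)
      s <- replace_runs(s, spec$n_fraction, function(x) rep("N", length(x)))
    if (spec$soft_mask_fraction > 0)
      s <- replace_runs(s, spec$soft_mask_fraction / (1 - spec$n_fraction),
                        tolower, skip = s == "N")
    s
  })
  res <- data.frame(id = spec$label, category = spec$label,
                    sequence = paste(seq_chars, collapse = ""),
                    stringsAsFactors = FALSE)
  class(res) <- c("source_seqs", "data.frame")
  res
}

## overwrite random runs (mean length 300) covering `fraction` of the
## not-skipped positions with f(run); exact to the nearest position
replace_runs <- function(s, fraction, f, skip = NULL) {
  eligible <- if (is.null(skip)) seq_along(s) else which(!skip)
  target <- round(fraction * length(eligible))
  if (target <= 0) return(s)
  done <- 0L
  guard <- 0L
  while (done < target && guard < 1e6) {
    guard <- guard + 1L
    start <- eligible[sample.int(length(eligible), 1L)]
    len <- min(stats::rgeom(1L, 1 / 300) + 1L, target - done)
    run <- start:min(start + len - 1L, length(s))
    if (!is.null(skip)) run <- run[!skip[run]]
    run <- run[s[run] %in% c("A", "C", "G", "T")]  # do not re-mask
    if (length(run) == 0L) next
    s[run] <- f(s[run])
    done <- done + length(run)
    if (is.null(skip)) eligible <- which(s %in% c("A", "C", "G", "T"))
  }
  s
}

#' Inject soft-masking and Ns into a sequence
#'
#' Test support for the N-filter and case-splitting steps: lower-cases
#' random runs and replaces random runs by `N` to hit the requested
#' fractions (to within rounding of the sequence length).
#'
#' @param seqs A `source_seqs` data frame (each row treated independently).
#' @param soft_mask_fraction,n_fraction Fractions in `[0, 1]`, summing to at
#'   most 1.
#' @param seed Integer seed.
#' @return The data frame with modified sequences.
#' @export
inject_mask_and_ns <- function(seqs, soft_mask_fraction = 0, n_fraction = 0,
                               seed = 1L) {
  if (soft_mask_fraction + n_fraction > 1)
    stop("mask and N fractions must sum to at most 1")
  if (soft_mask_fraction == 0 && n_fraction == 0) return(seqs)
  seqs$sequence <- vapply(seq_len(nrow(seqs)), function(r)
    with_seed(seed + r, {
      s <- strsplit(seqs$sequence[r], "", fixed = TRUE)[[1L]]
      if (n_fraction > 0)
        s <- replace_runs(s, n_fraction, function(x) rep("N", length(x)))
      if (soft_mask_fraction > 0)
        s <- replace_runs(s, soft_mask_fraction / (1 - n_fraction),
                          tolower, skip = s == "N")
      paste(s, collapse = "")
    }), character(1L))
  seqs
}

#' Simulate a panel of related species genomes
#'
#' Builds `n_species` order-1 Markov genomes sharing one base transition
#' matrix, each species' matrix perturbed multiplicatively by
#' `exp(divergence * z)` with independent standard-normal `z` per entry
#' (rows renormalized). At `divergence = 0` all species are statistically
#' identical; as divergence grows the species' oligonucleotide signatures
#' separate and a trained map partitions them into clean territories.
#'
#' @param n_species Number of species (>= 2).
#' @param divergence Perturbation magnitude in `[0, 1]`.
#' @param length Genome length per species, nt.
#' @param seed Integer seed driving both perturbation and sequence sampling.
#' @param gc_target Base G+C fraction of the shared matrix (default 0.5).
#' @param labels Optional category names (default `sp1`, `sp2`, ...).
#' @return A `source_seqs` data frame with one record per species.
#' @export
species_panel <- function(n_species, divergence, length, seed = 1L,
                          gc_target = 0.5, labels = NULL) {
  if (n_species < 2L) stop("'n_species' must be at least 2")
  if (divergence < 0 || divergence > 1)
    stop("'divergence' must be in [0, 1]")
  if (is.null(labels)) labels <- paste0("sp", seq_len(n_species))
  base_row <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
                (1 - gc_target) / 2)
  base <- matrix(base_row, nrow = 4L, ncol = 4L, byrow = TRUE)
  panels <- lapply(seq_len(n_species), function(s) {
    trans <- with_seed(seed * 1000L + s, {
      pert <- base * exp(divergence * matrix(stats::rnorm(16L), 4L, 4L))
      pert / rowSums(pert)
    })
    generate_genome(genome_spec(labels[s], length, order = 1L,
                                trans = trans, seed = seed * 1000L + 500L + s))
  })
  res <- do.call(rbind, panels)
  class(res) <- c("source_seqs", "data.frame")
  res
}
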