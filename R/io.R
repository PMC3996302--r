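#' Persist a trained map as plain-text files
#'
#' Writes a trained map into a directory as text: `weights.tsv` (one row
#' per lattice point, row-major, one column per slot), `assignment.tsv`,
#' and `map.json` (lattice dimensions, k-mer index parameters, training
#' hyperparameters, PCA frame and per-lattice majority categories). A map
#' restored with [read_blsom()] assigns queries identically to the
#' original.
#'
#' @param fit A [blsom()] fit.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_blsom <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$weights, file.path(dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = colnames(fit$weights))
  write_assignment_tsv(fit, file.path(dir, "assignment.tsv"))
  meta <- list(I = fit$I, J = fit$J, epochs = fit$epochs, alpha = fit$alpha,
               beta0 = fit$beta0, per_neuron = fit$per_neuron, n = fit$n,
               qe = fit$qe, cell_category = fit$cell_category,
               categories = fit$categories,
               pca = fit$pca[c("x_av", "b1", "b2", "sigma1", "sigma2")],
               index = if (!is.null(fit$index))
                 list(k = fit$index$k, degenerate = fit$index$degenerate))
  writeLines(to_json(meta), file.path(dir, "map.json"))
  invisible(dir)
}

#' Restore a map written by [write_blsom()]
#'
#' @param dir Directory containing `weights.tsv` and `map.json`.
#' @return An object of class `"blsom"`.
#' @export
read_blsom <- function(dir) {
  meta <- parse_json(paste(readLines(file.path(dir, "map.json")),
                           collapse = "\n"))
  W <- as.matrix(utils::read.table(file.path(dir, "weights.tsv"),
                                   sep = "\t", header = TRUE,
                                   check.names = FALSE))
  assignment <- utils::read.table(file.path(dir, "assignment.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  pca <- meta$pca
  class(pca) <- "blsom_pca"
  index <- if (!is.null(meta$index))
    kmer_index(meta$index$k, meta$index$degenerate)
  cell_category <- as.character(meta$cell_category)
  cell_category[cell_category == "NA"] <- NA_character_
  structure(list(weights = W, I = meta$I, J = meta$J, pca = pca,
                 assignment = assignment,
                 categories = if (!is.null(meta$categories))
                   as.character(meta$categories),
                 cell_category = cell_category, qe = as.numeric(meta$qe),
                 epochs = meta$epochs, alpha = as.numeric(meta$alpha),
                 beta0 = meta$beta0, per_neuron = meta$per_neuron,
                 index = index, n = meta$n),
            class = "blsom")
}

## JSON sidecar: numbers at full precision so a restored map assigns
## queries identically
to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "string")
}

parse_json <- function(txt) {
  jsonlite::fromJSON(txt)
}
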