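#' Gray levels for a U-matrix layer
#'
#' Linear min-max mapping of values to gray: the larger the neighbor
#' distance, the darker the point, so territory borders and peculiar zones
#' come out black.
#'
#' @param values Numeric vector or matrix of U-matrix values.
#' @return Character vector/matrix of colors (`"#rrggbb"`).
#' @export
umatrix_gray <- function(values) {
  v <- as.vector(values)
  rng <- range(v, finite = TRUE)
  t <- if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1L]) / diff(rng)
  col <- grDevices::gray(1 - t)
  if (is.matrix(values)) col <- matrix(col, nrow(values), ncol(values))
  col
}

#' Diverging colors for an observed/expected layer
#'
#' Symmetric red/white/blue coding on the log2 ratio: over-represented
#' (log2 ratio at or above `cutoff_log2`) grades to red, under-represented
#' to blue, and moderate values stay white. Infinite ratios (observed > 0
#' against zero expectation) are clipped to the deepest red.
#'
#' @param ratios Numeric vector or matrix of observed/expected ratios.
#' @param cutoff_log2 Absolute log2 ratio treated as saturated (default
#'   0.263, i.e. a ratio of about 1.2).
#' @return Character vector/matrix of colors.
#' @export
oe_colors <- function(ratios, cutoff_log2 = 0.263) {
  l2 <- log2(pmax(as.vector(ratios), 0))
  l2[!is.finite(l2) & as.vector(ratios) > 1] <- cutoff_log2
  l2[!is.finite(l2)] <- -cutoff_log2
  t <- pmax(-1, pmin(1, l2 / cutoff_log2))       # -1 blue .. 0 white .. 1 red
  ramp <- grDevices::colorRamp(c("#2166ac", "#ffffff", "#b2182b"))
  col <- grDevices::rgb(ramp((t + 1) / 2), maxColorValue = 255)
  if (is.matrix(ratios)) col <- matrix(col, nrow(ratios), ncol(ratios))
  col
}

#' Colors for a category layer
#'
#' Empty lattice points are white, multi-category points black, and each
#' category gets a distinct hue.
#'
#' @param layer Character matrix from [category_layer()].
#' @return Character matrix of colors, with a `"palette"` attribute naming
#'   the category colors.
#' @export
category_colors <- function(layer) {
  cats <- sort(setdiff(unique(as.vector(layer)), c("empty", "multi")))
  pal <- grDevices::hcl.colors(max(length(cats), 2L), "Dark 3")[seq_along(cats)]
  names(pal) <- cats
  lookup <- c(empty = "#ffffff", multi = "#000000", pal)
  col <- matrix(lookup[as.vector(layer)], nrow(layer), ncol(layer))
  attr(col, "palette") <- pal
  col
}

draw_layer <- function(col, main = "") {
  I <- nrow(col); J <- ncol(col)
  graphics::plot(NA, xlim = c(0, I), ylim = c(0, J), asp = 1, axes = FALSE,
                 xlab = "i", ylab = "j", main = main)
  graphics::rect(rep(0:(I - 1L), J), rep(0:(J - 1L), each = I),
                 rep(1:I, J), rep(1:J, each = I),
                 col = as.vector(col), border = NA)
}

#' Plot a trained map layer
#'
#' @param x A [blsom()] fit.
#' @param type One of `"category"`, `"umatrix"`, `"gc"`, `"oe"`, `"zones"`.
#' @param kmer Oligonucleotide for `type = "oe"`.
#' @param n_bins Equal-count bins for `type = "gc"` (default 21).
#' @param ... Unused.
#' @return The plotted layer, invisibly.
#' @export
plot.blsom <- function(x, type = c("category", "umatrix", "gc", "oe",
                                   "zones"), kmer = NULL, n_bins = 21L, ...) {
  type <- match.arg(type)
  layer <- switch(type,
    category = category_layer(x),
    umatrix = umatrix(x),
    gc = gc_layer(x),
    oe = {
      if (is.null(kmer)) stop("'kmer' is required for an o/e layer")
      oe_layer(x, kmer)
    },
    zones = detect_sz_zones(x)$labels)
  col <- switch(type,
    category = category_colors(layer),
    umatrix = umatrix_gray(layer),
    gc = {
      n_bins <- min(n_bins, length(layer))   # tiny lattices: fewer bins
      bins <- gc_quantile_bins(layer, n_bins)
      ramp <- grDevices::colorRamp(c("#1a9850", "#ffffff", "#7f1734"))
      pal <- grDevices::rgb(ramp((seq_len(n_bins) - 1) / (n_bins - 1)),
                            maxColorValue = 255)
      matrix(pal[as.vector(bins)], nrow(bins), ncol(bins))
    },
    oe = oe_colors(layer),
    zones = {
      ids <- max(layer)
      pal <- c("#ffffff", grDevices::hcl.colors(max(ids, 2L), "Set 2"))
      matrix(pal[as.vector(layer) + 1L], nrow(layer), ncol(layer))
    })
  main <- if (type == "oe") paste0("o/e ", toupper(kmer)) else type
  draw_layer(col, main = main)
  invisible(layer)
}

#' Render map layers to PNG files
#'
#' Writes one PNG per requested layer into `dir`, following the standard
#' conventions: black multi-category points, white empty points, grayscale
#' U-matrix, green-white-wine-red G+C bins, red/white/blue o/e ratios.
#'
#' @param fit A [blsom()] fit.
#' @param dir Output directory (created if missing).
#' @param types Layers to render (default all applicable).
#' @param kmers Oligonucleotides for o/e layers (one PNG each).
#' @param width,height Device size in pixels.
#' @return Character vector of files written, invisibly.
#' @export
render_layers <- function(fit, dir, types = c("category", "umatrix", "gc",
                                              "zones"),
                          kmers = NULL, width = 800, height = 600) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fit$categories)) types <- setdiff(types, "category")
  if (is.null(fit$index)) types <- setdiff(types, "gc")
  files <- character(0)
  for (ty in types) {
    f <- file.path(dir, paste0(ty, ".png"))
    grDevices::png(f, width = width, height = height)
    plot(fit, type = ty)
    grDevices::dev.off()
    files <- c(files, f)
  }
  for (km in kmers) {
    f <- file.path(dir, paste0("oe_", toupper(km), ".png"))
    grDevices::png(f, width = width, height = height)
    plot(fit, type = "oe", kmer = km)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

#' Export a lattice layer as TSV
#'
#' Writes an `I` x `J` layer as a tab-separated grid (rows = first lattice
#' dimension `i`, columns = second dimension `j`).
#'
#' @param layer Matrix from [umatrix()], [oe_layer()], [gc_layer()], ...
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layer_tsv <- function(layer, path) {
  utils::write.table(layer, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
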