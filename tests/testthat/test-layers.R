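test_that("the U-matrix measures neighbor distances with edge handling", {
  I <- 4L; J <- 5L
  # identical weights everywhere: all zeros
  W0 <- matrix(1, I * J, 3L)
  expect_true(all(umatrix(W0, I = I, J = J) == 0))

  # two-block map: left columns at u, right columns at v; the boundary
  # columns see the other block, interior columns do not
  u <- c(0, 0, 0); v <- c(3, 0, 0)
  blocks <- t(vapply(seq_len(I * J) - 1L, function(c0) {
    j <- c0 %% J
    if (j <= 1L) u else v
  }, numeric(3L)))
  um <- umatrix(blocks, I = I, J = J)
  expect_true(all(um[, c(2L, 3L)] > 0))        # boundary columns j=1, j=2
  expect_true(all(um[, c(1L, 4L, 5L)] == 0))   # interior columns
  # closed form: an interior boundary point has 6 existing cross-block pairs
  # out of 8 neighbors at distance 3 -> wait, only the 3 across the border
  expect_equal(um[2L, 2L], 3 * 3 / 8)

  # translation invariance and mirror symmetry
  um2 <- umatrix(blocks + 7, I = I, J = J)
  expect_equal(um2, um)
  mirror <- blocks[as.vector(t(matrix(seq_len(I * J), I, J, byrow = TRUE)[
    I:1, ])), ]
  expect_equal(umatrix(mirror, I = I, J = J), um[I:1, ])

  # 4-neighbor variant only sees the direct cross-border step
  um4 <- umatrix(blocks, I = I, J = J, neighbors = 4L)
  expect_equal(um4[2L, 2L], 3 / 4)
})

test_that("category coloring is the exact three-way convention", {
  W <- matrix(0, 6L, 2L)   # 3 x 2 lattice
  fit <- fake_fit(W, 3L, 2L, cell = c(1L, 1L, 2L, 2L, 4L),
                  categories = c("human", "human", "human", "mouse",
                                 "mouse"))
  layer <- category_layer(fit)
  expect_equal(layer[1L, 1L], "human")     # only human fragments
  expect_equal(layer[1L, 2L], "multi")     # human + mouse
  expect_equal(layer[2L, 2L], "mouse")
  expect_equal(layer[2L, 1L], "empty")     # nothing assigned
  # the three classes partition the lattice
  expect_equal(sum(layer %in% c("empty", "multi") |
                     layer %in% c("human", "mouse")), 6L)
})

test_that("equal-count binning is exact, tie-stable and matches a sort oracle", {
  expect_equal(unname(table(gc_quantile_bins(runif(42), 21L))),
               rep(2L, 21L), ignore_attr = TRUE)
  # constant values: ties broken by position, counts still equal
  bins_const <- gc_quantile_bins(rep(0.5, 42), 21L)
  expect_equal(unname(table(bins_const)), rep(2L, 21L), ignore_attr = TRUE)
  expect_equal(bins_const[1:4], c(1L, 1L, 2L, 2L))

  set.seed(41)
  v <- runif(100)
  bins <- gc_quantile_bins(v, 21L)
  # counts differ by at most one
  expect_lte(diff(range(table(bins))), 1L)
  # sort-based oracle: the b-th bin holds the b-th slice of the sorted values
  sizes <- rep(100L %/% 21L, 21L) + (seq_len(21L) <= 100L %% 21L)
  slices <- rep(seq_len(21L), sizes)
  expect_equal(bins[order(v)], slices)
  expect_error(gc_quantile_bins(runif(10), 21L), "fewer lattice points")
})

test_that("o/e layers read preference independent of mononucleotide content", {
  idx <- kmer_index(3)
  # a lattice whose weights equal their own expectation shows ratio 1
  mono <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  w_exp <- expected_frequency(mono, idx)
  W <- matrix(w_exp, 4L, idx$n_slots, byrow = TRUE)
  fit <- fake_fit(W, 2L, 2L, cell = c(1L, 2L, 3L, 4L), index = idx)
  layer <- oe_layer(fit, "AAC")
  expect_equal(unname(as.vector(layer)), rep(1, 4L))
  # either member of the pair names the same layer
  expect_equal(oe_layer(fit, "GTT"), layer)
  expect_error(oe_layer(fit, "AAAAA"), "unknown k-mer")

  # per-lattice oracle: expansion + enumeration at every lattice point
  set.seed(42)
  W2 <- matrix(runif(4L * idx$n_slots), 4L)
  fit2 <- fake_fit(W2, 2L, 2L, cell = c(1L, 2L, 3L, 4L), index = idx)
  slot <- idx$slot_of[["AAC"]]
  want <- apply(W2, 1L, function(w) {
    e <- enum_expected(expansion_mono(w, idx), idx)
    (w / sum(w))[slot] / (e / sum(e))[slot]
  })
  expect_equal(as.vector(t(oe_layer(fit2, "AAC"))), unname(want))
})

test_that("specific zones are flagged by darkness or enclosure", {
  # flat fully-occupied map: no zones at all
  W <- matrix(0, 25L, 2L)
  fit <- fake_fit(W, 5L, 5L, cell = 1:25, categories = rep("a", 25L))
  sz <- detect_sz_zones(fit)
  expect_equal(nrow(sz$zones), 0L)
  expect_true(all(sz$labels == 0L))

  # a 2 x 2 occupied island surrounded by empty points is one zone even
  # with a flat U-matrix (enclosure rule)
  cells_island <- c(7L, 8L, 12L, 13L)   # (i,j) = (1,1),(1,2),(2,1),(2,2)
  fit2 <- fake_fit(W, 5L, 5L, cell = cells_island,
                   categories = rep("a", 4L))
  sz2 <- detect_sz_zones(fit2)
  expect_equal(nrow(sz2$zones), 1L)
  expect_equal(sort(which(as.vector(t(sz2$labels)) == 1L)), cells_island)

  # zones smaller than min_size are discarded
  fit3 <- fake_fit(W, 5L, 5L, cell = 7L, categories = "a")
  expect_equal(nrow(detect_sz_zones(fit3, min_size = 2L)$zones), 0L)
})

test_that("an injected extreme minority genome is recovered as a zone", {
  set.seed(43)
  major <- species_panel(2L, divergence = 0.3, length = 4e5, seed = 44L)
  minor <- generate_genome(genome_spec("minor", 2e4, order = 1L,
                                       gc_target = 0.9, seed = 45L))
  comp <- genome_composition(rbind(major, minor), window = 5000L, k = 4L)
  labs <- comp$manifest$category[comp$manifest$included]
  fit <- blsom(comp, epochs = 60)
  sz <- detect_sz_zones(fit)
  minor_cells <- unique(fit$assignment$cell[labs == "minor"])
  flagged <- which(as.vector(t(sz$labels)) > 0L)
  expect_gte(mean(minor_cells %in% flagged), 0.9)
})

test_that("layer color mappings follow the stated conventions", {
  # gray level is monotone: larger U-matrix value, darker pixel
  set.seed(46)
  v <- runif(30)
  cols <- umatrix_gray(v)
  lum <- colMeans(grDevices::col2rgb(cols))
  expect_equal(order(lum), order(-v))
  # o/e colors: infinities clip to the deepest red; ratio 1 is white
  oc <- oe_colors(c(1, Inf, 2, 0.2))
  expect_equal(oc[1L], "#FFFFFF")
  expect_equal(oc[2L], oe_colors(100))
  rgb2 <- grDevices::col2rgb(oc)
  expect_gt(rgb2["red", 3L], rgb2["blue", 3L])    # over-represented: red
  expect_lt(rgb2["red", 4L], rgb2["blue", 4L])    # under-represented: blue
  # category palette: empty white, multi black
  cc <- category_colors(matrix(c("empty", "multi", "a", "b"), 2L))
  expect_equal(cc[1L, 1L], "#ffffff")
  expect_equal(cc[2L, 1L], "#000000")
})

test_that("rendering writes one PNG per layer, including degenerate maps", {
  comp <- panel_composition(n_species = 2L, length = 2e5, seed = 31L)
  fit <- blsom(comp, epochs = 20)
  dir <- tempfile()
  files <- render_layers(fit, dir, kmers = "AACC")
  expect_true(all(file.exists(file.path(dir, c("category.png", "umatrix.png",
                                               "gc.png", "zones.png",
                                               "oe_AACC.png")))))
  # 1 x 1 lattice renders without error
  f1 <- fake_fit(matrix(1, 1L, 3L), 1L, 1L, cell = 1L, categories = "a")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(f1, type = "umatrix"); grDevices::dev.off()
  expect_true(file.exists(tf))
  # TSV export round-trips a layer grid
  um <- umatrix(fit)
  tsv <- tempfile(fileext = ".tsv")
  write_layer_tsv(um, tsv)
  expect_equal(as.matrix(read.delim(tsv, header = FALSE)), um,
               ignore_attr = TRUE)
})
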