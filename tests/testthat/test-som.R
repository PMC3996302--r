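test_that("the PCA frame captures the widest spread of the input cloud", {
  set.seed(21)
  n <- 10000
  x <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1), rnorm(n, sd = 0.2))
  frame <- fit_pca(x)
  expect_equal(sqrt(sum(frame$b1^2)), 1)
  expect_equal(sum(frame$b1 * frame$b2), 0, tolerance = 1e-12)
  expect_gte(frame$sigma1, frame$sigma2)
  # definitional identity: sd of projections onto b1 equals sigma1
  proj <- sweep(x, 2L, frame$x_av) %*% frame$b1
  expect_equal(sd(proj), frame$sigma1)

  # isotropic cloud: the two sigmas agree within sampling tolerance
  xi <- matrix(rnorm(2 * n), ncol = 2L)
  fi <- fit_pca(xi)
  expect_equal(fi$sigma1 / fi$sigma2, 1, tolerance = 0.05)

  expect_error(fit_pca(x[1:2, ]), "at least 3")
})

test_that("rank-deficient inputs degrade gracefully", {
  # data on a line: sigma2 = 0 and the sizing rule collapses J to 1
  line <- outer(seq_len(40), c(1, 2, 3))
  frame <- fit_pca(line)
  expect_equal(frame$sigma2, 0)
  expect_warning(sz <- size_map(40, frame), "second map dimension")
  expect_equal(unname(sz[2L]), 1L)
  # one vector repeated: trains onto a degenerate 2 x 1 lattice
  rep1 <- matrix(1, 12, 4) + 0.0
  expect_warning(fit <- blsom(rep1, epochs = 3), "no variance")
  expect_true(all(fit$assignment$cell == fit$assignment$cell[1L]))
  expect_equal(fit$qe[fit$epochs], 0)
})

test_that("map sizing follows the aspect-ratio and occupancy rules", {
  frame <- list(sigma1 = 1, sigma2 = 0.5)
  sz <- size_map(1000, frame)
  expect_equal(unname(sz), c(22L, 12L))   # strictly-greater rule: 11 -> 12
  expect_equal(round(1000 / prod(sz)), 4)

  # near-square data yield a near-square map
  szq <- size_map(16 * 4, list(sigma1 = 1, sigma2 = 1))
  expect_equal(unname(szq[1L]), unname(szq[2L]) - 1L)  # J strictly exceeds I*rho
  expect_error(size_map(2, frame), "fewer fragments")
})

test_that("initial weights tile the principal plane five sigma1 wide", {
  set.seed(22)
  x <- matrix(rnorm(300), ncol = 3L) %*% diag(c(3, 1, 0.3))
  frame <- fit_pca(x)
  I <- 10L; J <- 6L
  W <- pca_init(frame, I, J)
  step <- 5 * frame$sigma1 / I
  expect_equal(step * I / frame$sigma1, 5)
  # at i = I/2, j = J/2 the weight is exactly the mean vector
  expect_identical(W[(I / 2) * J + J / 2 + 1L, ], frame$x_av)
  # planarity: residual after projecting (w - x_av) onto the b1/b2 plane is 0
  resid <- sweep(W, 2L, frame$x_av)
  resid <- resid - drop(resid %*% frame$b1) %o% frame$b1 -
    drop(resid %*% frame$b2) %o% frame$b2
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("assignment is the brute-force nearest weight with row-major ties", {
  set.seed(23)
  W <- matrix(rnorm(5 * 4 * 6), nrow = 20L)   # 5 x 4 lattice, 6 slots
  x <- matrix(rnorm(20 * 6), nrow = 20L)
  got <- assign_bmu(x, W)
  want <- brute_assign(x, W)
  expect_equal(got$cell, want$cell)
  expect_equal(got$dist, want$dist)
  # a vector equal to some weight lands on it with distance 0
  expect_equal(assign_bmu(W[7L, , drop = FALSE], W)$cell, 7L)
  # exact two-way tie goes to the earlier row-major lattice point
  W2 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(assign_bmu(matrix(c(0, 5), 1L), W2)$cell, 1L)
})

test_that("the batch update matches a scalar-loop oracle and its closed forms", {
  set.seed(24)
  I <- 3L; J <- 3L
  W <- matrix(rnorm(9 * 4), nrow = 9L)
  x <- matrix(rnorm(5 * 4), nrow = 5L)
  cell <- assign_bmu(x, W)$cell
  expect_equal(batch_update(W, x, cell, alpha = 0.5, beta = 1L, I, J),
               brute_update(W, x, cell, 0.5, 1L, I, J))

  # alpha = 0 leaves weights unchanged
  expect_equal(batch_update(W, x, cell, 0, 1L, I, J), W)

  # full contraction: alpha = 1 with an all-covering neighborhood maps every
  # weight to the overall data centroid
  up <- batch_update(W, x, cell, 1, beta = 3L, I, J)
  expect_equal(up, matrix(colMeans(x), 9L, 4L, byrow = TRUE))

  # identical data: every reached weight becomes that vector exactly
  v <- c(1, 2, 3, 4)
  xv <- matrix(v, 6L, 4L, byrow = TRUE)
  cellv <- assign_bmu(xv, W)$cell
  upv <- batch_update(W, xv, cellv, 1, beta = 3L, I, J)
  expect_equal(upv, matrix(v, 9L, 4L, byrow = TRUE))
})

test_that("training is exactly invariant under input row permutation", {
  comp <- panel_composition(n_species = 2L, length = 2e5, seed = 31L)
  x <- comp$matrix
  labs <- comp$manifest$category[comp$manifest$included]
  fit1 <- blsom(x, categories = labs, epochs = 40)
  set.seed(32); perm <- sample.int(nrow(x))
  fit2 <- blsom(x[perm, , drop = FALSE], categories = labs[perm],
                epochs = 40)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$qe, fit2$qe)
  # fragment-to-lattice mapping agrees after undoing the permutation
  expect_identical(fit1$assignment$cell, fit2$assignment$cell[order(perm)])
})

test_that("quantization error stabilizes over the late epochs", {
  comp <- panel_composition(n_species = 2L, length = 2e5, seed = 31L)
  fit <- blsom(comp, epochs = 60)
  qe <- tail(fit$qe, 10)
  expect_true(all(diff(qe) <= qe[-length(qe)] * 1e-9))
  # no fragment has a strictly closer weight than its assigned one
  d2 <- as.matrix(dist(rbind(comp$matrix, fit$weights)))
  n <- nrow(comp$matrix)
  dmin <- apply(d2[seq_len(n), -seq_len(n), drop = FALSE], 1L, min)
  expect_equal(unname(dmin), fit$assignment$dist)
})

test_that("queries inherit the territory of the training fragments", {
  comp <- panel_composition(n_species = 3L, seed = 2L)
  labs <- comp$manifest$category[comp$manifest$included]
  fit <- blsom(comp, epochs = 60)
  # training fragments map back to their own lattice point and category
  pred <- predict(fit, comp)
  expect_equal(pred$cell, fit$assignment$cell)
  agree <- pred$category == labs
  expect_gte(mean(agree[pred$category != "unassigned"]), 0.95)
  # a query sitting exactly on an empty lattice point is unassigned
  occ <- tabulate(fit$assignment$cell, nbins = fit$I * fit$J)
  empty <- which(occ == 0L)[1L]
  expect_false(is.na(empty))
  pe <- predict(fit, fit$weights[empty, , drop = FALSE])
  expect_equal(pe$category, "unassigned")
  # the classifier rule instead resolves to the nearest occupied territory
  po <- predict(fit, fit$weights[empty, , drop = FALSE], rule = "occupied")
  expect_true(po$category %in% labs)
  expect_gt(tabulate(fit$assignment$cell, nbins = fit$I * fit$J)[po$cell], 0L)
  expect_error(predict(fit, comp$matrix[, 1:10]), "dimensionality")
})

test_that("a persisted map restores to an equivalent predictor", {
  comp <- panel_composition(n_species = 2L, length = 2e5, seed = 31L)
  fit <- blsom(comp, epochs = 20)
  dir <- tempfile()
  write_blsom(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.tsv", "map.json",
                                               "assignment.tsv")))))
  back <- read_blsom(dir)
  expect_equal(back$weights, fit$weights, ignore_attr = TRUE,
               tolerance = 1e-12)
  p1 <- predict(fit, comp)
  p2 <- predict(back, comp)
  expect_equal(p1$cell, p2$cell)
  expect_equal(p1$category, p2$category)
})
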