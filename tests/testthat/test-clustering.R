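# Normalization, dimension selection, SNN clustering, cluster profiles and
# layer naming.

test_that("normalization centres, scales, clips and drops empty bins", {
  counts <- cbind(A = c(0L, 7L, NA, NA), B = c(3L, 3L, 3L, NA))
  pc <- make_pc(counts, n_cols = 2)
  expect_message(
    expect_warning(norm <- normalize_counts(pc), "zero-variance"),
    "dropped"
  )
  expect_identical(norm$kept, 1:3) # row 4 missing everywhere
  # hand-computed: A = log1p(c(0, 7, 0)) centred/scaled; B constant -> zeros
  a <- log1p(c(0, 7, 0))
  expect_equal(unname(norm$values[, "A"]), (a - mean(a)) / sd(a), tolerance = 1e-12)
  expect_true(all(norm$values[, "B"] == 0))
  expect_true(all(abs(norm$values) <= 10))
})

test_that("dimension selection counts components above unit SD, floored at 2", {
  # build a matrix with exactly known singular spectrum
  set.seed(4)
  n <- 200
  q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5)))
  q <- sweep(q, 2, colMeans(q)) # centred orthogonal-ish scores
  q <- sweep(q, 2, apply(q, 2, sd), "/")
  sds <- c(3, 2, 1.5, 0.9, 0.5)
  x <- q %*% diag(sds)
  v <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  norm <- structure(
    list(
      values = x %*% t(v), kept = 1:n,
      coords = data.frame(
        bin_row = seq_len(n), bin_col = 1, x_um = 1, y_um = seq_len(n)
      ),
      recipe = "log1p_scale", params = list(), marker_order = paste0("M", 1:5),
      section_id = "S"
    ),
    class = "normalized_matrix"
  )
  pca <- pca_and_select_dims(norm)
  expect_equal(pca$sdev, sort(sds, decreasing = TRUE), tolerance = 0.05)
  expect_identical(pca$n_dims, 3L)

  # all SDs below 1: floor at 2
  norm$values <- norm$values * 0.1
  expect_identical(pca_and_select_dims(norm)$n_dims, 2L)
})

test_that("well-separated blobs yield the right number of clusters", {
  set.seed(8)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 3, sd = 2), n, 3), 2, center, `+`)
  }
  # blobs separated along a two-marker axis so PC1 carries the split
  x <- rbind(blob(c(20, 20, 20), 60), blob(c(80, 80, 20), 60))
  counts <- matrix(as.integer(round(pmax(x, 0))), ncol = 3)
  pc <- make_pc(counts, n_cols = 10)
  norm <- normalize_counts(pc)
  pca <- pca_and_select_dims(norm)
  cl2 <- cluster_bins(pca, k_neighbors = 30, seed = 1)
  expect_identical(length(unique(cl2$cluster)), 2L)
  expect_identical(sort(unique(cl2$cluster)), 0:1)
  truth <- rep(0:1, each = 60)
  expect_equal(adjusted_rand_index(cl2$cluster, truth), 1)

  # single tight blob: one cluster
  x1 <- blob(c(40, 40, 40), 50)
  pc1 <- make_pc(matrix(as.integer(round(x1)), ncol = 3), n_cols = 10)
  cl1 <- cluster_bins(pca_and_select_dims(normalize_counts(pc1)),
    k_neighbors = 30, seed = 1
  )
  expect_identical(unique(cl1$cluster), 0L)

  # fewer bins than k: warn and reduce
  pc_small <- make_pc(matrix(as.integer(seq_len(24)), ncol = 3), n_cols = 4)
  expect_warning(
    cluster_bins(pca_and_select_dims(normalize_counts(pc_small)),
      k_neighbors = 20, seed = 1
    ),
    "k reduced"
  )
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(12)
  counts <- matrix(as.integer(sample(0:60, 300, replace = TRUE)), ncol = 3)
  pc <- make_pc(counts, n_cols = 10)
  pca <- pca_and_select_dims(normalize_counts(pc))
  a <- cluster_bins(pca, k_neighbors = 10, seed = 99)
  b <- cluster_bins(pca, k_neighbors = 10, seed = 99)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$embedding, b$embedding)
})

test_that("z-score profiles use the population SD across clusters", {
  counts <- cbind(A = c(10L, 10L, 20L, 20L), B = c(5L, 5L, 5L, 5L))
  pc <- make_pc(counts, n_cols = 2)
  assignment <- structure(
    list(
      cluster = c(0L, 0L, 1L, 1L), embedding = matrix(0, 4, 2),
      coords = pc$coords, kept = 1:4, section_id = "S1",
      params = list()
    ),
    class = "cluster_assignment"
  )
  prof <- cluster_zscore_profiles(pc, assignment)
  # means {10, 20} -> z = (x - 15) / sd({10, 20}) = -/+ 1/sqrt(2)
  expect_equal(unname(prof$z[, "A"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_true(all(prof$z[, "B"] == 0)) # constant marker
  # per-marker z across clusters: mean 0, unit SD (non-degenerate marker)
  expect_equal(mean(prof$z[, "A"]), 0, tolerance = 1e-12)
  expect_equal(sd(prof$z[, "A"]), 1, tolerance = 1e-12)
})

test_that("layer assignment takes arg-max clusters and resolves conflicts", {
  z <- rbind(
    `0` = c(OMP = 2.0, MAP2 = 1.8, CALB = -1.0, SYP = -0.5),
    `1` = c(OMP = -0.5, MAP2 = -0.6, CALB = 2.0, SYP = 1.5),
    `2` = c(OMP = -1.5, MAP2 = -1.2, CALB = -1.0, SYP = -1.0)
  )
  prof <- structure(list(z = z, means = z, order = 0:2, tree = NULL),
    class = "cluster_profile"
  )
  sig <- list(GL = c("OMP", "MAP2"), AON = c("CALB", "SYP"))
  lm <- assign_layers(prof, sig)
  expect_identical(lm$cluster_layer[["0"]], "GL")
  expect_identical(lm$cluster_layer[["1"]], "AON")
  expect_true(is.na(lm$cluster_layer[["2"]]))

  # both layers maximized by cluster 0: larger margin wins, loser takes
  # its runner-up
  z2 <- rbind(
    `0` = c(OMP = 2.0, MAP2 = 2.0, CALB = 1.0, SYP = 1.0),
    `1` = c(OMP = 0.5, MAP2 = 0.5, CALB = 0.9, SYP = 0.9)
  )
  prof2 <- structure(list(z = z2, means = z2, order = 0:1, tree = NULL),
    class = "cluster_profile"
  )
  lm2 <- assign_layers(prof2, sig)
  # GL margin at cluster 0: 2.0 - 0.5; AON margin: 1.0 - 0.9 -> GL wins 0
  expect_identical(lm2$cluster_layer[["0"]], "GL")
  expect_identical(lm2$cluster_layer[["1"]], "AON")

  expect_error(assign_layers(prof, list(L = "NOPE")), "unknown marker")
})

test_that("satellite clusters map to the nearest anchor layer", {
  z <- rbind(
    `0` = c(OMP = 2.0, MAP2 = 1.8, CALB = -1.0, SYP = -0.5),
    `1` = c(OMP = -0.5, MAP2 = -0.6, CALB = 2.0, SYP = 1.5),
    `2` = c(OMP = 1.7, MAP2 = 1.5, CALB = -0.8, SYP = -0.4) # near cluster 0
  )
  prof <- structure(list(z = z, means = z, order = 0:2, tree = NULL),
    class = "cluster_profile"
  )
  sig <- list(GL = c("OMP", "MAP2"), AON = c("CALB", "SYP"))
  full <- map_clusters_to_layers(prof, signatures = sig)
  expect_identical(unname(full[c("0", "1", "2")]), c("GL", "AON", "GL"))
})

test_that("spatial cluster tables round-trip bin coordinates", {
  counts <- cbind(A = c(10L, 10L, 20L, 20L, 30L, 30L))
  pc <- make_pc(counts, n_cols = 3)
  assignment <- structure(
    list(
      cluster = c(0L, 0L, 1L, 1L, 0L, 1L), embedding = matrix(0, 6, 2),
      coords = pc$coords, kept = 1:6, section_id = "S1", params = list()
    ),
    class = "cluster_assignment"
  )
  out <- plot_clusters_spatial(assignment)
  expect_identical(out$table[, c("bin_row", "bin_col")], pc$coords[, c("bin_row", "bin_col")])
  expect_identical(length(out$per_cluster), 2L)
  expect_s3_class(out$combined, "ggplot")
})

test_that("MTX export matches the dense matrix", {
  skip_if_not_installed("Matrix")
  counts <- cbind(A = c(0L, 5L, NA, 7L), B = c(1L, 0L, 2L, NA))
  pc <- make_pc(counts, n_cols = 2)
  dir <- tempfile()
  write_mtx(pc, dir)
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dense <- counts
  dense[is.na(dense)] <- 0L
  expect_equal(unname(m), unname(matrix(as.numeric(dense), ncol = 2)))
  expect_identical(readLines(file.path(dir, "markers.tsv")), c("A", "B"))
})
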