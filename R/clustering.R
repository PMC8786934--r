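# Unsupervised discovery of tissue layers from pseudo-count bins:
# normalization, PCA with dimension selection, shared-nearest-neighbour graph
# clustering with a UMAP embedding, per-cluster z-score profiles, and
# signature-driven layer naming.

#' Normalize a pseudo-count matrix
#'
#' Default recipe `"log1p_scale"`: bins whose pseudo-counts are missing for
#' every marker are dropped (and reported); remaining missing entries are
#' treated as 0 (below detection), `log1p` is applied, then each marker is
#' centred and scaled to unit variance with values clipped at `+/- clip`.
#' Zero-variance markers scale to all-zeros with a warning rather than being
#' dropped, so the marker panel stays intact downstream.
#'
#' @param pc a `pseudo_counts`.
#' @param clip symmetric clip bound after scaling (default 10).
#' @param recipe normalization recipe id; `"log1p_scale"` (default) or
#'   `"log1p"` (no scaling).
#' @return a `normalized_matrix`: list with `values` (bins x markers), `kept`
#'   (row indices into the source matrix), `coords` (kept rows), `recipe`,
#'   `params` and `marker_order`.
#' @export
normalize_counts <- function(pc, clip = 10, recipe = c("log1p_scale", "log1p")) {
  stopifnot(inherits(pc, "pseudo_counts"))
  recipe <- match.arg(recipe)
  all_na <- rowSums(!is.na(pc$counts)) == 0L
  if (any(all_na)) {
    message(sum(all_na), " bin(s) missing for every marker dropped before normalization")
  }
  kept <- which(!all_na)
  x <- pc$counts[kept, , drop = FALSE]
  x[is.na(x)] <- 0L
  v <- log1p(x)
  if (recipe == "log1p_scale") {
    mu <- colMeans(v)
    sdv <- apply(v, 2L, sd)
    zero_var <- sdv == 0
    if (any(zero_var)) {
      warning(
        "zero-variance marker(s) scaled to all-zeros: ",
        paste(colnames(v)[zero_var], collapse = ", ")
      )
      sdv[zero_var] <- 1
    }
    v <- sweep(sweep(v, 2L, mu, `-`), 2L, sdv, `/`)
    v[, zero_var] <- 0
    v <- pmin(pmax(v, -clip), clip)
  }
  structure(
    list(
      values = v, kept = kept, coords = pc$coords[kept, , drop = FALSE],
      recipe = recipe, params = list(clip = clip),
      marker_order = pc$marker_order, section_id = pc$section_id
    ),
    class = "normalized_matrix"
  )
}

#' PCA of normalized bins with dimension selection
#'
#' Full centred PCA of the normalized matrix; the number of informative
#' dimensions is the count of components whose standard deviation exceeds 1
#' (the elbow rule on unit-variance input), floored at 2 so downstream graphs
#' never degenerate.
#'
#' @param norm a `normalized_matrix`.
#' @return a `bin_pca`: list with `scores` (bins x components), `loadings`,
#'   `sdev` (non-increasing), `n_dims`, plus the coordinates carried through.
#' @export
pca_and_select_dims <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (ncol(norm$values) < 2L || nrow(norm$values) < 3L) {
    stop("PCA requires at least 2 markers and 3 bins")
  }
  pc <- prcomp(norm$values, center = TRUE, scale. = FALSE)
  n_dims <- max(2L, sum(pc$sdev > 1))
  n_dims <- min(n_dims, ncol(pc$x))
  structure(
    list(
      scores = pc$x, loadings = pc$rotation, sdev = pc$sdev, n_dims = n_dims,
      coords = norm$coords, kept = norm$kept,
      marker_order = norm$marker_order, section_id = norm$section_id
    ),
    class = "bin_pca"
  )
}

# k nearest neighbours (excluding self) from a score matrix; plain dense
# search — bin counts per section are a few hundred to a few thousand.
knn_indices <- function(scores, k) {
  d <- as.matrix(dist(scores))
  diag(d) <- Inf
  t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
}

# Shared-nearest-neighbour graph: Jaccard overlap of (self + k neighbours)
# sets, pruned below `prune`.
snn_graph <- function(nn, prune = 1 / 15) {
  n <- nrow(nn)
  k <- ncol(nn)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  member <- matrix(FALSE, n, n)
  for (i in seq_len(n)) member[i, sets[[i]]] <- TRUE
  # all-pairs Jaccard via one matrix product; bin counts per section are small
  overlap <- tcrossprod(member * 1)
  union_size <- outer(rowSums(member), rowSums(member), `+`) - overlap
  jac <- overlap / union_size
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' Cluster bins on the SNN graph
#'
#' Builds a shared-nearest-neighbour graph (Jaccard weights over k-nearest
#' neighbour sets, pruned at 1/15) on the first `n_dims` principal components,
#' partitions it by Leiden modularity optimization at the given resolution,
#' and embeds the same components in 2-D with UMAP under the same seed.
#' Cluster ids are dense integers from 0, ordered by decreasing size.
#'
#' @param pca a `bin_pca`.
#' @param n_dims number of components to use; defaults to the PCA's selected
#'   `n_dims`.
#' @param k_neighbors neighbours for the kNN graph (default 20; reduced with a
#'   warning when fewer bins are available).
#' @param resolution Leiden modularity resolution (default 0.8).
#' @param seed RNG seed controlling clustering and embedding.
#' @return a `cluster_assignment`: list with `cluster` (integer per bin, from
#'   0), `embedding` (bins x 2), `coords`, `kept` and `params`.
#' @export
cluster_bins <- function(pca, n_dims = NULL, k_neighbors = 20L, resolution = 0.8,
                         seed = 1L) {
  stopifnot(inherits(pca, "bin_pca"))
  n_dims <- n_dims %||% pca$n_dims
  if (n_dims > ncol(pca$scores)) stop("n_dims exceeds available components")
  scores <- pca$scores[, seq_len(n_dims), drop = FALSE]
  n <- nrow(scores)
  if (n <= k_neighbors) {
    warning("fewer bins than k_neighbors; k reduced to ", n - 1L)
    k_neighbors <- n - 1L
  }
  nn <- knn_indices(scores, k_neighbors)
  g <- snn_graph(nn)
  cl <- with_seed(seed, igraph::cluster_leiden(
    g,
    objective_function = "modularity",
    resolution = resolution, n_iterations = 10L
  ))
  memb <- igraph::membership(cl)
  # dense ids from 0, largest cluster first
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- unname(relabel[as.character(memb)])
  emb <- with_seed(seed, uwot::umap(
    scores,
    n_neighbors = min(15L, n - 1L), n_threads = 1L, n_sgd_threads = 0L
  ))
  colnames(emb) <- c("UMAP1", "UMAP2")
  structure(
    list(
      cluster = as.integer(cluster), embedding = emb,
      coords = pca$coords, kept = pca$kept, section_id = pca$section_id,
      params = list(
        n_dims = n_dims, k_neighbors = k_neighbors,
        resolution = resolution, seed = seed
      )
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(
    "cluster_assignment: ", length(x$cluster), " bins in ",
    length(unique(x$cluster)), " clusters (k = ", x$params$k_neighbors,
    ", resolution = ", x$params$resolution, ", seed = ", x$params$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Per-cluster marker z-score profiles
#'
#' Mean pseudo-count per marker within each cluster (missing entries treated
#' as 0), z-scored across clusters per marker (the standard `scale()`
#' convention, so two clusters with means 10 and 20 give -0.707 and +0.707);
#' markers constant across clusters get an all-zero row. Clusters
#' are ordered by an average-linkage hierarchical tree on the Euclidean
#' distance between profiles.
#'
#' @param pc the `pseudo_counts` the clustering was computed from.
#' @param assignment a `cluster_assignment` on the same section.
#' @return a `cluster_profile`: list with `z` (clusters x markers), `means`,
#'   `order` (hierarchical ordering of cluster ids) and `tree` (hclust, or
#'   `NULL` for a single cluster).
#' @export
cluster_zscore_profiles <- function(pc, assignment) {
  stopifnot(inherits(pc, "pseudo_counts"), inherits(assignment, "cluster_assignment"))
  x <- pc$counts[assignment$kept, , drop = FALSE]
  x[is.na(x)] <- 0L
  cl <- assignment$cluster
  ids <- sort(unique(cl))
  means <- t(vapply(
    ids,
    function(k) colMeans(x[cl == k, , drop = FALSE]),
    numeric(ncol(x))
  ))
  rownames(means) <- ids
  if (length(ids) > 1L) {
    mu <- colMeans(means)
    sdv <- apply(means, 2L, sd)
    z <- sweep(means, 2L, mu, `-`)
    z <- sweep(z, 2L, ifelse(sdv == 0, 1, sdv), `/`)
    z[, sdv == 0] <- 0
    tree <- hclust(dist(z), method = "average")
    ord <- ids[tree$order]
  } else {
    z <- means * 0
    tree <- NULL
    ord <- ids
  }
  structure(
    list(z = z, means = means, order = ord, tree = tree),
    class = "cluster_profile"
  )
}

#' Assign clusters to named layers by signature score
#'
#' Scores every cluster for each layer by the mean z of that layer's signature
#' markers; each layer takes its arg-max cluster, but a cluster can win at
#' most one layer. Conflicts are resolved in favour of the layer with the
#' larger score margin (best minus runner-up among still-available clusters);
#' the losing layer takes its runner-up. Ties between clusters within a layer
#' break to the lower cluster id. Layers left without an available cluster
#' stay unassigned.
#'
#' @param profile a `cluster_profile`.
#' @param signatures named list: layer name -> character vector of signature
#'   markers (all present in the profile's marker panel).
#' @return a `layer_map`: list with `assignment` (data.frame `layer`,
#'   `cluster`, `score`) and `cluster_layer` (named character vector mapping
#'   cluster id -> layer, `NA` for unassigned clusters).
#' @export
assign_layers <- function(profile, signatures) {
  stopifnot(inherits(profile, "cluster_profile"), length(signatures) >= 1L)
  markers <- colnames(profile$z)
  unknown <- setdiff(unique(unlist(signatures)), markers)
  if (length(unknown)) {
    stop("signature references unknown marker(s): ", paste(unknown, collapse = ", "))
  }
  ids <- as.integer(rownames(profile$z))
  score <- t(vapply(
    signatures,
    function(sig) rowMeans(profile$z[, sig, drop = FALSE]),
    numeric(length(ids))
  ))
  colnames(score) <- ids
  pending <- names(signatures)
  available <- as.character(ids)
  out <- data.frame(layer = character(), cluster = integer(), score = numeric())
  while (length(pending) && length(available)) {
    # each pending layer's best available cluster and its margin
    pick <- lapply(pending, function(ly) {
      s <- score[ly, available]
      best <- which(s == max(s))[1L] # ties -> lower cluster id (sorted ids)
      margin <- if (length(s) > 1L) max(s) - max(s[-best]) else Inf
      list(layer = ly, cluster = available[best], score = s[best], margin = margin)
    })
    chosen <- vapply(pick, `[[`, "", "cluster")
    margins <- vapply(pick, `[[`, 0, "margin")
    # resolve each contested cluster in favour of the largest margin
    winners <- vapply(unique(chosen), function(cl) {
      cand <- which(chosen == cl)
      cand[order(-margins[cand])][1L]
    }, 0L)
    for (w in winners) {
      out <- rbind(out, data.frame(
        layer = pick[[w]]$layer, cluster = as.integer(pick[[w]]$cluster),
        score = pick[[w]]$score
      ))
    }
    assigned_layers <- vapply(pick[winners], `[[`, "", "layer")
    pending <- setdiff(pending, assigned_layers)
    available <- setdiff(available, unique(chosen)[seq_along(winners)])
  }
  cluster_layer <- stats::setNames(rep(NA_character_, length(ids)), ids)
  cluster_layer[as.character(out$cluster)] <- out$layer
  structure(
    list(assignment = out, cluster_layer = cluster_layer),
    class = "layer_map"
  )
}

#' Map every cluster to a layer
#'
#' Completes a [assign_layers()] result into a full cluster -> layer
#' labelling: each layer's winning cluster is its anchor, and every remaining
#' cluster inherits the layer of the anchor with the nearest z-score profile
#' (Euclidean distance). This mirrors the practice of grouping several
#' clusters per anatomical layer: boundary-interface or substructure clusters
#' (e.g. glomeruli within the glomerular layer) attach to the layer they are
#' closest to in marker space.
#'
#' @param profile a `cluster_profile`.
#' @param layer_map a `layer_map` from [assign_layers()]; computed on the fly
#'   when omitted.
#' @param signatures signature table used when `layer_map` is omitted.
#' @return named character vector: cluster id -> layer name (every cluster
#'   mapped whenever at least one anchor exists).
#' @export
map_clusters_to_layers <- function(profile, layer_map = NULL,
                                   signatures = olfactory_bulb_signatures()) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (is.null(layer_map)) layer_map <- assign_layers(profile, signatures)
  out <- layer_map$cluster_layer
  anchors <- out[!is.na(out)]
  if (length(anchors) == 0L) {
    return(out)
  }
  sat <- names(out)[is.na(out)]
  for (cl in sat) {
    d <- vapply(names(anchors), function(a) {
      sqrt(sum((profile$z[cl, ] - profile$z[a, ])^2))
    }, 0)
    out[[cl]] <- anchors[[names(which.min(d))]]
  }
  out
}

#' Plot clusters and layers in tissue space
#'
#' Produces per-cluster slide plots, a combined plot coloured by cluster (or
#' by layer when a `layer_map` is given, unassigned clusters in grey), and
#' the machine-readable bin table.
#'
#' @param assignment a `cluster_assignment`.
#' @param layer_map optional `layer_map` from [assign_layers()].
#' @return list with `table` (`bin_row`, `bin_col`, `x_um`, `y_um`, `cluster`,
#'   `layer`), `combined` (ggplot) and `per_cluster` (named list of ggplots).
#' @export
plot_clusters_spatial <- function(assignment, layer_map = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  tab <- assignment$coords[, c("bin_row", "bin_col", "x_um", "y_um")]
  tab$cluster <- assignment$cluster
  tab$layer <- NA_character_
  if (!is.null(layer_map)) {
    tab$layer <- unname(layer_map$cluster_layer[as.character(tab$cluster)])
  }
  fill_var <- if (is.null(layer_map)) "cluster" else "layer"
  tab_plot <- tab
  tab_plot$cluster <- factor(tab_plot$cluster)
  if (!is.null(layer_map)) {
    tab_plot$layer <- ifelse(is.na(tab_plot$layer), "unassigned", tab_plot$layer)
  }
  combined <- ggplot2::ggplot(
    tab_plot,
    ggplot2::aes(x = .data$x_um, y = .data$y_um, fill = .data[[fill_var]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(layer_map)) {
    combined <- combined + ggplot2::scale_fill_manual(
      values = c(stats::setNames(
        grDevices::hcl.colors(max(1L, length(unique(stats::na.omit(tab$layer)))), "Dark 3"),
        unique(stats::na.omit(tab$layer))
      ), unassigned = "grey80")
    )
  }
  per_cluster <- lapply(sort(unique(tab$cluster)), function(k) {
    ggplot2::ggplot(
      tab_plot[tab_plot$cluster == k, ],
      ggplot2::aes(x = .data$x_um, y = .data$y_um)
    ) +
      ggplot2::geom_tile(fill = "grey20") +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = paste("cluster", k), x = "x (um)", y = "y (um)") +
      ggplot2::theme_minimal()
  })
  names(per_cluster) <- paste0("cluster_", sort(unique(tab$cluster)))
  list(table = tab, combined = combined, per_cluster = per_cluster)
}

#' Export a pseudo-count matrix as sparse MatrixMarket
#'
#' Writes the non-missing entries of the bins x markers matrix in MTX
#' coordinate format with row (bin) and column (marker) sidecar TSVs, for
#' interoperability with single-cell toolchains.
#'
#' @param pc a `pseudo_counts`.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `bins.tsv`, `markers.tsv`.
#' @export
write_mtx <- function(pc, dir) {
  stopifnot(inherits(pc, "pseudo_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(!is.na(pc$counts) & pc$counts != 0L, arr.ind = TRUE)
  vals <- pc$counts[idx]
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(paste(nrow(pc$counts), ncol(pc$counts), nrow(idx)), con)
  writeLines(paste(idx[, 1L], idx[, 2L], vals), con)
  close(con)
  write.table(pc$coords, file.path(dir, "bins.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  writeLines(pc$marker_order, file.path(dir, "markers.tsv"))
  invisible(dir)
}
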