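# End-to-end convenience wrappers tying the modules together. Each returns
# the intermediate objects so individual stages remain inspectable.

#' Pseudo-count matrices for a set of stacks
#'
#' @param stacks named list of `marker_stack`.
#' @param bin_side_um physical bin side (default 10).
#' @return named list of `pseudo_counts`.
#' @export
cohort_pseudo_counts <- function(stacks, bin_side_um = 10) {
  lapply(stacks, build_pseudo_counts, bin_side_um = bin_side_um)
}

#' Differential-label analysis for a cohort
#'
#' Runs binning, per-section trimmed-mean Poisson coding, positive-bin ratios
#' and the by-marker ANOVA/BH/Tukey screen in one call.
#'
#' @param stacks named list of `marker_stack` (or a `phantom_cohort`).
#' @param bin_side_um physical bin side.
#' @param trim trimmed-mean fraction for the section rates.
#' @param alpha_bin strict bin-coding threshold.
#' @param alpha_label strict marker flag threshold on the raw ANOVA p.
#' @param flag_on `"raw"` or `"adjusted"` flagging rule.
#' @return list with `pseudo_counts`, `codings`, `ratios` and `result` (a
#'   `differential_result`).
#' @export
run_differential_analysis <- function(stacks, bin_side_um = 10, trim = 0.05,
                                      alpha_bin = 0.05, alpha_label = 0.10,
                                      flag_on = "raw") {
  if (inherits(stacks, "phantom_cohort")) stacks <- stacks$stacks
  pcs <- cohort_pseudo_counts(stacks, bin_side_um = bin_side_um)
  codings <- lapply(pcs, code_bins, alpha_bin = alpha_bin, trim = trim)
  ratios <- label_ratios(codings)
  result <- anova_by_label(ratios, alpha_label = alpha_label, flag_on = flag_on)
  list(pseudo_counts = pcs, codings = codings, ratios = ratios, result = result)
}

#' String co-occurrence analysis for a cohort
#'
#' Encodes per-bin binary strings from existing codings, tallies them per
#' section and tests them across groups.
#'
#' @param codings named list of `binary_coding` (e.g. from
#'   [run_differential_analysis()]).
#' @param alpha_string strict flag threshold on the raw Kruskal-Wallis p.
#' @param min_total minimum cohort-wide string count to test.
#' @param normalize test per-total-normalized counts instead of raw counts.
#' @return list with `strings` (per-section string vectors), `freqs` and
#'   `result` (a `string_test_result`).
#' @export
run_string_analysis <- function(codings, alpha_string = 0.05, min_total = 10,
                                normalize = FALSE) {
  strings <- lapply(codings, encode_strings)
  freqs <- tally_strings(strings, vapply(codings, `[[`, "", "group"))
  result <- kruskal_dunn_by_string(freqs,
    alpha_string = alpha_string,
    min_total = min_total, normalize = normalize
  )
  list(strings = strings, freqs = freqs, result = result)
}

#' Layer discovery for one section
#'
#' Normalizes a pseudo-count matrix, selects PCA dimensions, clusters bins on
#' the SNN graph, profiles clusters by marker z-scores and names them from a
#' layer signature table.
#'
#' @param pc a `pseudo_counts`.
#' @param signatures layer signature table (default
#'   [olfactory_bulb_signatures()]).
#' @param k_neighbors neighbours for the SNN graph. The default adapts to
#'   section size: `min(20, max(5, ceiling(0.05 * n_bins)))` — an SNN graph
#'   cannot resolve communities much smaller than k, and the smallest bulb
#'   layer occupies roughly 5-10% of a section, so k is capped at 5% of the
#'   available bins (20 at full scale, smaller on desk-scale sections).
#' @param resolution,seed clustering parameters, see [cluster_bins()].
#' @return list with `norm`, `pca`, `clusters`, `profile`, `layers` (a
#'   `layer_map`: best cluster per layer) and `cluster_layer` (full cluster ->
#'   layer mapping from [map_clusters_to_layers()]).
#' @export
run_layer_analysis <- function(pc, signatures = olfactory_bulb_signatures(),
                               k_neighbors = NULL, resolution = 0.8, seed = 1L) {
  norm <- normalize_counts(pc)
  pca <- pca_and_select_dims(norm)
  k_neighbors <- k_neighbors %||%
    min(20L, max(5L, as.integer(ceiling(0.05 * nrow(norm$values)))))
  clusters <- cluster_bins(pca,
    k_neighbors = k_neighbors,
    resolution = resolution, seed = seed
  )
  profile <- cluster_zscore_profiles(pc, clusters)
  layers <- assign_layers(profile, signatures)
  cluster_layer <- map_clusters_to_layers(profile, layers)
  list(
    norm = norm, pca = pca, clusters = clusters,
    profile = profile, layers = layers, cluster_layer = cluster_layer
  )
}
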