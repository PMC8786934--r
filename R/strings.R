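# Marker co-occurrence strings: per-bin binary signatures, group tests, and
# spatial mapping of differential strings.

#' Encode per-bin binary marker strings
#'
#' Concatenates each bin's 0/1 codes over markers (in `marker_order`) into a
#' character string, e.g. coding row (1,0,1) becomes `"101"`. Identical
#' strings denote identical marker co-occurrence signatures.
#'
#' @param coding a `binary_coding`.
#' @return character vector, one string per bin, with attribute
#'   `marker_order`.
#' @export
encode_strings <- function(coding) {
  stopifnot(inherits(coding, "binary_coding"))
  s <- do.call(paste0, as.data.frame(coding$coding))
  attr(s, "marker_order") <- coding$marker_order
  s
}

#' Tally string frequencies per section
#'
#' Columns are the union of strings observed in any section; strings absent
#' from a section count 0, so every string is tested on all sections.
#'
#' @param strings named list (section_id -> character vector of bin strings).
#' @param groups group label per section, same order as `strings`.
#' @param marker_order canonical marker order the strings follow.
#' @return a `string_freqs`: list with `counts` (sections x strings integer
#'   matrix), `group` (factor), `totals` (bins per section) and
#'   `marker_order`.
#' @export
tally_strings <- function(strings, groups, marker_order = attr(strings[[1L]], "marker_order")) {
  stopifnot(length(strings) == length(groups), length(strings) >= 1L)
  lens <- unique(nchar(unlist(strings, use.names = FALSE)))
  if (length(lens) > 1L) stop("sections disagree on string length (marker panel)")
  all_strings <- sort(unique(unlist(strings, use.names = FALSE)))
  counts <- t(vapply(strings, function(s) {
    tab <- table(factor(s, levels = all_strings))
    as.integer(tab)
  }, integer(length(all_strings))))
  dimnames(counts) <- list(names(strings), all_strings)
  structure(
    list(
      counts = counts, group = factor(groups),
      totals = vapply(strings, length, 0L), marker_order = marker_order
    ),
    class = "string_freqs"
  )
}

# Tie-corrected Kruskal-Wallis; H defined as 0 (p = 1) when every
# observation is tied, where the tie-correction denominator vanishes.
kw_safe <- function(x, g) {
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1))
  }
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn post hoc test
#'
#' Pairwise rank-based z tests following a Kruskal-Wallis test, with the
#' standard tie correction: `z = (Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))`
#' where `Ri` are mean ranks and `T = sum(t^3 - t) / (12 (N - 1))` over tie
#' groups. Two-sided normal p-values are reported raw and BH-adjusted across
#' the pairwise comparisons.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return data.frame with `comparison`, `z`, `p`, `p_bh`.
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(factor(g))
  stopifnot(nlevels(g) >= 2L)
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2L)
  z <- apply(pairs, 2L, function(pr) {
    se <- sqrt(sigma2 * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    if (se == 0) {
      return(0)
    }
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(
    comparison = paste(pairs[1L, ], pairs[2L, ], sep = "-"),
    z = z, p = p, p_bh = p.adjust(p, method = "BH")
  )
}

#' Kruskal-Wallis and Dunn tests per string
#'
#' Each string's per-section counts (optionally normalized by section bin
#' totals) are tested across groups with a tie-corrected Kruskal-Wallis test;
#' BH adjustment is reported across strings, and Dunn pairwise post hoc tests
#' are computed for every tested string. Strings observed in fewer than
#' `min_total` bins cohort-wide are excluded from testing (and listed in the
#' result) to avoid the combinatorial tail of rare signatures.
#'
#' @param freqs a `string_freqs`.
#' @param alpha_string strict flag threshold on the raw p-value (default
#'   0.05).
#' @param min_total minimum cohort-wide count for a string to be tested
#'   (default 10).
#' @param normalize divide counts by each section's total bins before testing
#'   (default `FALSE`: raw counts).
#' @return a `string_test_result`: list with `table` (per string: `string`,
#'   `total`, `H`, `p`, `p_bh`, `differential`), `dunn` (named list of
#'   pairwise data.frames), `excluded` (string -> total for untested rare
#'   strings), `marker_order` and parameters.
#' @export
kruskal_dunn_by_string <- function(freqs, alpha_string = 0.05, min_total = 10,
                                   normalize = FALSE) {
  stopifnot(inherits(freqs, "string_freqs"))
  grp <- droplevels(freqs$group)
  if (nlevels(grp) < 2L) stop("at least two groups are required")
  totals <- colSums(freqs$counts)
  keep <- totals >= min_total
  excluded <- totals[!keep]
  if (length(excluded)) {
    message(
      length(excluded), " rare string(s) below min_total = ", min_total,
      " excluded from testing"
    )
  }
  tested <- colnames(freqs$counts)[keep]
  vals <- freqs$counts[, tested, drop = FALSE]
  if (normalize) vals <- sweep(vals, 1L, freqs$totals, `/`)
  rows <- lapply(tested, function(s) {
    kw <- kw_safe(vals[, s], grp)
    data.frame(string = s, total = totals[[s]], H = kw$H, p = kw$p)
  })
  table <- do.call(rbind, rows)
  if (is.null(table)) {
    table <- data.frame(
      string = character(), total = integer(), H = numeric(), p = numeric()
    )
  }
  table$p_bh <- p.adjust(table$p, method = "BH")
  table$differential <- table$p < alpha_string
  dunn <- lapply(tested, function(s) dunn_test(vals[, s], grp))
  names(dunn) <- tested
  structure(
    list(
      table = table, dunn = dunn, excluded = excluded,
      marker_order = freqs$marker_order,
      alpha_string = alpha_string, min_total = min_total,
      normalize = normalize
    ),
    class = "string_test_result"
  )
}

#' @export
print.string_test_result <- function(x, ...) {
  cat(
    "string_test_result: ", sum(x$table$differential), " of ", nrow(x$table),
    " tested strings flagged at raw p < ", x$alpha_string,
    " (", length(x$excluded), " rare strings untested)\n",
    sep = ""
  )
  print(head(x$table[order(x$table$p), ], 10L), row.names = FALSE)
  invisible(x)
}

#' Filter strings by the state of one marker
#'
#' Retains the strings whose character at the marker's position in
#' `marker_order` equals `'1'` (marker present) or `'0'` (`present = FALSE`),
#' e.g. to focus on all signatures that co-occur with tau.
#'
#' @param x a `string_test_result`, or a character vector of strings with a
#'   `marker_order` attribute.
#' @param marker marker name; must be in the marker order.
#' @param present keep strings where the marker is present (default) or
#'   absent.
#' @return the same type as `x`, subset to the matching strings.
#' @export
filter_strings_by_marker <- function(x, marker, present = TRUE) {
  mo <- if (inherits(x, "string_test_result")) x$marker_order else attr(x, "marker_order")
  pos <- match(marker, mo)
  if (is.na(pos)) stop("unknown marker '", marker, "'")
  want <- if (present) "1" else "0"
  if (inherits(x, "string_test_result")) {
    keep <- substr(x$table$string, pos, pos) == want
    x$table <- x$table[keep, , drop = FALSE]
    x$dunn <- x$dunn[x$table$string]
    x
  } else {
    out <- x[substr(x, pos, pos) == want]
    attr(out, "marker_order") <- mo
    out
  }
}

#' Plot selected strings in tissue space
#'
#' Places the bins carrying the selected strings at their tissue coordinates,
#' one colour per unique string, and returns the machine-readable table
#' alongside the figure.
#'
#' @param strings character vector of per-bin strings for one section.
#' @param selected strings to display.
#' @param coords bin coordinate table aligned with `strings` (columns
#'   `bin_row`, `bin_col`, `x_um`, `y_um`), e.g. `pc$coords`.
#' @param title plot title.
#' @return list with `table` (`bin_row`, `bin_col`, `x_um`, `y_um`, `string`)
#'   and `plot` (a ggplot; y axis reversed so the image origin is top-left).
#' @export
plot_string_bins <- function(strings, selected, coords, title = "string bins") {
  stopifnot(length(strings) == nrow(coords))
  keep <- strings %in% selected
  tab <- coords[keep, c("bin_row", "bin_col", "x_um", "y_um"), drop = FALSE]
  tab$string <- strings[keep]
  if (nrow(tab) == 0L) {
    warning("no bins carry the selected strings")
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x_um, y = .data$y_um, fill = .data$string)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (um)", y = "y (um)", fill = "string") +
    ggplot2::theme_minimal()
  list(table = tab, plot = p)
}

#' Marker-composition heat map of selected strings
#'
#' Decomposes each selected string into its 0/1 marker membership (markers in
#' rows, strings in columns). With more than one string and marker, rows and
#' columns are ordered by average-linkage hierarchical clustering on Jaccard
#' distance.
#'
#' @param selected character vector of strings (all the same length as the
#'   marker panel).
#' @param marker_order marker names, one per string position.
#' @return list with `matrix` (markers x strings 0/1, in clustered order) and
#'   `heatmap` (a pheatmap object, or `NULL` for a single string).
#' @export
string_composition_heatmap <- function(selected, marker_order) {
  stopifnot(length(selected) >= 1L, all(nchar(selected) == length(marker_order)))
  selected <- unique(selected)
  mat <- vapply(
    selected,
    function(s) as.integer(strsplit(s, "")[[1L]]),
    integer(length(marker_order))
  )
  mat <- matrix(mat,
    nrow = length(marker_order),
    dimnames = list(marker_order, selected)
  )
  hm <- NULL
  if (ncol(mat) > 1L && nrow(mat) > 1L) {
    hr <- hclust(dist(mat, method = "binary"), method = "average")
    hc <- hclust(dist(t(mat), method = "binary"), method = "average")
    mat <- mat[hr$order, hc$order, drop = FALSE]
    hm <- pheatmap::pheatmap(
      mat,
      cluster_rows = FALSE, cluster_cols = FALSE,
      color = c("grey95", "grey20"), legend = FALSE, silent = TRUE
    )
  }
  list(matrix = mat, heatmap = hm)
}
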