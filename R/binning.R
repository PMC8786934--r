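# Fixed square pixel bins and per-section pseudo-count matrices.
#
# Bins are "blunt-ended": complete, non-overlapping b x b pixel blocks;
# trailing partial rows/columns of pixels are excluded so that every bin
# summarizes the same number of pixels. Bin coordinates are 0-based
# (origin top-left, x = column, y = row).

#' Compute the pixel-bin grid for an image
#'
#' The bin side in pixels is the physical bin side divided by the pixel
#' resolution, rounded to the nearest integer (10 um at 0.325 um/px gives
#' 31 px). The grid keeps only complete bins: `n_rows = floor(H / b)`,
#' `n_cols = floor(W / b)`.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param resolution micrometres per pixel (isotropic).
#' @param bin_side_um physical bin side in micrometres (default 10).
#' @return a `bin_grid`: list with `bin_side_px`, `n_rows`, `n_cols`,
#'   `resolution`, `bin_side_um` and `bins`, a data.frame with one row per bin
#'   in row-major order: `bin_row`, `bin_col` (0-based), `row0`, `col0`
#'   (0-based pixel origin of the half-open extent) and physical centres
#'   `x_um`, `y_um`.
#' @export
#' @examples
#' g <- compute_bin_grid(93, 62, resolution = 0.325, bin_side_um = 10)
#' g$bin_side_px # 31
#' c(g$n_rows, g$n_cols) # 2 3
compute_bin_grid <- function(width_px, height_px, resolution, bin_side_um = 10) {
  stopifnot(resolution > 0, bin_side_um > 0)
  b <- as.integer(round_half_up(bin_side_um / resolution))
  b <- max(b, 1L)
  if (width_px < b || height_px < b) {
    stop(
      "grid error: image ", height_px, "x", width_px,
      " px is smaller than one ", b, "x", b, " px bin"
    )
  }
  n_rows <- as.integer(height_px %/% b)
  n_cols <- as.integer(width_px %/% b)
  bin_row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  bin_col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  bins <- data.frame(
    bin_row = bin_row,
    bin_col = bin_col,
    row0 = bin_row * b,
    col0 = bin_col * b,
    x_um = (bin_col * b + b / 2) * resolution,
    y_um = (bin_row * b + b / 2) * resolution
  )
  structure(
    list(
      bin_side_px = b, n_rows = n_rows, n_cols = n_cols,
      resolution = resolution, bin_side_um = bin_side_um, bins = bins
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(
    "bin_grid: ", x$n_rows, "x", x$n_cols, " bins of ", x$bin_side_px,
    "x", x$bin_side_px, " px (", x$bin_side_um, " um @ ", x$resolution,
    " um/px)\n",
    sep = ""
  )
  invisible(x)
}

#' Median of non-zero intensities per bin
#'
#' For each bin, the median of the strictly positive pixel intensities; bins
#' whose pixels are all zero yield `NA` (below detection everywhere). Even
#' pixel counts use the mean of the two central order statistics.
#'
#' @param pixels intensity matrix (rows = y, cols = x) or a `marker_image`.
#' @param grid a `bin_grid` computed from dimensions no larger than `pixels`.
#' @return numeric vector of length `n_rows * n_cols` in the grid's row-major
#'   bin order, values in \(0, 1\] or `NA`.
#' @export
bin_median_nonzero <- function(pixels, grid) {
  if (inherits(pixels, "marker_image")) pixels <- pixels$pixels
  b <- grid$bin_side_px
  hh <- grid$n_rows * b
  ww <- grid$n_cols * b
  if (nrow(pixels) < hh || ncol(pixels) < ww) {
    stop("image is smaller than the bin grid extent")
  }
  px <- pixels[seq_len(hh), seq_len(ww), drop = FALSE]
  # row-major bin id per pixel, matching grid$bins order
  bin_id <- ((seq_len(hh) - 1L) %/% b) * grid$n_cols # per pixel row
  id <- outer(bin_id, (seq_len(ww) - 1L) %/% b, `+`)
  vals <- split(px, id)
  out <- vapply(vals, function(v) {
    v <- v[v > 0]
    if (length(v) == 0L) NA_real_ else median(v)
  }, 0)
  # split() orders by numeric-as-character factor levels; restore bin order
  unname(out[order(as.integer(names(vals)))])
}

#' Build the pseudo-count matrix for one section
#'
#' Per-bin medians of non-zero intensity are multiplied by 100 and rounded
#' half away from zero to integers in \[0, 100\]; all-zero bins propagate as
#' `NA` and are never imputed.
#'
#' @param stack a `marker_stack`.
#' @param grid a `bin_grid`; defaults to the grid of the stack's dimensions.
#' @param bin_side_um bin side used when `grid` is not supplied.
#' @return a `pseudo_counts`: list with `section_id`, `group`, `counts`
#'   (integer matrix, bins x markers, `NA` allowed), `coords` (the grid's bin
#'   table, aligned row-for-row), `marker_order` and `grid`.
#' @export
build_pseudo_counts <- function(stack, grid = NULL, bin_side_um = 10) {
  stopifnot(inherits(stack, "marker_stack"))
  if (is.null(grid)) {
    grid <- compute_bin_grid(
      width_px = stack$dim[["width_px"]], height_px = stack$dim[["height_px"]],
      resolution = stack$resolution, bin_side_um = bin_side_um
    )
  }
  counts <- vapply(
    stack$images,
    function(im) {
      m <- bin_median_nonzero(im$pixels, grid)
      as.integer(round_half_up(100 * m))
    },
    integer(grid$n_rows * grid$n_cols)
  )
  counts <- matrix(counts,
    ncol = length(stack$marker_order),
    dimnames = list(NULL, stack$marker_order)
  )
  structure(
    list(
      section_id = stack$section_id, group = stack$group, counts = counts,
      coords = grid$bins, marker_order = stack$marker_order, grid = grid
    ),
    class = "pseudo_counts"
  )
}

#' @export
print.pseudo_counts <- function(x, ...) {
  cat(
    "pseudo_counts '", x$section_id, "': ", nrow(x$counts), " bins x ",
    ncol(x$counts), " markers (", sum(is.na(x$counts)), " missing entries)\n",
    sep = ""
  )
  invisible(x)
}

#' Write / read a pseudo-count matrix as TSV
#'
#' The TSV holds `bin_row`, `bin_col`, `x_um`, `y_um` then one column per
#' marker with `NA` for missing bins; grid metadata goes to a JSON sidecar
#' next to the TSV.
#'
#' @param pc a `pseudo_counts`.
#' @param path output TSV path (sidecar written to `<path>.json`).
#' @export
write_pseudo_counts <- function(pc, path) {
  stopifnot(inherits(pc, "pseudo_counts"))
  tab <- cbind(pc$coords[, c("bin_row", "bin_col", "x_um", "y_um")], pc$counts)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    section_id = pc$section_id, group = pc$group,
    marker_order = pc$marker_order,
    bin_side_px = pc$grid$bin_side_px, n_rows = pc$grid$n_rows,
    n_cols = pc$grid$n_cols, resolution = pc$grid$resolution,
    bin_side_um = pc$grid$bin_side_um
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pseudo_counts
#' @param path path to a TSV written by [write_pseudo_counts()].
#' @return for `read_pseudo_counts`, the reconstructed `pseudo_counts`.
#' @export
read_pseudo_counts <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.delim(path, check.names = FALSE)
  grid <- compute_bin_grid(
    width_px = meta$n_cols * meta$bin_side_px,
    height_px = meta$n_rows * meta$bin_side_px,
    resolution = meta$resolution, bin_side_um = meta$bin_side_um
  )
  counts <- as.matrix(tab[, meta$marker_order, drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(
    list(
      section_id = meta$section_id, group = meta$group, counts = counts,
      coords = grid$bins, marker_order = meta$marker_order, grid = grid
    ),
    class = "pseudo_counts"
  )
}
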