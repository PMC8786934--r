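# Shared fixture builders: small in-code objects so no binary fixtures are
# needed on disk.

# Minimal pseudo_counts from a bare counts matrix (row-major square-ish grid).
make_pc <- function(counts, section_id = "S1", group = "A",
                    n_cols = NULL, resolution = 0.325, bin_side_um = 10) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("M", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  n_cols <- if (is.null(n_cols)) {
    nc <- floor(sqrt(n))
    while (n %% nc != 0) nc <- nc - 1
    nc
  } else {
    n_cols
  }
  b <- as.integer(round(bin_side_um / resolution))
  grid <- compute_bin_grid(n_cols * b, (n / n_cols) * b, resolution, bin_side_um)
  structure(
    list(
      section_id = section_id, group = group, counts = counts,
      coords = grid$bins, marker_order = colnames(counts), grid = grid
    ),
    class = "pseudo_counts"
  )
}

# Minimal binary_coding from a 0/1 matrix.
make_coding <- function(coding, section_id = "S1", group = "A") {
  coding <- as.matrix(coding)
  if (is.null(colnames(coding))) {
    colnames(coding) <- paste0("M", seq_len(ncol(coding)))
  }
  storage.mode(coding) <- "integer"
  pc <- make_pc(coding, section_id = section_id, group = group)
  structure(
    list(
      section_id = section_id, group = group, coding = coding,
      alpha_bin = 0.05, lambdas = NULL, coords = pc$coords,
      marker_order = colnames(coding)
    ),
    class = "binary_coding"
  )
}

# string_freqs from a sections x strings count matrix.
make_freqs <- function(counts, groups, marker_order) {
  structure(
    list(
      counts = as.matrix(counts), group = factor(groups),
      totals = rowSums(counts), marker_order = marker_order
    ),
    class = "string_freqs"
  )
}

# Independent brute-force pseudo-count oracle: explicit per-bin double loop.
brute_force_counts <- function(pixels, b) {
  nr <- nrow(pixels) %/% b
  nc <- ncol(pixels) %/% b
  out <- rep(NA_integer_, nr * nc)
  i <- 0L
  for (br in seq_len(nr)) {
    for (bc in seq_len(nc)) {
      i <- i + 1L
      block <- pixels[((br - 1) * b + 1):(br * b), ((bc - 1) * b + 1):(bc * b)]
      v <- block[block > 0]
      if (length(v) > 0) {
        out[i] <- as.integer(floor(round(100 * median(v), 9) + 0.5))
      }
    }
  }
  out
}

# Write a small grayscale TIFF and return its path.
tmp_tiff <- function(values, bits = 8L) {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(values, path, bits.per.sample = bits)
  path
}

# Tiny marker stack with constant-intensity images.
const_stack <- function(levels, nrow_px = 62, ncol_px = 62, section_id = "S1",
                        group = "A", resolution = 0.325) {
  imgs <- lapply(names(levels), function(m) {
    new_marker_image(m, matrix(levels[[m]], nrow_px, ncol_px), resolution)
  })
  assemble_stack(imgs, section_id, group)
}
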