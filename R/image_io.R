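# Reading, validating and assembling per-marker grayscale images.
#
# All markers of a section are assumed to have been aligned upstream (the
# acquisition pipeline registers staining rounds on the DAPI channel); this
# module only verifies that dimensions and resolution are consistent.

# Rec. 709 luminance weights used to collapse RGB rasters to grayscale.
.LUMA <- c(0.2126, 0.7152, 0.0722)

#' Load one marker image
#'
#' Reads a single-marker grayscale intensity image from TIFF. Multi-channel
#' (RGB/RGBA) rasters are collapsed to single-channel luminance. Integer pixel
#' types are rescaled to \[0, 1\] by the type maximum; floating-point inputs
#' must already lie in \[0, 1\] (values outside that range raise an error
#' rather than being clipped silently).
#'
#' @param path path to a TIFF file.
#' @param marker_name marker label attached to the image.
#' @param resolution micrometres per pixel (isotropic). Default 0.325, the
#'   native resolution of a 20x slide-scanner tile.
#' @return a `marker_image`: list with `marker_name`, `pixels` (matrix, rows =
#'   image y, cols = image x, values in \[0, 1\]) and `resolution`.
#' @export
load_marker_image <- function(path, marker_name, resolution = 0.325) {
  if (!file.exists(path)) {
    stop("cannot read marker image: file not found: ", path)
  }
  px <- tryCatch(
    tiff::readTIFF(path),
    error = function(e) stop("cannot decode TIFF '", path, "': ", conditionMessage(e))
  )
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3]
    if (nch < 3L) {
      px <- px[, , 1L] # gray + alpha
    } else {
      px <- .LUMA[1] * px[, , 1L] + .LUMA[2] * px[, , 2L] + .LUMA[3] * px[, , 3L]
    }
  }
  if (anyNA(px) || min(px) < 0 || max(px) > 1) {
    stop(
      "intensities outside [0,1] in '", path,
      "': floating-point images must be pre-normalized (no silent clipping)"
    )
  }
  new_marker_image(marker_name, px, resolution)
}

#' Construct a marker image from an in-memory matrix
#'
#' @param marker_name marker label.
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param resolution micrometres per pixel, > 0.
#' @return a `marker_image`.
#' @export
new_marker_image <- function(marker_name, pixels, resolution) {
  stopifnot(is.character(marker_name), length(marker_name) == 1L)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("pixels must be a matrix with dimensions >= 1x1")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0,1] for marker '", marker_name, "'")
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("resolution must be a positive scalar (micrometres per pixel)")
  }
  structure(
    list(marker_name = marker_name, pixels = pixels, resolution = resolution),
    class = "marker_image"
  )
}

#' Write a marker image to TIFF
#'
#' Inverse of [load_marker_image()] for 8/16-bit grayscale output; values are
#' quantized to the integer grid of the chosen bit depth, so a load/save/load
#' round trip of an integer-typed source is bit-exact.
#'
#' @param image a `marker_image`.
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @export
write_marker_image <- function(image, path, bits = 16L) {
  stopifnot(inherits(image, "marker_image"), bits %in% c(8L, 16L))
  tiff::writeTIFF(image$pixels, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Assemble the aligned marker stack for one section
#'
#' @param images list of `marker_image` objects for a single section.
#' @param section_id section identifier.
#' @param group case-group label (e.g. NSP/AD/PD).
#' @param marker_order canonical marker order used by all downstream matrices
#'   and strings; defaults to the order of `images`.
#' @return a `marker_stack`: list with `section_id`, `group`, `images` (named,
#'   in `marker_order`), `marker_order`, `dim` and `resolution`.
#' @export
assemble_stack <- function(images, section_id, group,
                           marker_order = vapply(images, `[[`, "", "marker_name")) {
  if (length(images) == 0L) {
    stop("design error: section '", section_id, "' has an empty marker list")
  }
  names(images) <- vapply(images, `[[`, "", "marker_name")
  if (anyDuplicated(names(images))) {
    stop("design error: duplicated marker names in section '", section_id, "'")
  }
  missing <- setdiff(marker_order, names(images))
  if (length(missing)) {
    stop(
      "design error: section '", section_id, "' is missing marker(s): ",
      paste(missing, collapse = ", ")
    )
  }
  marker_order <- unname(marker_order)
  images <- images[marker_order]
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  ref <- dims[, 1]
  bad <- which(dims[1, ] != ref[1] | dims[2, ] != ref[2])
  if (length(bad)) {
    stop(
      "alignment error in section '", section_id, "': marker(s) ",
      paste(marker_order[bad], collapse = ", "),
      " do not match the ", ref[1], "x", ref[2], " px reference dimensions"
    )
  }
  res <- vapply(images, `[[`, 0, "resolution")
  if (length(unique(res)) != 1L) {
    stop("alignment error in section '", section_id, "': markers differ in resolution")
  }
  structure(
    list(
      section_id = section_id, group = group, images = images,
      marker_order = marker_order,
      dim = c(height_px = ref[1], width_px = ref[2]),
      resolution = res[[1]]
    ),
    class = "marker_stack"
  )
}

#' @export
print.marker_stack <- function(x, ...) {
  cat(
    "marker_stack '", x$section_id, "' (group ", x$group, "): ",
    length(x$marker_order), " markers, ", x$dim[1], "x", x$dim[2], " px @ ",
    x$resolution, " um/px\n",
    sep = ""
  )
  invisible(x)
}

#' Read a cohort design table
#'
#' The design CSV has columns `section_id`, `group`, `marker`, `path`, one row
#' per (section, marker) image. Every section must provide a file for every
#' marker and each group must contain at least one section.
#'
#' @param path CSV file path.
#' @return a validated data.frame with the four design columns.
#' @export
read_cohort_design <- function(path) {
  design <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_design(design)
}

#' Validate a cohort design table
#'
#' @param design data.frame with columns `section_id`, `group`, `marker`,
#'   `path`.
#' @return the design, validated: every section provides every marker and no
#'   section sits in two groups (group-count requirements are checked by the
#'   statistical stages).
#' @export
validate_cohort_design <- function(design) {
  need <- c("section_id", "group", "marker", "path")
  if (!all(need %in% names(design))) {
    stop(
      "design error: design table must have columns ",
      paste(need, collapse = ", ")
    )
  }
  markers <- sort(unique(design$marker))
  by_sec <- split(design$marker, design$section_id)
  incomplete <- names(by_sec)[!vapply(by_sec, function(m) setequal(m, markers), TRUE)]
  if (length(incomplete)) {
    stop(
      "design error: section(s) missing marker files: ",
      paste(incomplete, collapse = ", ")
    )
  }
  grp <- unique(design[, c("section_id", "group")])
  if (anyDuplicated(grp$section_id)) {
    stop("design error: a section is listed under more than one group")
  }
  design
}

#' Load all stacks named in a cohort design
#'
#' @param design data.frame as returned by [read_cohort_design()].
#' @param marker_order canonical marker order; defaults to the order of first
#'   appearance in the design.
#' @param resolution micrometres per pixel for all images.
#' @return named list of `marker_stack`, one per section.
#' @export
load_cohort <- function(design, marker_order = unique(design$marker),
                        resolution = 0.325) {
  design <- validate_cohort_design(design)
  sections <- unique(design$section_id)
  stacks <- lapply(sections, function(sec) {
    rows <- design[design$section_id == sec, ]
    imgs <- Map(
      function(p, m) load_marker_image(p, m, resolution = resolution),
      rows$path, rows$marker
    )
    assemble_stack(unname(imgs), sec, rows$group[[1]], marker_order = marker_order)
  })
  names(stacks) <- sections
  stacks
}
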