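# Synthetic tissue phantoms: multi-marker image cohorts with known laminar
# geometry, focal structures, noise and group effects.
#
# The default geometry mimics the olfactory bulb's concentric lamination:
# an AON-like core wrapped by LOT-, GCL-, EPL- and GL-like annular bands,
# with layer marker signatures following the conserved olfactory-bulb
# signature table, glomerulus-like blobs in the outer band and vessel-like
# streaks. Per-section jitter of the band radii and random focal structures
# give sections realistic between-subject variability.

#' Conserved olfactory-bulb layer marker signatures
#'
#' The five-layer signature table used as the default phantom ground truth
#' and as the default input of [assign_layers()]: glomerular layer (OMP,
#' UEA-I lectin, PGP9.5, MAP2), external plexiform layer (GFAP,
#' synaptophysin), granule cell layer (DAPI, histones), lateral olfactory
#' tract (GFAP, S100, PGP9.5) and anterior olfactory nucleus (PGP9.5,
#' calbindin, synaptophysin).
#'
#' @return named list: layer -> character vector of signature markers.
#' @export
olfactory_bulb_signatures <- function() {
  list(
    AON = c("PGP9.5", "CALB", "SYP"),
    LOT = c("GFAP", "S100", "PGP9.5"),
    GCL = c("DAPI", "HIST"),
    EPL = c("GFAP", "SYP"),
    GL = c("OMP", "UEA.I", "PGP9.5", "MAP2")
  )
}

#' Phantom configuration
#'
#' Defines the study conditions of a synthetic cohort. Layers are concentric
#' annular bands, innermost first in `layer_order`, delimited by
#' `band_breaks` on the normalized radius (distance to the image centre over
#' half the image width; pixels beyond the last break belong to the outermost
#' layer). Signature markers take `signature_intensity` inside their layers
#' and `base_intensity` elsewhere; per-pixel Gaussian noise, dropout to exact
#' zero, and clipping to \[0, 1\] are applied after group effects.
#'
#' Group effects come in two forms: `group_intensity` rescales a marker's
#' mean multiplicatively (absolute brightness; largely cancelled by the
#' per-section Poisson thresholding), while `group_area` adds focal
#' high-expression discs covering a given fraction of the section, which is
#' what moves a marker's positive-bin fraction.
#'
#' @param seed master seed (mandatory); per-section sub-seeds derive from it.
#' @param image_px square image side in pixels.
#' @param resolution micrometres per pixel.
#' @param signatures layer signature table (innermost layer first is not
#'   required; `layer_order` controls geometry).
#' @param layer_order layer names innermost to outermost; must name entries of
#'   `signatures`.
#' @param band_breaks increasing normalized radii separating consecutive
#'   layers (length `length(layer_order) - 1`).
#' @param extra_markers markers carried in the panel without a layer (e.g. a
#'   pathology marker placed only via `planted`).
#' @param base_intensity,signature_intensity mean intensity outside/inside a
#'   marker's signature layers.
#' @param noise_sd per-pixel Gaussian noise SD.
#' @param dropout_prob probability a pixel is zeroed (below detection); a
#'   scalar, or a named vector giving per-marker probabilities (markers not
#'   named keep the `".default"` entry or 0).
#' @param band_jitter_sd per-section SD of additive jitter on `band_breaks`.
#' @param blobs list `n` (mean count, Poisson-distributed per section),
#'   `radius_px`, `layer`, `markers`, `intensity` for glomerulus-like foci;
#'   `NULL` for none.
#' @param streaks list `n`, `width_px`, `markers`, `intensity` for
#'   vessel-like lines; `NULL` for none.
#' @param groups group labels.
#' @param sections_per_group scalar or named vector of sections per group.
#' @param group_intensity named list: group -> named numeric multiplicative
#'   factors per marker.
#' @param group_area named list: group -> named numeric target fraction of the
#'   section covered by extra high-intensity discs per marker.
#' @param area_disc_radius_px radius of `group_area` discs.
#' @param planted optional focal co-occurrence plant: list `markers`,
#'   `layer` (band the discs are confined to), `area` (named numeric per
#'   group: fraction of that band's pixels covered), `intensity`,
#'   `disc_radius_px`.
#' @return a validated `phantom_config`.
#' @export
phantom_config <- function(seed,
                           image_px = 465L,
                           resolution = 0.325,
                           signatures = olfactory_bulb_signatures(),
                           layer_order = c("AON", "LOT", "GCL", "EPL", "GL"),
                           band_breaks = c(0.30, 0.50, 0.68, 0.84),
                           extra_markers = character(),
                           base_intensity = 0.08,
                           signature_intensity = 0.70,
                           noise_sd = 0.15,
                           dropout_prob = 0.05,
                           band_jitter_sd = 0.02,
                           blobs = list(
                             n = 6, radius_px = 20, layer = "GL",
                             markers = c("OMP", "MAP2", "UEA.I"), intensity = 0.85
                           ),
                           streaks = list(
                             n = 2, width_px = 3, markers = "UEA.I", intensity = 0.70
                           ),
                           groups = c("NSP", "AD", "PD"),
                           sections_per_group = 5L,
                           group_intensity = NULL,
                           group_area = NULL,
                           area_disc_radius_px = 15,
                           planted = NULL) {
  if (missing(seed)) stop("a master seed is mandatory for a phantom_config")
  stopifnot(
    image_px >= 1L, resolution > 0,
    setequal(names(signatures), union(names(signatures), layer_order)),
    all(layer_order %in% names(signatures)),
    length(band_breaks) == length(layer_order) - 1L,
    all(diff(band_breaks) > 0), all(band_breaks > 0)
  )
  ints <- c(
    base_intensity, signature_intensity,
    if (!is.null(blobs)) blobs$intensity,
    if (!is.null(streaks)) streaks$intensity,
    if (!is.null(planted)) planted$intensity
  )
  if (any(ints < 0 | ints > 1)) {
    stop("validation error: mean intensities must lie in [0,1]")
  }
  marker_order <- unique(c(unlist(signatures[layer_order], use.names = FALSE), extra_markers))
  if (length(sections_per_group) == 1L) {
    sections_per_group <- stats::setNames(rep(sections_per_group, length(groups)), groups)
  }
  stopifnot(setequal(names(sections_per_group), groups), all(sections_per_group >= 1L))
  if (!is.null(planted)) {
    planted$disc_radius_px <- planted$disc_radius_px %||% 15
    stopifnot(
      all(planted$markers %in% marker_order),
      planted$layer %in% layer_order,
      setequal(names(planted$area), groups)
    )
  }
  structure(
    list(
      seed = as.integer(seed), image_px = as.integer(image_px),
      resolution = resolution, signatures = signatures,
      layer_order = layer_order, band_breaks = band_breaks,
      marker_order = marker_order, base_intensity = base_intensity,
      signature_intensity = signature_intensity, noise_sd = noise_sd,
      dropout_prob = dropout_prob, band_jitter_sd = band_jitter_sd,
      blobs = blobs, streaks = streaks, groups = groups,
      sections_per_group = sections_per_group,
      group_intensity = group_intensity, group_area = group_area,
      area_disc_radius_px = area_disc_radius_px, planted = planted
    ),
    class = "phantom_config"
  )
}

# Deterministic 32-bit sub-seed for (master seed, section index).
section_seed <- function(seed, section_index) {
  as.integer((as.double(seed) * 48271 + section_index * 16807) %% 2147483647)
}

# Disc-union mask over candidate pixel positions: samples enough random disc
# centres (among `candidates`, linear indices) to cover ~`target_px` pixels,
# using the Poisson coverage formula for the expected union area.
disc_mask <- function(h, w, candidates, target_px, radius) {
  mask <- matrix(FALSE, h, w)
  if (target_px <= 0 || length(candidates) == 0L) {
    return(mask)
  }
  disc_area <- pi * radius^2
  frac <- min(target_px / length(candidates), 0.95)
  n_discs <- max(1L, ceiling(-log(1 - frac) * length(candidates) / disc_area))
  centers <- candidates[sample.int(length(candidates), n_discs, replace = TRUE)]
  cy <- (centers - 1L) %% h + 1L
  cx <- (centers - 1L) %/% h + 1L
  for (i in seq_len(n_discs)) {
    ys <- max(1L, cy[i] - radius):min(h, cy[i] + radius)
    xs <- max(1L, cx[i] - radius):min(w, cx[i] + radius)
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, `+`) <= radius^2
    mask[ys, xs] <- mask[ys, xs] | dd
  }
  mask
}

#' Generate one phantom section with ground truth
#'
#' Deterministic for a given `(config$seed, section_index)` pair; the group
#' label selects the group-level effects.
#'
#' @param config a `phantom_config`.
#' @param section_index integer index unique within the cohort.
#' @param group group label (must be one of `config$groups`).
#' @param section_id identifier for the resulting stack.
#' @return list with `stack` (a `marker_stack`) and `truth`: `layer_px`
#'   (integer matrix of layer indices into `config$layer_order`), `bin_layer`
#'   (majority layer name per grid bin), `bin_planted` (logical per bin: any
#'   overlap with the planted focal region), `true_positive_fraction` (per
#'   marker: fraction of bins whose noise-free median intensity exceeds the
#'   base/signature midpoint) and `grid`.
#' @export
generate_section <- function(config, section_index, group,
                             section_id = sprintf("%s_%02d", group, section_index)) {
  stopifnot(inherits(config, "phantom_config"), group %in% config$groups)
  with_seed(section_seed(config$seed, section_index), {
    n <- config$image_px
    half <- n / 2
    coord <- seq_len(n) - 0.5 # pixel centres
    r <- sqrt(outer((coord - half)^2, (coord - half)^2, `+`)) / half
    breaks <- sort(pmax(config$band_breaks + rnorm(
      length(config$band_breaks), 0, config$band_jitter_sd
    ), 0.01))
    layer_px <- matrix(
      findInterval(r, breaks) + 1L, n, n
    ) # 1 = innermost layer
    layer_px[layer_px > length(config$layer_order)] <- length(config$layer_order)

    in_sig_layer <- function(marker) {
      idx <- which(vapply(
        config$layer_order,
        function(ly) marker %in% config$signatures[[ly]], TRUE
      ))
      layer_px %in% idx
    }

    means <- lapply(config$marker_order, function(m) {
      mu <- matrix(config$base_intensity, n, n)
      mu[in_sig_layer(m)] <- config$signature_intensity
      mu
    })
    names(means) <- config$marker_order

    # glomerulus-like blobs confined to their band
    if (!is.null(config$blobs) && config$blobs$n > 0) {
      band_idx <- match(config$blobs$layer, config$layer_order)
      cand <- which(layer_px == band_idx)
      n_blob <- rpois(1L, config$blobs$n)
      if (n_blob > 0 && length(cand)) {
        bm <- disc_mask(
          n, n, cand,
          target_px = n_blob * pi * config$blobs$radius_px^2,
          radius = config$blobs$radius_px
        )
        for (m in intersect(config$blobs$markers, config$marker_order)) {
          means[[m]][bm] <- pmax(means[[m]][bm], config$blobs$intensity)
        }
      }
    }

    # vessel-like streaks: random lines through the section
    if (!is.null(config$streaks) && config$streaks$n > 0) {
      for (i in seq_len(config$streaks$n)) {
        x0 <- runif(1L, 0, n)
        y0 <- runif(1L, 0, n)
        th <- runif(1L, 0, pi)
        dline <- abs(
          outer(coord - y0, rep(1, n)) * cos(th) -
            outer(rep(1, n), coord - x0) * sin(th)
        )
        sm <- dline <= config$streaks$width_px / 2
        for (m in intersect(config$streaks$markers, config$marker_order)) {
          means[[m]][sm] <- pmax(means[[m]][sm], config$streaks$intensity)
        }
      }
    }

    # group-level extra high-expression area (moves positive-bin fractions)
    if (!is.null(config$group_area) && !is.null(config$group_area[[group]])) {
      ga <- config$group_area[[group]]
      for (m in names(ga)) {
        am <- disc_mask(
          n, n, seq_len(n * n),
          target_px = ga[[m]] * n * n,
          radius = config$area_disc_radius_px
        )
        means[[m]][am] <- pmax(means[[m]][am], config$signature_intensity)
      }
    }

    # planted focal co-occurrence region inside one band
    planted_mask <- matrix(FALSE, n, n)
    if (!is.null(config$planted)) {
      band_idx <- match(config$planted$layer, config$layer_order)
      cand <- which(layer_px == band_idx)
      planted_mask <- disc_mask(
        n, n, cand,
        target_px = config$planted$area[[group]] * length(cand),
        radius = config$planted$disc_radius_px
      )
      for (m in config$planted$markers) {
        means[[m]][planted_mask] <- pmax(means[[m]][planted_mask], config$planted$intensity)
      }
    }

    # multiplicative group intensity factors, then noise, dropout, clipping
    gi <- if (!is.null(config$group_intensity)) config$group_intensity[[group]] else NULL
    images <- lapply(config$marker_order, function(m) {
      mu <- means[[m]]
      if (!is.null(gi) && m %in% names(gi)) mu <- mu * gi[[m]]
      px <- mu
      if (config$noise_sd > 0) px <- px + rnorm(n * n, 0, config$noise_sd)
      dp <- config$dropout_prob
      if (!is.null(names(dp))) {
        dp <- if (m %in% names(dp)) {
          dp[[m]]
        } else if (".default" %in% names(dp)) {
          dp[[".default"]]
        } else {
          0
        }
      }
      if (dp > 0) {
        px[runif(n * n) < dp] <- 0
      }
      px <- pmin(pmax(px, 0), 1)
      new_marker_image(m, matrix(px, n, n), config$resolution)
    })
    stack <- assemble_stack(images, section_id, group,
      marker_order = config$marker_order
    )

    grid <- compute_bin_grid(n, n, config$resolution)
    bin_mode <- vapply(
      split_bins(layer_px, grid),
      function(v) as.integer(names(which.max(table(v)))), 0L
    )
    bin_layer <- config$layer_order[bin_mode]
    bin_planted <- vapply(split_bins(planted_mask, grid), any, TRUE)
    midpoint <- (config$base_intensity + config$signature_intensity) / 2
    tpf <- vapply(config$marker_order, function(m) {
      med <- vapply(split_bins(means[[m]], grid), median, 0)
      mean(med > midpoint)
    }, 0)
    truth <- list(
      layer_px = layer_px, bin_layer = bin_layer, bin_planted = bin_planted,
      true_positive_fraction = tpf, grid = grid
    )
    list(stack = stack, truth = truth)
  })
}

# Split a pixel matrix into per-bin value lists in the grid's row-major order.
split_bins <- function(pixels, grid) {
  b <- grid$bin_side_px
  hh <- grid$n_rows * b
  ww <- grid$n_cols * b
  px <- pixels[seq_len(hh), seq_len(ww), drop = FALSE]
  bin_id <- ((seq_len(hh) - 1L) %/% b) * grid$n_cols
  id <- outer(bin_id, (seq_len(ww) - 1L) %/% b, `+`)
  vals <- split(px, id)
  vals[order(as.integer(names(vals)))]
}

#' Generate a full phantom cohort
#'
#' Sections receive reproducible sub-seeds derived from the master seed; the
#' design table and all stacks plus ground truths are returned in memory (use
#' [write_cohort()] to materialize TIFFs and the design CSV).
#'
#' @param config a `phantom_config`.
#' @return a `phantom_cohort`: list with `design` (data.frame `section_id`,
#'   `group`), `stacks` (named list of `marker_stack`), `truths` (named list)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  idx <- 0L
  stacks <- list()
  truths <- list()
  design <- NULL
  for (g in config$groups) {
    for (i in seq_len(config$sections_per_group[[g]])) {
      idx <- idx + 1L
      sec <- generate_section(config, idx, g)
      sid <- sec$stack$section_id
      stacks[[sid]] <- sec$stack
      truths[[sid]] <- sec$truth
      design <- rbind(design, data.frame(section_id = sid, group = g))
    }
  }
  structure(
    list(design = design, stacks = stacks, truths = truths, config = config),
    class = "phantom_cohort"
  )
}

#' Write a phantom cohort to disk
#'
#' Materializes one 16-bit grayscale TIFF per marker per section, a design
#' CSV with columns `section_id`, `group`, `marker`, `path`, and one
#' ground-truth TSV per section (per-bin majority layer and planted flag).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @return the path of the design CSV.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sid in names(cohort$stacks)) {
    stack <- cohort$stacks[[sid]]
    for (m in stack$marker_order) {
      path <- file.path(dir, paste0(sid, "_", gsub("[^A-Za-z0-9]", "", m), ".tif"))
      write_marker_image(stack$images[[m]], path, bits = 16L)
      rows[[length(rows) + 1L]] <- data.frame(
        section_id = sid, group = stack$group, marker = m, path = path
      )
    }
    truth <- cohort$truths[[sid]]
    tt <- cbind(
      truth$grid$bins[, c("bin_row", "bin_col")],
      layer = truth$bin_layer, planted = truth$bin_planted
    )
    write.table(tt, file.path(dir, paste0(sid, "_truth.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  design <- do.call(rbind, rows)
  out <- file.path(dir, "design.csv")
  write.csv(design, out, row.names = FALSE)
  out
}
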