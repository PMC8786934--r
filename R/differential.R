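# Poisson thresholding of pseudo-count bins and by-marker group tests.
#
# Thresholding is self-calibrating per section: each marker's rate parameter
# is its own trimmed mean across that section's bins, so absolute intensity
# differences between sections (staining round, exposure) cancel out and only
# the relative spatial enrichment of a marker drives the coding.

#' Per-marker trimmed-mean Poisson rate
#'
#' For each marker, the trimmed mean of the non-missing pseudo-counts in one
#' section: `floor(trim * n)` smallest and largest values are dropped before
#' averaging (the behaviour of `mean(x, trim = )`).
#'
#' @param pc a `pseudo_counts`.
#' @param trim trim fraction in \[0, 0.5); default 0.05.
#' @return named numeric vector of rates (one per marker) with attribute
#'   `trim`.
#' @export
trimmed_mean_lambda <- function(pc, trim = 0.05) {
  stopifnot(inherits(pc, "pseudo_counts"), trim >= 0, trim < 0.5)
  lam <- vapply(pc$marker_order, function(m) {
    x <- pc$counts[, m]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(NA_real_)
    }
    mean(x, trim = trim)
  }, 0)
  if (anyNA(lam)) {
    stop(
      "rate undefined: marker(s) with no non-missing bins: ",
      paste(pc$marker_order[is.na(lam)], collapse = ", ")
    )
  }
  attr(lam, "trim") <- trim
  lam
}

#' Strict Poisson upper-tail probability
#'
#' `P(X > count)` for `X ~ Poisson(lambda)` — the probability of exceeding the
#' observed pseudo-count under the section's background rate.
#'
#' @param count non-negative integer vector of pseudo-counts.
#' @param lambda non-negative rate(s), recycled against `count`.
#' @return upper-tail probabilities in \[0, 1\].
#' @export
#' @examples
#' poisson_upper_tail(0, 1) # 1 - exp(-1)
poisson_upper_tail <- function(count, lambda) {
  stopifnot(all(count >= 0, na.rm = TRUE), all(lambda >= 0))
  ppois(count, lambda, lower.tail = FALSE)
}

#' Code bins as marker-positive or -negative
#'
#' A bin is coded 1 for a marker iff its strict Poisson upper-tail probability
#' under that marker's section rate is below `alpha_bin`; missing pseudo-counts
#' (all-zero bins) code to 0.
#'
#' @param pc a `pseudo_counts`.
#' @param lambdas rates from [trimmed_mean_lambda()] on the same matrix;
#'   computed on the fly if omitted.
#' @param alpha_bin strict threshold on the upper-tail probability
#'   (default 0.05).
#' @param trim trim fraction used when `lambdas` is omitted.
#' @return a `binary_coding`: list with `section_id`, `group`, `coding`
#'   (integer 0/1 matrix, bins x markers), `alpha_bin`, `lambdas`, `coords`
#'   and `marker_order`.
#' @export
code_bins <- function(pc, lambdas = NULL, alpha_bin = 0.05, trim = 0.05) {
  stopifnot(inherits(pc, "pseudo_counts"), alpha_bin > 0, alpha_bin < 1)
  if (is.null(lambdas)) lambdas <- trimmed_mean_lambda(pc, trim = trim)
  stopifnot(setequal(names(lambdas), pc$marker_order))
  coding <- vapply(pc$marker_order, function(m) {
    p <- poisson_upper_tail(pc$counts[, m], lambdas[[m]])
    out <- as.integer(!is.na(p) & p < alpha_bin)
    out
  }, integer(nrow(pc$counts)))
  coding <- matrix(coding,
    ncol = length(pc$marker_order),
    dimnames = list(NULL, pc$marker_order)
  )
  structure(
    list(
      section_id = pc$section_id, group = pc$group, coding = coding,
      alpha_bin = alpha_bin, lambdas = lambdas, coords = pc$coords,
      marker_order = pc$marker_order
    ),
    class = "binary_coding"
  )
}

#' Positive-bin ratios per section and marker
#'
#' For each section, the number of bins coded 1 per marker divided by the
#' total number of grid bins of that section (missing bins stay in the
#' denominator).
#'
#' @param codings list of `binary_coding`, one per section.
#' @return a `ratio_table`: list with `ratios` (sections x markers numeric
#'   matrix in \[0, 1\]), `group` (factor per section) and `marker_order`.
#' @export
label_ratios <- function(codings) {
  stopifnot(length(codings) >= 1L)
  mo <- codings[[1L]]$marker_order
  ok <- vapply(codings, function(cd) identical(cd$marker_order, mo), TRUE)
  if (!all(ok)) stop("sections disagree on marker_order")
  vals <- vapply(
    codings,
    function(cd) colSums(cd$coding) / nrow(cd$coding),
    numeric(length(mo))
  )
  ratios <- if (length(mo) == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(ratios) <- list(
    vapply(codings, `[[`, "", "section_id"), mo
  )
  structure(
    list(
      ratios = ratios,
      group = factor(vapply(codings, `[[`, "", "group")),
      marker_order = mo
    ),
    class = "ratio_table"
  )
}

#' One-way ANOVA per marker with BH correction and Tukey HSD
#'
#' Tests each marker's positive-bin ratios for differences across case groups.
#' Raw p-values are corrected across markers by Benjamini-Hochberg; Tukey HSD
#' (Tukey-Kramer under unequal group sizes) gives pairwise group differences.
#' A marker is flagged differential when its uncorrected p-value is below
#' `alpha_label` (0.10 by default); set `flag_on = "adjusted"` to flag on the
#' BH-adjusted p instead.
#'
#' @param ratios a `ratio_table`.
#' @param alpha_label flag threshold (strict), default 0.10.
#' @param flag_on `"raw"` (default) or `"adjusted"`.
#' @return a `differential_result`: list with `table` (per marker: `F`, `df1`,
#'   `df2`, `p`, `p_bh`, `testable`, `differential`), `tukey` (named list of
#'   pairwise data.frames with `comparison`, `diff`, `lwr`, `upr`, `p_adj`)
#'   and the thresholds used.
#' @export
anova_by_label <- function(ratios, alpha_label = 0.10, flag_on = c("raw", "adjusted")) {
  stopifnot(inherits(ratios, "ratio_table"))
  flag_on <- match.arg(flag_on)
  grp <- ratios$group
  if (nlevels(droplevels(grp)) < 2L) stop("at least two groups are required")
  res <- lapply(ratios$marker_order, function(m) {
    r <- ratios$ratios[, m]
    fit <- aov(r ~ grp)
    # anova() warns on essentially perfect fits; degenerate layouts are
    # resolved explicitly from the sums of squares below
    tab <- suppressWarnings(anova(fit))
    fval <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
    ssb <- tab[["Sum Sq"]][1L]
    ssw <- tab[["Sum Sq"]][2L]
    tot <- ssb + ssw
    if (tot < 1e-20 * max(1, sum(r^2))) {
      # no variance anywhere: undefined, never p = 0
      fval <- NA_real_
      p <- NA_real_
      testable <- FALSE
    } else if (ssw < 1e-12 * tot) {
      # zero residual variance with distinct group means: perfect separation
      fval <- Inf
      p <- 0
      testable <- TRUE
    } else {
      testable <- is.finite(fval)
    }
    tk <- tryCatch(
      {
        t0 <- TukeyHSD(fit)$grp
        data.frame(
          comparison = rownames(t0), diff = t0[, "diff"], lwr = t0[, "lwr"],
          upr = t0[, "upr"], p_adj = t0[, "p adj"], row.names = NULL
        )
      },
      error = function(e) NULL
    )
    list(
      row = data.frame(
        marker = m, F = fval, df1 = tab$Df[1L], df2 = tab$Df[2L],
        p = p, testable = testable
      ),
      tukey = tk
    )
  })
  table <- do.call(rbind, lapply(res, `[[`, "row"))
  table$p[!table$testable] <- NA_real_
  table$p_bh <- p.adjust(table$p, method = "BH")
  pflag <- if (flag_on == "raw") table$p else table$p_bh
  table$differential <- !is.na(pflag) & pflag < alpha_label
  tukey <- lapply(res, `[[`, "tukey")
  names(tukey) <- table$marker
  structure(
    list(
      table = table, tukey = tukey,
      alpha_label = alpha_label, flag_on = flag_on
    ),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  cat(
    "differential_result: ", sum(x$table$differential), " of ",
    nrow(x$table), " markers flagged at ", x$flag_on, " p < ",
    x$alpha_label, "\n",
    sep = ""
  )
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Covariance-based PCA of case ratio profiles
#'
#' Principal components of the sections x markers positive-bin-ratio matrix,
#' centred but not variance-scaled (covariance PCA). By default only markers
#' flagged differential are used, mirroring the screening-then-ordination
#' workflow.
#'
#' @param ratios a `ratio_table`.
#' @param differential a `differential_result`; when supplied together with
#'   `differential_only = TRUE`, restricts the PCA to flagged markers.
#' @param differential_only use only flagged markers (default `TRUE` when
#'   `differential` is given).
#' @return list with `scores` (data.frame: `section_id`, `group`, `PC1`,
#'   `PC2`), `explained` (variance fractions of PC1/PC2), `markers` used and
#'   the full `prcomp` object.
#' @export
case_pca <- function(ratios, differential = NULL, differential_only = !is.null(differential)) {
  stopifnot(inherits(ratios, "ratio_table"))
  if (nrow(ratios$ratios) < 3L) stop("case PCA requires at least 3 sections")
  markers <- ratios$marker_order
  if (differential_only) {
    if (is.null(differential)) stop("differential result required to subset flagged markers")
    markers <- differential$table$marker[differential$table$differential]
    if (length(markers) == 0L) stop("no differential markers to ordinate")
  }
  x <- ratios$ratios[, markers, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- matrix(0, nrow(x), 2L, dimnames = list(NULL, c("PC1", "PC2")))
  scores[, seq_len(k)] <- pc$x[, seq_len(k)]
  tot <- sum(pc$sdev^2)
  explained <- if (tot > 0) (pc$sdev^2 / tot)[seq_len(k)] else rep(0, k)
  list(
    scores = data.frame(
      section_id = rownames(ratios$ratios),
      group = as.character(ratios$group),
      PC1 = scores[, 1L], PC2 = scores[, 2L]
    ),
    explained = explained, markers = markers, pca = pc
  )
}
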