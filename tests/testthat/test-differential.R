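# Trimmed-mean rates, Poisson coding, positive-bin ratios and the by-marker
# ANOVA screen.

test_that("trimmed mean drops floor(trim * n) order statistics per side", {
  pc <- make_pc(cbind(A = 1:10, B = 1:10 * 0L + 7L), n_cols = 5)
  lam <- trimmed_mean_lambda(pc, trim = 0.05)
  expect_equal(unname(lam["A"]), 5.5) # floor(0.5) = 0 dropped
  expect_equal(unname(lam["B"]), 7)

  pc20 <- make_pc(cbind(A = 1:20), n_cols = 5)
  expect_equal(unname(trimmed_mean_lambda(pc20, 0.05)["A"]), mean(2:19)) # 10.5

  pc_na <- make_pc(cbind(A = c(NA, NA, NA, NA), B = c(1L, 2L, 3L, 4L)), n_cols = 2)
  expect_error(trimmed_mean_lambda(pc_na), "A")
})

test_that("Poisson upper tail matches term-by-term pmf summation", {
  expect_equal(poisson_upper_tail(0, 0), 0)
  expect_equal(poisson_upper_tail(0, 1), 1 - exp(-1), tolerance = 1e-12)

  # independent oracle: cumulative pmf via the series lambda^k e^-lambda / k!
  oracle <- function(count, lambda) {
    if (lambda == 0) {
      return(0)
    }
    k <- 0:count
    1 - sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
  }
  expect_equal(poisson_upper_tail(5, 5), oracle(5, 5), tolerance = 1e-10)
  expect_equal(oracle(5, 5), 0.384039, tolerance = 1e-6)

  set.seed(3)
  for (i in 1:50) {
    lam <- runif(1, 0, 50)
    ct <- rpois(1, lam)
    expect_equal(poisson_upper_tail(ct, lam), oracle(ct, lam), tolerance = 1e-10)
  }
})

test_that("bin coding is strict at alpha and missing codes to zero", {
  counts <- cbind(A = c(5L, 9L, NA, 0L))
  pc <- make_pc(counts, n_cols = 2)
  lam <- c(A = 4)
  p5 <- poisson_upper_tail(5, 4)
  # alpha exactly equal to the attained p: strict inequality keeps the bin 0
  cd_eq <- code_bins(pc, lambdas = lam, alpha_bin = p5)
  expect_identical(unname(cd_eq$coding[1, "A"]), 0L)
  cd_above <- code_bins(pc, lambdas = lam, alpha_bin = p5 + 1e-12)
  expect_identical(unname(cd_above$coding[1, "A"]), 1L)
  expect_identical(unname(cd_eq$coding[3, "A"]), 0L) # NA -> 0
})

test_that("coding is monotone in the pseudo-count for fixed lambda", {
  pc <- make_pc(cbind(A = as.integer(0:99)), n_cols = 10)
  cd <- code_bins(pc, lambdas = c(A = 20), alpha_bin = 0.05)
  expect_true(all(diff(cd$coding[, "A"]) >= 0))
  # a flat section at its own rate never codes positive
  pc_flat <- make_pc(cbind(A = rep(50L, 100)), n_cols = 10)
  cd_flat <- code_bins(pc_flat, alpha_bin = 0.05)
  expect_true(all(cd_flat$coding == 0L))
})

test_that("positive-bin ratios use the full grid as denominator", {
  cd1 <- make_coding(cbind(A = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)), "S1", "g1")
  cd2 <- make_coding(cbind(A = rep(0L, 10)), "S2", "g2")
  cd3 <- make_coding(cbind(A = rep(1L, 10)), "S3", "g2")
  rt <- label_ratios(list(cd1, cd2, cd3))
  expect_equal(unname(rt$ratios[, "A"]), c(0.3, 0, 1))
  expect_identical(levels(rt$group), c("g1", "g2"))
})

test_that("per-marker ANOVA matches the closed-form sums of squares", {
  r <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("A", "B", "C"), each = 3)
  rt <- structure(
    list(
      ratios = matrix(r / 10,
        ncol = 1,
        dimnames = list(paste0("S", 1:9), "M")
      ),
      group = factor(g), marker_order = "M"
    ),
    class = "ratio_table"
  )
  res <- anova_by_label(rt)
  # closed-form oracle
  x <- r / 10
  grand <- mean(x)
  ssb <- 3 * sum((tapply(x, g, mean) - grand)^2)
  ssw <- sum((x - ave(x, g))^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$table$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$table$F, 3.0, tolerance = 1e-10)
  expect_identical(c(res$table$df1, res$table$df2), c(2L, 6L))
  expect_equal(res$table$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_false(res$table$differential) # p ~ 0.125 > 0.10

  # Tukey HSD against the textbook Tukey-Kramer interval
  tk <- res$tukey$M
  mse <- ssw / 6
  qcrit <- qtukey(0.95, nmeans = 3, df = 6)
  half <- qcrit * sqrt(mse / 2 * (1 / 3 + 1 / 3))
  expect_equal(tk$diff[tk$comparison == "B-A"], 0.1, tolerance = 1e-10)
  expect_equal(tk$upr - tk$diff, rep(half, 3), tolerance = 1e-10)
})

test_that("degenerate layouts are reported, not misreported", {
  # identical group means with spread: F = 0, p = 1
  rt <- structure(
    list(
      ratios = matrix(c(0.1, 0.3, 0.1, 0.3, 0.1, 0.3) / 1,
        ncol = 1, dimnames = list(paste0("S", 1:6), "M")
      ),
      group = factor(rep(c("A", "B", "C"), each = 2)), marker_order = "M"
    ),
    class = "ratio_table"
  )
  res <- anova_by_label(rt)
  expect_equal(res$table$F, 0, tolerance = 1e-12)
  expect_equal(res$table$p, 1, tolerance = 1e-12)

  # zero variance everywhere: untestable, never p = 0
  rt0 <- rt
  rt0$ratios[] <- 0.5
  res0 <- anova_by_label(rt0)
  expect_false(res0$table$testable)
  expect_true(is.na(res0$table$p))
  expect_false(res0$table$differential)
})

test_that("BH adjustment follows the step-up formula and dominates raw p", {
  # oracle: adjusted_i = min over j >= i of p_(j) * m / j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in rank
  }
})

test_that("case PCA is covariance-based and separates distinct profiles", {
  ratios <- rbind(
    matrix(rep(c(0.1, 0.5), each = 4), 4), # group A: marker1 low
    matrix(rep(c(0.4, 0.5), each = 4), 4) # group B: marker1 high
  )
  colnames(ratios) <- c("M1", "M2")
  rownames(ratios) <- paste0("S", 1:8)
  rt <- structure(
    list(
      ratios = ratios, group = factor(rep(c("A", "B"), each = 4)),
      marker_order = c("M1", "M2")
    ),
    class = "ratio_table"
  )
  out <- case_pca(rt, differential_only = FALSE)
  pc1_a <- out$scores$PC1[out$scores$group == "A"]
  pc1_b <- out$scores$PC1[out$scores$group == "B"]
  expect_true(max(pc1_a) < min(pc1_b) || min(pc1_a) > max(pc1_b))
  expect_equal(out$explained[1], 1) # all variance on the M1 axis

  rt_const <- rt
  rt_const$ratios[] <- 0.2
  out0 <- case_pca(rt_const, differential_only = FALSE)
  expect_true(all(abs(c(out0$scores$PC1, out0$scores$PC2)) < 1e-12))

  rt2 <- rt
  rt2$ratios <- rt2$ratios[1:2, , drop = FALSE]
  rt2$group <- rt2$group[1:2]
  expect_error(case_pca(rt2, differential_only = FALSE), "at least 3")
})
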