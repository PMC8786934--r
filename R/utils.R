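# Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; pseudo-counts use the conventional
#' "round half up" rule for non-negative values so that e.g. `0.305 * 100`
#' becomes 31. Inputs are first snapped to 9 decimals so that binary
#' representation noise (e.g. `100 * 0.305 = 30.49999...96`) cannot push an
#' exact decimal half below the rounding boundary.
#'
#' @param x numeric vector, non-negative.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(round(x, 9) + 0.5)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score recovered clusters against ground-truth layer labels.
#'
#' @param a,b vectors of labels of equal length (any type coercible to factor).
#' @return a scalar in \[-1, 1\]; 1 means identical partitions up to renaming.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
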