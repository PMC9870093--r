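#' Two-sample Wilcoxon rank-sum test
#'
#' Self-contained rank-sum test shared by the marker-detection and
#' time-course modules. The statistic `W` is the sum of pooled ranks
#' (midranks for ties) of the first sample. For small tie-free problems
#' (pooled n at most `exact_limit`) the permutation distribution of `W` is
#' enumerated exactly and the two-sided p-value doubles the smaller tail
#' (capped at 1); otherwise a normal approximation with tie-corrected
#' variance and optional continuity correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param exact_limit Largest pooled sample size for which the tie-free
#'   permutation distribution is enumerated (default 12).
#' @return An object of class `rank_sum_result`: a list with `statistic`
#'   (rank sum of `x`), `p_value`, `method` (`"exact"` or
#'   `"normal-approximation"`), `n1`, `n2`, and `tie_correction`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))
#' @export
rank_sum_test <- function(x, y, continuity = TRUE, exact_limit = 12L) {
  if (length(x) < 1 || length(y) < 1) {
    abort("Both samples must be non-empty.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Samples must be finite numeric vectors.")
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && n <= exact_limit) {
    # exact: enumerate every C(n, n1) assignment of ranks 1..n to sample 1
    sets <- combn(n, n1)
    wdist <- colSums(matrix(seq_len(n)[sets], nrow = n1))
    p <- min(1, 2 * min(mean(wdist <= w), mean(wdist >= w)))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - if (continuity) 0.5 else 0) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal-approximation"
  }

  structure(
    list(
      statistic = w, p_value = p, method = method,
      n1 = n1, n2 = n2, tie_correction = has_ties
    ),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum test (%s)\n  W = %g, n = %d vs %d, p = %.4g%s\n",
    x$method, x$statistic, x$n1, x$n2, x$p_value,
    if (x$tie_correction) " (tie-corrected)" else ""
  ))
  invisible(x)
}

#' @rdname rank_sum_test
#' @param x A `rank_sum_result`.
#' @param ... Unused.
#' @export
tidy.rank_sum_result <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value, method = x$method,
    n1 = x$n1, n2 = x$n2, tie_correction = x$tie_correction
  )
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size `m` and caps at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values, same length as `p_values`.
#' @examples
#' bonferroni(c(0.01, 0.4), m = 5)
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  check_count_scalar(m, "m", min = 1L)
  pmin(1, p_values * m)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector.
#' @return A one-row tibble with `mean`, `sem` (sample sd over sqrt(n);
#'   `NA` with a warning when n < 2), and `n`.
#' @examples
#' mean_sem(c(0.1, 0.2, 0.3))
#' @export
mean_sem <- function(values) {
  if (!is.numeric(values) || length(values) < 1 || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector.")
  }
  n <- length(values)
  if (n < 2) {
    warn("SEM is undefined for fewer than 2 values; returning NA.")
    sem <- NA_real_
  } else {
    sem <- sd(values) / sqrt(n)
  }
  tibble(mean = mean(values), sem = sem, n = n)
}
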