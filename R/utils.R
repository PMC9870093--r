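# internal helpers shared across modules

# counts must be a genes x barcodes matrix of non-negative integers with
# unique dimnames; every public entry point funnels through here
check_counts <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric genes x barcodes matrix.", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must carry gene rownames and barcode colnames.", arg))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort(sprintf("`%s` has duplicated gene or barcode identifiers.", arg))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort(sprintf("`%s` must contain non-negative integer counts.", arg))
  }
  invisible(counts)
}

check_prob_vector <- function(p, arg, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1 || any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be a non-negative finite numeric vector.", arg))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", arg, sum(p)))
  }
  invisible(p)
}

check_scalar <- function(x, arg, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", arg))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", arg))
  invisible(x)
}

check_count_scalar <- function(x, arg, min = 0L) {
  check_scalar(x, arg, positive = FALSE)
  if (x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", arg, min))
  }
  invisible(as.integer(x))
}

# seed-scoped evaluation: all generator randomness flows from one explicit
# seed and the caller's RNG state is untouched
with_sim_seed <- function(seed, code) {
  check_count_scalar(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}
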