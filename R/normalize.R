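#' Log-normalize a count matrix
#'
#' Scales each cell's counts to a common library size and log-transforms:
#' `value = ln(1 + count / cell_total * scale_factor)`. This is the
#' standard normalization for UMI matrices; the default scale factor is
#' 10,000.
#'
#' @param counts Genes x cells integer count matrix; every cell must have a
#'   positive total.
#' @param scale_factor Target library size (default 10000).
#' @return A genes x cells numeric matrix with attribute `scale_factor`.
#' @examples
#' m <- matrix(c(1L, 1L), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
#' log_normalize(m) # both entries ln(5001)
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  check_counts(counts)
  check_scalar(scale_factor, "scale_factor")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    abort(sprintf(
      "Cell(s) with zero total counts cannot be normalized (e.g. %s).",
      colnames(counts)[which(totals == 0)[1]]
    ))
  }
  out <- log1p(sweep(counts, 2, totals, "/") * scale_factor)
  attr(out, "scale_factor") <- scale_factor
  out
}
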