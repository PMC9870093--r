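#' Rank barcodes by total UMI count
#'
#' Sorts barcodes in descending order of their total UMI counts, breaking
#' ties lexicographically by barcode identifier, and keeps the top
#' `max_barcodes` (mirroring the 5,000 core barcodes typically exported
#' from a droplet library).
#'
#' @param counts Genes x barcodes integer count matrix with dimnames.
#' @param max_barcodes Number of top-ranked barcodes to keep (default 5000).
#' @return A tibble with `barcode`, `total`, `rank`, sorted by rank.
#' @examples
#' m <- matrix(c(10, 30, 20), nrow = 1,
#'             dimnames = list("g1", c("A", "B", "C")))
#' rank_barcodes(m)
#' @export
rank_barcodes <- function(counts, max_barcodes = 5000L) {
  check_counts(counts)
  max_barcodes <- check_count_scalar(max_barcodes, "max_barcodes", min = 1L)
  totals <- colSums(counts)
  if (sum(totals) == 0) {
    abort("All counts are zero: nothing to rank.")
  }
  ord <- order(-totals, colnames(counts), method = "radix")
  keep <- head(ord, max_barcodes)
  tibble(
    barcode = colnames(counts)[keep],
    total = unname(totals[keep]),
    rank = seq_along(keep)
  )
}

#' Classify barcodes as cells or ambient background
#'
#' Implements slope-based cell calling on the cumulative-read-fraction
#' curve: barcodes are ranked by total UMIs, the pointwise slope of the
#' cumulative fraction at rank i (with unit rank spacing) is that barcode's
#' share of the total, `total_i / grand_total`, and the average slope over
#' the N barcodes considered is therefore exactly `1/N`. Barcodes whose
#' slope is below the average are called background; barcodes at or above
#' it are called cells. Equivalently, a barcode is a cell iff its total is
#' at least the mean total of the barcodes considered.
#'
#' @inheritParams rank_barcodes
#' @return A `barcode_classification` tibble with `barcode`, `total`,
#'   `rank`, `slope`, `label` (`"cell"`/`"background"`), plus attributes
#'   `average_slope` and `max_barcodes_used`.
#' @examples
#' m <- matrix(c(100, 50, 30, 10, 5, 5), nrow = 1,
#'             dimnames = list("g1", paste0("BC", 1:6)))
#' classify_barcodes(m)
#' @export
classify_barcodes <- function(counts, max_barcodes = 5000L) {
  ranked <- rank_barcodes(counts, max_barcodes)
  if (nrow(ranked) < 2) {
    abort("At least 2 barcodes are required to classify.")
  }
  grand_total <- sum(ranked$total)
  out <- dplyr::mutate(
    ranked,
    slope = .data$total / grand_total,
    label = ifelse(.data$slope >= 1 / dplyr::n(), "cell", "background")
  )
  structure(
    out,
    average_slope = 1 / nrow(out),
    max_barcodes_used = nrow(out),
    class = c("barcode_classification", class(out))
  )
}

#' @export
print.barcode_classification <- function(x, ...) {
  cat(sprintf(
    "Barcode classification: %d cells / %d background (average slope %.3g)\n",
    sum(x$label == "cell"), sum(x$label == "background"),
    attr(x, "average_slope")
  ))
  NextMethod()
}

#' @rdname classify_barcodes
#' @param x A `barcode_classification`.
#' @param ... Unused.
#' @export
glance.barcode_classification <- function(x, ...) {
  tibble(
    n_cells = sum(x$label == "cell"),
    n_background = sum(x$label == "background"),
    average_slope = attr(x, "average_slope"),
    max_barcodes_used = attr(x, "max_barcodes_used")
  )
}

#' @rdname classify_barcodes
#' @param object A `barcode_classification`.
#' @method autoplot barcode_classification
#' @export
autoplot.barcode_classification <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$total,
                                       colour = .data$label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Barcode rank", y = "Total UMIs", colour = NULL,
                  title = "Barcode-rank curve") +
    ggplot2::theme_classic()
}

#' Fit the per-gene ambient background model
#'
#' For each gene, records the nearest-rank 95th-percentile UMI count (order
#' statistic at `ceiling(quantile_level * n_background)`) across the
#' barcodes labeled background. These integer thresholds model ambient RNA
#' and are later subtracted from the count matrix.
#'
#' @inheritParams rank_barcodes
#' @param classification A [classify_barcodes()] result.
#' @param quantile_level Quantile of the background distribution to record,
#'   in (0, 1); default 0.95.
#' @return A `background_model` tibble with `gene` and integer `threshold`,
#'   plus attributes `quantile_level` and `n_background_barcodes`.
#' @export
fit_background_model <- function(counts, classification,
                                 quantile_level = 0.95) {
  check_counts(counts)
  if (!inherits(classification, "barcode_classification")) {
    abort("`classification` must come from classify_barcodes().")
  }
  check_scalar(quantile_level, "quantile_level")
  if (quantile_level >= 1) abort("`quantile_level` must lie in (0, 1).")
  bg <- classification$barcode[classification$label == "background"]
  bg <- intersect(bg, colnames(counts))
  if (length(bg) == 0) {
    abort(paste(
      "No background barcodes: ambient subtraction is undefined.",
      "Check the classification or lower `max_barcodes`."
    ))
  }
  k <- ceiling(quantile_level * length(bg))
  sub <- counts[, bg, drop = FALSE]
  thresholds <- apply(sub, 1, function(v) sort(v)[k])
  structure(
    tibble(gene = rownames(counts), threshold = as.integer(thresholds)),
    quantile_level = quantile_level,
    n_background_barcodes = length(bg),
    class = c("background_model", "tbl_df", "tbl", "data.frame")
  )
}

#' Subtract ambient background and keep cell barcodes
#'
#' Subtracts each gene's background threshold from every barcode's counts,
#' floors negatives at zero, and then restricts the matrix to the barcodes
#' labeled as cells.
#'
#' @inheritParams fit_background_model
#' @param background A [fit_background_model()] result covering every gene
#'   of `counts`.
#' @return The corrected genes x cells integer matrix.
#' @export
subtract_background <- function(counts, background, classification) {
  check_counts(counts)
  if (!inherits(background, "background_model")) {
    abort("`background` must come from fit_background_model().")
  }
  if (!inherits(classification, "barcode_classification")) {
    abort("`classification` must come from classify_barcodes().")
  }
  idx <- match(rownames(counts), background$gene)
  if (anyNA(idx)) {
    abort(sprintf(
      "Background model lacks %d gene(s) present in the matrix (e.g. %s).",
      sum(is.na(idx)), rownames(counts)[which(is.na(idx))[1]]
    ))
  }
  corrected <- counts - background$threshold[idx]
  corrected[corrected < 0] <- 0L
  storage.mode(corrected) <- "integer"
  cells <- classification$barcode[classification$label == "cell"]
  cells <- intersect(colnames(counts), cells)
  corrected[, cells, drop = FALSE]
}

#' One-call droplet preprocessing
#'
#' Runs [classify_barcodes()], [fit_background_model()], and
#' [subtract_background()] in sequence.
#'
#' @inheritParams rank_barcodes
#' @inheritParams fit_background_model
#' @return A list with `counts` (corrected cell-only matrix),
#'   `classification`, and `background`.
#' @export
preprocess_droplets <- function(counts, max_barcodes = 5000L,
                                quantile_level = 0.95) {
  classification <- classify_barcodes(counts, max_barcodes)
  background <- fit_background_model(counts, classification, quantile_level)
  list(
    counts = subtract_background(counts, background, classification),
    classification = classification,
    background = background
  )
}
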