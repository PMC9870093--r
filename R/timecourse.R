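# histogram Otsu over a 1-D intensity vector (used to pick the
# marker-positivity cutoff over candidate nuclei); maximizes between-class
# variance over histogram split points
otsu_threshold <- function(x, n_bins = 256L) {
  if (length(x) < 2 || max(x) <= min(x)) return(max(x))
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu_t <- sum(p * mids)
  mu0 <- cumsum(p * mids)
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # empty bins between modes form a plateau; take its middle, as canonical
  # Otsu implementations do
  mean(mids[between == max(between)])
}

#' Per-animal fraction of marker-positive nuclei
#'
#' For one animal's set of images: nuclei are segmented from DAPI, the
#' candidate (denominator) nuclei are those whose centroid falls inside the
#' lineage-positive region (Otsu foreground of the lineage channel,
#' hole-filled), and the positives are candidates whose mean marker
#' intensity exceeds the threshold. The threshold is chosen per animal by
#' Otsu over all candidate nucleus intensities (`threshold_mode = "otsu"`)
#' or fixed (`threshold_mode = "fixed"`). Candidates are pooled across the
#' animal's images before dividing.
#'
#' @param imgs A [channel_image()] or list of them (one animal's images).
#' @param lineage_role Channel role delimiting the lineage-positive region
#'   (default `"mcherry"`; an Anxa4 stain imaged in the same plane plays
#'   the same part).
#' @param marker_role Channel role of the nuclear marker (PCNA, BrdU, H3P).
#' @param threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param threshold Fixed marker cutoff, required for
#'   `threshold_mode = "fixed"`.
#' @param nuclear_min_area Passed to [nuclear_mask()].
#' @return One-row tibble with `n_nuclei`, `n_positive`, `fraction`, and
#'   the `threshold` used. With zero candidate nuclei the fraction is `NA`
#'   and a warning is raised.
#' @export
positive_nuclei_fraction <- function(imgs,
                                     lineage_role = "mcherry",
                                     marker_role = "marker",
                                     threshold_mode = c("otsu", "fixed"),
                                     threshold = NULL,
                                     nuclear_min_area = 10L) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(threshold)) {
    abort("`threshold` is required when `threshold_mode = \"fixed\"`.")
  }
  if (inherits(imgs, "channel_image")) imgs <- list(imgs)

  marker_means <- numeric(0)
  for (img in imgs) {
    nuclei <- nuclear_mask(img, min_area = nuclear_min_area)
    if (max(nuclei) == 0) next
    region <- EBImage::fillHull(otsu_foreground(get_plane(img, lineage_role))) > 0
    cents <- label_centroids(nuclei)
    inside <- vapply(seq_len(nrow(cents)), function(i) {
      region[round(cents$row[i]) + 1L, round(cents$col[i]) + 1L]
    }, logical(1))
    candidates <- cents$id[inside]
    if (length(candidates) == 0) next
    marker <- get_plane(img, marker_role)
    marker_means <- c(marker_means, vapply(candidates, function(id) {
      mean(marker[nuclei == id])
    }, numeric(1)))
  }

  if (length(marker_means) == 0) {
    warn("No candidate nuclei inside the lineage-positive region.")
    return(tibble(n_nuclei = 0L, n_positive = 0L, fraction = NA_real_,
                  threshold = NA_real_))
  }
  th <- if (threshold_mode == "otsu") otsu_threshold(marker_means) else threshold
  n_pos <- sum(marker_means > th)
  tibble(
    n_nuclei = length(marker_means),
    n_positive = n_pos,
    fraction = n_pos / length(marker_means),
    threshold = th
  )
}

#' Time-course statistics on per-animal positive fractions
#'
#' Summarizes per-animal marker-positive fractions by timepoint (group mean
#' and SEM over animals) and tests each timepoint against the reference
#' (mock) group with the two-sided Wilcoxon rank-sum test, Bonferroni-
#' adjusting over the number of timepoint-vs-reference comparisons.
#'
#' @param fractions Data frame with columns `animal`, `timepoint`,
#'   `fraction`.
#' @param reference Reference timepoint (default `"mock"`).
#' @param timepoint_order Optional display/order vector for timepoints.
#' @return A `timecourse_result` tibble: `timepoint`, `mean`, `sem`, `n`,
#'   `p_value`, `p_adj` (both `NA` for the reference row).
#' @export
timecourse_test <- function(fractions, reference = "mock",
                            timepoint_order = NULL) {
  fractions <- as_tibble(fractions)
  needed <- c("animal", "timepoint", "fraction")
  if (!all(needed %in% names(fractions))) {
    abort("`fractions` needs columns animal, timepoint, fraction.")
  }
  tps <- unique(as.character(fractions$timepoint))
  if (!reference %in% tps) {
    abort(sprintf("Reference group `%s` is missing.", reference))
  }
  if (!is.null(timepoint_order)) {
    tps <- intersect(timepoint_order, tps)
  } else {
    tps <- c(reference, sort(setdiff(tps, reference)))
  }
  small <- names(which(table(fractions$timepoint) < 2))
  if (length(small) > 0) {
    warn(sprintf("Group(s) with fewer than 2 animals: %s.",
                 paste(small, collapse = ", ")))
  }

  ref_vals <- fractions$fraction[fractions$timepoint == reference]
  out <- purrr::map_dfr(tps, function(tp) {
    v <- fractions$fraction[fractions$timepoint == tp]
    ms <- suppressWarnings(mean_sem(v))
    p <- if (tp == reference) NA_real_ else rank_sum_test(v, ref_vals)$p_value
    tibble(timepoint = tp, mean = ms$mean, sem = ms$sem, n = ms$n,
           p_value = p)
  })
  n_comp <- sum(!is.na(out$p_value))
  out$p_adj <- NA_real_
  if (n_comp > 0) {
    out$p_adj[!is.na(out$p_value)] <-
      bonferroni(out$p_value[!is.na(out$p_value)], m = n_comp)
  }
  structure(
    out,
    reference = reference, n_comparisons = n_comp,
    class = c("timecourse_result", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname timecourse_test
#' @param x A `timecourse_result`.
#' @param ... Unused.
#' @export
glance.timecourse_result <- function(x, ...) {
  tibble(
    reference = attr(x, "reference"),
    n_comparisons = attr(x, "n_comparisons"),
    n_significant = sum(x$p_adj < 0.05, na.rm = TRUE)
  )
}

#' @rdname timecourse_test
#' @param object A `timecourse_result`.
#' @method autoplot timecourse_result
#' @export
autoplot.timecourse_result <- function(object, ...) {
  df <- as_tibble(object)
  df$timepoint <- factor(df$timepoint, levels = df$timepoint)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                   group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
    ), colour = "#1B7837") +
    ggplot2::labs(x = NULL, y = "Fraction positive nuclei",
                  title = "Marker-positive nuclei over regeneration") +
    ggplot2::theme_classic()
}
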