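check_labels <- function(normalized, labels) {
  if (is.null(colnames(normalized))) {
    abort("`normalized` must carry cell colnames.")
  }
  if (length(labels) != ncol(normalized)) {
    abort("`labels` must have one entry per cell (column).")
  }
  as.character(labels)
}

#' Dot-plot statistics per gene and cluster
#'
#' For each requested gene and each cluster, computes the average
#' log-normalized expression over the cluster's cells and the fraction of
#' those cells expressing the gene (normalized value > 0, i.e. raw count
#' > 0).
#'
#' @param normalized Genes x cells matrix from [log_normalize()].
#' @param labels Cluster label per cell.
#' @param genes Genes to summarize (default: all).
#' @return Tibble with `gene`, `cluster`, `avg_expression`,
#'   `fraction_expressing`.
#' @export
dotplot_stats <- function(normalized, labels, genes = rownames(normalized)) {
  labels <- check_labels(normalized, labels)
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing) > 0) {
    abort(sprintf("Unknown gene(s): %s.", paste(missing, collapse = ", ")))
  }
  clusters <- sort(unique(labels))
  purrr::map_dfr(clusters, function(cl) {
    cols <- labels == cl
    if (!any(cols)) abort(sprintf("Cluster `%s` is empty.", cl))
    sub <- normalized[genes, cols, drop = FALSE]
    tibble(
      gene = genes,
      cluster = cl,
      avg_expression = unname(rowMeans(sub)),
      fraction_expressing = unname(rowMeans(sub > 0))
    )
  })
}

# per-gene summaries for a one-vs-rest split of a normalized matrix
split_summaries <- function(normalized, in_cols) {
  x_in <- normalized[, in_cols, drop = FALSE]
  x_out <- normalized[, !in_cols, drop = FALSE]
  mean_in <- rowMeans(x_in)
  mean_out <- rowMeans(x_out)
  list(
    mean_in = mean_in,
    mean_out = mean_out,
    pct_in = rowMeans(x_in > 0),
    pct_out = rowMeans(x_out > 0),
    # fold change on the de-logged scale, consistent with log1p normalization
    log_fc = log((rowMeans(expm1(x_in)) + 1) / (rowMeans(expm1(x_out)) + 1))
  )
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, genes passing the detection-fraction and
#' log-fold-change prefilters are tested one-vs-rest with the two-sided
#' Wilcoxon rank-sum test ([rank_sum_test()]). Only positive markers are
#' considered (mean expression higher inside the cluster). P-values are
#' Bonferroni-adjusted over the full family of genes times cluster
#' comparisons (not merely the tests surviving the prefilters: the
#' fold-change prefilter selects genes with correlated small p-values, so
#' a post-selection family would not control the family-wise error), and
#' rows with adjusted p below `alpha` are returned.
#'
#' @inheritParams dotplot_stats
#' @param min_fraction Minimum detection fraction in either population
#'   (default 0.1).
#' @param min_logfc Minimum natural-log fold change of de-logged means, with
#'   pseudocount 1 (default 0.25).
#' @param alpha Adjusted-p cutoff for reporting (default 0.05).
#' @return A `marker_result` tibble with `gene`, `cluster`, `avg_in`,
#'   `avg_rest`, `log_fc`, `pct_in`, `pct_out`, `p_value`, `p_adj`, sorted
#'   by cluster then adjusted p. Attribute `n_tests` records the Bonferroni
#'   family size; `params` records the prefilters.
#' @export
find_markers <- function(normalized, labels, min_fraction = 0.1,
                         min_logfc = 0.25, alpha = 0.05) {
  labels <- check_labels(normalized, labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) {
    abort("At least 2 clusters are required for marker detection.")
  }

  rows <- list()
  n_comparisons <- 0L
  for (cl in clusters) {
    in_cols <- labels == cl
    if (sum(in_cols) < 3) {
      warn(sprintf("Cluster `%s` has fewer than 3 cells; skipped.", cl))
      next
    }
    n_comparisons <- n_comparisons + 1L
    s <- split_summaries(normalized, in_cols)
    test_genes <- which(
      pmax(s$pct_in, s$pct_out) >= min_fraction & s$log_fc >= min_logfc
    )
    if (length(test_genes) == 0) next
    p <- vapply(test_genes, function(g) {
      rank_sum_test(normalized[g, in_cols], normalized[g, !in_cols])$p_value
    }, numeric(1))
    rows[[cl]] <- tibble(
      gene = rownames(normalized)[test_genes],
      cluster = cl,
      avg_in = unname(s$mean_in[test_genes]),
      avg_rest = unname(s$mean_out[test_genes]),
      log_fc = unname(s$log_fc[test_genes]),
      pct_in = unname(s$pct_in[test_genes]),
      pct_out = unname(s$pct_out[test_genes]),
      p_value = p
    )
  }

  out <- dplyr::bind_rows(rows)
  n_tests <- nrow(normalized) * n_comparisons
  if (nrow(out) > 0) {
    out$p_adj <- bonferroni(out$p_value, m = n_tests)
    out <- out[out$p_adj < alpha & out$avg_in > out$avg_rest, , drop = FALSE]
    out <- dplyr::arrange(out, .data$cluster, .data$p_adj, .data$gene)
  } else {
    out <- tibble(
      gene = character(), cluster = character(), avg_in = numeric(),
      avg_rest = numeric(), log_fc = numeric(), pct_in = numeric(),
      pct_out = numeric(), p_value = numeric(), p_adj = numeric()
    )
  }
  structure(
    out,
    n_tests = n_tests,
    params = list(min_fraction = min_fraction, min_logfc = min_logfc,
                  alpha = alpha),
    class = c("marker_result", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname find_markers
#' @param x A `marker_result`.
#' @param ... Unused.
#' @export
glance.marker_result <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_clusters = length(unique(x$cluster)),
    n_tests = attr(x, "n_tests"),
    min_fraction = attr(x, "params")$min_fraction,
    min_logfc = attr(x, "params")$min_logfc,
    alpha = attr(x, "params")$alpha
  )
}

#' Assign cell types to clusters from marker panels
#'
#' A cluster is assigned a cell type when at least 3 of that type's panel
#' genes appear among the cluster's retained markers (e.g. fabp10a / tfa /
#' cp for hepatocytes, anxa4 / krt18a.1 / alcama for biliary epithelial
#' cells). Clusters matching no panel remain `"unassigned"`; a cluster
#' matching two panels is an error, surfacing the ambiguity rather than
#' resolving it.
#'
#' @param markers A [find_markers()] result (or compatible tibble with
#'   `gene` and `cluster`).
#' @param panel Named list: cell type -> character vector of at least 3
#'   marker genes.
#' @param min_markers Markers required for an assignment (default 3).
#' @param clusters Clusters to assign; defaults to those present in
#'   `markers` (pass explicitly to include clusters with no retained
#'   markers).
#' @return Tibble with `cluster`, `cell_type`, `n_panel_markers`.
#' @export
identify_cluster <- function(markers, panel, min_markers = 3L,
                             clusters = NULL) {
  if (!all(c("gene", "cluster") %in% names(markers))) {
    abort("`markers` needs `gene` and `cluster` columns.")
  }
  if (!is.list(panel) || is.null(names(panel))) {
    abort("`panel` must be a named list of marker gene vectors.")
  }
  short <- names(panel)[lengths(panel) < min_markers]
  if (length(short) > 0) {
    abort(sprintf("Panel(s) with fewer than %d genes: %s.",
                  min_markers, paste(short, collapse = ", ")))
  }
  clusters <- clusters %||% sort(unique(as.character(markers$cluster)))
  purrr::map_dfr(clusters, function(cl) {
    genes <- markers$gene[markers$cluster == cl]
    hits <- vapply(panel, function(p) sum(p %in% genes), integer(1))
    matched <- names(hits)[hits >= min_markers]
    if (length(matched) > 1) {
      abort(sprintf(
        "Cluster `%s` matches >= %d markers of multiple cell types: %s.",
        cl, min_markers, paste(matched, collapse = ", ")
      ))
    }
    tibble(
      cluster = cl,
      cell_type = if (length(matched) == 1) matched else "unassigned",
      n_panel_markers = if (length(matched) == 1) hits[[matched]] else
        max(hits, 0L)
    )
  })
}

# head-to-head DE between two clusters: number of genes passing the
# prefilters (in either direction) with Bonferroni-adjusted p < alpha
pairwise_n_de <- function(normalized, cols_a, cols_b, min_fraction,
                          min_logfc, alpha) {
  sub <- normalized[, cols_a | cols_b, drop = FALSE]
  in_a <- cols_a[cols_a | cols_b]
  s <- split_summaries(sub, in_a)
  test_genes <- which(
    pmax(s$pct_in, s$pct_out) >= min_fraction & abs(s$log_fc) >= min_logfc
  )
  if (length(test_genes) == 0) return(0L)
  p <- vapply(test_genes, function(g) {
    rank_sum_test(sub[g, in_a], sub[g, !in_a])$p_value
  }, numeric(1))
  # family = all genes considered, as in find_markers
  sum(bonferroni(p, m = nrow(sub)) < alpha)
}

#' Merge clusters indistinct by marker expression
#'
#' Clusters that are not different based on marker gene expression are
#' merged: every cluster pair is tested head-to-head with the same
#' prefilters and Wilcoxon/Bonferroni machinery as [find_markers()] (in
#' both directions); a pair with zero significant genes is indistinct.
#' Indistinct relations are closed transitively and each connected
#' component collapses to its smallest original label.
#'
#' @inheritParams find_markers
#' @return Character vector of merged labels (same length as `labels`)
#'   with attribute `mapping`, a tibble of `old` -> `new` labels.
#' @export
merge_indistinct_clusters <- function(normalized, labels, min_fraction = 0.1,
                                      min_logfc = 0.25, alpha = 0.05) {
  labels <- check_labels(normalized, labels)
  clusters <- sort(unique(labels))
  parent <- setNames(seq_along(clusters), clusters)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(clusters) > 1) {
    pairs <- combn(length(clusters), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- clusters[pairs[1, k]]
      b <- clusters[pairs[2, k]]
      n_de <- pairwise_n_de(normalized, labels == a, labels == b,
                            min_fraction, min_logfc, alpha)
      if (n_de == 0) {
        ra <- find_root(pairs[1, k])
        rb <- find_root(pairs[2, k])
        # smallest label (sort order) survives
        parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  new_label <- vapply(seq_along(clusters),
                      function(i) clusters[find_root(i)], character(1))
  mapping <- tibble(old = clusters, new = new_label)
  out <- mapping$new[match(labels, mapping$old)]
  attr(out, "mapping") <- mapping
  out
}
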