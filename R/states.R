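#' Build cell-state labels from timepoint and cell type
#'
#' A cell state combines when and what: the state label is the
#' deterministic concatenation `timepoint.cell_type` (e.g. `"2dpa.BEC"`,
#' hepatocytes at 3 days post-ablation are `"3dpa.HC"`).
#'
#' @param meta Data frame with columns `barcode`, `timepoint`, `cell_type`
#'   (no missing values).
#' @return The input as a tibble with a `state` column appended.
#' @examples
#' build_states(tibble::tibble(barcode = "b1", timepoint = "0dpa",
#'                             cell_type = "BEC"))
#' @export
build_states <- function(meta) {
  meta <- as_tibble(meta)
  needed <- c("barcode", "timepoint", "cell_type")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("`meta` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  bad <- is.na(meta$timepoint) | meta$timepoint == "" |
    is.na(meta$cell_type) | meta$cell_type == ""
  if (any(bad)) {
    abort(sprintf("Cell(s) with missing labels: %s.",
                  paste(head(meta$barcode[bad], 5), collapse = ", ")))
  }
  if (any(grepl(".", meta$timepoint, fixed = TRUE)) ||
      any(grepl(".", meta$cell_type, fixed = TRUE))) {
    abort("`timepoint` and `cell_type` must not contain '.'.")
  }
  dplyr::mutate(meta, state = paste(.data$timepoint, .data$cell_type,
                                    sep = "."))
}

#' @rdname build_states
#' @param state Character vector of state labels to split back into parts.
#' @export
parse_state <- function(state) {
  parts <- strsplit(as.character(state), ".", fixed = TRUE)
  ok <- lengths(parts) == 2
  if (any(!ok)) {
    abort(sprintf("Malformed state label(s): %s.",
                  paste(head(state[!ok], 5), collapse = ", ")))
  }
  tibble(
    state = as.character(state),
    timepoint = vapply(parts, `[[`, character(1), 1),
    cell_type = vapply(parts, `[[`, character(1), 2)
  )
}

# row-wise (x - min) / (max - min); constant rows map to all zeros
scale_rows <- function(m) {
  rmin <- apply(m, 1, min)
  rmax <- apply(m, 1, max)
  rng <- rmax - rmin
  out <- (m - rmin) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  out
}

new_scaled_heatmap <- function(values, column_order) {
  structure(values, column_order = column_order,
            class = c("scaled_heatmap", class(values)))
}

#' Row min-max scaled average-expression heatmap over cell states
#'
#' Averages log-normalized expression per cell state (or cluster), then
#' rescales each gene row to [0, 1] by `(x - min) / (max - min)`. Constant
#' rows are mapped to all zeros. This is the scaled-expression display used
#' for the regeneration branch heatmaps.
#'
#' @inheritParams dotplot_stats
#' @param states State (or cluster) label per cell, or a [build_states()]
#'   tibble aligned with the matrix columns.
#' @param genes Gene rows, in display order.
#' @param column_order Explicit column order; every listed state must have
#'   at least one cell. Defaults to the sorted unique states.
#' @return A `scaled_heatmap`: genes x states numeric matrix in [0, 1] with
#'   attribute `column_order`.
#' @export
state_heatmap <- function(normalized, states, genes,
                          column_order = NULL) {
  if (is.data.frame(states)) {
    if (!"state" %in% names(states)) {
      abort("`states` data frame needs a `state` column (see build_states()).")
    }
    states <- states$state
  }
  states <- check_labels(normalized, states)
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing) > 0) {
    abort(sprintf("Unknown gene(s): %s.", paste(missing, collapse = ", ")))
  }
  column_order <- column_order %||% sort(unique(states))
  empty <- setdiff(column_order, unique(states))
  if (length(empty) > 0) {
    abort(sprintf("State(s) with no cells: %s.", paste(empty, collapse = ", ")))
  }
  avg <- vapply(column_order, function(s) {
    rowMeans(normalized[genes, states == s, drop = FALSE])
  }, numeric(length(genes)))
  avg <- matrix(avg, nrow = length(genes),
                dimnames = list(genes, column_order))
  new_scaled_heatmap(scale_rows(avg), column_order)
}

#' @rdname state_heatmap
#' @param object A `scaled_heatmap`.
#' @param ... Unused.
#' @method autoplot scaled_heatmap
#' @export
autoplot.scaled_heatmap <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(unclass(object),
                                      responseName = "scaled"))
  names(df)[1:2] <- c("gene", "state")
  df$state <- factor(df$state, levels = attr(object, "column_order"))
  df$gene <- factor(df$gene, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$gene,
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Scaled\nexpression") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
tidy.scaled_heatmap <- function(x, ...) {
  df <- as_tibble(as.data.frame.table(unclass(x), responseName = "scaled"))
  names(df)[1:2] <- c("gene", "state")
  df$gene <- as.character(df$gene)
  df$state <- as.character(df$state)
  df
}

#' Cross-species scaled heatmaps of orthologous markers
#'
#' Given one normalized matrix + cluster labels per species and an ortholog
#' table (one column of gene identifiers per species, one row per ortholog
#' group), computes a per-species cluster-averaged, row min-max scaled
#' heatmap with a shared row order. Ortholog rows not resolvable in every
#' species' matrix are dropped with a warning.
#'
#' @param species Named list; each element a list with `normalized` (genes
#'   x cells matrix) and `labels` (cluster per cell).
#' @param ortholog_table Data frame with one gene-identifier column per
#'   species (same names as `species`).
#' @param column_orders Optional named list of cluster orders per species.
#' @return Named list of [state_heatmap()]-style `scaled_heatmap`s, one per
#'   species, rows aligned to the (filtered) ortholog table.
#' @export
conserved_marker_heatmap <- function(species, ortholog_table,
                                     column_orders = NULL) {
  if (!is.list(species) || is.null(names(species)) || length(species) < 1) {
    abort("`species` must be a named list of (normalized, labels) pairs.")
  }
  ortholog_table <- as_tibble(ortholog_table)
  missing <- setdiff(names(species), names(ortholog_table))
  if (length(missing) > 0) {
    abort(sprintf("`ortholog_table` lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  resolvable <- rep(TRUE, nrow(ortholog_table))
  for (sp in names(species)) {
    resolvable <- resolvable &
      ortholog_table[[sp]] %in% rownames(species[[sp]]$normalized)
  }
  if (any(!resolvable)) {
    warn(sprintf("Dropping %d ortholog row(s) not resolvable in all species.",
                 sum(!resolvable)))
  }
  kept <- ortholog_table[resolvable, , drop = FALSE]
  if (nrow(kept) == 0) abort("No ortholog rows resolvable in all species.")

  purrr::imap(species, function(sp, nm) {
    state_heatmap(sp$normalized, sp$labels, genes = kept[[nm]],
                  column_order = column_orders[[nm]])
  })
}
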