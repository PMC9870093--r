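#' Specify state-structured time-course expression
#'
#' Describes a time course of cell states (labels of the form
#' `timepoint.celltype`, e.g. `"2dpa.BEC"`) with gene programs whose mean
#' expression varies across states. The defaults emulate the regeneration
#' branch dynamics observed after hepatocyte ablation: biliary identity
#' genes decay along the hepatocyte branch, hepatocyte genes switch on from
#' 3 dpa, hepatoblast transcription factors and proliferation genes peak
#' mid-course, growth-factor ligands rise early, and a housekeeping program
#' stays flat.
#'
#' @param states Ordered character vector of state labels; each must parse
#'   as `timepoint.celltype`.
#' @param cells_per_state Cells simulated per state.
#' @param gene_programs Named list of programs, each a list with `genes`
#'   (character) and `levels` (named numeric: mean expression per state;
#'   every state present in `states`, levels non-negative). A gene may
#'   appear in only one program.
#' @param dispersion Negative-binomial size parameter (larger is closer to
#'   Poisson). Default 2, a typical UMI-level overdispersion.
#' @param seed Integer seed.
#' @return A `state_sim_spec` object.
#' @seealso [simulate_state_expression()]
#' @export
state_sim_spec <- function(states = default_states(),
                           cells_per_state = 50,
                           gene_programs = default_gene_programs(states),
                           dispersion = 2,
                           seed = 1L) {
  if (!is.character(states) || length(states) < 1 || anyDuplicated(states)) {
    abort("`states` must be distinct state labels.")
  }
  parse_state(states) # validates the timepoint.celltype form
  cells_per_state <- check_count_scalar(cells_per_state, "cells_per_state", min = 1L)
  check_scalar(dispersion, "dispersion")
  if (!is.list(gene_programs) || is.null(names(gene_programs))) {
    abort("`gene_programs` must be a named list.")
  }
  all_genes <- character(0)
  for (nm in names(gene_programs)) {
    prog <- gene_programs[[nm]]
    if (!is.list(prog) || !all(c("genes", "levels") %in% names(prog))) {
      abort(sprintf("Program `%s` needs `genes` and `levels`.", nm))
    }
    lv <- prog$levels
    if (is.null(names(lv)) || any(!is.finite(lv)) || any(lv < 0)) {
      abort(sprintf("Program `%s` levels must be named, finite, non-negative.", nm))
    }
    unknown <- setdiff(names(lv), states)
    if (length(unknown) > 0) {
      abort(sprintf("Program `%s` references unknown state(s): %s.",
                    nm, paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(states, names(lv))
    if (length(missing) > 0) {
      abort(sprintf("Program `%s` lacks levels for state(s): %s.",
                    nm, paste(missing, collapse = ", ")))
    }
    if (any(prog$genes %in% all_genes)) {
      abort(sprintf("Program `%s` reuses genes already assigned.", nm))
    }
    all_genes <- c(all_genes, prog$genes)
  }

  structure(
    list(
      states = states, cells_per_state = cells_per_state,
      gene_programs = gene_programs, dispersion = dispersion,
      seed = check_count_scalar(seed, "seed")
    ),
    class = "state_sim_spec"
  )
}

#' @rdname state_sim_spec
#' @export
default_states <- function() {
  c(
    "mock.BEC", "0dpa.BEC", "1dpa.BEC", "2dpa.BEC", "3dpa.BEC", "7dpa.BEC",
    "3dpa.HC", "7dpa.HC"
  )
}

#' @rdname state_sim_spec
#' @export
default_gene_programs <- function(states = default_states()) {
  lv <- function(...) {
    v <- c(...)
    stopifnot(length(v) == length(states))
    setNames(v, states)
  }
  list(
    #                mock 0dpa 1dpa 2dpa 3dpaB 7dpaB 3dpaHC 7dpaHC
    biliary = list(
      genes = c("anxa4", "krt18a.1", "alcama", "sox9b", "cldn15la"),
      levels = lv(10, 6, 4, 3, 6, 10, 1.5, 0.5)
    ),
    hepatocyte = list(
      genes = c("fabp10a", "tfa", "cp", "bhmt", "apoa2"),
      levels = lv(0.2, 0.1, 0.1, 0.5, 1, 1.5, 8, 12)
    ),
    hepatoblast_tf = list(
      genes = c("prox1a", "hnf4a", "hhex", "foxa3"),
      levels = lv(1, 1.5, 3, 8, 4, 2, 5, 2)
    ),
    proliferation = list(
      genes = c("pcna", "mki67", "ccnb1", "mcm2"),
      levels = lv(0.5, 1, 4, 9, 8, 1, 7, 1)
    ),
    growth_factor = list(
      genes = c("igfbp1a", "hbegfa", "hgfa"),
      levels = lv(0.3, 2, 6, 7, 3, 1, 3, 0.5)
    ),
    housekeeping = list(
      genes = sprintf("hk_%02d", 1:30),
      levels = lv(rep(2, length(states)))
    )
  )
}

#' Simulate state-structured expression counts
#'
#' Draws negative-binomial counts with state-dependent means given by the
#' spec's gene programs and returns the matrix together with a state table
#' (one row per cell: barcode, timepoint, cell type, state).
#'
#' @param spec A [state_sim_spec()].
#' @return List with `counts` (genes x cells integer matrix) and `states`
#'   (tibble: `barcode`, `timepoint`, `cell_type`, `state`).
#' @examples
#' sim <- simulate_state_expression(state_sim_spec(cells_per_state = 10))
#' table(sim$states$state)
#' @export
simulate_state_expression <- function(spec) {
  if (!inherits(spec, "state_sim_spec")) {
    abort("`spec` must be a `state_sim_spec`.")
  }
  genes <- unlist(lapply(spec$gene_programs, `[[`, "genes"), use.names = FALSE)
  n_cells <- length(spec$states) * spec$cells_per_state
  cell_state <- rep(spec$states, each = spec$cells_per_state)

  # per-gene, per-state mean table
  mu <- matrix(0, nrow = length(genes), ncol = length(spec$states),
               dimnames = list(genes, spec$states))
  for (prog in spec$gene_programs) {
    mu[prog$genes, names(prog$levels)] <-
      matrix(prog$levels, nrow = length(prog$genes),
             ncol = length(prog$levels), byrow = TRUE)
  }

  with_sim_seed(spec$seed, {
    barcodes <- sprintf("cell_%04d", seq_len(n_cells))
    counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, barcodes))
    for (s in spec$states) {
      idx <- which(cell_state == s)
      m <- mu[, s]
      draw <- rnbinom(length(genes) * length(idx), mu = rep(m, length(idx)),
                      size = spec$dispersion)
      counts[, idx] <- draw
    }
    storage.mode(counts) <- "integer"
    parsed <- parse_state(cell_state)
    list(
      counts = counts,
      states = tibble(
        barcode = barcodes,
        timepoint = parsed$timepoint,
        cell_type = parsed$cell_type,
        state = cell_state
      ),
      state_means = mu
    )
  })
}
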