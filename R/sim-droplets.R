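#' Specify a synthetic droplet library
#'
#' Describes a droplet scRNA-seq library as a population of true cells plus
#' a much larger population of ambient (cell-free) barcodes. True cells draw
#' their UMIs from a mixture of a cell-type expression profile and the
#' shared ambient profile; background barcodes draw purely from the ambient
#' profile at much lower depth. The defaults mirror the study conditions
#' used throughout the package's tests: 50 cells over 2,000 ambient
#' barcodes, sequencing depths of 2,000 versus 20 expected UMIs.
#'
#' @param n_cells Number of true cells (may be 0).
#' @param n_background Number of ambient background barcodes.
#' @param n_genes Number of genes.
#' @param cell_depth_mean Expected UMIs per true cell (Poisson mean).
#' @param background_depth_mean Expected UMIs per background barcode; must
#'   be smaller than `cell_depth_mean`.
#' @param ambient_profile Probability vector over genes for ambient RNA;
#'   defaults to a realistic lysis-derived profile: the average of the
#'   cell-type profiles with extra weight on the most highly expressed
#'   genes.
#' @param celltype_profiles List of per-cell-type probability vectors over
#'   genes; defaults to two cell types with disjoint blocks of enriched
#'   marker genes on a shared baseline.
#' @param ambient_fraction Share of each true cell's UMIs drawn from the
#'   ambient profile, in [0, 1).
#' @param seed Integer seed; identical specs and seeds give identical
#'   simulated libraries.
#' @return A `droplet_sim_spec` object (validated list).
#' @seealso [simulate_droplets()]
#' @export
droplet_sim_spec <- function(n_cells = 50,
                             n_background = 2000,
                             n_genes = 100,
                             cell_depth_mean = 2000,
                             background_depth_mean = 20,
                             ambient_profile = NULL,
                             celltype_profiles = NULL,
                             ambient_fraction = 0.1,
                             seed = 1L) {
  n_cells <- check_count_scalar(n_cells, "n_cells")
  n_background <- check_count_scalar(n_background, "n_background", min = 1L)
  n_genes <- check_count_scalar(n_genes, "n_genes", min = 2L)
  check_scalar(cell_depth_mean, "cell_depth_mean")
  check_scalar(background_depth_mean, "background_depth_mean")
  if (cell_depth_mean <= background_depth_mean) {
    abort("`cell_depth_mean` must exceed `background_depth_mean`.")
  }
  check_scalar(ambient_fraction, "ambient_fraction", positive = FALSE)
  if (ambient_fraction < 0 || ambient_fraction >= 1) {
    abort("`ambient_fraction` must lie in [0, 1).")
  }

  if (is.null(celltype_profiles)) {
    celltype_profiles <- default_celltype_profiles(n_genes)
  }
  if (!is.list(celltype_profiles) || length(celltype_profiles) < 1) {
    abort("`celltype_profiles` must be a non-empty list of probability vectors.")
  }
  if (is.null(names(celltype_profiles))) {
    names(celltype_profiles) <- paste0("type", seq_along(celltype_profiles))
  }
  for (nm in names(celltype_profiles)) {
    check_prob_vector(celltype_profiles[[nm]], paste0("celltype_profiles$", nm))
    if (length(celltype_profiles[[nm]]) != n_genes) {
      abort(sprintf("Profile `%s` must have length n_genes = %d.", nm, n_genes))
    }
  }
  if (is.null(ambient_profile)) {
    ambient_profile <- default_ambient_profile(celltype_profiles)
  }
  check_prob_vector(ambient_profile, "ambient_profile")
  if (length(ambient_profile) != n_genes) {
    abort("`ambient_profile` must have length n_genes.")
  }

  structure(
    list(
      n_cells = n_cells, n_background = n_background, n_genes = n_genes,
      cell_depth_mean = cell_depth_mean,
      background_depth_mean = background_depth_mean,
      ambient_profile = ambient_profile,
      celltype_profiles = celltype_profiles,
      ambient_fraction = ambient_fraction,
      seed = check_count_scalar(seed, "seed")
    ),
    class = "droplet_sim_spec"
  )
}

# two cell types with disjoint 10%-of-genes marker blocks enriched 20x over
# a flat baseline
default_celltype_profiles <- function(n_genes) {
  block <- max(1L, n_genes %/% 10L)
  make_profile <- function(idx) {
    p <- rep(1, n_genes)
    p[idx] <- 20
    p / sum(p)
  }
  list(
    typeA = make_profile(seq_len(block)),
    typeB = make_profile(block + seq_len(block))
  )
}

# ambient RNA comes from lysed cells: average of the cell-type profiles,
# with the most highly expressed genes over-represented (as for hemoglobin
# in real dissociations)
default_ambient_profile <- function(celltype_profiles) {
  avg <- Reduce(`+`, celltype_profiles) / length(celltype_profiles)
  boost <- order(avg, decreasing = TRUE)[seq_len(max(1L, length(avg) %/% 20L))]
  avg[boost] <- avg[boost] * 3
  avg / sum(avg)
}

#' Simulate a droplet digital gene expression matrix with known truth
#'
#' Each true cell's depth is Poisson(`cell_depth_mean`) and its UMIs are a
#' multinomial draw from the mixture
#' `(1 - ambient_fraction) * celltype_profile + ambient_fraction * ambient_profile`;
#' cell types are assigned round-robin. Background barcodes draw
#' Poisson(`background_depth_mean`) UMIs from the ambient profile alone.
#' Barcode columns are returned in randomized order.
#'
#' @param spec A [droplet_sim_spec()].
#' @return A list with `counts` (genes x barcodes integer matrix), `truth`
#'   (tibble: `barcode`, `is_cell`, `cell_type`), and `profiles` (the
#'   cell-type probability vectors used).
#' @examples
#' sim <- simulate_droplets(droplet_sim_spec(n_cells = 5, n_background = 50,
#'                                           n_genes = 20, seed = 7))
#' dim(sim$counts)
#' @export
simulate_droplets <- function(spec) {
  if (!inherits(spec, "droplet_sim_spec")) {
    abort("`spec` must be a `droplet_sim_spec`.")
  }
  n_total <- spec$n_cells + spec$n_background
  genes <- sprintf("gene_%03d", seq_len(spec$n_genes))

  with_sim_seed(spec$seed, {
    barcodes <- sprintf("BC%05d", sample.int(n_total))
    is_cell <- c(rep(TRUE, spec$n_cells), rep(FALSE, spec$n_background))
    type_names <- names(spec$celltype_profiles)
    cell_type <- rep(NA_character_, n_total)
    if (spec$n_cells > 0) {
      cell_type[seq_len(spec$n_cells)] <-
        type_names[((seq_len(spec$n_cells) - 1L) %% length(type_names)) + 1L]
    }

    depths <- integer(n_total)
    counts <- matrix(0L, nrow = spec$n_genes, ncol = n_total,
                     dimnames = list(genes, barcodes))
    for (j in seq_len(n_total)) {
      if (is_cell[j]) {
        mix <- (1 - spec$ambient_fraction) * spec$celltype_profiles[[cell_type[j]]] +
          spec$ambient_fraction * spec$ambient_profile
        depths[j] <- rpois(1, spec$cell_depth_mean)
        if (depths[j] > 0) counts[, j] <- rmultinom(1, depths[j], mix)
      } else {
        depths[j] <- rpois(1, spec$background_depth_mean)
        if (depths[j] > 0) counts[, j] <- rmultinom(1, depths[j], spec$ambient_profile)
      }
    }
    storage.mode(counts) <- "integer"

    list(
      counts = counts,
      truth = tibble(
        barcode = barcodes, is_cell = is_cell, cell_type = cell_type,
        depth = depths
      ),
      profiles = spec$celltype_profiles
    )
  })
}
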