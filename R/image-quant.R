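#' Multi-channel image container
#'
#' Bundles a rows x cols x channels pixel array with a role map naming
#' which plane carries which stain (DAPI, GFP, mCherry, CFP, or a nuclear
#' marker such as PCNA/BrdU/H3P).
#'
#' @param image Numeric array `(rows, cols, channels)` with non-negative
#'   intensities; a matrix is treated as a single plane.
#' @param channel_roles Named integer vector, role -> plane index.
#' @return A `channel_image` object.
#' @export
channel_image <- function(image, channel_roles) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3) {
    abort("`image` must be a rows x cols x channels array.")
  }
  if (any(image < 0)) abort("Intensities must be non-negative.")
  if (is.null(names(channel_roles)) ||
      any(channel_roles < 1) || any(channel_roles > dim(image)[3])) {
    abort("`channel_roles` must name existing planes.")
  }
  structure(
    list(image = image, channel_roles = channel_roles),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "channel_image: %d x %d px, %d plane(s) [%s]\n",
    dim(x$image)[1], dim(x$image)[2], dim(x$image)[3],
    paste(names(x$channel_roles), collapse = ", ")
  ))
  invisible(x)
}

get_plane <- function(img, role) {
  if (!inherits(img, "channel_image")) {
    abort("`img` must be a `channel_image`.")
  }
  if (!role %in% names(img$channel_roles)) {
    abort(sprintf("Channel role `%s` is not present.", role))
  }
  img$image[, , img$channel_roles[[role]]]
}

# global Otsu foreground of one plane; empty mask for flat planes
otsu_foreground <- function(plane) {
  top <- max(plane)
  if (top <= min(plane)) return(matrix(FALSE, nrow(plane), ncol(plane)))
  th <- EBImage::otsu(EBImage::Image(plane / top), range = c(0, 1)) * top
  plane > th
}

# 8-connected component labeling by iterative label propagation; returns an
# integer matrix with labels 1..k in first-pixel (column-major) order
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  shift_max <- function(m) {
    out <- m
    z_r <- matrix(0L, 1, nc)
    z_c <- matrix(0L, nr, 1)
    up <- rbind(m[-1, , drop = FALSE], z_r)
    dn <- rbind(z_r, m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], z_c)
    rt <- cbind(z_c, m[, -nc, drop = FALSE])
    out <- pmax(out, up, dn, lf, rt)
    out <- pmax(out,
                rbind(lf[-1, , drop = FALSE], z_r), rbind(z_r, lf[-nr, , drop = FALSE]),
                rbind(rt[-1, , drop = FALSE], z_r), rbind(z_r, rt[-nr, , drop = FALSE]))
    out
  }
  repeat {
    nxt <- shift_max(lab)
    nxt[!mask] <- 0L
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  # relabel to 1..k in order of first appearance
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], sort(ids))
  lab
}

drop_small_objects <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  if (length(keep) > 0) lab[lab > 0] <- match(lab[lab > 0], keep)
  lab
}

drop_border_objects <- function(lab) {
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border) > 0) {
    inform(sprintf("Excluding %d object(s) touching the image border.",
                   length(border)))
    lab[lab %in% border] <- 0L
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) > 0) lab[lab > 0] <- match(lab[lab > 0], ids)
  }
  lab
}

#' Cellular mask from the lineage reporter channels
#'
#' Builds a binary cell mask as the union of per-channel global Otsu
#' foregrounds of the GFP and mCherry planes, fills holes, removes objects
#' below `min_area`, optionally drops objects touching the image border,
#' and labels 8-connected components.
#'
#' @param img A [channel_image()] with `gfp` and `mcherry` roles.
#' @param min_area Smallest object kept, in px^2 (default 50).
#' @param channels Roles whose Otsu foregrounds are unioned.
#' @param exclude_border Drop mask objects touching the border (default
#'   `TRUE`); such cells are clipped and cannot be measured faithfully.
#' @return Integer label matrix (0 = background).
#' @export
cellular_mask <- function(img, min_area = 50L,
                          channels = c("gfp", "mcherry"),
                          exclude_border = TRUE) {
  planes <- lapply(channels, function(ch) get_plane(img, ch))
  fg <- Reduce(`|`, lapply(planes, otsu_foreground))
  fg <- EBImage::fillHull(fg) > 0
  lab <- label_components(fg)
  lab <- drop_small_objects(lab, min_area)
  if (exclude_border) lab <- drop_border_objects(lab)
  lab
}

#' Nuclear mask from the DAPI channel
#'
#' Global Otsu foreground of the DAPI plane, hole-filled, small objects
#' removed, 8-connected labeling.
#'
#' @param img A [channel_image()] with a `dapi` role.
#' @param min_area Smallest nucleus kept, in px^2 (default 10).
#' @return Integer label matrix (0 = background).
#' @export
nuclear_mask <- function(img, min_area = 10L) {
  fg <- otsu_foreground(get_plane(img, "dapi"))
  fg <- EBImage::fillHull(fg) > 0
  drop_small_objects(label_components(fg), min_area)
}

label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(tibble(id = integer(), row = numeric(), col = numeric()))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  vals <- lab[lab > 0]
  tibble(
    id = ids,
    # 0-based pixel-centered coordinates
    row = as.numeric(tapply(idx[, 1] - 1, vals, mean)),
    col = as.numeric(tapply(idx[, 2] - 1, vals, mean))
  )
}

#' Assign nuclei to cells by centroid containment
#'
#' A nucleus belongs to the cell whose label covers the pixel at its
#' centroid; nuclei whose centroid falls on mask background belong to no
#' cell.
#'
#' @param cells,nuclei Integer label matrices of the same shape.
#' @return A list with `assignments` (tibble: `nucleus`, `cell` with 0 for
#'   unassigned, centroid coordinates) and `counts` (tibble: `cell`,
#'   `nucleus_count` for every cell label).
#' @export
assign_nuclei <- function(cells, nuclei) {
  if (!all(dim(cells) == dim(nuclei))) {
    abort("`cells` and `nuclei` must share the same shape.")
  }
  cents <- label_centroids(nuclei)
  owner <- integer(nrow(cents))
  for (i in seq_len(nrow(cents))) {
    r <- round(cents$row[i]) + 1L
    c_ <- round(cents$col[i]) + 1L
    owner[i] <- cells[r, c_]
  }
  cell_ids <- sort(unique(cells[cells > 0]))
  counts <- tibble(
    cell = cell_ids,
    nucleus_count = vapply(cell_ids, function(id) sum(owner == id), integer(1))
  )
  list(
    assignments = dplyr::mutate(cents, cell = owner,
                                .keep = "all") |>
      dplyr::rename(nucleus = "id"),
    counts = counts
  )
}

#' Measure morphology and fluorescence per cell
#'
#' For each labeled cell: pixel area, centroid (0-based, pixel-centered),
#' eccentricity of the ellipse with matching normalized second central
#' moments (`sqrt(1 - lambda_minor/lambda_major)`), nucleus count by
#' centroid containment, and the mean intensity of every channel over the
#' cell's pixels.
#'
#' @param cells Labeled cell mask from [cellular_mask()].
#' @param nuclei Labeled nuclear mask from [nuclear_mask()].
#' @param img The underlying [channel_image()].
#' @return A tibble of cell records: `cell`, `centroid_row`,
#'   `centroid_col`, `area`, `eccentricity`, `nucleus_count`, and one
#'   `intensity_<role>` column per channel role.
#' @export
measure_cells <- function(cells, nuclei, img) {
  if (!inherits(img, "channel_image")) abort("`img` must be a `channel_image`.")
  if (!all(dim(cells) == dim(img$image)[1:2])) {
    abort("`cells` mask does not match the image shape.")
  }
  counts <- assign_nuclei(cells, nuclei)$counts
  ids <- sort(unique(cells[cells > 0]))
  if (length(ids) == 0) {
    out <- tibble(cell = integer(), centroid_row = numeric(),
                  centroid_col = numeric(), area = numeric(),
                  eccentricity = numeric(), nucleus_count = integer())
    for (role in names(img$channel_roles)) {
      out[[paste0("intensity_", role)]] <- numeric()
    }
    return(out)
  }

  idx <- which(cells > 0, arr.ind = TRUE)
  vals <- cells[cells > 0]
  recs <- purrr::map_dfr(ids, function(id) {
    px <- idx[vals == id, , drop = FALSE]
    r <- px[, 1] - 1
    c_ <- px[, 2] - 1
    n <- nrow(px)
    mr <- mean(r)
    mc <- mean(c_)
    # normalized second central moments and their eigenvalues
    mu_rr <- mean((r - mr)^2)
    mu_cc <- mean((c_ - mc)^2)
    mu_rc <- mean((r - mr) * (c_ - mc))
    half_tr <- (mu_rr + mu_cc) / 2
    det_rt <- sqrt(((mu_rr - mu_cc) / 2)^2 + mu_rc^2)
    l_max <- half_tr + det_rt
    l_min <- half_tr - det_rt
    ecc <- if (l_max <= 0) 0 else sqrt(max(0, 1 - l_min / l_max))
    tibble(cell = id, centroid_row = mr, centroid_col = mc,
           area = as.numeric(n), eccentricity = ecc)
  })
  recs <- dplyr::left_join(recs, counts, by = "cell")
  recs$nucleus_count[is.na(recs$nucleus_count)] <- 0L

  for (role in names(img$channel_roles)) {
    plane <- get_plane(img, role)
    recs[[paste0("intensity_", role)]] <- vapply(ids, function(id) {
      mean(plane[cells == id])
    }, numeric(1))
  }
  recs
}

#' Keep only mono-nucleated cells
#'
#' Drops cell records whose nucleus count is not exactly 1; the cells
#' retained are the ones whose centroids anchor the downstream grid export
#' and measurements.
#'
#' @param records A [measure_cells()] tibble (needs `nucleus_count`).
#' @return The retained records; a message reports how many were removed
#'   and why.
#' @export
filter_single_nucleus <- function(records) {
  if (!"nucleus_count" %in% names(records)) {
    abort("`records` needs a `nucleus_count` column.")
  }
  n0 <- sum(records$nucleus_count == 0)
  n2 <- sum(records$nucleus_count >= 2)
  if (n0 + n2 > 0) {
    inform(sprintf(
      "filter_single_nucleus: removed %d cell(s) with 0 nuclei and %d with >= 2.",
      n0, n2
    ))
  }
  records[records$nucleus_count == 1, , drop = FALSE]
}

#' Export per-cell thumbnails as a grid image
#'
#' Crops a square thumbnail around each cell centroid from every channel,
#' tiles them row-major into one grid image per channel, and writes a
#' multi-page TIFF plus an index CSV mapping grid position to cell id.
#' Crops extending past the image bounds are zero-padded.
#'
#' @param records Cell records with `cell`, `centroid_row`, `centroid_col`.
#' @param img The source [channel_image()].
#' @param thumb_size Thumbnail side length in px (default 32).
#' @param path Output TIFF path; the index CSV is written alongside with
#'   suffix `_index.csv`. `NULL` skips writing.
#' @return (Invisibly) a list with `grid` (array: rows x cols x channels),
#'   `index` (tibble: `cell`, `grid_row`, `grid_col`), and the paths
#'   written.
#' @export
export_grid <- function(records, img, thumb_size = 32L, path = NULL) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  if (!inherits(img, "channel_image")) abort("`img` must be a `channel_image`.")
  thumb_size <- check_count_scalar(thumb_size, "thumb_size", min = 4L)
  n <- nrow(records)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  n_chan <- dim(img$image)[3]
  grid <- array(0, dim = c(nrow_grid * thumb_size, ncol_grid * thumb_size,
                           n_chan))
  half <- thumb_size %/% 2

  index <- tibble(
    cell = records$cell,
    grid_row = ((seq_len(n) - 1) %/% ncol_grid) + 1L,
    grid_col = ((seq_len(n) - 1) %% ncol_grid) + 1L
  )
  for (i in seq_len(n)) {
    cr <- round(records$centroid_row[i]) + 1L # to 1-based
    cc <- round(records$centroid_col[i]) + 1L
    rows <- (cr - half):(cr - half + thumb_size - 1L)
    cols <- (cc - half):(cc - half + thumb_size - 1L)
    ok_r <- rows >= 1 & rows <= dim(img$image)[1]
    ok_c <- cols >= 1 & cols <= dim(img$image)[2]
    thumb <- array(0, dim = c(thumb_size, thumb_size, n_chan))
    thumb[ok_r, ok_c, ] <- img$image[rows[ok_r], cols[ok_c], , drop = FALSE]
    r0 <- (index$grid_row[i] - 1L) * thumb_size
    c0 <- (index$grid_col[i] - 1L) * thumb_size
    grid[r0 + seq_len(thumb_size), c0 + seq_len(thumb_size), ] <- thumb
  }

  paths <- NULL
  if (!is.null(path)) {
    write_channel_tiff(channel_image(grid, img$channel_roles), path)
    index_path <- sub("\\.tiff?$", "", path)
    index_path <- paste0(index_path, "_index.csv")
    readr::write_csv(index, index_path)
    paths <- c(tiff = path, index = index_path)
  }
  invisible(list(grid = grid, index = index, paths = paths))
}

#' @rdname export_grid
#' @param grid Grid array as produced by `export_grid()`.
#' @param index The matching index tibble.
#' @param cell Cell id to extract.
#' @export
extract_grid_cell <- function(grid, index, cell, thumb_size = 32L) {
  row <- index[index$cell == cell, , drop = FALSE]
  if (nrow(row) != 1) abort(sprintf("Cell %s not found in the index.", cell))
  r0 <- (row$grid_row - 1L) * thumb_size
  c0 <- (row$grid_col - 1L) * thumb_size
  grid[r0 + seq_len(thumb_size), c0 + seq_len(thumb_size), , drop = FALSE]
}

#' Classify lineage from reporter intensities
#'
#' Calls a cell GFP-lineage when its mean GFP exceeds `gfp_threshold` while
#' mean mCherry stays at or below `mcherry_threshold`; symmetric for the
#' mCherry (biliary-derived) lineage; anything else is ambiguous.
#'
#' @param records Cell records with `intensity_gfp` and `intensity_mcherry`.
#' @param gfp_threshold,mcherry_threshold Non-negative intensity cutoffs.
#' @return `records` with a `lineage` column (`"gfp"`, `"mcherry"`,
#'   `"ambiguous"`).
#' @export
classify_lineage <- function(records, gfp_threshold, mcherry_threshold) {
  if (gfp_threshold < 0 || mcherry_threshold < 0) {
    abort("Thresholds must be non-negative.")
  }
  needed <- c("intensity_gfp", "intensity_mcherry")
  if (!all(needed %in% names(records))) {
    abort("`records` needs `intensity_gfp` and `intensity_mcherry` columns.")
  }
  dplyr::mutate(
    records,
    lineage = dplyr::case_when(
      .data$intensity_gfp > gfp_threshold &
        .data$intensity_mcherry <= mcherry_threshold ~ "gfp",
      .data$intensity_mcherry > mcherry_threshold &
        .data$intensity_gfp <= gfp_threshold ~ "mcherry",
      TRUE ~ "ambiguous"
    )
  )
}

#' Fraction of hepatocytes that are biliary-derived
#'
#' Among cells called hepatocytes by CFP positivity (mean CFP above
#' `cfp_threshold`), the fraction carrying the mCherry lineage label, i.e.
#' hepatocytes descended from biliary epithelial cells.
#'
#' @param records Lineage-classified records with `intensity_cfp`.
#' @param cfp_threshold CFP positivity cutoff.
#' @return A one-row tibble with `fraction`, `n_hepatocytes`,
#'   `n_biliary_derived`. With zero CFP-positive cells the fraction is `NA`
#'   and a warning is raised.
#' @export
biliary_derived_fraction <- function(records, cfp_threshold) {
  needed <- c("intensity_cfp", "lineage")
  if (!all(needed %in% names(records))) {
    abort("`records` needs `intensity_cfp` and `lineage` (see classify_lineage()).")
  }
  hep <- records[records$intensity_cfp > cfp_threshold, , drop = FALSE]
  if (nrow(hep) == 0) {
    warn("No CFP-positive cells: biliary-derived fraction is undefined.")
    return(tibble(fraction = NA_real_, n_hepatocytes = 0L,
                  n_biliary_derived = 0L))
  }
  n_mch <- sum(hep$lineage == "mcherry")
  tibble(
    fraction = n_mch / nrow(hep),
    n_hepatocytes = nrow(hep),
    n_biliary_derived = n_mch
  )
}

#' Quantify one field end-to-end
#'
#' Convenience wrapper: cellular + nuclear masks, measurement, and the
#' exactly-one-nucleus filter.
#'
#' @inheritParams cellular_mask
#' @param nuclear_min_area Passed to [nuclear_mask()].
#' @param single_nucleus_only Apply [filter_single_nucleus()] (default
#'   `TRUE`).
#' @return A tibble of cell records.
#' @export
quantify_field <- function(img, min_area = 50L, nuclear_min_area = 10L,
                           channels = c("gfp", "mcherry"),
                           exclude_border = TRUE,
                           single_nucleus_only = TRUE) {
  cells <- cellular_mask(img, min_area = min_area, channels = channels,
                         exclude_border = exclude_border)
  nuclei <- nuclear_mask(img, min_area = nuclear_min_area)
  recs <- measure_cells(cells, nuclei, img)
  if (single_nucleus_only) recs <- filter_single_nucleus(recs)
  recs
}
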