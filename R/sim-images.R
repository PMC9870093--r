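#' Specify a synthetic multi-channel microscopy field
#'
#' Describes a 2-D field of non-overlapping elliptical cells with known
#' geometry, nucleus counts, and per-channel fluorescence, rendered into a
#' multi-channel image. Analytic ground truth (area `pi*a*b`, eccentricity
#' `sqrt(1 - (b/a)^2)`, nucleus count, channel intensities) accompanies the
#' rendering so segmentation and measurement can be checked exactly.
#' Overlapping cells are rejected: the measurement pipeline deliberately
#' has no object-splitting step, so the generator must not produce touching
#' objects.
#'
#' @param cells A data frame, one row per cell, with columns `center_row`,
#'   `center_col` (0-based pixel-centered coordinates), `semi_major`,
#'   `semi_minor` (pixels; `semi_major >= semi_minor > 0`), `orientation`
#'   (radians, major axis relative to the column axis), `n_nuclei`,
#'   `nucleus_radius` (pixels), and one intensity column per channel role
#'   (e.g. `dapi`, `gfp`, `mcherry`, `cfp`, `marker`).
#' @param image_shape `(rows, cols)` in pixels.
#' @param channel_roles Named integer vector mapping role to plane index.
#' @param background_level Per-channel additive background (scalar or named
#'   by role).
#' @param noise_sd Per-channel Gaussian noise standard deviation (scalar or
#'   named by role).
#' @param seed Integer seed (used only for the noise).
#' @return An `image_sim_spec` object.
#' @seealso [simulate_image()], [random_image_spec()]
#' @export
image_sim_spec <- function(cells,
                           image_shape = c(128L, 128L),
                           channel_roles = c(dapi = 1L, gfp = 2L, mcherry = 3L,
                                             cfp = 4L, marker = 5L),
                           background_level = 0,
                           noise_sd = 0,
                           seed = 1L) {
  cells <- as_tibble(cells)
  if (nrow(cells) < 1) abort("`cells` must contain at least one cell.")
  needed <- c("center_row", "center_col", "semi_major", "semi_minor",
              "orientation", "n_nuclei", "nucleus_radius")
  missing <- setdiff(needed, names(cells))
  if (length(missing) > 0) {
    abort(sprintf("`cells` lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    abort("`image_shape` must be (rows, cols), each >= 8.")
  }
  image_shape <- as.integer(image_shape)
  if (is.null(names(channel_roles)) || anyDuplicated(names(channel_roles))) {
    abort("`channel_roles` must be uniquely named.")
  }
  roles <- names(channel_roles)
  missing_int <- setdiff(roles, names(cells))
  if (length(missing_int) > 0) {
    abort(sprintf("`cells` lacks intensity column(s): %s.",
                  paste(missing_int, collapse = ", ")))
  }

  if (any(cells$semi_minor <= 0) || any(cells$semi_major < cells$semi_minor)) {
    abort("Each cell needs `semi_major >= semi_minor > 0`.")
  }
  if (any(cells$n_nuclei < 0) || any(cells$n_nuclei != round(cells$n_nuclei))) {
    abort("`n_nuclei` must be non-negative integers.")
  }
  if (any(cells$nucleus_radius > 0.4 * cells$semi_minor & cells$n_nuclei > 0)) {
    abort("`nucleus_radius` must be at most 0.4 * semi_minor.")
  }
  multi <- cells$n_nuclei > 1
  if (any(multi)) {
    spacing <- cells$semi_major[multi] / (cells$n_nuclei[multi] - 1)
    if (any(spacing <= 2 * cells$nucleus_radius[multi])) {
      abort("Nuclei would touch: reduce `n_nuclei` or `nucleus_radius`.")
    }
  }
  # bounding boxes must fit inside the image (0-based pixel-centered coords)
  th <- cells$orientation
  half_c <- sqrt((cells$semi_major * cos(th))^2 + (cells$semi_minor * sin(th))^2)
  half_r <- sqrt((cells$semi_major * sin(th))^2 + (cells$semi_minor * cos(th))^2)
  if (any(cells$center_row - half_r < 0) ||
      any(cells$center_row + half_r > image_shape[1] - 1) ||
      any(cells$center_col - half_c < 0) ||
      any(cells$center_col + half_c > image_shape[2] - 1)) {
    abort("All ellipses must lie fully inside the image.")
  }

  expand <- function(x, arg) {
    if (length(x) == 1) x <- setNames(rep(x, length(roles)), roles)
    if (!all(roles %in% names(x)) || any(x < 0)) {
      abort(sprintf("`%s` must be non-negative, scalar or named per role.", arg))
    }
    x[roles]
  }

  structure(
    list(
      cells = cells, image_shape = image_shape,
      channel_roles = channel_roles,
      background_level = expand(background_level, "background_level"),
      noise_sd = expand(noise_sd, "noise_sd"),
      seed = check_count_scalar(seed, "seed")
    ),
    class = "image_sim_spec"
  )
}

# logical mask of an ellipse evaluated at pixel centers (1-based matrix
# indices, 0-based coordinates)
ellipse_mask <- function(shape, center_row, center_col, a, b, theta) {
  r <- matrix(seq_len(shape[1]) - 1, nrow = shape[1], ncol = shape[2])
  c_ <- matrix(seq_len(shape[2]) - 1, nrow = shape[1], ncol = shape[2],
               byrow = TRUE)
  dx <- c_ - center_col
  dy <- r - center_row
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(shape, center_row, center_col, radius) {
  ellipse_mask(shape, center_row, center_col, radius, radius, 0)
}

#' Render a synthetic field and return its ground truth
#'
#' Each cell is drawn as a filled ellipse in every channel whose intensity
#' is positive, except DAPI, where only the nuclei (filled disks placed
#' along the major axis, fully inside the ellipse) are drawn. Per-channel
#' background and Gaussian noise are then added and negative pixels clamped
#' to zero.
#'
#' @param spec An [image_sim_spec()].
#' @return A list with `image` (a [channel_image()]) and `truth` (tibble
#'   with per-cell `cell`, centroid, analytic `area` and `eccentricity`,
#'   rendered `pixel_area`, `n_nuclei`, and the configured per-role
#'   intensities).
#' @examples
#' spec <- image_sim_spec(
#'   cells = tibble::tibble(
#'     center_row = 40, center_col = 40, semi_major = 10, semi_minor = 10,
#'     orientation = 0, n_nuclei = 1, nucleus_radius = 3,
#'     dapi = 150, gfp = 200, mcherry = 0, cfp = 120, marker = 0
#'   ),
#'   image_shape = c(80, 80)
#' )
#' field <- simulate_image(spec)
#' field$truth$area # pi * 100
#' @export
simulate_image <- function(spec) {
  if (!inherits(spec, "image_sim_spec")) {
    abort("`spec` must be an `image_sim_spec`.")
  }
  shape <- spec$image_shape
  roles <- names(spec$channel_roles)
  n_chan <- max(spec$channel_roles)
  img <- array(0, dim = c(shape[1], shape[2], n_chan))
  claimed <- matrix(0L, shape[1], shape[2])
  cells <- spec$cells
  n <- nrow(cells)
  pixel_area <- integer(n)

  for (i in seq_len(n)) {
    m <- ellipse_mask(shape, cells$center_row[i], cells$center_col[i],
                      cells$semi_major[i], cells$semi_minor[i],
                      cells$orientation[i])
    if (any(claimed[m] > 0)) {
      abort(sprintf("Cell %d overlaps a previously placed cell.", i))
    }
    claimed[m] <- i
    pixel_area[i] <- sum(m)
    for (role in setdiff(roles, "dapi")) {
      inten <- cells[[role]][i]
      if (inten > 0) {
        plane <- spec$channel_roles[[role]]
        img[, , plane][m] <- inten
      }
    }
    # nuclei along the major axis
    if (cells$n_nuclei[i] > 0 && "dapi" %in% roles) {
      f <- if (cells$n_nuclei[i] == 1) 0 else
        seq(-0.5, 0.5, length.out = cells$n_nuclei[i])
      th <- cells$orientation[i]
      for (k in seq_len(cells$n_nuclei[i])) {
        nr <- cells$center_row[i] + f[k] * cells$semi_major[i] * sin(th)
        nc <- cells$center_col[i] + f[k] * cells$semi_major[i] * cos(th)
        dm <- disk_mask(shape, nr, nc, cells$nucleus_radius[i])
        plane <- spec$channel_roles[["dapi"]]
        img[, , plane][dm] <- cells[["dapi"]][i]
      }
    }
  }

  with_sim_seed(spec$seed, {
    for (role in roles) {
      plane <- spec$channel_roles[[role]]
      img[, , plane] <- img[, , plane] + spec$background_level[[role]]
      if (spec$noise_sd[[role]] > 0) {
        img[, , plane] <- img[, , plane] +
          rnorm(shape[1] * shape[2], sd = spec$noise_sd[[role]])
      }
    }
  })
  img[img < 0] <- 0

  truth <- tibble(
    cell = seq_len(n),
    center_row = cells$center_row,
    center_col = cells$center_col,
    area = pi * cells$semi_major * cells$semi_minor,
    eccentricity = sqrt(1 - (cells$semi_minor / cells$semi_major)^2),
    pixel_area = pixel_area,
    n_nuclei = cells$n_nuclei
  )
  for (role in roles) truth[[paste0("intensity_", role)]] <- cells[[role]]

  list(
    image = channel_image(img, spec$channel_roles),
    truth = truth
  )
}

#' Random non-overlapping field specification
#'
#' Places `n_cells` random ellipses on a jittered grid so that cells can
#' never overlap, with sizes, orientations, and intensities drawn from
#' ranges typical of dissociated liver cells in the tests.
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param n_nuclei Per-cell nucleus counts (recycled).
#' @param semi_major_range,axis_ratio_range Ranges for ellipse geometry.
#' @param intensities Named list of per-role intensity ranges
#'   (`c(min, max)`) or fixed values.
#' @inheritParams image_sim_spec
#' @return An [image_sim_spec()].
#' @export
random_image_spec <- function(n_cells = 6,
                              seed = 1L,
                              n_nuclei = 1L,
                              semi_major_range = c(10, 16),
                              axis_ratio_range = c(0.7, 1),
                              intensities = list(dapi = 150, gfp = c(120, 220),
                                                 mcherry = 0, cfp = 100,
                                                 marker = 0),
                              background_level = 0,
                              noise_sd = 0) {
  n_cells <- check_count_scalar(n_cells, "n_cells", min = 1L)
  with_sim_seed(seed, {
    per_side <- ceiling(sqrt(n_cells))
    cell_px <- 2 * ceiling(max(semi_major_range)) + 8
    shape <- rep(per_side * cell_px + 8L, 2)
    slots <- expand.grid(gr = seq_len(per_side), gc = seq_len(per_side))
    slots <- slots[sample.int(nrow(slots), n_cells), , drop = FALSE]
    a <- stats::runif(n_cells, semi_major_range[1], semi_major_range[2])
    b <- a * stats::runif(n_cells, axis_ratio_range[1], axis_ratio_range[2])
    jitter_amt <- (cell_px / 2 - max(semi_major_range)) - 1
    cells <- tibble(
      center_row = 4 + (slots$gr - 0.5) * cell_px +
        stats::runif(n_cells, -jitter_amt, jitter_amt),
      center_col = 4 + (slots$gc - 0.5) * cell_px +
        stats::runif(n_cells, -jitter_amt, jitter_amt),
      semi_major = a,
      semi_minor = b,
      orientation = stats::runif(n_cells, 0, pi),
      n_nuclei = as.integer(rep_len(n_nuclei, n_cells)),
      # keep nuclei well separated so rasterized disks never touch
      nucleus_radius = pmin(3, 0.4 * b,
                            ifelse(rep_len(n_nuclei, n_cells) > 1,
                                   (a / pmax(1, rep_len(n_nuclei, n_cells) - 1) - 3) / 2,
                                   Inf))
    )
    for (role in names(intensities)) {
      rng <- intensities[[role]]
      cells[[role]] <- if (length(rng) == 2) {
        stats::runif(n_cells, rng[1], rng[2])
      } else {
        rep(rng, n_cells)
      }
    }
    image_sim_spec(cells, image_shape = shape,
                   background_level = background_level, noise_sd = noise_sd,
                   seed = seed)
  })
}
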