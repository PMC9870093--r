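test_that("simulated cells carry closed-form truth", {
  circ <- single_cell_field(a = 10, b = 10)
  expect_equal(circ$truth$area, pi * 100)
  expect_equal(circ$truth$eccentricity, 0)
  # rendered pixel count close to the analytic area
  expect_lt(abs(circ$truth$pixel_area - pi * 100) / (pi * 100), 0.02)

  ell <- single_cell_field(a = 5, b = 3)
  expect_equal(ell$truth$eccentricity, 0.8) # sqrt(1 - 9/25)

  bi <- single_cell_field(a = 12, b = 9, n_nuclei = 2)
  expect_equal(bi$truth$n_nuclei, 2)
})

test_that("overlapping cells are rejected and seeds reproduce noise", {
  cells <- tibble::tibble(
    center_row = c(40, 44), center_col = c(40, 44),
    semi_major = c(8, 8), semi_minor = c(8, 8), orientation = 0,
    n_nuclei = 1, nucleus_radius = 2,
    dapi = 100, gfp = 100, mcherry = 0, cfp = 0, marker = 0
  )
  spec <- image_sim_spec(cells, image_shape = c(90, 90))
  expect_error(simulate_image(spec), "overlaps")

  spec2 <- random_image_spec(n_cells = 3, seed = 5, noise_sd = 4)
  f1 <- simulate_image(spec2)
  f2 <- simulate_image(spec2)
  expect_identical(f1$image$image, f2$image$image)
})

test_that("cellular mask is the union of the reporter channels", {
  one <- single_cell_field(a = 10, b = 7, gfp = 200, mcherry = 0)
  lab <- cellular_mask(one$image)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), one$truth$pixel_area)
  expect_lt(abs(sum(lab > 0) - pi * 70) / (pi * 70), 0.02)

  two <- image_sim_spec(
    cells = tibble::tibble(
      center_row = c(25, 70), center_col = c(25, 70),
      semi_major = 9, semi_minor = 7, orientation = 0,
      n_nuclei = 1, nucleus_radius = 2.5,
      dapi = 120, gfp = c(180, 0), mcherry = c(0, 180), cfp = 0, marker = 0
    ),
    image_shape = c(96, 96)
  )
  field <- simulate_image(two)
  expect_equal(max(cellular_mask(field$image)), 2)

  blank <- channel_image(array(0, c(40, 40, 3)),
                         c(dapi = 1, gfp = 2, mcherry = 3))
  expect_equal(max(cellular_mask(blank)), 0)
})

test_that("nuclear mask recovers separated nuclei with plausible areas", {
  spec <- image_sim_spec(
    cells = tibble::tibble(
      center_row = c(20, 20, 60), center_col = c(20, 60, 40),
      semi_major = 10, semi_minor = 9, orientation = 0,
      n_nuclei = 1, nucleus_radius = 3,
      dapi = 150, gfp = 100, mcherry = 0, cfp = 0, marker = 0
    ),
    image_shape = c(80, 80)
  )
  field <- simulate_image(spec)
  nuc <- nuclear_mask(field$image)
  expect_equal(max(nuc), 3)
  areas <- tabulate(nuc[nuc > 0])
  expect_true(all(abs(areas - pi * 9) / (pi * 9) < 0.2))

  blank <- channel_image(array(0, c(30, 30, 1)), c(dapi = 1))
  expect_equal(max(nuclear_mask(blank)), 0)
})

test_that("nuclei attach to cells by centroid containment", {
  cells <- matrix(0L, 20, 20)
  cells[3:10, 3:10] <- 1L
  cells[12:18, 12:18] <- 2L
  nuclei <- matrix(0L, 20, 20)
  nuclei[4:6, 4:6] <- 1L    # inside cell 1
  nuclei[8:9, 8:9] <- 2L    # also inside cell 1
  nuclei[14:16, 14:16] <- 3L # inside cell 2
  nuclei[1:2, 18:19] <- 4L  # on background: belongs to no cell
  asg <- assign_nuclei(cells, nuclei)
  expect_equal(asg$counts$nucleus_count[asg$counts$cell == 1], 2)
  expect_equal(asg$counts$nucleus_count[asg$counts$cell == 2], 1)
  expect_equal(asg$assignments$cell[asg$assignments$nucleus == 4], 0)
})

test_that("the exactly-one-nucleus filter retains the mono-nucleate set", {
  recs <- tibble::tibble(cell = c("A", "B", "C"),
                         nucleus_count = c(1L, 2L, 0L), area = c(10, 20, 30))
  expect_message(kept <- filter_single_nucleus(recs), "removed")
  expect_equal(kept$cell, "A")
  expect_equal(kept$area, 10) # surviving measurements untouched

  all_ok <- tibble::tibble(cell = 1:3, nucleus_count = rep(1L, 3))
  expect_identical(filter_single_nucleus(all_ok), all_ok)

  # 5 mono- and 3 bi-nucleate rendered cells
  spec <- random_image_spec(n_cells = 8, seed = 6,
                            n_nuclei = c(1, 1, 1, 1, 1, 2, 2, 2))
  field <- simulate_image(spec)
  recs2 <- quantify_field(field$image, single_nucleus_only = FALSE)
  expect_equal(sort(recs2$nucleus_count), c(1, 1, 1, 1, 1, 2, 2, 2))
  expect_message(kept2 <- filter_single_nucleus(recs2))
  expect_equal(nrow(kept2), 5)
})

test_that("moment-based measurements recover geometry and intensity", {
  circ <- single_cell_field(a = 10, b = 10, cfp = 120)
  cells <- cellular_mask(circ$image)
  nuclei <- nuclear_mask(circ$image)
  recs <- measure_cells(cells, nuclei, circ$image)
  expect_lt(recs$eccentricity, 0.1)
  expect_equal(recs$intensity_cfp, 120) # uniform fill, zero noise
  expect_equal(recs$area, circ$truth$pixel_area)
  expect_equal(recs$centroid_row, circ$truth$center_row, tolerance = 0.05)

  ell <- single_cell_field(a = 5, b = 3, gfp = 200)
  cells2 <- cellular_mask(ell$image, min_area = 20)
  recs2 <- measure_cells(cells2, nuclear_mask(ell$image, min_area = 3),
                         ell$image)
  expect_equal(recs2$eccentricity, 0.8, tolerance = 0.05)
})

test_that("eccentricity grows monotonically with elongation at fixed b", {
  eccs <- vapply(c(6, 9, 12, 15, 18), function(a) {
    f <- single_cell_field(a = a, b = 6, shape = c(60, 60))
    cells <- cellular_mask(f$image)
    measure_cells(cells, nuclear_mask(f$image), f$image)$eccentricity
  }, numeric(1))
  expect_true(all(diff(eccs) > 0))
  expect_lt(eccs[1], 0.1)
  expect_gt(eccs[5], 0.9)
})

test_that("border-touching cells are excluded and logged", {
  img <- array(0, c(40, 40, 3))
  img[1:10, 5:15, 2] <- 200   # touches row 1
  img[20:30, 20:30, 2] <- 200 # interior
  ci <- channel_image(img, c(dapi = 1, gfp = 2, mcherry = 3))
  expect_message(lab <- cellular_mask(ci), "border")
  expect_equal(max(lab), 1)
  lab2 <- suppressMessages(cellular_mask(ci, exclude_border = FALSE))
  expect_equal(max(lab2), 2)
})

test_that("grid export tiles thumbnails and round-trips pixel-exactly", {
  spec <- random_image_spec(n_cells = 4, seed = 7)
  field <- simulate_image(spec)
  recs <- quantify_field(field$image)
  path <- file.path(withr::local_tempdir(), "grid.tiff")
  grid <- export_grid(recs, field$image, thumb_size = 32, path = path)
  expect_equal(dim(grid$grid)[1:2], c(64, 64)) # 4 cells -> 2 x 2 tiles
  expect_equal(nrow(grid$index), nrow(recs))

  # single cell -> single tile
  g1 <- export_grid(recs[1, ], field$image, thumb_size = 32)
  expect_equal(dim(g1$grid)[1:2], c(32, 32))

  # round trip through the TIFF recovers each centered crop exactly
  reread <- read_channel_tiff(path)
  for (id in grid$index$cell) {
    crop <- extract_grid_cell(reread$image, grid$index, id, 32)
    rec <- recs[recs$cell == id, ]
    r0 <- round(rec$centroid_row) + 1
    c0 <- round(rec$centroid_col) + 1
    direct <- field$image$image[(r0 - 16):(r0 + 15), (c0 - 16):(c0 + 15), ,
                                drop = FALSE]
    expect_equal(crop, round(direct))
  }
})

test_that("lineage calls follow the reporter thresholds", {
  recs <- tibble::tibble(intensity_gfp = c(200, 200, 10),
                         intensity_mcherry = c(0, 200, 180))
  out <- classify_lineage(recs, 50, 50)
  expect_equal(out$lineage, c("gfp", "ambiguous", "mcherry"))

  # mixed rendered field at 10:1 contrast, zero noise: all calls correct
  spec <- random_image_spec(
    n_cells = 12, seed = 8,
    intensities = list(dapi = 150, gfp = 0, mcherry = 0, cfp = 100,
                       marker = 0)
  )
  cells <- spec$cells
  truth_lineage <- rep(c("gfp", "mcherry"), 6)
  cells$gfp <- ifelse(truth_lineage == "gfp", 200, 20)
  cells$mcherry <- ifelse(truth_lineage == "mcherry", 200, 20)
  field <- simulate_image(image_sim_spec(cells, spec$image_shape,
                                         seed = spec$seed))
  recs2 <- quantify_field(field$image)
  recs2 <- classify_lineage(recs2, gfp_threshold = 100,
                            mcherry_threshold = 100)
  expect_equal(nrow(recs2), 12)
  # map measured objects back to generating cells by nearest centroid
  truth_idx <- vapply(seq_len(nrow(recs2)), function(i) {
    which.min((field$truth$center_row - recs2$centroid_row[i])^2 +
                (field$truth$center_col - recs2$centroid_col[i])^2)
  }, integer(1))
  expect_equal(recs2$lineage, truth_lineage[truth_idx])
})

test_that("biliary-derived fraction counts mCherry-lineage hepatocytes", {
  recs <- tibble::tibble(
    intensity_cfp = c(rep(150, 10), rep(5, 4)),
    lineage = c(rep("mcherry", 9), "gfp", rep("mcherry", 4))
  )
  out <- biliary_derived_fraction(recs, cfp_threshold = 50)
  expect_equal(out$fraction, 0.9)
  expect_equal(out$n_hepatocytes, 10)

  none <- tibble::tibble(intensity_cfp = c(150, 150),
                         lineage = c("gfp", "gfp"))
  expect_equal(biliary_derived_fraction(none, 50)$fraction, 0)

  expect_warning(
    und <- biliary_derived_fraction(
      tibble::tibble(intensity_cfp = 1, lineage = "gfp"), 50
    ),
    "undefined"
  )
  expect_true(is.na(und$fraction))

  # rendered field with a known 85% biliary-derived composition
  spec <- random_image_spec(n_cells = 20, seed = 9)
  cells <- spec$cells
  lineage <- c(rep("mcherry", 17), rep("gfp", 3))
  cells$gfp <- ifelse(lineage == "gfp", 200, 0)
  cells$mcherry <- ifelse(lineage == "mcherry", 200, 0)
  cells$cfp <- 120
  field <- simulate_image(image_sim_spec(cells, spec$image_shape,
                                         seed = spec$seed))
  recs3 <- quantify_field(field$image)
  recs3 <- classify_lineage(recs3, 50, 50)
  expect_equal(biliary_derived_fraction(recs3, 50)$fraction, 0.85)
})

test_that("quantification is deterministic for fixed inputs", {
  spec <- random_image_spec(n_cells = 5, seed = 10, noise_sd = 2)
  field <- simulate_image(spec)
  expect_identical(quantify_field(field$image), quantify_field(field$image))
})
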