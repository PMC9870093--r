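test_that("barcodes rank by descending total with lexicographic ties", {
  m <- counts_from_totals(c(A = 10, B = 30, C = 20))
  expect_equal(rank_barcodes(m, 3)$barcode, c("B", "C", "A"))

  tie <- counts_from_totals(c(B = 5, A = 5))
  expect_equal(rank_barcodes(tie, 2)$barcode, c("A", "B"))

  zero <- counts_from_totals(c(A = 0, B = 0))
  expect_error(rank_barcodes(zero), "zero")
})

test_that("truncation keeps exactly the top max_barcodes", {
  set.seed(21)
  totals <- rpois(6000, 10)
  names(totals) <- sprintf("bc%04d", seq_along(totals))
  m <- counts_from_totals(totals)
  ranked <- rank_barcodes(m, 5000)
  expect_equal(nrow(ranked), 5000)
  dropped <- setdiff(names(totals), ranked$barcode)
  expect_true(min(ranked$total) >= max(totals[dropped]))
  # brute-force comparison against a plain sort
  expect_equal(sum(ranked$total), sum(sort(totals, decreasing = TRUE)[1:5000]))
})

test_that("cumulative-fraction slopes classify the worked example", {
  m <- counts_from_totals(c(b1 = 100, b2 = 50, b3 = 30, b4 = 10, b5 = 5,
                            b6 = 5))
  cls <- classify_barcodes(m)
  expect_equal(cls$slope, c(0.5, 0.25, 0.15, 0.05, 0.025, 0.025))
  expect_equal(attr(cls, "average_slope"), 1 / 6)
  expect_equal(cls$label, c("cell", "cell", rep("background", 4)))
  # slopes over the barcodes considered always sum to 1
  expect_equal(sum(cls$slope), 1)
})

test_that("uniform totals put every barcode at the average slope: all cells", {
  m <- counts_from_totals(c(a = 7, b = 7, c = 7, d = 7))
  cls <- classify_barcodes(m)
  expect_true(all(cls$label == "cell"))
  expect_error(classify_barcodes(counts_from_totals(c(only = 5))),
               "At least 2")
})

test_that("slope rule equals the brute-force mean-total rule on random data", {
  set.seed(22)
  for (i in 1:200) {
    m <- random_counts(n_genes = 5, n_barcodes = sample(3:40, 1),
                       lambda = sample(c(1, 5, 50), 1))
    if (sum(m) == 0) next
    max_bc <- sample(2:ncol(m), 1)
    cls <- classify_barcodes(m, max_barcodes = max_bc)
    expect_equal(attr(cls, "average_slope"), 1 / nrow(cls))
    oracle <- ifelse(cls$total >= mean(cls$total), "cell", "background")
    expect_identical(cls$label, oracle)
  }
})

test_that("background thresholds are nearest-rank order statistics", {
  # 20 background barcodes with known per-gene count patterns, plus one
  # dominant cell barcode that absorbs the 'cell' label
  bg_counts <- rbind(
    g_sparse = c(rep(0L, 19), 3L),        # 19th order stat -> 0
    g_half = rep(c(0L, 1L), each = 10),   # ceil(.95*20)=19th -> 1
    g_absent = rep(0L, 20)                # -> 0
  )
  m <- cbind(bg_counts, CELL = c(500L, 500L, 500L))
  colnames(m) <- c(sprintf("bg%02d", 1:20), "CELL")
  rownames(m) <- rownames(bg_counts)
  cls <- classify_barcodes(m)
  expect_equal(sum(cls$label == "cell"), 1)
  bgm <- fit_background_model(m, cls)
  expect_equal(bgm$threshold[match(c("g_sparse", "g_half", "g_absent"),
                                   bgm$gene)],
               c(0L, 1L, 0L))
  expect_equal(attr(bgm, "n_background_barcodes"), 20)
})

test_that("subtraction floors at zero and keeps only cell barcodes", {
  m <- matrix(c(5L, 1L, 9L,
                4L, 0L, 7L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("big", "tiny", "mid")))
  cls <- classify_barcodes(m)
  bgm <- tibble::tibble(gene = c("gA", "gB"), threshold = c(2L, 7L))
  attr(bgm, "quantile_level") <- 0.95
  attr(bgm, "n_background_barcodes") <- 1L
  class(bgm) <- c("background_model", class(bgm))

  out <- subtract_background(m, bgm, cls)
  cells <- cls$barcode[cls$label == "cell"]
  expect_setequal(colnames(out), cells)
  expect_equal(out["gA", "big"], 5L - 2L)
  expect_equal(out["gB", "big"], 0L) # 4 - 7 floored to zero
  expect_true(all(out <= m[, colnames(out)])) # monotone correction

  # all-zero thresholds leave the cell columns untouched
  bgm0 <- bgm
  bgm0$threshold <- c(0L, 0L)
  expect_equal(subtract_background(m, bgm0, cls), m[, colnames(out)])

  # gene coverage is enforced
  expect_error(subtract_background(m, bgm[1, ], cls), "lacks")
})

test_that("subtract-then-restrict equals restrict-then-subtract", {
  set.seed(23)
  m <- random_counts(20, 50, lambda = 3)
  m[, 1:3] <- m[, 1:3] + 40L # a few clear cells
  pre <- preprocess_droplets(m, quantile_level = 0.95)
  cells <- pre$classification$barcode[pre$classification$label == "cell"]
  idx <- match(rownames(m), pre$background$gene)
  alt <- m[, intersect(colnames(m), cells), drop = FALSE] -
    pre$background$threshold[idx]
  alt[alt < 0] <- 0L
  storage.mode(alt) <- "integer"
  expect_identical(pre$counts, alt)
})

test_that("genes absent from background barcodes pass through unchanged", {
  set.seed(24)
  m <- random_counts(10, 30, lambda = 2)
  m[, 1] <- m[, 1] + 100L
  m[4, ] <- 0L
  m[4, 1] <- 50L # expressed only in the cell barcode
  pre <- preprocess_droplets(m)
  expect_equal(pre$background$threshold[4], 0L)
  expect_equal(pre$counts[4, colnames(m)[1]], 50L)
})

test_that("ambient subtraction moves cell profiles toward the truth", {
  # paired comparison on a handful of seeds; the acceptance suite runs 20
  improved <- vapply(1:5, function(s) {
    spec <- droplet_sim_spec(ambient_fraction = 0.2, seed = s)
    sim <- simulate_droplets(spec)
    pre <- preprocess_droplets(sim$counts)
    mad_for <- function(counts) {
      devs <- vapply(names(spec$celltype_profiles), function(tp) {
        bcs <- intersect(
          sim$truth$barcode[sim$truth$is_cell & sim$truth$cell_type == tp],
          colnames(counts)
        )
        pooled <- rowSums(counts[, bcs, drop = FALSE])
        mean(abs(pooled / sum(pooled) - spec$celltype_profiles[[tp]]))
      }, numeric(1))
      mean(devs)
    }
    cells <- sim$truth$barcode[sim$truth$is_cell]
    mad_raw <- mad_for(sim$counts[, cells, drop = FALSE])
    mad_cor <- mad_for(pre$counts)
    mad_cor < mad_raw
  }, logical(1))
  expect_true(all(improved))
})
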