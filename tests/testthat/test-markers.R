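test_that("dot-plot fractions and averages match a per-cell loop oracle", {
  m <- matrix(0L, nrow = 2, ncol = 4,
              dimnames = list(c("gX", "gY"), sprintf("c%d", 1:4)))
  m["gX", 1] <- 5L
  m["gY", ] <- 1L
  nm <- log_normalize(m)
  st <- dotplot_stats(nm, rep("K", 4))
  expect_equal(st$fraction_expressing[st$gene == "gX"], 0.25)
  gx <- st[st$gene == "gX", ]
  expect_equal(gx$avg_expression, mean(nm["gX", ]))

  # absent gene: average 0, fraction 0
  m2 <- rbind(m, gZ = 0L)
  nm2 <- log_normalize(m2)
  st2 <- dotplot_stats(nm2, rep("K", 4), genes = "gZ")
  expect_equal(st2$avg_expression, 0)
  expect_equal(st2$fraction_expressing, 0)

  # random two-cluster fixture against an explicit loop
  set.seed(51)
  fx <- two_cluster_counts(n_genes = 15, n_per_side = 12,
                           shift_genes = 1:3, fold = 4)
  nmr <- log_normalize(fx$counts)
  st3 <- dotplot_stats(nmr, fx$labels)
  for (k in seq_len(nrow(st3))) {
    cols <- which(fx$labels == st3$cluster[k])
    vals <- vapply(cols, function(j) nmr[st3$gene[k], j], numeric(1))
    expect_equal(st3$avg_expression[k], sum(vals) / length(vals))
    expect_equal(st3$fraction_expressing[k], sum(vals > 0) / length(vals))
  }
  expect_error(dotplot_stats(nmr, fx$labels, genes = "nope"), "Unknown gene")
})

test_that("a strong one-sided shift is reported for its cluster only", {
  set.seed(52)
  fx <- two_cluster_counts(n_genes = 60, n_per_side = 100,
                           shift_genes = 5, fold = 8)
  nm <- log_normalize(fx$counts)
  mk <- find_markers(nm, fx$labels)
  hit <- mk[mk$gene == "g005", ]
  expect_equal(hit$cluster, "A")
  expect_true(all(mk$p_adj < 0.05))
  expect_true(all(mk$avg_in > mk$avg_rest))
  expect_gte(glance(mk)$n_tests, nrow(mk))
})

test_that("genes elevated in the rest are never reported (positive-only)", {
  set.seed(53)
  fx <- two_cluster_counts(n_genes = 60, n_per_side = 80,
                           shift_genes = 7, fold = 8)
  nm <- log_normalize(fx$counts)
  # g007 is high in A, so from B's perspective it is a "rest" gene
  mk <- find_markers(nm, fx$labels)
  expect_false("g007" %in% mk$gene[mk$cluster == "B"])
})

test_that("tiny clusters are skipped with a warning", {
  set.seed(54)
  fx <- two_cluster_counts(n_genes = 20, n_per_side = 10)
  labels <- fx$labels
  labels[1:2] <- "C" # a 2-cell cluster
  nm <- log_normalize(fx$counts)
  expect_warning(mk <- find_markers(nm, labels), "fewer than 3")
  expect_false("C" %in% mk$cluster)
})

test_that("retained marker sets match a naive wilcox.test pipeline exactly", {
  set.seed(55)
  for (rep in 1:5) {
    fx <- two_cluster_counts(n_genes = 50, n_per_side = 30,
                             shift_genes = sample(50, 4), fold = 6)
    nm <- log_normalize(fx$counts)
    mk <- find_markers(nm, fx$labels)

    # independent re-derivation: explicit loops + stats::wilcox.test;
    # Bonferroni family = genes x cluster comparisons
    rows <- list()
    for (cl in c("A", "B")) {
      for (g in rownames(nm)) {
        x <- nm[g, fx$labels == cl]
        y <- nm[g, fx$labels != cl]
        pct <- c(mean(x > 0), mean(y > 0))
        lfc <- log((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))
        if (max(pct) >= 0.1 && lfc >= 0.25) {
          p <- suppressWarnings(wilcox.test(x, y)$p.value)
          rows[[length(rows) + 1]] <-
            data.frame(gene = g, cluster = cl, p = p,
                       positive = mean(x) > mean(y))
        }
      }
    }
    oracle <- do.call(rbind, rows)
    oracle$p_adj <- pmin(1, oracle$p * nrow(nm) * 2)
    kept <- oracle[oracle$p_adj < 0.05 & oracle$positive, ]
    expect_setequal(paste(mk$gene, mk$cluster),
                    paste(kept$gene, kept$cluster))
  }
})

test_that("clusters are identified by at least 3 panel markers", {
  panel <- list(
    hepatocyte = c("fabp10a", "tfa", "cp"),
    bec = c("anxa4", "krt18a.1", "alcama")
  )
  mk <- tibble::tibble(
    gene = c("fabp10a", "tfa", "cp", "anxa4", "krt18a.1"),
    cluster = c("1", "1", "1", "2", "2")
  )
  ids <- identify_cluster(mk, panel)
  expect_equal(ids$cell_type[ids$cluster == "1"], "hepatocyte")
  expect_equal(ids$cell_type[ids$cluster == "2"], "unassigned") # only 2 hits

  ids2 <- identify_cluster(mk[0, ], panel, clusters = "9")
  expect_equal(ids2$cell_type, "unassigned")

  ambiguous <- tibble::tibble(
    gene = c(panel$hepatocyte, panel$bec), cluster = "1"
  )
  expect_error(identify_cluster(ambiguous, panel), "hepatocyte, bec")
  expect_error(identify_cluster(mk, list(two = c("a", "b"))), "fewer than 3")
})

test_that("exchangeable clusters merge and distinct clusters do not", {
  set.seed(56)
  merged <- vapply(1:20, function(i) {
    fx <- two_cluster_counts(n_genes = 200, n_per_side = 100)
    nm <- log_normalize(fx$counts)
    out <- merge_indistinct_clusters(nm, fx$labels)
    length(unique(out)) == 1
  }, logical(1))
  expect_gte(mean(merged), 0.95)

  fx <- two_cluster_counts(n_genes = 200, n_per_side = 100,
                           shift_genes = 1:10, fold = 8)
  nm <- log_normalize(fx$counts)
  out <- merge_indistinct_clusters(nm, fx$labels)
  expect_equal(sort(unique(out)), c("A", "B"))

  single <- merge_indistinct_clusters(nm, rep("only", ncol(nm)))
  expect_true(all(single == "only"))
})

test_that("merging collapses to the smallest label and closes transitively", {
  set.seed(57)
  fx <- two_cluster_counts(n_genes = 150, n_per_side = 60)
  labels <- rep(c("c1", "c2", "c3"), length.out = ncol(fx$counts))
  nm <- log_normalize(fx$counts)
  out <- merge_indistinct_clusters(nm, labels)
  # all three arise from one generative profile: one component, label c1
  expect_true(all(out == "c1"))
  expect_equal(attr(out, "mapping")$new, rep("c1", 3))
})
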