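# shared fixture builders (all data generated in code)

# one-gene matrix whose column totals are exactly `totals`
counts_from_totals <- function(totals) {
  m <- matrix(as.integer(totals), nrow = 1,
              dimnames = list("g1", names(totals)))
  m
}

# random small count matrix with heavy-tailed totals
random_counts <- function(n_genes, n_barcodes, lambda = 5) {
  m <- matrix(rpois(n_genes * n_barcodes, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("b%03d", seq_len(n_barcodes))))
  storage.mode(m) <- "integer"
  m
}

# two-cluster negative-binomial expression fixture: `shift_genes` have
# `fold`-times higher mean in cluster A
two_cluster_counts <- function(n_genes = 200, n_per_side = 100,
                               shift_genes = integer(0), fold = 8,
                               base_mean = 1, dispersion = 2) {
  mu <- matrix(base_mean, nrow = n_genes, ncol = 2 * n_per_side)
  mu[shift_genes, seq_len(n_per_side)] <- base_mean * fold
  m <- matrix(
    rnbinom(length(mu), mu = mu, size = dispersion),
    nrow = n_genes,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(2 * n_per_side)))
  )
  # guard against all-zero cells in tiny fixtures
  zero <- colSums(m) == 0
  m[1, zero] <- 1L
  storage.mode(m) <- "integer"
  list(counts = m,
       labels = rep(c("A", "B"), each = n_per_side))
}

# independent full-enumeration oracle for the two-sided rank-sum p-value:
# enumerates every assignment of the pooled *values* to the first group
enumerate_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(rank(pooled)[idx]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# one-cell field helper: a single ellipse with one nucleus
single_cell_field <- function(a, b, orientation = 0, n_nuclei = 1,
                              nucleus_radius = min(2.5, 0.4 * b),
                              shape = c(96, 96), dapi = 150, gfp = 200,
                              mcherry = 0, cfp = 120, marker = 0,
                              noise_sd = 0, seed = 1) {
  spec <- image_sim_spec(
    cells = tibble::tibble(
      center_row = (shape[1] - 1) / 2, center_col = (shape[2] - 1) / 2,
      semi_major = a, semi_minor = b, orientation = orientation,
      n_nuclei = n_nuclei, nucleus_radius = nucleus_radius,
      dapi = dapi, gfp = gfp, mcherry = mcherry, cfp = cfp, marker = marker
    ),
    image_shape = shape, noise_sd = noise_sd, seed = seed
  )
  simulate_image(spec)
}
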