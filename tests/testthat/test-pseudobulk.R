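test_that("aggregation sums cells per sample and conserves totals", {
  # identity: one cell per sample
  m <- matrix(1:6, 2, 3, dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  cc <- cell_counts(m, c("s1", "s2", "s3"),
                    stats::setNames(c("A", "A", "B"), c("s1", "s2", "s3")))
  pb <- aggregate_cells(cc)
  expect_equal(unname(pb$counts), unname(m))

  # two cells in one sample: (1,2) + (3,4) = (4,6)
  m2 <- matrix(c(1, 2, 3, 4), 2, 2)
  cc2 <- cell_counts(m2, c("s1", "s1"), c(s1 = "A"))
  expect_equal(unname(aggregate_cells(cc2)$counts[, 1]), c(4, 6))

  # random matrix vs loop-based summation oracle
  set.seed(11)
  m3 <- matrix(rpois(20 * 15, 3), 20, 15)
  smp <- sample(paste0("s", 1:3), 15, replace = TRUE)
  cc3 <- cell_counts(m3, smp, stats::setNames(rep("A", 3), paste0("s", 1:3)))
  pb3 <- aggregate_cells(cc3)
  for (s in paste0("s", 1:3)) {
    manual <- rowSums(m3[, smp == s, drop = FALSE])
    expect_equal(unname(pb3$counts[, s]), manual)
  }
  expect_equal(sum(pb3$counts), sum(m3))
  expect_equal(pb3$samples$n_cells,
               as.integer(table(smp)[pb3$samples$sample_id]))

  # zero-cell sample is an error naming the sample
  cc4 <- cell_counts(m2, c("s1", "s1"), c(s1 = "A", s2 = "A"))
  expect_error(aggregate_cells(cc4), "s2")
})

test_that("gene filtering applies the 30-read total threshold", {
  counts <- rbind(g1 = c(10, 10, 9),   # total 29: removed
                  g2 = c(10, 10, 10),  # total 30: retained
                  g3 = c(50, 0, 0))
  pb <- pseudobulk(counts, rep("A", 3))
  f <- filter_genes(pb)
  expect_equal(rownames(f$counts), c("g2", "g3"))
  expect_equal(unname(f$lib_size), unname(colSums(counts[-1, ])))

  expect_equal(filter_genes(pb, min_total = 0)$counts, pb$counts)

  set.seed(2)
  m <- matrix(rpois(300, 4), 100, 3,
              dimnames = list(sprintf("gene%d", 1:100), NULL))
  pbr <- pseudobulk(m, rep("A", 3))
  keep <- vapply(seq_len(100), function(g) sum(m[g, ]) >= 12, TRUE)
  expect_equal(rownames(filter_genes(pbr, 12)$counts), rownames(m)[keep])

  expect_error(filter_genes(pb, min_total = 1e9), "all genes")
})

test_that("sample filtering applies cell and library thresholds", {
  m <- matrix(rpois(40, 20), 10, 4)
  pb <- pseudobulk(m, c("A", "A", "B", "B"),
                   cells_per_sample = c(49, 50, 200, 10))
  f <- suppressWarnings(filter_samples(pb))
  expect_equal(f$samples$n_cells, c(50L, 200L))

  expect_equal(filter_samples(pb, 0, 0)$counts, pb$counts)

  set.seed(3)
  cells <- sample(10:100, 4)
  pbr <- pseudobulk(m, rep(c("A", "B"), 2), cells_per_sample = cells)
  surv <- cells >= 40 & pbr$lib_size >= 150
  if (any(surv)) {
    fr <- suppressWarnings(filter_samples(pbr, 40, 150))
    expect_equal(fr$samples$sample_id, pbr$samples$sample_id[surv])
  }

  # emptied group is a recorded warning, not fatal
  expect_warning(f2 <- filter_samples(pb, min_cells = 60), "A")
  expect_equal(f2$meta$filter_samples$groups_emptied, "A")
})

test_that("TMM factors behave like the trimmed weighted mean of M-values", {
  set.seed(4)
  base <- matrix(rnbinom(50 * 4, mu = 60, size = 5), 50, 4)

  pb_same <- pseudobulk(base[, c(1, 1, 1)], rep("A", 3))
  expect_equal(unname(tmm_norm_factors(pb_same)$norm_factor), rep(1, 3))

  # pure depth change: identical compositions at different depths
  depth <- cbind(base[, 1], base[, 1] * 4, base[, 1] * 2)
  nf <- tmm_norm_factors(pseudobulk(depth, rep("A", 3)))$norm_factor
  expect_equal(unname(nf), rep(1, 3), tolerance = 1e-6)

  # composition shift vs the straight-line oracle
  shift <- base
  shift[1:10, 4] <- shift[1:10, 4] * 8
  pbs <- tmm_norm_factors(pseudobulk(shift, rep("A", 4)))
  expect_equal(unname(pbs$norm_factor), tmm_oracle(shift), tolerance = 1e-8)
  expect_equal(exp(mean(log(pbs$norm_factor))), 1, tolerance = 1e-8)

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  nf_p <- tmm_norm_factors(pseudobulk(shift[, perm], rep("A", 4)))$norm_factor
  expect_equal(unname(nf_p), unname(pbs$norm_factor[perm]), tolerance = 1e-10)

  bad <- pseudobulk(cbind(base[, 1], 0), rep("A", 2))
  expect_error(tmm_norm_factors(bad), "library size")
})

test_that("log-CPM follows the voom offset convention", {
  pb <- pseudobulk(matrix(c(0, 10), 1, 2), rep("A", 2))
  pb$lib_size <- c(999999, 999999)
  lc <- log_cpm(pb)
  expect_equal(lc$values[1, 1], log2(0.5 / 1e6 * 1e6))  # = -1

  set.seed(5)
  m <- matrix(rpois(60, 1000), 20, 3)
  pb2 <- tmm_norm_factors(pseudobulk(m, rep("A", 3)))
  lc2 <- log_cpm(pb2)
  elib <- pb2$lib_size * pb2$norm_factor
  manual <- log2(sweep(m + 0.5, 2, elib + 1, "/") * 1e6)
  expect_equal(unname(lc2$values), unname(manual))
  expect_true(all(is.finite(lc2$values)))

  # doubling a large count raises log-CPM by ~1; monotone in the count
  pb3 <- pseudobulk(matrix(c(5000, 10000), 1, 2), rep("A", 2))
  pb3$lib_size <- c(1e6, 1e6)
  v <- log_cpm(pb3)$values
  expect_equal(v[1, 2] - v[1, 1], 1, tolerance = 1e-3)
})
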