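test_that("contrast fits match closed forms and the oracle", {
  set.seed(70)
  G <- 50; n <- 6
  E <- matrix(rnorm(G * n, 6), G, n,
              dimnames = list(sprintf("gene%d", 1:G), paste0("s", 1:n)))
  X <- cbind(a = rep(c(1, 0), each = 3), b = rep(c(0, 1), each = 3))
  wle <- structure(list(E = E, weights = matrix(1, G, n), design = X,
                        method = "voom"), class = "pbvoom_fit")
  f <- lm_contrast_fit(wle, c(1, -1))
  expect_equal(f$logFC, unname(rowMeans(E[, 1:3]) - rowMeans(E[, 4:6])))

  f0 <- lm_contrast_fit(wle, c(0, 0))
  expect_false(f0$valid)
  expect_equal(f0$logFC, rep(0, G))
  expect_error(moderated_t_table(f0), "invalid")

  W <- matrix(rexp(G * n) + 0.2, G, n)
  wle$weights <- W
  fw <- lm_contrast_fit(wle, c(1, -1))
  orc <- wls_oracle(E, X, W)
  cvec <- c(1, -1)
  expect_equal(fw$logFC, as.vector(orc$coef %*% cvec), tolerance = 1e-10)
  su <- vapply(seq_len(G), function(g)
    sqrt(drop(t(cvec) %*% orc$cov[g, , ] %*% cvec)), 0)
  expect_equal(fw$stdev_unscaled, su, tolerance = 1e-10)

  # string contrasts name design columns
  fs <- lm_contrast_fit(wle, "a-b")
  expect_equal(fs$logFC, fw$logFC)
  expect_error(lm_contrast_fit(wle, "a-z"), "design columns")
})

test_that("variance squeezing recovers the generating prior", {
  # degenerate prior: identical variances
  sq <- squeeze_var(rep(2.5, 100), df_resid = 4)
  expect_equal(sq$d0, Inf)
  expect_equal(sq$s2_post, rep(2.5, 100), tolerance = 1e-6)

  # parameter recovery: s2 ~ s0^2 * F(df, d0), s0^2 = 1, df = 4, d0 = 10
  set.seed(71)
  n <- 5000; df <- 4; d0 <- 10; s0 <- 1
  s2 <- s0 * (rchisq(n, df) / df) / (rchisq(n, d0) / d0)
  sq2 <- squeeze_var(s2, df)
  expect_equal(sq2$s0_sq, s0, tolerance = 0.05)
  expect_equal(sq2$d0, d0, tolerance = 0.30)
  # posterior between the prior and the observation, elementwise
  expect_true(all(sq2$s2_post >= pmin(s2, sq2$s0_sq) - 1e-12))
  expect_true(all(sq2$s2_post <= pmax(s2, sq2$s0_sq) + 1e-12))
})

test_that("variance squeezing agrees with limma::squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(72)
  s2 <- rchisq(3000, 5) / 5 * 1.4
  sq <- squeeze_var(s2, 6)
  ref <- limma::squeezeVar(s2, df = 6)
  expect_equal(sq$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(sq$s0_sq, ref$var.prior, tolerance = 1e-6)
  expect_equal(sq$s2_post, ref$var.post, tolerance = 1e-8)
})

test_that("moderated t reduces to ordinary t and BH matches the step-up", {
  set.seed(73)
  G <- 200; n <- 6
  E <- matrix(rnorm(G * n, 4), G, n,
              dimnames = list(sprintf("gene%d", 1:G), NULL))
  X <- cbind(a = rep(c(1, 0), each = 3), b = rep(c(0, 1), each = 3))
  wle <- structure(list(E = E, weights = matrix(1, G, n), design = X,
                        method = "voom"), class = "pbvoom_fit")
  f <- lm_contrast_fit(wle, c(1, -1))

  # d0 = 0: the prior is disabled and t is the ordinary statistic
  tab0 <- moderated_t_table(f, squeeze = list(d0 = 0, s0_sq = NA,
                                              s2_post = f$s2))
  ord_t <- unname(f$logFC / (f$stdev_unscaled * sqrt(f$s2)))
  expect_equal(tab0$t[match(rownames(E), tab0$gene)], ord_t,
               tolerance = 1e-12)

  # closed-form BH on (0.01, 0.02, 0.03)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  tab <- moderated_t_table(f)
  expect_equal(sort(tab$adj.P.Val), sort(bh_oracle(tab$P.Value)))
  expect_true(!is.unsorted(tab$P.Value))
  expect_true(all(tab$adj.P.Val >= tab$P.Value))

  # monotonicity: inflating |logFC| with all else fixed never shrinks |t|
  f2 <- f; f2$logFC <- f$logFC * 3
  tab2 <- moderated_t_table(f2, squeeze = squeeze_var(f$s2, f$df_resid))
  m <- match(tab$gene, tab2$gene)
  expect_true(all(abs(tab2$t[m]) >= abs(tab$t) - 1e-12))
})

test_that("DE calls respect the cutoff and are nested", {
  empty <- tibble::tibble(gene = character(0), adj.P.Val = numeric(0))
  expect_equal(decide_de(empty, 0.05), character(0))

  tab <- tibble::tibble(gene = c("a", "b"), adj.P.Val = c(0.04, 0.06))
  expect_equal(decide_de(tab, 0.05), "a")

  set.seed(74)
  tabr <- tibble::tibble(gene = sprintf("g%d", 1:100),
                         adj.P.Val = runif(100))
  for (q in c(0.05, 0.2)) {
    expect_equal(decide_de(tabr, q), tabr$gene[tabr$adj.P.Val <= q])
  }
  expect_true(all(decide_de(tabr, 0.05) %in% decide_de(tabr, 0.2)))
})

test_that("p-values are uniform under the global null", {
  set.seed(75)
  G <- 10000; n <- 8
  E <- matrix(rnorm(G * n, 5), G, n,
              dimnames = list(sprintf("gene%d", 1:G), NULL))
  X <- cbind(a = rep(c(1, 0), each = 4), b = rep(c(0, 1), each = 4))
  wle <- structure(list(E = E, weights = matrix(1, G, n), design = X,
                        method = "voom"), class = "pbvoom_fit")
  tab <- de_test(wle, c(1, -1))
  ks <- suppressWarnings(stats::ks.test(tab$P.Value, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(mean(tab$adj.P.Val <= 0.05), 0.01)
})
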