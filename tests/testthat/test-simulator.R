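test_that("effective cell number and the aggregation formula are exact", {
  expect_equal(effective_cell_number(rep(3.2, 7)), 7)
  expect_equal(effective_cell_number(5), 1)
  expect_equal(effective_cell_number(c(1, 2)), 9 / 5)
  expect_error(effective_cell_number(numeric(0)), "empty")

  expect_equal(aggregated_dispersion(0.37, 1, rep(1, 50)), 0.37)
  expect_equal(aggregated_dispersion(0.37, 0, rep(2, 10)), 1 / 10)
  expect_equal(aggregated_dispersion(0.448, 0.1, rep(1, 250)),
               0.1 * 0.448 + 0.9 / 250)  # = 0.04482, BCV ~0.212
})

test_that("the approximate inversion reproduces its arithmetic anchors", {
  expect_equal(solve_phi_sc(0.22, 0.1, 250), (0.22^2 - 0.9 / 250) / 0.1)
  expect_equal(solve_phi_sc(0.22, 0.1, 250), 0.448, tolerance = 1e-3)
  expect_equal(solve_phi_sc(0.20, 0.1, 250), 0.364, tolerance = 1e-3)
  expect_equal(solve_phi_sc(0.26, 0.1, 250), 0.640, tolerance = 1e-3)
  expect_equal(solve_phi_sc(0.28, 0.1, 250), 0.748, tolerance = 1e-3)
  # round trip to machine precision
  for (b in c(0.2, 0.25, 0.3)) {
    phi <- solve_phi_sc(b, 0.1, 250)
    expect_equal(aggregated_dispersion(phi, 0.1, rep(1, 250)), b^2,
                 tolerance = 1e-12)
  }
  expect_error(solve_phi_sc(0.01, 0.1, 250), "floor")
})

test_that("baseline proportions are valid and heavy-tailed", {
  u <- rep(1 / 100, 100)
  expect_identical(make_baseline(100, proportions = u), u)
  expect_error(make_baseline(100, proportions = u[1:50]), "length")
  expect_error(make_baseline(3, proportions = c(0.5, 0.6, -0.1)),
               "non-negative")

  b <- make_baseline(10000, seed = 90)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_identical(b, make_baseline(10000, seed = 90))
  q <- stats::quantile(b, c(0.005, 0.995))
  expect_gt(q[[2]] / q[[1]], 1e4)  # spans >= 4 orders of magnitude
})

test_that("simulated counts have the intended NB moments", {
  # phi_sc = 0: pure Poisson, variance/mean ~ 1
  cfg0 <- sim_config(n_genes = 200,
                     groups = list(list(name = "g", phi_sc = 0,
                                        cell_counts = 4000L)),
                     rho = 0, n_de_per_group = 0, libsize_meanlog = log(2000),
                     libsize_sdlog = 0, seed = 91L)
  cells0 <- simulate_dataset(cfg0)$cells$counts
  ratio <- apply(cells0, 1, var) / rowMeans(cells0)
  expect_equal(mean(ratio), 1, tolerance = 0.05)

  # phi_sc = 0.5, equal expected libraries: var ~ mu + 0.5 mu^2 within 5%
  cfg1 <- sim_config(n_genes = 400,
                     groups = list(list(name = "g", phi_sc = 0.5,
                                        cell_counts = 2500L)),
                     rho = 0, n_de_per_group = 0,
                     baseline = rep(1 / 400, 400),
                     libsize_meanlog = log(400 * 100), libsize_sdlog = 0,
                     seed = 92L)
  cells1 <- simulate_dataset(cfg1)$cells$counts  # each mu = 100
  v <- mean(apply(cells1, 1, var))
  mu <- mean(cells1)
  expect_equal(v, mu + 0.5 * mu^2, tolerance = 0.05)
})

test_that("the copula induces the computed within-subject correlation", {
  # two cells per subject, many subjects; one dominant high-expression gene
  base <- c(0.90, rep(0.10 / 49, 49))
  cfg <- sim_config(n_genes = 50,
                    groups = list(list(name = "g", phi_sc = 0.448,
                                       cell_counts = rep(2L, 2500))),
                    rho = 0.1, n_de_per_group = 0, baseline = base,
                    libsize_meanlog = log(5000), libsize_sdlog = 0,
                    seed = 93L)
  sim <- simulate_dataset(cfg)
  y <- sim$cells$counts[1, ]
  first <- y[seq(1, length(y), 2)]
  second <- y[seq(2, length(y), 2)]
  r_target <- copula_gamma_correlation(1 / 0.448, 0.1)
  expect_lt(abs(cor(first, second) - r_target), 0.03)
  # cells of different subjects are uncorrelated
  expect_equal(cor(first[-1], second[-length(second)]), 0, tolerance = 0.05)
  # and the induced correlation is mildly attenuated below rho
  expect_lt(r_target, 0.1)
  expect_gt(r_target, 0.08)
})

test_that("simulation is reproducible and aggregation-consistent", {
  cfg <- sim_config(n_genes = 300,
                    groups = list(list(name = "a", phi_sc = 0.4,
                                       cell_counts = rep(30L, 2)),
                                  list(name = "b", phi_sc = 0.4,
                                       cell_counts = rep(45L, 2))),
                    seed = 94L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$cells$counts, s2$cells$counts)

  # streaming pseudo-bulk equals aggregated cells, draw for draw
  ps <- simulate_pseudobulk(cfg)
  expect_equal(ps$pb$counts, aggregate_cells(s1$cells)$counts)
  expect_identical(ps$truth$de_genes, s1$truth$de_genes)

  # fast spline quantile path matches exact qgamma
  gq_fast <- pbvoom:::gamma_quantile_fun(1 / 0.448, fast = TRUE)
  gq_exact <- pbvoom:::gamma_quantile_fun(1 / 0.448, fast = FALSE)
  z <- seq(-7.2, 7.2, length.out = 2000)
  expect_equal(gq_fast(z), gq_exact(z), tolerance = 1e-6)
})

test_that("realized pseudo-bulk dispersion matches the stated approximation", {
  # the approximate relation is documented to hold within 15%
  phi_sc <- 0.448
  cfg <- sim_config(n_genes = 2000,
                    groups = list(list(name = "g", phi_sc = phi_sc,
                                       cell_counts = rep(250L, 40))),
                    rho = 0.1, n_de_per_group = 0, seed = 95L)
  sim <- simulate_pseudobulk(cfg)
  pb <- tmm_norm_factors(filter_genes(sim$pb))
  est <- estimate_common_dispersion(pb)$phi
  approx <- aggregated_dispersion(phi_sc, 0.1, rep(1, 250))
  expect_lt(abs(est - approx) / approx, 0.15)
  # and the exact relation predicts it much more closely
  exact <- realized_dispersion(phi_sc, 0.1, 250)
  expect_lt(abs(est - exact) / exact, 0.06)
})

test_that("scenario presets encode the study designs", {
  for (sc in paste0("scenario", 1:4)) {
    cfg <- scenario_preset(sc)
    expect_length(cfg$groups, 4)
    expect_equal(sum(vapply(cfg$groups, function(g)
      length(g$cell_counts), 0L)), 12)
    expect_equal(cfg$rho, 0.1)
    expect_equal(cfg$n_de_per_group, 50L)
    expect_equal(cfg$log2fc, 2)
  }
  s3 <- scenario_preset("scenario3")
  expect_equal(s3$groups[[4]]$cell_counts, c(250L, 750L, 750L))
  expect_equal(s3$groups[[2]]$cell_counts, c(250L, 200L, 200L))
  # dispersion ladder follows the BCV targets
  s1 <- scenario_preset("scenario1")
  phis <- vapply(s1$groups, `[[`, 0, "phi_sc")
  expect_true(!is.unsorted(phis))
  expect_error(scenario_preset("scenario9"), "unknown")
})

test_that("library size scales with cell number", {
  cfg <- scenario_preset("scenario3", n_genes = 1500)
  cfg$seed <- 96L
  libs <- numeric(0)
  for (r in 1:3) {
    cfg$seed <- 96L + r
    sim <- simulate_pseudobulk(cfg)
    lb <- sim$pb$lib_size
    n750 <- sim$pb$samples$n_cells == 750
    n250 <- sim$pb$samples$n_cells == 250
    libs <- c(libs, mean(lb[n750]) / mean(lb[n250]))
  }
  expect_equal(mean(libs), 3, tolerance = 0.05)
})

test_that("configs round-trip through JSON", {
  cfg <- scenario_preset("scenario2", seed = 7L, n_genes = 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back)[names(unclass(cfg))], unclass(cfg),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(simulate_pseudobulk(back)$pb$counts,
                   simulate_pseudobulk(cfg)$pb$counts)
})
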