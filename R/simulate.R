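#' Effective cell number of a sample
#'
#' The library-size-weighted effective number of cells,
#' `N = (sum L)^2 / sum(L^2)`, which governs how much Poisson-level
#' (technical) variation survives aggregation to pseudo-bulk. Equal library
#' sizes give `N` equal to the cell count.
#'
#' @param L Vector of positive cell-wise library sizes.
#' @return The effective cell number (scalar).
#' @export
effective_cell_number <- function(L) {
  if (length(L) == 0) stop("empty library-size vector")
  if (any(L <= 0)) stop("library sizes must be positive")
  sum(L)^2 / sum(L^2)
}

#' Pseudo-bulk dispersion implied by single-cell dispersion
#'
#' The approximate aggregation relation
#' `phi_agg = rho * phi_sc + (1 - rho) / N`, where `rho` is the intra-subject
#' correlation, `phi_sc` the single-cell NB dispersion, and `N` the
#' [effective_cell_number()] of the aggregated cells.
#'
#' @param phi_sc Single-cell NB dispersion (> 0).
#' @param rho Intra-subject correlation in `[0, 1]`.
#' @param L Cell-wise library sizes of the aggregated cells.
#' @return The pseudo-bulk dispersion `phi_agg`.
#' @export
aggregated_dispersion <- function(phi_sc, rho, L) {
  stopifnot(phi_sc >= 0, rho >= 0, rho <= 1)
  rho * phi_sc + (1 - rho) / effective_cell_number(L)
}

#' Solve for the single-cell dispersion hitting a target pseudo-bulk BCV
#'
#' Inverts the aggregation relation at equal library sizes:
#' `phi_sc = (bcv^2 - (1 - rho)/N) / rho`.
#'
#' @param target_bcv Target pseudo-bulk BCV (square root of `phi_agg`).
#' @param rho Intra-subject correlation (> 0).
#' @param n_cells_baseline Baseline number of cells per sample.
#' @return The required single-cell dispersion `phi_sc`.
#' @export
solve_phi_sc <- function(target_bcv, rho, n_cells_baseline) {
  stopifnot(rho > 0, rho <= 1, n_cells_baseline >= 1)
  phi <- (target_bcv^2 - (1 - rho) / n_cells_baseline) / rho
  if (phi <= 0)
    stop("target BCV ", target_bcv, " is below the technical floor ",
         "sqrt((1-rho)/N) = ", sqrt((1 - rho) / n_cells_baseline))
  phi
}

#' Gamma-scale correlation induced by the normal copula
#'
#' A normal copula with correlation `rho` between two standard normal
#' deviates induces a slightly smaller Pearson correlation between the
#' gamma variates obtained by quantile transformation. This computes the
#' induced correlation exactly via the Hermite expansion of the transform
#' `z -> qgamma(pnorm(z), shape)`: `r = sum_k a_k^2 rho^k / shape`, with the
#' coefficients `a_k` evaluated by numerical quadrature.
#'
#' @param shape Gamma shape parameter (`1 / phi_sc`).
#' @param rho Normal-scale correlation in `[0, 1)`.
#' @param kmax Number of Hermite terms (the series converges geometrically
#'   in `rho`).
#' @return The gamma-scale Pearson correlation (scalar, `<= rho`).
#' @export
copula_gamma_correlation <- function(shape, rho, kmax = 16L) {
  if (rho == 0) return(0)
  key <- sprintf("%.10g", shape)
  a2 <- .attenuation_cache[[key]]
  if (is.null(a2)) {
    # Simpson's rule on a dense grid; the integrands are smooth and the
    # normal weight kills the tails well inside |z| = 8.
    m <- 8001L
    z <- seq(-8, 8, length.out = m)
    h <- z[2] - z[1]
    sw <- rep(c(2, 4), length.out = m); sw[1] <- sw[m] <- 1
    g <- stats::qgamma(stats::pnorm(z, lower.tail = FALSE),
                       shape = shape, lower.tail = FALSE)
    base <- g * stats::dnorm(z) * sw * (h / 3)
    a2 <- numeric(kmax)
    he_prev <- rep(1, m)                  # He_0
    he_cur <- z                           # He_1
    for (k in seq_len(kmax)) {
      a2[k] <- sum(base * he_cur)^2 / factorial(k)
      he_next <- z * he_cur - k * he_prev # He_{k+1} = z He_k - k He_{k-1}
      he_prev <- he_cur; he_cur <- he_next
    }
    .attenuation_cache[[key]] <- a2
  }
  sum(a2 * rho^seq_along(a2)) / shape
}

.attenuation_cache <- new.env(parent = emptyenv())

#' Exact pseudo-bulk dispersion of the simulator
#'
#' The dispersion the generated pseudo-bulk data actually obeys (with
#' library-size offsets absorbing per-subject depth variation):
#' `phi_agg = phi_sc * (r + (1 - r)/N)`, where `r` is the copula-induced
#' gamma-scale correlation ([copula_gamma_correlation()]) and `N` the
#' expected [effective_cell_number()] of `n_cells` log-normal cell
#' libraries, `N = n_cells / (1 + cv^2)` with `cv^2 = exp(sdlog^2) - 1`.
#' The relation `rho * phi_sc + (1 - rho)/N` is its first-order
#' approximation (see [aggregated_dispersion()]).
#'
#' @param phi_sc Single-cell NB dispersion.
#' @param rho Normal-scale intra-subject correlation.
#' @param n_cells Cells per sample.
#' @param libsize_sdlog Log-normal sdlog of the per-cell library sizes.
#' @return The realized pseudo-bulk dispersion.
#' @export
realized_dispersion <- function(phi_sc, rho, n_cells, libsize_sdlog = 0.35) {
  if (phi_sc == 0) return(0)
  r <- copula_gamma_correlation(1 / phi_sc, rho)
  N <- n_cells / exp(libsize_sdlog^2)
  phi_sc * (r + (1 - r) / N)
}

#' Calibrate the single-cell dispersion to a target pseudo-bulk BCV
#'
#' Inverts [realized_dispersion()] so that simulated pseudo-bulk data attain
#' the target common BCV, by root finding on `phi_sc`. Used by
#' [scenario_preset()]; [solve_phi_sc()] is the first-order approximate
#' inversion.
#'
#' @inheritParams solve_phi_sc
#' @param libsize_sdlog Log-normal sdlog of the per-cell library sizes.
#' @return The calibrated single-cell dispersion `phi_sc`.
#' @export
calibrate_phi_sc <- function(target_bcv, rho, n_cells_baseline,
                             libsize_sdlog = 0.35) {
  stopifnot(rho > 0, rho <= 1)
  f <- function(phi)
    realized_dispersion(phi, rho, n_cells_baseline, libsize_sdlog) -
      target_bcv^2
  stats::uniroot(f, c(1e-4, 20), tol = 1e-8)$root
}

#' Baseline expression proportions
#'
#' Either validates a user-supplied proportions vector, or synthesizes a
#' heavy-tailed expression spectrum by drawing log-normal intensities
#' (meanlog -1, sdlog 2) and normalizing to sum 1 — emulating the dynamic
#' range of real UMI expression profiles.
#'
#' @param n_genes Number of genes.
#' @param proportions Optional user-supplied non-negative vector of length
#'   `n_genes`; returned renormalized only if it does not already sum to 1.
#' @param meanlog,sdlog Log-normal parameters of the synthetic spectrum.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Proportions vector summing to 1.
#' @export
make_baseline <- function(n_genes, proportions = NULL, meanlog = -1,
                          sdlog = 2, seed = NULL) {
  stopifnot(n_genes >= 1)
  if (!is.null(proportions)) {
    if (length(proportions) != n_genes)
      stop("supplied proportions have length ", length(proportions),
           ", expected ", n_genes)
    if (any(proportions < 0) || any(!is.finite(proportions)))
      stop("proportions must be finite and non-negative")
    s <- sum(proportions)
    if (abs(s - 1) > 1e-8) proportions <- proportions / s
    return(proportions)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  x / sum(x)
}

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param groups List of group specs, each a list with `name`, `phi_sc`
#'   (single-cell NB dispersion) and `cell_counts` (integer vector, one entry
#'   per sample in the group).
#' @param rho Intra-subject (copula) correlation.
#' @param n_de_per_group Number of genes upregulated in each group.
#' @param log2fc True log2 fold change of upregulated genes.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the expected
#'   per-cell library size.
#' @param baseline Optional baseline proportions vector (default: synthesized
#'   per replicate; see [make_baseline()]).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   full configuration.
#' @param fast_quantile Evaluate the gamma quantile transform through a
#'   monotone spline (relative error ~3e-8); set `FALSE` for the exact
#'   `qgamma` path.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_genes = 10000,
                       groups = lapply(1:4, function(i)
                         list(name = paste0("g", i), phi_sc = 0.448,
                              cell_counts = rep(250L, 3))),
                       rho = 0.1, n_de_per_group = 50, log2fc = 2,
                       libsize_meanlog = 7.5, libsize_sdlog = 0.35,
                       baseline = NULL, seed = 1L, fast_quantile = TRUE) {
  stopifnot(rho >= 0, rho <= 1, n_genes >= 1, n_de_per_group >= 0)
  for (g in groups) {
    stopifnot(is.character(g$name), g$phi_sc >= 0,
              all(g$cell_counts >= 1))
  }
  if (length(groups) * n_de_per_group > n_genes)
    stop("not enough genes for disjoint DE sets")
  structure(list(n_genes = as.integer(n_genes), groups = groups, rho = rho,
                 n_de_per_group = as.integer(n_de_per_group),
                 log2fc = log2fc, libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, baseline = baseline,
                 seed = as.integer(seed), fast_quantile = fast_quantile),
            class = "sim_config")
}

#' Scenario presets
#'
#' The four study designs: 12 samples (4 groups x 3), 10,000 genes,
#' intra-subject correlation 0.1, 50 upregulated genes per group at log2FC 2
#' (disjoint across groups, so every pairwise comparison has 100 true DE
#' genes). Single-cell dispersions are solved so pseudo-bulk common BCVs hit
#' the stated targets at the 250-cell baseline:
#'
#' * `scenario1`: 250 cells/sample; group BCV targets 0.20, 0.22, 0.26, 0.28
#'   (biological heteroscedasticity).
#' * `scenario2`: 250 cells/sample; all targets 0.22 (null).
#' * `scenario3`: targets all 0.22; cells per sample scaled by 1:1:1,
#'   1:0.8:0.8, 1:2:2, 1:3:3 off the 250-cell baseline (technical
#'   heteroscedasticity).
#' * `scenario4`: cells as scenario3; targets 0.22, 0.22, 0.24, 0.24
#'   (both sources combined).
#'
#' @param name One of `"scenario1"`..`"scenario4"`.
#' @param seed Seed stored in the returned config.
#' @param n_genes Number of genes (default 10,000).
#' @return A [sim_config()] object with attributes `bcv_target` and
#'   `var_level` (per-group `"Low"`/`"High"`/`"Equal"` labels).
#' @export
scenario_preset <- function(name, seed = 1L, n_genes = 10000) {
  cells_equal <- replicate(4, rep(250L, 3), simplify = FALSE)
  cells_uneq <- list(c(250L, 250L, 250L), c(250L, 200L, 200L),
                     c(250L, 500L, 500L), c(250L, 750L, 750L))
  spec <- switch(name,
    scenario1 = list(bcv = c(0.20, 0.22, 0.26, 0.28), cells = cells_equal,
                     level = c("Low", "Low", "High", "High")),
    scenario2 = list(bcv = rep(0.22, 4), cells = cells_equal,
                     level = rep("Equal", 4)),
    scenario3 = list(bcv = rep(0.22, 4), cells = cells_uneq,
                     level = rep("Equal", 4)),
    scenario4 = list(bcv = c(0.22, 0.22, 0.24, 0.24), cells = cells_uneq,
                     level = c("Low", "Low", "High", "High")),
    stop("unknown scenario: ", name)
  )
  groups <- lapply(1:4, function(i)
    list(name = paste0("g", i),
         phi_sc = calibrate_phi_sc(spec$bcv[i], rho = 0.1,
                                   n_cells_baseline = 250),
         cell_counts = spec$cells[[i]]))
  cfg <- sim_config(n_genes = n_genes, groups = groups, rho = 0.1,
                    n_de_per_group = 50, log2fc = 2, seed = seed)
  attr(cfg, "scenario") <- name
  attr(cfg, "bcv_target") <- spec$bcv
  attr(cfg, "var_level") <- stats::setNames(spec$level,
                                            vapply(groups, `[[`, "", "name"))
  cfg
}

# Monotone-spline evaluation of qgamma(pnorm(z), shape) as a function of the
# normal deviate z. u is clipped to [1e-12, 1 - 1e-12] (|z| <= 7.035), so a
# spline on [-7.1, 7.1] covers the whole range.
gamma_quantile_fun <- function(shape, fast = TRUE) {
  zclip <- stats::qnorm(1 - 1e-12)
  if (!fast) {
    return(function(z) {
      z <- pmin(pmax(z, -zclip), zclip)
      stats::qgamma(stats::pnorm(z), shape = shape)
    })
  }
  grid <- seq(-7.1, 7.1, length.out = 4001)
  f <- stats::splinefun(grid, stats::qgamma(stats::pnorm(grid), shape = shape),
                        method = "hyman")
  function(z) {
    z <- pmin(pmax(z, -zclip), zclip)
    pmax(f(z), 0)
  }
}

# Draw one sample's gene-by-cell counts. RNG order (fixed for
# reproducibility): cell library sizes, subject factor, cell factors, Poisson.
# prop: the group's (DE-spiked) baseline proportions.
sim_sample_counts <- function(cfg, prop, phi_sc, n_cells, gq) {
  G <- cfg$n_genes
  lib <- stats::rlnorm(n_cells, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- outer(prop, lib)                    # G x K expected counts
  if (phi_sc == 0) {
    lam <- mu
  } else {
    a <- stats::rnorm(G)
    b <- matrix(stats::rnorm(G * n_cells), G, n_cells)
    z <- sqrt(cfg$rho) * a + sqrt(1 - cfg$rho) * b
    lam <- gq(z) * (phi_sc * mu)            # Gamma(1/phi, scale mu*phi)
  }
  y <- stats::rpois(G * n_cells, lam)
  matrix(y, G, n_cells)
}

# Shared driver: iterates groups/samples in fixed order, handing each
# sample's count matrix to `consume(sample_id, group, counts)`. The truth
# (baseline draw and DE gene picks) consumes the RNG stream before any cell
# is generated, so `truth_only = TRUE` reproduces exactly the truth of a
# full simulation at a fraction of the cost.
sim_drive <- function(cfg, consume, truth_only = FALSE) {
  set.seed(cfg$seed)
  G <- cfg$n_genes
  baseline <- make_baseline(G, proportions = cfg$baseline)
  gene_ids <- sprintf("gene%d", seq_len(G))
  n_groups <- length(cfg$groups)
  de_idx <- list()
  pool <- seq_len(G)
  for (g in cfg$groups) {
    pick <- if (cfg$n_de_per_group > 0) sample(pool, cfg$n_de_per_group)
            else integer(0)
    de_idx[[g$name]] <- sort(pick)
    pool <- setdiff(pool, pick)
  }
  if (!truth_only) for (g in cfg$groups) {
    prop <- baseline
    prop[de_idx[[g$name]]] <- prop[de_idx[[g$name]]] * 2^cfg$log2fc
    prop <- prop / sum(prop)
    gq <- if (g$phi_sc > 0)
      gamma_quantile_fun(1 / g$phi_sc, fast = cfg$fast_quantile) else NULL
    for (s in seq_along(g$cell_counts)) {
      cnt <- sim_sample_counts(cfg, prop, g$phi_sc, g$cell_counts[s], gq)
      consume(paste0(g$name, "_s", s), g$name, cnt)
    }
  }
  truth <- list(
    de_genes = lapply(de_idx, function(i) gene_ids[i]),
    true_log2fc = cfg$log2fc,
    phi_sc = stats::setNames(vapply(cfg$groups, `[[`, 0, "phi_sc"),
                             vapply(cfg$groups, `[[`, "", "name")),
    rho = cfg$rho,
    expected_group_bcv = stats::setNames(vapply(cfg$groups, function(g)
      sqrt(mean(vapply(g$cell_counts, function(k)
        aggregated_dispersion(g$phi_sc, cfg$rho, rep(1, k)), 0))),
      0), vapply(cfg$groups, `[[`, "", "name")),
    gene_ids = gene_ids
  )
  truth
}

#' Simulation truth without generating counts
#'
#' Reproduces exactly the truth (per-group DE gene sets, fold change,
#' dispersions) that [simulate_dataset()] would record for the same
#' configuration, without drawing any cells.
#'
#' @param cfg A [sim_config()].
#' @return The truth list.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_drive(cfg, function(...) NULL, truth_only = TRUE)
}

#' Simulate a correlated NB single-cell dataset
#'
#' Generates gene-by-cell UMI counts with correlated negative binomial
#' marginals via a Gaussian copula: for each subject, equicorrelated normal
#' deviates (one-factor construction, correlation `rho` within subject) are
#' mapped through the gamma quantile function to "true" expression levels,
#' and Poisson counts are drawn with those expectations. Marginally each
#' count is NB with mean `mu` and variance `mu + phi_sc * mu^2`; the gamma
#' layer carries the biological variation (correlated within subject), the
#' Poisson layer the independent technical variation.
#'
#' @param cfg A [sim_config()].
#' @return A list with `cells` (a [cell_counts()] object) and `truth`
#'   (per-group DE gene sets, true log2FC, dispersions and expected
#'   pseudo-bulk BCVs).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  blocks <- list(); samp <- character(0); grp <- character(0)
  ncells <- integer(0)
  truth <- sim_drive(cfg, function(sid, g, cnt) {
    blocks[[sid]] <<- cnt
    samp <<- c(samp, rep(sid, ncol(cnt)))
    grp[sid] <<- g
    ncells[sid] <<- ncol(cnt)
  })
  counts <- do.call(cbind, blocks)
  storage.mode(counts) <- "integer"
  rownames(counts) <- truth$gene_ids
  colnames(counts) <- paste0(samp, "_c", sequence(ncells))
  cc <- cell_counts(counts, cell_sample = samp, sample_group = grp)
  list(cells = cc, truth = truth)
}

#' Simulate directly to pseudo-bulk
#'
#' Identical draws to [simulate_dataset()] (same seed gives the same
#' aggregate), but each sample's cells are summed as they are generated, so
#' only the gene-by-sample matrix is kept. Preferred for benchmarking at
#' full scale.
#'
#' @param cfg A [sim_config()].
#' @return A list with `pb` (a [pseudobulk()] object, normalization factors
#'   1) and `truth`.
#' @export
simulate_pseudobulk <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cols <- list(); grp <- character(0); ncells <- integer(0)
  truth <- sim_drive(cfg, function(sid, g, cnt) {
    cols[[sid]] <<- rowSums(cnt)
    grp[sid] <<- g
    ncells[sid] <<- ncol(cnt)
  })
  m <- do.call(cbind, cols)
  rownames(m) <- truth$gene_ids
  pb <- pseudobulk(m, sample_group = unname(grp[colnames(m)]),
                   cells_per_sample = unname(ncells[colnames(m)]))
  list(pb = pb, truth = truth)
}

#' Round-trip a simulation configuration as JSON
#'
#' @param cfg A `sim_config`.
#' @param path Output path.
#' @return `write_sim_config` invisibly returns `path`; `read_sim_config`
#'   returns the `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$scenario <- attr(cfg, "scenario")
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(seq_len(nrow(x$groups)), function(i)
    list(name = x$groups$name[i], phi_sc = x$groups$phi_sc[i],
         cell_counts = as.integer(x$groups$cell_counts[[i]])))
  cfg <- sim_config(n_genes = x$n_genes, groups = groups, rho = x$rho,
                    n_de_per_group = x$n_de_per_group, log2fc = x$log2fc,
                    libsize_meanlog = x$libsize_meanlog,
                    libsize_sdlog = x$libsize_sdlog,
                    baseline = x$baseline, seed = x$seed,
                    fast_quantile = x$fast_quantile)
  if (!is.null(x$scenario)) attr(cfg, "scenario") <- x$scenario
  cfg
}

#' Write simulation truth as JSON
#'
#' @param truth Truth list from [simulate_dataset()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sim_truth <- function(truth, path) {
  truth$gene_ids <- NULL
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(path)
}
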