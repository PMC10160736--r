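#' Run the FDR/power simulation benchmark
#'
#' For each replicate: simulate a scenario, aggregate to pseudo-bulk, filter
#' genes with fewer than 30 total reads, TMM-normalize, fit each method on
#' the full 4-group design, and score every pairwise group comparison
#' against the known truth at each adjusted-p cutoff. Pairwise contrasts are
#' fit on the joint design (not by subsetting to the two groups), so residual
#' information is pooled across all groups exactly as in the voom-family
#' pipeline. A comparison calling zero genes contributes FDR 0.
#'
#' @param scenario Scenario name (see [scenario_preset()]) or a `sim_config`
#'   template (its seed is replaced per replicate).
#' @param methods Subset of `"voom"`, `"voomQWB"`, `"voomByGroup"`.
#' @param reps Number of simulation replicates.
#' @param cutoffs Adjusted p-value cutoffs.
#' @param seed Base seed; replicate `r` uses a seed derived from `seed` and
#'   `r`, so the whole table is a deterministic function of `(seed, reps)`.
#' @param min_total Gene filter threshold (total reads across samples).
#' @return A tibble of class `pb_benchmark`: one row per
#'   (method, comparison, rep, cutoff) with `n_called`, `tp`, `fp`, `fdr`
#'   (`fp / max(n_called, 1)`), `tpr` (`tp / truth size`) and the
#'   comparison's variability class.
#' @export
run_benchmark <- function(scenario = "scenario1",
                          methods = c("voom", "voomQWB", "voomByGroup"),
                          reps = 10, cutoffs = c(0.01, 0.05, 0.10),
                          seed = 1L, min_total = 30) {
  methods <- match.arg(methods, c("voom", "voomQWB", "voomByGroup"),
                       several.ok = TRUE)
  stopifnot(reps >= 1)
  rows <- list()
  failed <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(benchmark_rep(scenario, methods, r, cutoffs, seed,
                                  min_total),
                    error = function(e) {
                      warning("replicate ", r, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) failed <- failed + 1L else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all replicates failed")
  out <- dplyr::bind_rows(rows)
  attr(out, "failed_reps") <- failed
  class(out) <- c("pb_benchmark", class(out))
  out
}

rep_seed <- function(seed, r) as.integer((seed %% 200000L) * 10000L + r)

benchmark_rep <- function(scenario, methods, r, cutoffs, seed, min_total) {
  cfg <- if (inherits(scenario, "sim_config")) scenario
         else if (file.exists(scenario)) read_sim_config(scenario)
         else scenario_preset(scenario, seed = 1L)
  cfg$seed <- rep_seed(seed, r)
  sim <- simulate_pseudobulk(cfg)
  pb <- tmm_norm_factors(filter_genes(sim$pb, min_total = min_total))
  X <- design_matrix(pb, ~ 0 + group)
  groups <- unique(pb$samples$group)
  level <- attr(cfg, "var_level")
  if (is.null(level)) level <- stats::setNames(rep("Equal", length(groups)),
                                               groups)
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  fits <- list()
  for (m in methods) {
    fits[[m]] <- switch(m,
      voom = voom_weights(pb, X),
      voomQWB = voom_qwb(pb, X, group = pb$samples$group),
      voomByGroup = voom_by_group(pb, X, group = pb$samples$group,
                                  compute_bcv = FALSE))
  }
  out <- list()
  for (m in methods) {
    for (pr in pairs) {
      tab <- de_test(fits[[m]], paste0(pr[1], "-", pr[2]))
      truth <- union(sim$truth$de_genes[[pr[1]]],
                     sim$truth$de_genes[[pr[2]]])
      cls <- paste(sort(c(level[[pr[1]]], level[[pr[2]]])), collapse = " vs ")
      for (q in cutoffs) {
        called <- decide_de(tab, q)
        tp <- length(intersect(called, truth))
        fp <- length(called) - tp
        out[[length(out) + 1]] <- tibble::tibble(
          method = m, comparison = paste0(pr[1], "-", pr[2]),
          class = cls, rep = r, cutoff = q,
          n_called = length(called), tp = tp, fp = fp,
          fdr = fp / max(length(called), 1L),
          tpr = tp / length(truth))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize benchmark results
#'
#' Replicate means of FDR and TPR per (method, comparison, cutoff), with
#' Monte-Carlo standard errors and the comparison's variability class.
#'
#' @param results A `pb_benchmark` tibble from [run_benchmark()].
#' @return A tibble with `mean_fdr`, `se_fdr`, `mean_tpr`, `se_tpr`,
#'   `n_reps`.
#' @export
summarize_benchmark <- function(results) {
  stopifnot(nrow(results) > 0)
  dplyr::summarise(
    dplyr::group_by(results, .data$method, .data$comparison, .data$class,
                    .data$cutoff),
    mean_fdr = mean(.data$fdr),
    se_fdr = stats::sd(.data$fdr) / sqrt(dplyr::n()),
    mean_tpr = mean(.data$tpr),
    se_tpr = stats::sd(.data$tpr) / sqrt(dplyr::n()),
    n_reps = dplyr::n(),
    .groups = "drop")
}

#' Write benchmark outputs
#'
#' Tidy per-replicate results as TSV and the replicate-mean summary as JSON.
#'
#' @param results A `pb_benchmark` tibble.
#' @param prefix Output path prefix (writes `<prefix>_results.tsv`,
#'   `<prefix>_summary.json`).
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(results, prefix) {
  tsv <- paste0(prefix, "_results.tsv")
  js <- paste0(prefix, "_summary.json")
  utils::write.table(as.data.frame(results), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(summarize_benchmark(results), js, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(c(tsv, js))
}
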