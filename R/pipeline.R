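# End-to-end orchestration: threshold sweeps of graph metrics, the
# model-comparison sweep (with optional quantile subsampling), CCDF export
# for distribution plots, and the full report bundle.

#' Threshold sweep of whole-network metrics
#'
#' Computes every graph summary for each matrix at each threshold, then
#' aggregates per threshold across the collection (per-dataset-first: each
#' matrix is summarised on its own, then the across-matrix mean and
#' standard deviation are taken). The per-threshold mean cost is
#' additionally normalised by its maximum over the sweep
#' (`Cost -> Cost/Max(Cost)`), and `efficiency_per_cost` is the mean
#' efficiency divided by that sweep-normalised cost. `delta_transitivity`
#' is the forward difference `C(i) - C(i+1)` of the mean transitivity along
#' the threshold grid (`NA` at the last threshold).
#'
#' @param collection List of connectivity matrices.
#' @param thresholds Ascending thresholds in \[0, 1\]; default
#'   `seq(0, 0.9, by = 0.1)`.
#' @return Data frame with one row per threshold: means and standard
#'   deviations of the per-matrix metrics, plus the sweep-normalised cost
#'   and efficiency per cost.
#' @export
metric_sweep <- function(collection, thresholds = seq(0, 0.9, by = 0.1)) {
  check_collection(collection)
  check_thresholds(thresholds)
  ids <- collection_ids(collection)
  rows <- lapply(seq_along(collection), function(i) {
    w <- as_connectivity(collection[[i]])
    do.call(rbind, lapply(thresholds, function(rc) graph_summary(w, rc, ids[i])))
  })
  per_matrix <- do.call(rbind, rows)
  agg <- function(col, f) {
    vapply(thresholds, function(rc) f(per_matrix[[col]][per_matrix$r_c == rc]), numeric(1))
  }
  out <- data.frame(
    r_c = thresholds,
    connection_ratio = agg("connection_ratio", mean),
    connection_ratio_sd = agg("connection_ratio", stats::sd),
    mean_strength = agg("mean_strength", mean),
    mean_strength_sd = agg("mean_strength", stats::sd),
    largest_component_fraction = agg("largest_component_fraction", mean),
    largest_component_fraction_sd = agg("largest_component_fraction", stats::sd),
    transitivity = agg("transitivity", mean),
    transitivity_sd = agg("transitivity", stats::sd),
    avg_path_length = agg("avg_path_length", mean),
    avg_path_length_sd = agg("avg_path_length", stats::sd),
    efficiency = agg("efficiency", mean),
    efficiency_sd = agg("efficiency", stats::sd),
    cost = agg("cost", mean)
  )
  out$delta_transitivity <- c(out$transitivity[-nrow(out)] -
                                out$transitivity[-1], NA_real_)
  max_cost <- max(out$cost)
  out$normalized_cost <- if (max_cost > 0) out$cost / max_cost else 0
  out$efficiency_per_cost <- ifelse(out$normalized_cost > 0,
                                    out$efficiency / out$normalized_cost, NaN)
  out
}

check_collection <- function(collection) {
  if (!is.list(collection) || length(collection) == 0) {
    rpl_stop("rplnet_param_error", "`collection` must be a nonempty list of matrices")
  }
  invisible(collection)
}

check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) == 0 ||
      any(thresholds < 0 | thresholds > 1) || is.unsorted(thresholds)) {
    rpl_stop("rplnet_param_error",
             "`thresholds` must be an ascending numeric vector within [0, 1]")
  }
  invisible(thresholds)
}

collection_ids <- function(collection) {
  if (!is.null(names(collection)) && all(nzchar(names(collection)))) {
    names(collection)
  } else {
    paste0("m", seq_along(collection))
  }
}

#' Model-comparison sweep across thresholds
#'
#' For each threshold: computes the chosen node statistic (degree or
#' strength) for each matrix, drops zero values, optionally quantile-
#' subsamples to `subsample_n` points, fits the three candidate models and
#' selects by AICc, then summarises selection ratios and mean-AICc
#' differences across the collection. Matrices yielding fewer than 5
#' positive values at a threshold are skipped and counted in `n_skipped`.
#'
#' @param collection List of connectivity matrices.
#' @param thresholds Ascending thresholds; default `seq(0.2, 0.7, by = 0.1)`.
#' @param stat_kind `"degree"` or `"strength"`.
#' @param subsample_n Optional quantile-subsample size applied before
#'   fitting (only when the prepared sample is at least that large).
#' @return Data frame with one row per threshold and model (columns of
#'   [summarize_selection()] plus `stat_kind`, `n_skipped`).
#' @export
comparison_sweep <- function(collection, thresholds = seq(0.2, 0.7, by = 0.1),
                             stat_kind = c("degree", "strength"),
                             subsample_n = NULL) {
  check_collection(collection)
  check_thresholds(thresholds)
  stat_kind <- match.arg(stat_kind)
  mats <- lapply(collection, as_connectivity)
  out <- lapply(thresholds, function(rc) {
    results <- list()
    skipped <- 0L
    for (w in mats) {
      stats_i <- if (stat_kind == "degree") {
        node_degree(binarize(w, rc))
      } else {
        node_strength(w, rc)
      }
      prep <- tryCatch(prepare_fit_data(stats_i),
                       rplnet_insufficient_data_error = function(e) NULL)
      if (is.null(prep)) {
        skipped <- skipped + 1L
        next
      }
      vals <- prep$values
      if (!is.null(subsample_n) && subsample_n <= length(vals)) {
        vals <- subsample(vals, subsample_n)$values
      }
      # flat-likelihood notes are kept on the fit objects; the per-fit
      # warning would flood a sweep, so it is muffled here
      cmp <- withCallingHandlers(
        tryCatch(compare_models(vals), error = function(e) NULL),
        rplnet_flat_likelihood_warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(cmp)) {
        skipped <- skipped + 1L
        next
      }
      results[[length(results) + 1L]] <- cmp
    }
    if (length(results) == 0) {
      message(sprintf("comparison_sweep: all %d matrices skipped at r_c = %g",
                      length(mats), rc))
      return(NULL)
    }
    if (skipped > 0) {
      message(sprintf("comparison_sweep: skipped %d of %d matrices at r_c = %g (too few positive values)",
                      skipped, length(mats), rc))
    }
    summ <- summarize_selection(results, rc)
    summ$stat_kind <- stat_kind
    summ$n_skipped <- skipped
    summ
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    rpl_stop("rplnet_fit_error", "no threshold yielded enough data to fit")
  }
  do.call(rbind, out)
}

#' Empirical complementary cumulative distribution table
#'
#' For each sorted sample value `x`, the fraction of values `>= x` -- the
#' form plotted on log-log axes against the node statistic. The largest of
#' `N` distinct values has CCDF `1/N`.
#'
#' @param values Numeric sample.
#' @return Data frame with columns `value` (ascending) and `ccdf`.
#' @export
ccdf_table <- function(values) {
  if (!is.numeric(values) || length(values) == 0) {
    rpl_stop("rplnet_param_error", "`values` must be a nonempty numeric sample")
  }
  s <- sort(values)
  data.frame(value = s, ccdf = vapply(s, function(v) mean(values >= v), numeric(1)))
}

#' Run the full analysis and write a report bundle
#'
#' Generates (or accepts) a matrix collection, runs the metric sweep and
#' the model-comparison sweep (degree and strength, with optional
#' subsampled variants), exports CCDF tables of the strength sample of the
#' first matrix at each comparison threshold, fits the restricted and
#' truncated models to that matrix at the middle comparison threshold and
#' simulates mean-strength stability, and writes everything plus a run
#' manifest under `out_dir`.
#'
#' @param config A [synthetic_config()] describing the collection, or a
#'   list of connectivity matrices.
#' @param out_dir Output directory (created if needed).
#' @param metric_thresholds,comparison_thresholds Threshold grids.
#' @param subsample_sizes Optional vector of subsample sizes for the
#'   comparison sweep variants.
#' @param n_replicates Replicates for the stability simulation.
#' @return (Invisibly) a list with the in-memory tables and the paths
#'   written: `metrics.csv`, `comparison.csv`, `comparison.json`,
#'   `ccdf.csv`, `simulation.json`, `manifest.json`.
#' @export
run_full_analysis <- function(config = synthetic_config(),
                              out_dir = tempfile("rplnet_run_"),
                              metric_thresholds = seq(0, 0.9, by = 0.1),
                              comparison_thresholds = seq(0.2, 0.7, by = 0.1),
                              subsample_sizes = NULL,
                              n_replicates = 200) {
  if (inherits(config, "synthetic_config")) {
    collection <- generate_collection(config)
    seed <- config$seed
    config_desc <- unclass(config)
  } else if (is.list(config)) {
    collection <- config
    seed <- NA_integer_
    config_desc <- list(input = "user-supplied collection",
                        n_matrices = length(config))
  } else {
    rpl_stop("rplnet_config_error",
             "`config` must be a synthetic_config or a list of matrices")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  metrics <- metric_sweep(collection, metric_thresholds)
  comparisons <- list(
    comparison_sweep(collection, comparison_thresholds, "degree"),
    comparison_sweep(collection, comparison_thresholds, "strength")
  )
  comparisons[[1]]$subsample_n <- NA_integer_
  comparisons[[2]]$subsample_n <- NA_integer_
  for (ns in subsample_sizes) {
    cs <- comparison_sweep(collection, comparison_thresholds, "strength",
                           subsample_n = ns)
    cs$subsample_n <- as.integer(ns)
    comparisons[[length(comparisons) + 1L]] <- cs
  }
  comparison <- do.call(rbind, comparisons)

  w1 <- as_connectivity(collection[[1]])
  ccdf <- do.call(rbind, lapply(comparison_thresholds, function(rc) {
    s <- node_strength(w1, rc)$values
    s <- s[s > 0]
    if (length(s) == 0) return(NULL)
    tab <- ccdf_table(s)
    tab$r_c <- rc
    tab$matrix_id <- collection_ids(collection)[1]
    tab
  }))

  mid_rc <- comparison_thresholds[ceiling(length(comparison_thresholds) / 2)]
  sim_report <- tryCatch({
    prep <- prepare_fit_data(node_strength(w1, mid_rc))
    ref_mean <- mean(vapply(collection, function(w) {
      mean(node_strength(as_connectivity(w), mid_rc)$values)
    }, numeric(1)))
    sims <- lapply(c("restricted", "truncated"), function(id) {
      fit <- if (id == "restricted") fit_restricted(prep) else fit_truncated(prep)
      sim <- simulate_strength_means(id, fit$params, n_nodes = nrow(w1),
                                     n_replicates = n_replicates,
                                     seed = derive_seed(if (is.na(seed)) 0 else seed, 99))
      list(model = id, params = fit$params, n_nodes = sim$n_nodes,
           n_replicates = sim$n_replicates, mean_of_means = sim$mean_of_means,
           delta_mean = delta_mean_strength(sim, ref_mean))
    })
    list(r_c = mid_rc, reference_mean = ref_mean, simulations = sims)
  }, error = function(e) list(error = conditionMessage(e)))

  paths <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    comparison_csv = file.path(out_dir, "comparison.csv"),
    comparison_json = file.path(out_dir, "comparison.json"),
    ccdf = file.path(out_dir, "ccdf.csv"),
    simulation = file.path(out_dir, "simulation.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(comparison, paths$comparison_csv, row.names = FALSE)
  jsonlite::write_json(comparison, paths$comparison_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(ccdf, paths$ccdf, row.names = FALSE)
  jsonlite::write_json(sim_report, paths$simulation, auto_unbox = TRUE, digits = NA)

  config_json <- jsonlite::toJSON(config_desc, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "rplnet",
    version = as.character(utils::packageVersion("rplnet")),
    seed = seed,
    config = config_desc,
    config_checksum = sum(utf8ToInt(as.character(config_json))),
    n_matrices = length(collection),
    metric_thresholds = metric_thresholds,
    comparison_thresholds = comparison_thresholds,
    subsample_sizes = subsample_sizes
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, comparison = comparison, ccdf = ccdf,
                 simulation = sim_report, paths = paths, out_dir = out_dir))
}
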