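# Inverse-CDF simulation of node-strength collections under a fitted model
# and the mean-strength stability comparison.
#
# The mean node strength is a proxy for the (weighted) network cost, so the
# difference between the simulated and observed mean strength measures how
# stably a fitted distribution model predicts the cost. The bounded support
# of the restricted power law suppresses tail divergence; the truncated
# power law has no hard upper limit and can overshoot.

#' Simulate replicate mean node strengths under a fitted model
#'
#' Each replicate draws `n_nodes` strength values by inverse-CDF sampling
#' from the given model (a uniform sequence mapped through the model's
#' inverse cumulative distribution) and records the replicate mean;
#' repeating mimics re-simulating each dataset of a collection.
#'
#' @param model_id One of `"restricted"`, `"truncated"`, `"powerlaw"`.
#' @param params Named parameter list for the model (see [sample_model()]).
#' @param n_nodes Values drawn per replicate (the network's node count).
#' @param n_replicates Number of replicates; the study-scale analogue is
#'   one per dataset in the collection.
#' @param seed Optional integer seed for reproducibility.
#' @return A `strength_simulation`: list with `model_id`, `params`,
#'   `n_nodes`, `n_replicates`, `replicate_means`, and `mean_of_means`.
#' @examples
#' sim <- simulate_strength_means("restricted",
#'   list(gamma = 2.22, x_min = 0.546, x_max = 33.5), 177, 50, seed = 1)
#' sim$mean_of_means
#' @export
simulate_strength_means <- function(model_id, params, n_nodes,
                                    n_replicates = 200, seed = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 1) {
    rpl_stop("rplnet_param_error", "`n_nodes` must be a positive count")
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 1) {
    rpl_stop("rplnet_param_error", "`n_replicates` must be a positive count")
  }
  means <- with_seed(seed, {
    vapply(seq_len(n_replicates),
           function(i) mean(sample_model(model_id, params, n_nodes)),
           numeric(1))
  })
  structure(list(model_id = model_id, params = params,
                 n_nodes = as.integer(n_nodes),
                 n_replicates = as.integer(n_replicates),
                 replicate_means = means,
                 mean_of_means = mean(means)),
            class = "strength_simulation")
}

#' @export
print.strength_simulation <- function(x, ...) {
  cat(sprintf("strength_simulation [%s]: %d replicates x %d nodes, <s> = %.4f\n",
              x$model_id, x$n_replicates, x$n_nodes, x$mean_of_means))
  invisible(x)
}

#' Mean-strength difference from a reference
#'
#' `delta <s> = <s>_simulation - <s>_reference`: the simulated
#' mean-of-means minus an observed (or analytic) reference mean. Values
#' near zero indicate the fitted model predicts the network's mean strength
#' -- and hence its cost -- stably.
#'
#' @param result A `strength_simulation` from [simulate_strength_means()].
#' @param reference_mean Finite reference mean (e.g. the observed
#'   per-matrix-then-across-matrix mean strength).
#' @return The signed difference.
#' @export
delta_mean_strength <- function(result, reference_mean) {
  if (!inherits(result, "strength_simulation")) {
    rpl_stop("rplnet_param_error", "`result` must come from simulate_strength_means()")
  }
  check_scalar_number(reference_mean, "reference_mean")
  result$mean_of_means - reference_mean
}
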