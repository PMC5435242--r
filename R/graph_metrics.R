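# Thresholded graph construction and whole-network summaries.
#
# A connectivity matrix holds correlation weights w_ij in [-1, 1]; the
# topological (binary) network at threshold r_c keeps an edge wherever
# |w_ij| > r_c (strict). All summaries exclude the diagonal.

#' Validate and normalise a connectivity matrix
#'
#' Checks that `w` is a square numeric matrix with `|w_ij| <= 1`, symmetric
#' within `tol`; symmetrises by averaging `(w_ij + w_ji)/2` and zeroes the
#' diagonal. Validation happens once at ingestion so the per-threshold
#' operations can assume a clean matrix.
#'
#' @param w Square numeric matrix of connection weights.
#' @param tol Symmetry tolerance (maximum allowed `|w_ij - w_ji|`).
#' @return The validated matrix (numeric, symmetric, zero diagonal).
#' @export
as_connectivity <- function(w, tol = 1e-9) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w)) {
    rpl_stop("rplnet_validation_error", "connectivity must be a square numeric matrix")
  }
  if (any(!is.finite(w))) {
    rpl_stop("rplnet_validation_error", "connectivity contains non-finite entries")
  }
  if (max(abs(w)) > 1 + 1e-12) {
    rpl_stop("rplnet_validation_error",
             "connectivity weights must lie in [-1, 1] (max |w| = %g)", max(abs(w)))
  }
  if (max(abs(w - t(w))) > tol) {
    rpl_stop("rplnet_validation_error",
             "connectivity matrix is not symmetric (max asymmetry %g > %g)",
             max(abs(w - t(w))), tol)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

#' Binarise a connectivity matrix at a threshold
#'
#' Builds the topological network: `a_ij = 1` iff `i != j` and
#' `|w_ij| > r_c` (strict inequality; ties at exactly `r_c` are excluded).
#' The absolute value means strong negative correlations also count as
#' connections.
#'
#' @param w Connectivity matrix (validated via [as_connectivity()]).
#' @param r_c Threshold in \[0, 1\].
#' @return A `binary_network`: list with integer `adjacency`, `threshold`,
#'   and node count `n`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- -0.5
#' sum(binarize(w, 0.4)$adjacency) / 2  # 1 edge: |-0.5| > 0.4
#' @export
binarize <- function(w, r_c) {
  check_scalar_number(r_c, "r_c")
  if (r_c < 0 || r_c > 1) {
    rpl_stop("rplnet_param_error", "`r_c` must lie in [0, 1]")
  }
  w <- as_connectivity(w)
  a <- (abs(w) > r_c) * 1L
  diag(a) <- 0L
  structure(list(adjacency = a, threshold = r_c, n = nrow(a)),
            class = "binary_network")
}

as_binary_network <- function(net) {
  if (!inherits(net, "binary_network")) {
    rpl_stop("rplnet_validation_error", "expected a `binary_network` (see binarize())")
  }
  net
}

net_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected", diag = FALSE)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges, threshold r_c = %g\n",
              x$n, sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}

new_node_stats <- function(values, stat_kind, threshold) {
  structure(list(values = values, stat_kind = stat_kind, threshold = threshold),
            class = "node_stats")
}

#' @export
print.node_stats <- function(x, ...) {
  cat(sprintf("node_stats: %s at r_c = %g (N = %d, %d positive)\n",
              x$stat_kind, x$threshold, length(x$values), sum(x$values > 0)))
  invisible(x)
}

#' Node degree of a binary network
#'
#' `k_i` counts the supra-threshold connections of node `i` (the row sum of
#' the adjacency matrix).
#'
#' @param net A `binary_network` from [binarize()].
#' @return A `node_stats` object with integer values in `[0, n - 1]`.
#' @export
node_degree <- function(net) {
  net <- as_binary_network(net)
  new_node_stats(rowSums(net$adjacency), "degree", net$threshold)
}

#' Node strength of a thresholded connectivity matrix
#'
#' `s_i` sums `|w_ij|` over the neighbours `j` that pass the same
#' supra-threshold condition `|w_ij| > r_c`; it is the weighted analogue of
#' the degree, so `s_i >= r_c * k_i` always.
#'
#' @inheritParams binarize
#' @return A `node_stats` object with nonnegative values.
#' @export
node_strength <- function(w, r_c) {
  check_scalar_number(r_c, "r_c")
  if (r_c < 0 || r_c > 1) rpl_stop("rplnet_param_error", "`r_c` must lie in [0, 1]")
  w <- as_connectivity(w)
  aw <- abs(w)
  new_node_stats(rowSums(aw * (aw > r_c)), "strength", r_c)
}

#' Connection ratio at a threshold
#'
#' Fraction of unordered off-diagonal node pairs with `|w_ij| > r_c`;
#' equivalent to the edge count normalised by `N(N-1)/2` and proportional to
#' the average degree. Non-increasing in `r_c`.
#'
#' @inheritParams binarize
#' @return A fraction in \[0, 1\].
#' @export
connection_ratio <- function(w, r_c) {
  w <- as_connectivity(w)
  check_scalar_number(r_c, "r_c")
  n <- nrow(w)
  mean(abs(w[upper.tri(w)]) > r_c)
}

#' Largest connected component fraction
#'
#' Size of the largest connected component divided by the node count. The
#' value 1 marks a fully connected network; an empty network on `n` nodes
#' gives `1/n` (each isolated node is a component of size 1). The drop of
#' this fraction along a threshold sweep locates the connected-to-fragmented
#' transition.
#'
#' @param net A `binary_network`.
#' @return A fraction in `(0, 1]`.
#' @export
largest_component_fraction <- function(net) {
  net <- as_binary_network(net)
  comp <- igraph::components(net_igraph(net))
  max(comp$csize) / net$n
}

#' Global transitivity (clustering coefficient)
#'
#' `C = 3 * triangles / connected triples`: the probability that two
#' neighbours of a node are themselves connected. Returns 0 when the network
#' has no connected triples.
#'
#' @param net A `binary_network`.
#' @return `C` in \[0, 1\].
#' @export
net_transitivity <- function(net) {
  net <- as_binary_network(net)
  val <- igraph::transitivity(net_igraph(net), type = "global")
  if (is.nan(val)) 0 else val
}

path_length_matrix <- function(net) {
  d <- igraph::distances(net_igraph(net))
  d[!is.finite(d)] <- net$n
  d
}

#' Characteristic (average minimum) path length
#'
#' Mean shortest-path hop count `L_ij` over all ordered node pairs
#' `i != j`. Unreachable pairs are substituted by `L_ij = n`, the total
#' number of nodes, so fragmentation inflates the average instead of being
#' dropped.
#'
#' @param net A `binary_network` with at least 2 nodes.
#' @return Mean path length `>= 1` (dimensionless hops).
#' @export
avg_path_length <- function(net) {
  net <- as_binary_network(net)
  if (net$n < 2) rpl_stop("rplnet_param_error", "path length needs at least 2 nodes")
  d <- path_length_matrix(net)
  sum(d) / (net$n * (net$n - 1))
}

#' Global network efficiency
#'
#' `E = mean over ordered pairs of 1/L_ij`, a proxy for parallel
#' information-transfer capacity. By default unreachable pairs contribute
#' `1/L = 0` (the standard global-efficiency convention);
#' `unreachable = "substitute"` instead applies the same `L_ij = n`
#' substitution used for the characteristic path length.
#'
#' @param net A `binary_network` with at least 2 nodes.
#' @param unreachable `"zero"` (default) or `"substitute"`.
#' @return `E` in \[0, 1\].
#' @export
global_efficiency <- function(net, unreachable = c("zero", "substitute")) {
  net <- as_binary_network(net)
  unreachable <- match.arg(unreachable)
  if (net$n < 2) rpl_stop("rplnet_param_error", "efficiency needs at least 2 nodes")
  d <- igraph::distances(net_igraph(net))
  inv <- 1 / d
  inv[!is.finite(d)] <- if (unreachable == "zero") 0 else 1 / net$n
  diag(inv) <- 0
  sum(inv) / (net$n * (net$n - 1))
}

#' Network cost (edge count)
#'
#' `Cost = sum(a_ij)/2`, the total number of connections -- a simple proxy
#' for the metabolic/wiring expense of the network. The per-network
#' normalised cost divides by the maximum possible `n(n-1)/2`; threshold
#' sweeps additionally normalise the per-threshold mean cost by its maximum
#' over the sweep (see [metric_sweep()]).
#'
#' @param net A `binary_network`.
#' @return List with integer `cost` and `normalized_cost` in \[0, 1\].
#' @export
network_cost <- function(net) {
  net <- as_binary_network(net)
  cost <- sum(net$adjacency) / 2
  list(cost = cost, normalized_cost = cost / (net$n * (net$n - 1) / 2))
}

#' Efficiency per unit cost
#'
#' The cost-effectiveness measure `E / Cost` (with the normalised cost).
#' Along a threshold sweep this trades off communication efficiency against
#' wiring expense; its interior maximum marks the threshold where the two
#' balance. Returns `NaN` with a warning when the network has no edges.
#'
#' @param summary A list (or one-row data frame) with fields `efficiency`
#'   and `normalized_cost`, e.g. from [graph_summary()].
#' @return Nonnegative real, or `NaN` for an empty network.
#' @export
efficiency_per_cost <- function(summary) {
  e <- summary$efficiency
  nc <- summary$normalized_cost
  if (is.null(e) || is.null(nc)) {
    rpl_stop("rplnet_param_error",
             "summary must contain `efficiency` and `normalized_cost`")
  }
  if (nc == 0) {
    rpl_warn("rplnet_zero_cost_warning",
             "normalized cost is 0 (empty network); efficiency per cost undefined")
    return(NaN)
  }
  e / nc
}

#' All whole-network summaries at one threshold
#'
#' Convenience wrapper computing every summary statistic for one matrix at
#' one threshold, as a one-row data frame ready for row-binding across a
#' sweep.
#'
#' @inheritParams binarize
#' @param matrix_id Optional identifier carried into the output.
#' @return One-row data frame with columns `matrix_id`, `r_c`,
#'   `connection_ratio`, `mean_strength`, `largest_component_fraction`,
#'   `transitivity`, `avg_path_length`, `efficiency`, `cost`,
#'   `normalized_cost`, `efficiency_per_cost`.
#' @export
graph_summary <- function(w, r_c, matrix_id = NA_character_) {
  w <- as_connectivity(w)
  net <- binarize(w, r_c)
  cost <- network_cost(net)
  eff <- global_efficiency(net)
  epc <- if (cost$cost == 0) NaN else eff / cost$normalized_cost
  data.frame(
    matrix_id = matrix_id,
    r_c = r_c,
    connection_ratio = connection_ratio(w, r_c),
    mean_strength = mean(node_strength(w, r_c)$values),
    largest_component_fraction = largest_component_fraction(net),
    transitivity = net_transitivity(net),
    avg_path_length = avg_path_length(net),
    efficiency = eff,
    cost = cost$cost,
    normalized_cost = cost$normalized_cost,
    efficiency_per_cost = epc,
    stringsAsFactors = FALSE
  )
}
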