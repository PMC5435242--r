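# Maximum-likelihood fitting of the three candidate models and AICc-based
# selection.
#
# All likelihood arithmetic is in log space (the raw likelihood product
# underflows already at N ~ 170). In every model x_min is plugged in from
# the data minimum and not counted as a free parameter, so K = 1 for the
# plain power law (alpha) and K = 2 for the truncated (alpha, x_c) and
# restricted (gamma, x_max) models.

fit_values <- function(x) {
  if (inherits(x, "prepared_sample")) return(x$values)
  if (inherits(x, "node_stats")) x <- x$values
  if (!is.numeric(x)) rpl_stop("rplnet_param_error", "sample must be numeric")
  x
}

#' Prepare a node-statistic sample for distribution fitting
#'
#' Drops zero values (unconnected nodes carry no information about the
#' supra-threshold connectivity distribution) and records the sample
#' minimum and maximum used downstream as plug-in support bounds.
#'
#' @param stats A `node_stats` object or numeric vector of nonnegative
#'   values.
#' @return A `prepared_sample`: list with `values`, `x_min`, `x_max`, `n`,
#'   and `n_removed`.
#' @export
prepare_fit_data <- function(stats) {
  x <- fit_values(stats)
  if (any(!is.finite(x)) || any(x < 0)) {
    rpl_stop("rplnet_param_error", "node statistics must be finite and nonnegative")
  }
  keep <- x > 0
  vals <- x[keep]
  if (length(vals) < 5) {
    rpl_stop("rplnet_insufficient_data_error",
             "need at least 5 positive values to fit (got %d)", length(vals))
  }
  structure(list(values = vals, x_min = min(vals), x_max = max(vals),
                 n = length(vals), n_removed = sum(!keep)),
            class = "prepared_sample")
}

#' Corrected Akaike information criterion
#'
#' \deqn{AICc = -2 \log L(\hat\theta) + 2K + \frac{2K(K+1)}{N-K-1},}
#' where the final term is the finite-sample correction; it vanishes as
#' `N` grows but matters at the modest sample sizes a single thresholded
#' network yields. Smaller is better.
#'
#' @param log_likelihood Maximised log-likelihood (natural log).
#' @param K Number of free parameters.
#' @param N Sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @examples
#' aicc(0, K = 2, N = 10)  # 4 + 12/7
#' @export
aicc <- function(log_likelihood, K, N) {
  check_scalar_number(log_likelihood, "log_likelihood")
  if (N <= K + 1) {
    rpl_stop("rplnet_aicc_error", "AICc needs N > K + 1 (got N = %d, K = %d)", N, K)
  }
  -2 * log_likelihood + 2 * K + 2 * K * (K + 1) / (N - K - 1)
}

new_model_fit <- function(model_id, params, log_lik, K, N, notes = character()) {
  structure(list(model_id = model_id, params = params,
                 log_likelihood = log_lik, K = K, N = N,
                 aicc = aicc(log_lik, K, N), notes = notes),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  pv <- paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("model_fit [%s]: %s; logL = %.3f, K = %d, N = %d, AICc = %.3f\n",
              x$model_id, pv, x$log_likelihood, x$K, x$N, x$aicc))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the plain power law by closed-form MLE
#'
#' With `x_min` plugged in as the sample minimum, the continuous MLE of the
#' exponent is \eqn{\hat\alpha = 1 + N / \sum_i \ln(x_i/x_{min})}.
#'
#' @param sample Positive numeric vector, `node_stats`, or
#'   [prepare_fit_data()] output.
#' @return A `model_fit` with `K = 1`.
#' @examples
#' fit_powerlaw(c(1, 2, 4))$params$alpha  # 1 + 1/log(2)
#' @export
fit_powerlaw <- function(sample) {
  x <- fit_values(sample)
  n <- length(x)
  if (n < 2) rpl_stop("rplnet_insufficient_data_error", "need at least 2 values")
  x_min <- min(x)
  slog <- sum(log(x / x_min))
  if (slog <= 0) {
    rpl_stop("rplnet_degenerate_error",
             "all sample values equal; power-law MLE diverges")
  }
  alpha <- 1 + n / slog
  ll <- n * log(alpha - 1) - n * log(x_min) - alpha * slog
  new_model_fit("powerlaw", list(alpha = alpha, x_min = x_min), ll, K = 1, N = n)
}

tpl_neg_loglik <- function(par, x, x_min, n, sum_log, sum_x) {
  alpha <- par[1]
  x_c <- exp(par[2])
  # infeasible corners probed by the optimizer return a large penalty
  lz <- suppressWarnings(
    tryCatch(tpl_log_norm(alpha, x_c, x_min), error = function(e) NA_real_))
  if (!is.finite(lz)) return(1e10)
  nll <- -((alpha - 1) * sum_log - sum_x / x_c - n * lz)
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit the exponentially truncated power law by numerical MLE
#'
#' Maximises the log-likelihood of the decaying truncated power law over
#' `(alpha, log x_c)` with bounded quasi-Newton (`L-BFGS-B`) from five
#' deterministic moment-based starting points, with `x_min` plugged in as
#' the sample minimum.
#'
#' @inheritParams fit_powerlaw
#' @return A `model_fit` with `K = 2`.
#' @export
fit_truncated <- function(sample) {
  x <- fit_values(sample)
  n <- length(x)
  if (n < 5) rpl_stop("rplnet_insufficient_data_error", "need at least 5 values")
  x_min <- min(x)
  sum_log <- sum(log(x))
  sum_x <- sum(x)
  m <- mean(x)
  v <- stats::var(x)
  xc0 <- max(v / m, m / 10, x_min / 10)
  a0 <- min(max(m^2 / max(v, 1e-12), -4), 800)
  lower <- c(-5, log(x_min) - 9)
  upper <- c(1000, log(max(x)) + 14)
  starts <- list(c(a0, log(xc0)),
                 c(a0 - 1, log(2 * xc0)),
                 c(a0 + 1, log(xc0 / 2)),
                 c(1, log(m)),
                 c(0.5, log(4 * xc0)))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    res <- tryCatch(
      stats::optim(s, tpl_neg_loglik, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   x = x, x_min = x_min, n = n, sum_log = sum_log, sum_x = sum_x),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    rpl_stop("rplnet_optim_error",
             "truncated power-law fit failed to converge (N = %d, range [%g, %g])",
             n, x_min, max(x))
  }
  notes <- character()
  if (best$par[2] >= upper[2] - 1e-6) {
    notes <- "x_c at upper bound: likelihood flat in the cut-off (power-law-like sample)"
  }
  new_model_fit("truncated",
                list(alpha = best$par[1], x_c = exp(best$par[2]), x_min = x_min),
                -best$value, K = 2, N = n, notes = notes)
}

rpl_neg_loglik <- function(par, x, x_min, n) {
  g <- par[1]
  xm <- par[2]
  if (xm <= max(x)) return(1e10)
  nll <- suppressWarnings(
    -(n * log1p(g) - n * (1 + g) * log(xm - x_min) + g * sum(log(xm - x))))
  if (!is.finite(nll)) 1e10 else nll
}

# moment-based initial gamma for a given trial x_max
rpl_gamma_init <- function(m, x_min, xm) {
  q <- (xm - m) / (xm - x_min)
  q <- min(max(q, 0.05), 0.95)
  (2 * q - 1) / (1 - q)
}

#' Fit the restricted (bounded) power law by numerical MLE
#'
#' Maximises the bounded-support power-law log-likelihood over
#' `(gamma, x_max)` subject to `x_max > max(sample)` (enforced through the
#' lower box bound `max(sample) * (1 + 1e-6)`) and the upper box bound
#' `100 * max(sample)`, with `x_min` plugged in as the sample minimum.
#' Optimisation is bounded quasi-Newton from five deterministic starting
#' points whose `gamma` values are moment-matched to each trial `x_max`.
#' Hitting the upper `x_max` bound is reported as a flat-likelihood note.
#'
#' @inheritParams fit_powerlaw
#' @return A `model_fit` with `K = 2`.
#' @export
fit_restricted <- function(sample) {
  x <- fit_values(sample)
  n <- length(x)
  if (n < 5) rpl_stop("rplnet_insufficient_data_error", "need at least 5 values")
  x_min <- min(x)
  mx <- max(x)
  if (mx == x_min) {
    rpl_stop("rplnet_degenerate_error", "all sample values equal; fit is degenerate")
  }
  m <- mean(x)
  lower <- c(-0.99, mx * (1 + 1e-6))
  upper <- c(50, 100 * mx)
  xm_starts <- mx * c(1.05, 1.01, 1.2, 1.5, 3)
  best <- NULL
  for (xm0 in xm_starts) {
    s <- c(rpl_gamma_init(m, x_min, xm0), xm0)
    s <- pmin(pmax(s, lower), upper)
    res <- tryCatch(
      stats::optim(s, rpl_neg_loglik, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   x = x, x_min = x_min, n = n),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    rpl_stop("rplnet_optim_error",
             "restricted power-law fit failed to converge (N = %d, range [%g, %g])",
             n, x_min, mx)
  }
  notes <- character()
  if (best$par[2] >= upper[2] * (1 - 1e-6)) {
    notes <- "x_max at upper bound: likelihood flat in the bound (unbounded-looking sample)"
    rpl_warn("rplnet_flat_likelihood_warning",
             "restricted fit hit the x_max search bound (%g); likelihood is flat in x_max",
             upper[2])
  }
  new_model_fit("restricted",
                list(gamma = best$par[1], x_min = x_min, x_max = best$par[2]),
                -best$value, K = 2, N = n, notes = notes)
}

#' Fit all three models and select by AICc
#'
#' Fits the plain power law, the truncated power law and the restricted
#' power law to the same sample and selects the model with the smallest
#' AICc. Exact ties are broken by smaller `K`, then by the fixed order
#' (powerlaw, truncated, restricted). A model whose fit errors is excluded
#' and the exclusion recorded in `errors`.
#'
#' @inheritParams fit_powerlaw
#' @return A `model_comparison`: list with `fits` (named list of
#'   `model_fit`), `best_model`, `delta_aic` (AICc minus the minimum, named
#'   per model), and `errors` (named list of failure messages).
#' @export
compare_models <- function(sample) {
  x <- fit_values(sample)
  fitters <- list(powerlaw = fit_powerlaw, truncated = fit_truncated,
                  restricted = fit_restricted)
  fits <- list()
  errors <- list()
  for (id in model_ids()) {
    res <- tryCatch(fitters[[id]](x), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      fits[[id]] <- res
    }
  }
  if (length(fits) == 0) {
    rpl_stop("rplnet_fit_error", "all three model fits failed: %s",
             paste(unlist(errors), collapse = " | "))
  }
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  # names(av) follow model_ids() order = ascending K then fixed order,
  # and which.min takes the first of exact ties, giving the tie-break.
  best <- names(av)[which.min(av)]
  structure(list(fits = fits, best_model = best, delta_aic = av - min(av),
                 errors = errors),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison: best =", x$best_model, "\n")
  for (f in x$fits) print(f)
  if (length(x$errors)) {
    cat("  excluded:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise model selection across a matrix collection
#'
#' For one threshold, computes each model's selection ratio (fraction of
#' datasets for which it attains the minimum AICc) and the mean-AICc
#' difference from the best mean (each model's AICc averaged across the
#' collection, minus the minimum of the three averages).
#'
#' @param results List of `model_comparison` objects, one per matrix.
#' @param r_c The threshold the results were computed at (carried into the
#'   output).
#' @return Data frame with one row per model: `r_c`, `model`, `n`,
#'   `n_selected`, `selection_ratio`, `mean_aicc`, `mean_delta_aic`.
#' @export
summarize_selection <- function(results, r_c = NA_real_) {
  if (!is.list(results) || length(results) == 0) {
    rpl_stop("rplnet_param_error", "`results` must be a nonempty list of model comparisons")
  }
  ids <- model_ids()
  best <- vapply(results, function(r) r$best_model, character(1))
  counts <- vapply(ids, function(id) sum(best == id), numeric(1))
  mean_aicc <- vapply(ids, function(id) {
    vals <- vapply(results, function(r) {
      if (!is.null(r$fits[[id]])) r$fits[[id]]$aicc else NA_real_
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  data.frame(
    r_c = r_c,
    model = ids,
    n = length(results),
    n_selected = counts,
    selection_ratio = counts / length(results),
    mean_aicc = mean_aicc,
    mean_delta_aic = mean_aicc - min(mean_aicc, na.rm = TRUE),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
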