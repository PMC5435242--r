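# MLE fitting and AICc selection.

test_that("prepare_fit_data filters zeros and guards small samples", {
  prep <- prepare_fit_data(c(0, 2, 1, 3, 0, 4, 5, 6))
  expect_equal(prep$n, 6)
  expect_equal(prep$n_removed, 2)
  expect_equal(prep$x_min, 1)
  expect_equal(prep$x_max, 6)
  expect_error(prepare_fit_data(c(0, 0, 3, 1)),
               class = "rplnet_insufficient_data_error")
  all_pos <- c(2, 4, 1, 7, 9)
  expect_equal(prepare_fit_data(all_pos)$values, all_pos)

  set.seed(5)
  x <- c(rep(0, 12), runif(88, 1, 5))
  expect_equal(prepare_fit_data(x)$n, 88)
})

test_that("aicc implements the corrected criterion", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-10, 1, 1000), 22 + 4 / 998)
  # correction vanishes with N
  expect_lt(aicc(0, 2, 1e6) - 4, 1e-4)
  expect_error(aicc(0, 2, 3), class = "rplnet_aicc_error")
  # decreasing in logL at fixed (K, N); increasing in K at fixed (logL, N)
  expect_lt(aicc(-5, 2, 50), aicc(-6, 2, 50))
  expect_lt(aicc(-5, 1, 50), aicc(-5, 2, 50))
})

test_that("power-law MLE has its closed form and matches a grid search", {
  fit <- fit_powerlaw(c(1, 2, 4))
  expect_equal(fit$params$alpha, 1 + 1 / log(2), tolerance = 1e-12)
  expect_equal(fit$K, 1)
  expect_error(fit_powerlaw(rep(2, 10)), class = "rplnet_degenerate_error")

  # estimator within 3 standard errors (alpha - 1)/sqrt(N)
  set.seed(23)
  x <- rplaw(5000, 2.5, 1)
  expect_lt(abs(fit_powerlaw(x)$params$alpha - 2.5), 0.06)

  # brute-force grid maximization of the log-likelihood over alpha
  set.seed(22)
  xs <- rplaw(200, 2.2, 1)
  grid <- seq(1.2, 4, by = 1e-4)
  ll <- vapply(grid, function(a) sum(dplaw(xs, a, min(xs), log = TRUE)), numeric(1))
  expect_equal(fit_powerlaw(xs)$params$alpha, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("truncated power-law MLE recovers generating parameters", {
  set.seed(31)
  x <- rtpl(5000, 2.17, 5.67, 0.5)
  fit <- fit_truncated(x)
  expect_lt(abs(fit$params$alpha - 2.17), 0.15)
  expect_lt(abs(fit$params$x_c - 5.67) / 5.67, 0.15)
  expect_equal(fit$K, 2)

  # optimum at least as good as random feasible points
  set.seed(32)
  xs <- rtpl(300, 2.17, 5.67, 0.5)
  fit2 <- fit_truncated(xs)
  for (i in 1:100) {
    a <- runif(1, -2, 8)
    xc <- exp(runif(1, log(0.1), log(50)))
    ll <- sum(dtpl(xs, a, xc, min(xs), log = TRUE))
    expect_lte(ll, fit2$log_likelihood + 1e-6)
  }

  # near-power-law sample pushes the cut-off beyond the sample maximum
  set.seed(33)
  xp <- rplaw(400, 2.5, 1)
  fit3 <- fit_truncated(xp)
  expect_gt(fit3$params$x_c, max(xp))
})

test_that("restricted power-law MLE recovers generating parameters", {
  set.seed(41)
  x <- rrpl(5000, 2.22, 0.546, 33.5)
  fit <- fit_restricted(x)
  expect_lt(abs(fit$params$gamma - 2.22), 0.15)
  expect_lt(abs(fit$params$x_max - 33.5) / 33.5, 0.05)

  # uniform data is the gamma = 0 special case
  set.seed(42)
  u <- runif(5000, 1, 5)
  expect_lt(abs(fit_restricted(u)$params$gamma), 0.1)

  # optimum at least as good as random feasible points
  set.seed(43)
  xs <- rrpl(300, 2.22, 0.546, 33.5)
  fit2 <- fit_restricted(xs)
  for (i in 1:100) {
    g <- runif(1, -0.9, 8)
    xm <- max(xs) * (1 + runif(1, 1e-5, 2))
    ll <- sum(drpl(xs, g, min(xs), xm, log = TRUE))
    expect_lte(ll, fit2$log_likelihood + 1e-6)
  }
  expect_error(fit_restricted(rep(3, 10)), class = "rplnet_degenerate_error")
})

test_that("model comparison selects by AICc with stable tie-breaking", {
  set.seed(51)
  cmp <- compare_models(rrpl(400, 2.22, 0.546, 33.5))
  expect_setequal(names(cmp$fits), c("powerlaw", "truncated", "restricted"))
  expect_equal(min(cmp$delta_aic), 0)
  expect_equal(unname(cmp$delta_aic[cmp$best_model]), 0)

  # a sample every model can fit: best is the smallest AICc
  aiccs <- vapply(cmp$fits, function(f) f$aicc, numeric(1))
  expect_equal(cmp$best_model, names(which.min(aiccs)))
})

test_that("the generating model wins the AICc contest (selection consistency)", {
  gens <- list(
    restricted = function() rrpl(150, 2.22, 0.546, 33.5),
    truncated = function() rtpl(150, 2.17, 5.67, 0.5),
    powerlaw = function() rplaw(150, 2.5, 1)
  )
  set.seed(61)
  for (gen_id in names(gens)) {
    best <- suppressWarnings(
      replicate(40, compare_models(gens[[gen_id]]())$best_model))
    counts <- table(factor(best, levels = names(gens)))
    expect_equal(names(which.max(counts)), gen_id)
  }
})

test_that("the generating model dominates rival likelihoods per point", {
  set.seed(62)
  hits <- suppressWarnings(replicate(50, {
    x <- rrpl(1000, 2.22, 0.546, 33.5)
    cmp <- compare_models(x)
    ll <- vapply(cmp$fits, function(f) f$log_likelihood, numeric(1))
    all(ll["restricted"] >= ll[c("powerlaw", "truncated")])
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("selection summaries aggregate ratios and mean AICc differences", {
  set.seed(71)
  results <- lapply(1:10, function(i) compare_models(rrpl(120, 2.22, 0.546, 33.5)))
  summ <- summarize_selection(results, r_c = 0.4)
  expect_equal(sum(summ$selection_ratio), 1)
  expect_equal(min(summ$mean_delta_aic), 0)
  expect_equal(summ$model, c("powerlaw", "truncated", "restricted"))

  # arithmetic on a constructed split: counts (858, 100, 28) of 986
  fake <- function(best) structure(list(best_model = best, fits = list()),
                                   class = "model_comparison")
  mix <- c(replicate(858, fake("restricted"), simplify = FALSE),
           replicate(100, fake("truncated"), simplify = FALSE),
           replicate(28, fake("powerlaw"), simplify = FALSE))
  s2 <- suppressWarnings(summarize_selection(mix, 0.4))
  expect_equal(s2$selection_ratio[s2$model == "restricted"], 858 / 986)
  expect_equal(s2$selection_ratio[s2$model == "truncated"], 100 / 986)
  expect_equal(s2$selection_ratio[s2$model == "powerlaw"], 28 / 986)
  expect_error(summarize_selection(list()), class = "rplnet_param_error")
})
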