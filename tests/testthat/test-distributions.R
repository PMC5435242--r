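# The three candidate distribution models: densities, CDFs, inverses,
# moments, samplers.

test_that("restricted power law density matches its closed form", {
  # gamma = 0 collapses to the uniform density
  expect_equal(drpl(c(0.2, 1.7), 0, 0, 2), c(0.5, 0.5))
  # direct evaluation at gamma = 1
  expect_equal(drpl(1, 1, 0, 2), 0.5)
  # zero at the upper bound for gamma > 0, zero outside support
  expect_equal(drpl(2, 1, 0, 2), 0)
  expect_equal(drpl(c(-1, 3), 1, 0, 2), c(0, 0))
  # integrates to 1 (quadrature oracle)
  q <- integrate(function(x) drpl(x, 2.22, 0.546, 33.5), 0.546, 33.5)
  expect_equal(q$value, 1, tolerance = 1e-8)
  expect_error(drpl(1, -1.5, 0, 2), class = "rplnet_param_error")
  expect_error(drpl(1, 1, 2, 1), class = "rplnet_param_error")
})

test_that("restricted CDF and inverse CDF are closed-form consistent", {
  expect_equal(prpl(0, 1, 0, 2), 0)
  expect_equal(prpl(2, 1, 0, 2), 1)
  # analytic integration oracle at gamma = 1: F(1) = 1 - (1/2)^2
  expect_equal(prpl(1, 1, 0, 2), 0.75)
  expect_equal(qrpl(0.75, 1, 0, 2), 1)
  # round trip on a grid
  x <- seq(0.6, 33, length.out = 41)
  expect_equal(qrpl(prpl(x, 2.22, 0.546, 33.5), 2.22, 0.546, 33.5), x,
               tolerance = 1e-10)
  expect_error(qrpl(1.2, 1, 0, 2), class = "rplnet_prob_error")
})

test_that("restricted mean has the stated closed form", {
  # uniform special case: midpoint
  expect_equal(rpl_mean(0, 1, 5), 3)
  # reported strength-fit parameter set, against quadrature
  m <- rpl_mean(2.22, 0.546, 33.5)
  mq <- integrate(function(x) x * drpl(x, 2.22, 0.546, 33.5), 0.546, 33.5,
                  rel.tol = 1e-10)$value
  expect_equal(m, mq, tolerance = 1e-8)
  expect_equal(m, 8.355, tolerance = 1e-3)
  # random parameter draws against quadrature
  set.seed(71)
  for (i in 1:10) {
    g <- runif(1, -0.8, 4)
    lo <- runif(1, 0, 2)
    hi <- lo + runif(1, 0.5, 30)
    mq <- integrate(function(x) x * drpl(x, g, lo, hi), lo, hi,
                    rel.tol = 1e-10)$value
    expect_equal(rpl_mean(g, lo, hi), mq, tolerance = 1e-8)
  }
})

test_that("truncated power law density normalizes and locates its mode", {
  # alpha = 1, x_min -> 0 limit: exponential with rate 1/x_c
  expect_equal(dtpl(1e-9, 1, 2, 1e-9), 0.5, tolerance = 1e-6)
  # normalization at the reported truncated-fit parameters
  q <- integrate(function(x) dtpl(x, 2.17, 5.67, 0.5), 0.5, Inf)
  expect_equal(q$value, 1, tolerance = 1e-8)
  # density decreasing beyond the mode (alpha - 1) * x_c for alpha > 1
  mode <- (2.17 - 1) * 5.67
  xs <- seq(mode, mode + 30, length.out = 50)
  expect_true(all(diff(dtpl(xs, 2.17, 5.67, 0.5)) < 0))
  # alpha <= 0 handled through the quadrature normalization
  q2 <- integrate(function(x) dtpl(x, -1.5, 5.67, 0.5), 0.5, Inf)
  expect_equal(q2$value, 1, tolerance = 1e-8)
  expect_error(dtpl(1, 2, -1, 0.5), class = "rplnet_param_error")
})

test_that("truncated CDF and numeric inverse agree", {
  p <- ptpl(c(0.5, 2, 10, 50), 2.17, 5.67, 0.5)
  expect_equal(p[1], 0)
  expect_true(all(diff(p) > 0))
  # quadrature oracle for the CDF
  pq <- integrate(function(x) dtpl(x, 2.17, 5.67, 0.5), 0.5, 10)$value
  expect_equal(p[3], pq, tolerance = 1e-8)
  # inverse round trip
  u <- c(0.05, 0.3, 0.5, 0.9, 0.99)
  expect_equal(ptpl(qtpl(u, 2.17, 5.67, 0.5), 2.17, 5.67, 0.5), u,
               tolerance = 1e-8)
  expect_equal(qtpl(0, 2.17, 5.67, 0.5), 0.5)
  expect_identical(qtpl(1, 2.17, 5.67, 0.5), Inf)
})

test_that("plain power law matches closed forms", {
  expect_equal(dplaw(1, 2.5, 1), 1.5)   # (alpha-1)/x_min at the boundary
  expect_equal(dplaw(2, 2, 1), 0.25)
  q <- integrate(function(x) dplaw(x, 2.5, 1), 1, Inf)
  expect_equal(q$value, 1, tolerance = 1e-8)
  u <- c(0.1, 0.5, 0.9)
  expect_equal(pplaw(qplaw(u, 2.5, 1), 2.5, 1), u, tolerance = 1e-12)
  expect_error(dplaw(1, 1, 1), class = "rplnet_param_error")
})

test_that("all densities integrate to 1 across a randomized parameter grid", {
  set.seed(402)
  for (i in 1:20) {
    g <- runif(1, -0.9, 5)
    lo <- runif(1, 0.05, 2)
    hi <- lo + runif(1, 0.5, 40)
    expect_equal(integrate(function(x) drpl(x, g, lo, hi), lo, hi,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    al <- runif(1, -2, 5)
    xc <- runif(1, 0.2, 20)
    xm <- runif(1, 0.05, 2)
    expect_equal(integrate(function(x) dtpl(x, al, xc, xm), xm, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    ap <- runif(1, 1.2, 4)
    expect_equal(integrate(function(x) dplaw(x, ap, xm), xm, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
})

test_that("limiting behaviour connects the three models", {
  # restricted with x_max -> Inf at fixed x - x_min flattens
  r <- drpl(1.5, 2.22, 0.5, 1e7) / drpl(0.5, 2.22, 0.5, 1e7)
  expect_equal(r, 1, tolerance = 1e-5)
  # truncated with x_c -> Inf tends pointwise to the pure x^(alpha-1) shape
  # on a compact window (renormalized via a density ratio)
  x0 <- 2
  xs <- c(1, 3, 6, 9)
  ratio <- dtpl(xs, -1.5, 1e8, 1) / dtpl(x0, -1.5, 1e8, 1)
  expect_equal(ratio, (xs / x0)^(-1.5 - 1), tolerance = 1e-5)
})

test_that("inverse-CDF samplers are deterministic under seed and match their CDFs", {
  s1 <- sample_model("restricted", ref_restricted, 100, seed = 7)
  s2 <- sample_model("restricted", ref_restricted, 100, seed = 7)
  expect_identical(s1, s2)
  expect_error(sample_model("cauchy", list(), 10), class = "rplnet_model_error")

  # uniform limit of the restricted sampler
  set.seed(11)
  u <- rrpl(1e5, 0, 1, 5)
  se <- sqrt(4^2 / 12 / 1e5)
  expect_lt(abs(mean(u) - 3), 3 * se)

  # Kolmogorov-Smirnov distance below the 1% critical value 1.63/sqrt(n)
  n <- 1e4
  crit <- 1.63 / sqrt(n)
  ks <- function(x, cdf) max(abs(cdf(sort(x)) - (seq_along(x) - 0.5) / length(x)))
  set.seed(12)
  expect_lt(ks(rrpl(n, 2.22, 0.546, 33.5),
               function(x) prpl(x, 2.22, 0.546, 33.5)), crit)
  expect_lt(ks(rplaw(n, 2.5, 1), function(x) pplaw(x, 2.5, 1)), crit)
  expect_lt(ks(rtpl(n, 2.17, 5.67, 0.5),
               function(x) ptpl(x, 2.17, 5.67, 0.5)), crit)
})
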